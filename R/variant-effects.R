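#' Translate codons with the standard genetic code
#'
#' Nuclear plant genes use the standard code (translation table 1); stops are
#' reported as `"*"`. Ambiguous or non-ACGT bases are an error, not expanded.
#'
#' @param codon Character vector of 3-base codons (case-insensitive).
#' @return Character vector of single-letter amino acids.
#' @export
#' @examples
#' translate_codon(c("TTT", "TGA", "ATG"))
translate_codon <- function(codon) {
  codon <- toupper(codon)
  bad <- !grepl("^[ACGT]{3}$", codon)
  if (any(bad)) {
    abort(sprintf("Invalid codon(s): %s (need exactly 3 of A/C/G/T).",
                  paste(unique(codon[bad]), collapse = ", ")))
  }
  unname(Biostrings::GENETIC_CODE[codon])
}

#' Classify the effect of a single-base codon change
#'
#' @param ref_codon,alt_codon Character vectors of codons differing at
#'   exactly one position (biallelic SNV assumption; anything else errors).
#' @return Character vector: `"synonymous"` (amino acid unchanged),
#'   `"nonsense"` (gain of stop), `"stop_loss"` (loss of stop), or
#'   `"missense"`.
#' @export
#' @examples
#' classify_effect(c("TTT", "CCT", "TGG"), c("TAT", "CCG", "TAG"))
classify_effect <- function(ref_codon, alt_codon) {
  ref_codon <- toupper(ref_codon)
  alt_codon <- toupper(alt_codon)
  ndiff <- mapply(function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }, ref_codon, alt_codon, USE.NAMES = FALSE)
  ref_aa <- translate_codon(ref_codon)
  alt_aa <- translate_codon(alt_codon)
  if (any(ndiff != 1L)) {
    abort(sprintf("Codon pair(s) differing at %s positions; expected exactly 1.",
                  paste(unique(ndiff[ndiff != 1L]), collapse = "/")))
  }
  dplyr::case_when(
    ref_aa == alt_aa ~ "synonymous",
    alt_aa == "*" ~ "nonsense",
    ref_aa == "*" ~ "stop_loss",
    TRUE ~ "missense"
  )
}

complement_base <- function(b) {
  chartr("ACGTacgt", "TGCAtgca", b)
}

# CDS sequence of one gene in transcription order, after concatenating the
# genomic-order segments (reverse-complemented for minus-strand genes).
gene_cds_seq <- function(gene, ref_seq) {
  chrom <- gene$chrom[1]
  segs <- mapply(function(s, e) substring(ref_seq[[chrom]], s, e),
                 gene$start, gene$end)
  cds <- paste(segs, collapse = "")
  if (gene$strand[1] == "-") {
    cds <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
  }
  cds
}

#' Map a SNP onto its codon and amino-acid change
#'
#' Locates a genomic SNP within a gene's CDS, extracts the reference and
#' alternate codons on the transcript strand (minus-strand genes are
#' reverse-complemented, with the alleles complemented accordingly), and
#' classifies the effect. Positions outside the CDS return a `"non_coding"`
#' row rather than an error; a mismatch between the supplied reference allele
#' and the reference sequence is an error.
#'
#' @param gene One gene model: the rows of a [read_gene_models()] tibble for
#'   a single `gene_id`.
#' @param ref_seq Reference from [read_fasta()].
#' @param pos Genomic position (1-based).
#' @param ref,alt Reference and alternate alleles on the genome strand.
#' @return A one-row tibble: `gene_id`, `pos`, `codon_number`, `codon_pos`,
#'   `ref_codon`, `alt_codon`, `ref_aa`, `alt_aa`, `effect`.
#' @export
snp_to_codon <- function(gene, ref_seq, pos, ref, alt) {
  stopifnot(nrow(gene) >= 1)
  gene <- dplyr::arrange(gene, .data$start)
  gid <- gene$gene_id[1]
  non_coding <- tibble(gene_id = gid, pos = pos, codon_number = NA_integer_,
                       codon_pos = NA_integer_, ref_codon = NA_character_,
                       alt_codon = NA_character_, ref_aa = NA_character_,
                       alt_aa = NA_character_, effect = "non_coding")
  seg <- which(gene$start <= pos & pos <= gene$end)
  if (length(seg) == 0L) return(non_coding)
  seg <- seg[1]

  genome_base <- ref_base(ref_seq, gene$chrom[1], pos)
  if (genome_base != toupper(ref)) {
    abort(sprintf("Reference mismatch at %s:%d: sequence has %s, record says %s.",
                  gene$chrom[1], pos, genome_base, ref))
  }

  widths <- gene$end - gene$start + 1
  genomic_offset <- sum(widths[seq_len(seg - 1)]) + (pos - gene$start[seg] + 1)
  total <- sum(widths)
  offset <- if (gene$strand[1] == "+") genomic_offset else total - genomic_offset + 1

  phase <- gene$phase[1]
  o <- offset - phase
  if (o < 1) return(non_coding)  # inside the incomplete leading codon
  codon_number <- (o - 1) %/% 3 + 1
  codon_pos <- (o - 1) %% 3 + 1

  cds <- substring(gene_cds_seq(gene, ref_seq), phase + 1)
  codon_start <- 3 * (codon_number - 1) + 1
  ref_codon <- substr(cds, codon_start, codon_start + 2)
  if (nchar(ref_codon) < 3) {
    warn(sprintf("SNP at %s:%d falls in an incomplete trailing codon.",
                 gene$chrom[1], pos))
    return(dplyr::mutate(non_coding, effect = "incomplete_codon"))
  }
  alt_tx <- if (gene$strand[1] == "-") complement_base(toupper(alt)) else toupper(alt)
  alt_codon <- ref_codon
  substr(alt_codon, codon_pos, codon_pos) <- alt_tx

  ref_aa <- translate_codon(ref_codon)
  alt_aa <- translate_codon(alt_codon)
  effect <- if (ref_codon == alt_codon) "synonymous" else classify_effect(ref_codon, alt_codon)
  tibble(gene_id = gid, pos = pos, codon_number = as.integer(codon_number),
         codon_pos = as.integer(codon_pos), ref_codon = ref_codon, alt_codon = alt_codon,
         ref_aa = ref_aa, alt_aa = alt_aa, effect = effect)
}

#' Annotate coding SNPs with codon-level effects
#'
#' Maps each variant onto every gene model whose CDS contains it and reports
#' the codon change and effect class. For a recessive mutant, candidate sites
#' are expected to be homozygous in the mutant bulk; `min_mut_index` (if
#' given) keeps only sites whose mutant-pool SNP-index is at least that value
#' before annotation.
#'
#' @param records Allele-depth tibble (`chrom, pos, ref, alt`, plus depth
#'   columns if `min_mut_index` is used).
#' @param gene_models Tibble from [read_gene_models()].
#' @param ref_seq Reference from [read_fasta()].
#' @param min_mut_index Optional homozygosity pre-filter on the mutant-pool
#'   SNP-index (e.g. 0.9); `NULL` disables it.
#' @return A tibble of codon changes, one row per (variant, overlapping
#'   gene), ordered by `chrom`, `pos`, `gene_id`; per-class counts are
#'   attached as attribute `effect_counts`.
#' @export
annotate_variants <- function(records, gene_models, ref_seq,
                              min_mut_index = NULL) {
  if (!is.null(min_mut_index)) {
    idx <- snp_index(records$mut_ref, records$mut_alt)
    records <- records[!is.na(idx) & idx >= min_mut_index, ]
  }
  if (nrow(records) == 0L || nrow(gene_models) == 0L) {
    out <- tibble(chrom = character(), pos = integer(), ref = character(),
                  alt = character(), gene_id = character(),
                  codon_number = integer(), codon_pos = integer(),
                  ref_codon = character(), alt_codon = character(),
                  ref_aa = character(), alt_aa = character(),
                  effect = character())
    attr(out, "effect_counts") <- tibble(effect = character(), n = integer())
    return(out)
  }
  genes <- split(gene_models, gene_models$gene_id)
  out <- purrr::map_dfr(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    hits <- purrr::keep(genes, function(g) {
      g$chrom[1] == r$chrom && any(g$start <= r$pos & r$pos <= g$end)
    })
    purrr::map_dfr(hits, function(g) {
      ann <- snp_to_codon(g, ref_seq, r$pos, r$ref, r$alt)
      dplyr::bind_cols(tibble(chrom = r$chrom, pos = r$pos, ref = r$ref,
                              alt = r$alt),
                       dplyr::select(ann, !"pos"))
    })
  })
  out <- dplyr::arrange(out, .data$chrom, .data$pos, .data$gene_id)
  attr(out, "effect_counts") <- dplyr::count(out, .data$effect)
  out
}

#' Genotype/phenotype co-segregation of a candidate SNP
#'
#' For a fully recessive causal SNP, every mutant plant is homozygous for the
#' mutant allele and no wildtype plant is. This reports the fraction of F2
#' plants whose phenotype matches that expectation at a marker — 1 for the
#' causal SNP, lower for linked but non-causal SNPs.
#'
#' @param population An `f2_population`.
#' @param chrom,pos Marker to test.
#' @return A one-row tibble: `chrom`, `pos`, `n`, `n_concordant`,
#'   `concordance`.
#' @export
cosegregation_rate <- function(population, chrom, pos) {
  stopifnot(inherits(population, "f2_population"))
  i <- which(population$markers$chrom == chrom & population$markers$pos == pos)
  if (length(i) != 1L) abort(sprintf("Marker %s:%s not found.", chrom, pos))
  expected_mutant <- population$genotypes[, i] == 2L
  ok <- expected_mutant == (population$phenotype == "mutant")
  tibble(chrom = chrom, pos = pos, n = length(ok), n_concordant = sum(ok),
         concordance = mean(ok))
}

#' Bundled candidate-SNP codon table
#'
#' The 36 homozygous candidate SNPs of the yellow-green-leaf mapping interval
#' (a tandem lipoxygenase cluster on cucumber chromosome 4), with their
#' genomic alleles and the published wild-type/mutant codon pairs on the
#' transcript strand. Useful as a worked input for [translate_codon()] and
#' [classify_effect()].
#'
#' @return A tibble with columns `pos`, `ref`, `alt`, `gene`, `codon_a`,
#'   `codon_b`, `aa_a`, `aa_b`, `annotation`.
#' @export
candidate_snp_table <- function() {
  path <- system.file("extdata", "table2_snps.tsv", package = "bsascan",
                      mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
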