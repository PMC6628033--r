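#' Read pooled allele-depth variant records
#'
#' Reads biallelic SNP records with per-pool reference/alternate read depths
#' from a VCF (per-sample `AD` field) or a plain TSV with columns
#' `chrom, pos, ref, alt, mut_ref, mut_alt, wt_ref, wt_alt`. Records are
#' returned sorted by chromosome then position. Multi-allelic VCF sites are
#' skipped with a reported count; a sample whose `AD` entry is missing at a
#' site yields `NA` depths for that pool (the scan decides what to do with
#' such sites).
#'
#' @param path Input file; gzip-compressed input is accepted.
#' @param format `"auto"` (by extension), `"vcf"` or `"tsv"`.
#' @param samples Length-2 character vector naming the mutant-bulk and
#'   wildtype-bulk samples in the VCF, in that order.
#' @param chrom_order Optional chromosome ordering used for sorting.
#' @return A tibble of allele-depth records. The number of skipped
#'   multi-allelic sites is attached as attribute `n_multiallelic`.
#' @export
read_variants <- function(path, format = c("auto", "vcf", "tsv"),
                          samples = c("mutant", "wildtype"),
                          chrom_order = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "tsv"
  }
  if (length(samples) != 2L) abort("`samples` must name exactly two pools.")
  rec <- if (format == "vcf") {
    read_variants_vcf(path, samples)
  } else {
    read_variants_tsv(path)
  }
  out <- arrange_sites(rec$records, chrom_order)
  attr(out, "n_multiallelic") <- rec$n_multiallelic
  out
}

read_variants_vcf <- function(path, samples) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  have <- colnames(v@gt)[-1]
  missing <- setdiff(samples, have)
  if (length(missing) > 0) {
    abort(sprintf("Sample(s) %s not present in %s (found: %s).",
                  paste(missing, collapse = ", "), path,
                  paste(have, collapse = ", ")))
  }
  fmt <- v@gt[, "FORMAT"]
  if (nrow(v@gt) > 0 && !any(grepl("(^|:)AD(:|$)", fmt))) {
    abort(sprintf("No per-sample allele-depth field `AD` in %s.", path))
  }
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT %||% character(0))
  ad <- vcfR::extract.gt(v, element = "AD")
  parse_ad <- function(x) {
    parts <- strsplit(ifelse(is.na(x) | x == ".", "NA,NA", x), ",", fixed = TRUE)
    ref <- suppressWarnings(as.integer(vapply(parts, `[`, "", 1L)))
    alt <- suppressWarnings(as.integer(vapply(parts, function(p) p[2] %||% NA_character_, "")))
    list(ref = ref, alt = alt)
  }
  ad_mut <- parse_ad(ad[, samples[1]])
  ad_wt <- parse_ad(ad[, samples[2]])
  records <- tibble(
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    mut_ref = ad_mut$ref, mut_alt = ad_mut$alt,
    wt_ref = ad_wt$ref, wt_alt = ad_wt$alt
  )
  n_multi <- sum(multi)
  if (n_multi > 0) {
    inform(sprintf("Skipped %d multi-allelic site(s).", n_multi))
    records <- records[!multi, ]
  }
  list(records = records, n_multiallelic = n_multi)
}

read_variants_tsv <- function(path) {
  need <- c("chrom", "pos", "ref", "alt", "mut_ref", "mut_alt", "wt_ref", "wt_alt")
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(need, names(x))
  if (length(missing) > 0) {
    abort(sprintf("TSV %s lacks column(s): %s.", path,
                  paste(missing, collapse = ", ")))
  }
  x <- x[, need]
  x$pos <- as.integer(x$pos)
  for (col in c("mut_ref", "mut_alt", "wt_ref", "wt_alt")) {
    x[[col]] <- as.integer(x[[col]])
  }
  list(records = as_tibble(x), n_multiallelic = 0L)
}

#' Write allele-depth records as TSV
#'
#' The plain-text companion of [write_simulated_vcf()]; round-trips through
#' [read_variants()].
#'
#' @param records Allele-depth tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variants_tsv <- function(records, path) {
  readr::write_tsv(records, path, progress = FALSE)
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Extracts the CDS chains of each mRNA (or, failing a transcript parent,
#' each gene) as one gene model: ordered, non-overlapping CDS segments with
#' 1-based inclusive coordinates, a strand, and the phase of the first
#' segment in transcription order.
#'
#' @param path Path to a GFF3 file (gzip accepted).
#' @return A tibble with one row per CDS segment: `gene_id`, `chrom`,
#'   `strand`, `start`, `end`, `phase`, sorted by genomic coordinate within
#'   gene.
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  gr <- rtracklayer::import(path, format = "gff3")
  cds <- gr[gr$type == "CDS"]
  if (length(cds) == 0L) {
    return(tibble(gene_id = character(), chrom = character(),
                  strand = character(), start = integer(), end = integer(),
                  phase = integer()))
  }
  df <- as.data.frame(cds)
  parent <- if ("Parent" %in% names(df)) {
    vapply(df$Parent, function(p) {
      if (length(p) == 0) NA_character_ else as.character(p[[1]])
    }, "")
  } else {
    rep(NA_character_, nrow(df))
  }
  ids <- ifelse(is.na(parent) | parent == "",
                as.character(df$ID %||% seq_len(nrow(df))), parent)
  strand <- as.character(df$strand)
  if (any(strand == "*")) {
    abort("CDS feature without a strand in GFF3; cannot build gene models.")
  }
  phase <- if ("phase" %in% names(df)) {
    suppressWarnings(as.integer(as.character(df$phase)))
  } else {
    rep(0L, nrow(df))
  }
  phase[is.na(phase)] <- 0L

  models <- tibble(
    gene_id = ids,
    chrom = as.character(df$seqnames),
    strand = strand,
    start = as.integer(df$start),
    end = as.integer(df$end),
    phase = phase
  ) |>
    dplyr::arrange(.data$gene_id, .data$start)

  # validate per gene: single strand/chrom, no overlapping segments,
  # keep only the transcription-leading phase
  split_models <- split(models, models$gene_id)
  out <- purrr::map_dfr(split_models, function(m) {
    if (length(unique(m$strand)) > 1 || length(unique(m$chrom)) > 1) {
      abort(sprintf("Gene %s mixes strands or chromosomes.", m$gene_id[1]))
    }
    if (nrow(m) > 1 && any(m$start[-1] <= m$end[-nrow(m)])) {
      abort(sprintf("Gene %s has overlapping CDS segments.", m$gene_id[1]))
    }
    first <- if (m$strand[1] == "+") 1L else nrow(m)
    m$phase <- m$phase[first]
    total <- sum(m$end - m$start + 1)
    if (m$phase[1] == 0L && total %% 3 != 0) {
      warn(sprintf("Gene %s: CDS length %d not divisible by 3.", m$gene_id[1], total))
    }
    m
  })
  dplyr::arrange(out, .data$gene_id, .data$start)
}

#' Read a reference sequence from FASTA
#'
#' @param path Path to a (possibly gzipped) FASTA file.
#' @return A named upper-cased character vector, one element per sequence.
#'   Lookups via [ref_base()] are 1-based.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  ss <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) {
    abort(sprintf("Duplicate sequence id(s) in %s: %s.", path,
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  setNames(toupper(as.character(ss)), ids)
}

#' Look up reference bases (1-based)
#'
#' @param ref_seq Named character vector from [read_fasta()].
#' @param chrom Chromosome id.
#' @param pos 1-based position vector.
#' @return Character vector of bases.
#' @export
ref_base <- function(ref_seq, chrom, pos) {
  if (!chrom %in% names(ref_seq)) {
    abort(sprintf("Chromosome %s not in reference.", chrom))
  }
  n <- nchar(ref_seq[[chrom]])
  if (any(pos < 1 | pos > n)) {
    abort(sprintf("Position out of range 1..%d on %s.", n, chrom))
  }
  substring(ref_seq[[chrom]], pos, pos)
}
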