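#' Configure a synthetic F2 bulk-sequencing experiment
#'
#' Bundles every parameter of the simulated experiment: an F2 population from
#' two inbred parents segregating a single fully recessive locus, two
#' phenotype-selected bulks, and short-read allele-depth sampling over a set
#' of marker SNPs. Defaults describe a typical single-gene mapping design:
#' one 20 Mb chromosome carrying the causal locus at 11.2 Mb, a marker SNP
#' every 10 kb, 156 F2 plants, bulks of 33 plants each, and ~80x mean pooled
#' read depth.
#'
#' Genotype codes count parent-B alleles: 0 = homozygous parent-A,
#' 1 = heterozygous, 2 = homozygous parent-B. The mutant phenotype requires
#' genotype 2 at the causal locus (recessive, fully penetrant unless
#' `misclass_rate > 0`). Parent A supplies the reference alleles, so the
#' SNP-index of a bulk at a marker estimates its parent-B allele frequency.
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths in bp.
#' @param markers Data frame with columns `chrom` and `pos` (1-based bp)
#'   giving marker SNP positions, or `NULL` to place one marker every
#'   `marker_spacing` bp on every chromosome.
#' @param marker_spacing Spacing (bp) used when `markers` is `NULL`.
#' @param causal_chrom,causal_pos Location of the causal locus; must coincide
#'   with a marker. Set `causal_chrom = NA` for a null experiment with no
#'   segregating phenotype locus (phenotypes are then assigned at random in
#'   the Mendelian 1:3 proportion, so bulks are random draws from the F2).
#' @param genetic_lengths Named numeric vector, genetic length of each
#'   chromosome in Morgans (expected crossovers per gamete). Default 0.8 M
#'   per 20 Mb (~4 cM/Mb).
#' @param n_individuals Number of F2 plants.
#' @param bulk_size Plants per phenotype-selected bulk.
#' @param depth Mean read depth per pool per site.
#' @param depth_model `"poisson"` (per-site depth ~ Poisson(`depth`)) or
#'   `"fixed"` (every site sequenced at exactly `depth`).
#' @param error_rate Per-base sequencing error probability in `[0, 0.5)`.
#' @param misclass_rate Probability that a plant's phenotype label is flipped
#'   before bulking (bulk contamination). Default 0.
#' @param seed Master random seed; all stage streams derive from it.
#'
#' @return An object of class `f2_sim_config`.
#' @export
#' @examples
#' cfg <- f2_sim_config(n_individuals = 24, bulk_size = 3, seed = 1)
#' cfg
f2_sim_config <- function(chrom_lengths = c(chr4 = 20e6),
                          markers = NULL,
                          marker_spacing = 10e3,
                          causal_chrom = "chr4",
                          causal_pos = 11.2e6,
                          genetic_lengths = NULL,
                          n_individuals = 156,
                          bulk_size = 33,
                          depth = 80,
                          depth_model = c("poisson", "fixed"),
                          error_rate = 0.001,
                          misclass_rate = 0,
                          seed = 1L) {
  depth_model <- match.arg(depth_model)
  if (is.null(names(chrom_lengths)) || anyNA(names(chrom_lengths))) {
    abort("`chrom_lengths` must be a named vector of chromosome lengths.")
  }
  if (is.null(genetic_lengths)) {
    genetic_lengths <- chrom_lengths / 20e6 * 0.8
  }
  if (!all(names(chrom_lengths) %in% names(genetic_lengths))) {
    abort("`genetic_lengths` must name every chromosome in `chrom_lengths`.")
  }
  if (is.null(markers)) {
    markers <- purrr::imap_dfr(as.list(chrom_lengths), function(len, chr) {
      tibble(chrom = chr, pos = seq(marker_spacing, len, by = marker_spacing))
    })
  }
  markers <- as_tibble(markers)[, c("chrom", "pos")]
  markers <- arrange_sites(markers, chrom_order = names(chrom_lengths))
  if (!all(markers$chrom %in% names(chrom_lengths))) {
    abort("All markers must lie on a chromosome listed in `chrom_lengths`.")
  }
  bad <- markers$pos < 1 | markers$pos > chrom_lengths[markers$chrom]
  if (any(bad)) {
    abort(sprintf("%d marker(s) fall outside their chromosome length.", sum(bad)))
  }
  check_scalar_number(n_individuals, "n_individuals", min = 1)
  check_scalar_number(bulk_size, "bulk_size", min = 0)
  check_scalar_number(depth, "depth", min = 1)
  check_scalar_number(error_rate, "error_rate", min = 0, max = 0.5 - 1e-12)
  check_scalar_number(misclass_rate, "misclass_rate", min = 0, max = 1)

  causal <- NULL
  if (!is.na(causal_chrom)) {
    hit <- markers$chrom == causal_chrom & markers$pos == causal_pos
    if (!any(hit)) {
      abort("The causal locus must coincide with one of the marker positions.")
    }
    causal <- list(chrom = causal_chrom, pos = causal_pos)
  }

  streams <- derive_seeds(seed, 6,
    names = c("meiosis", "phenotype", "bulks", "bases", "reads_mut", "reads_wt"))

  structure(
    list(
      chrom_lengths = chrom_lengths,
      genetic_lengths = genetic_lengths[names(chrom_lengths)],
      markers = markers,
      causal = causal,
      n_individuals = as.integer(n_individuals),
      bulk_size = as.integer(bulk_size),
      depth = depth,
      depth_model = depth_model,
      error_rate = error_rate,
      misclass_rate = misclass_rate,
      seed = as.integer(seed),
      streams = streams
    ),
    class = "f2_sim_config"
  )
}

#' Read a simulator configuration from a YAML file
#'
#' Keys mirror the arguments of [f2_sim_config()]; `chrom_lengths` and
#' `genetic_lengths` are given as named mappings.
#'
#' @param path Path to a YAML file.
#' @return An `f2_sim_config`.
#' @export
read_f2_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  for (nm in c("chrom_lengths", "genetic_lengths")) {
    if (!is.null(raw[[nm]])) raw[[nm]] <- unlist(raw[[nm]])
  }
  if (!is.null(raw$markers)) raw$markers <- as_tibble(raw$markers)
  do.call(f2_sim_config, raw)
}

#' @export
print.f2_sim_config <- function(x, ...) {
  cat("<f2_sim_config>\n")
  cat(sprintf("  chromosomes : %s (%s bp)\n",
              paste(names(x$chrom_lengths), collapse = ", "),
              paste(format(x$chrom_lengths, big.mark = ","), collapse = ", ")))
  cat(sprintf("  markers     : %d\n", nrow(x$markers)))
  if (is.null(x$causal)) {
    cat("  causal locus: none (null experiment)\n")
  } else {
    cat(sprintf("  causal locus: %s:%s (recessive)\n", x$causal$chrom,
                format(x$causal$pos, big.mark = ",")))
  }
  cat(sprintf("  F2 plants   : %d, bulks of %d\n", x$n_individuals, x$bulk_size))
  cat(sprintf("  depth       : %g per pool (%s), error %g, seed %d\n",
              x$depth, x$depth_model, x$error_rate, x$seed))
  invisible(x)
}

# One meiosis per gamete: crossover count ~ Poisson(genetic length in
# Morgans), breakpoints uniform on the chromosome, no interference. Returns an
# n x n_markers 0/1 matrix of parent-B allele carriage.
simulate_gametes <- function(n, marker_pos, chrom_len, morgans) {
  out <- matrix(0L, nrow = n, ncol = length(marker_pos))
  n_co <- rpois(n, morgans)
  start <- sample(0:1, n, replace = TRUE)
  for (i in seq_len(n)) {
    if (n_co[i] == 0L) {
      out[i, ] <- start[i]
    } else {
      bp <- sort(runif(n_co[i], min = 1, max = chrom_len))
      out[i, ] <- (start[i] + findInterval(marker_pos, bp)) %% 2L
    }
  }
  out
}

#' Simulate an F2 population
#'
#' Each F2 plant is formed from two independent F1 gametes; each gamete is a
#' parental haplotype with Poisson-distributed crossovers placed uniformly
#' along the chromosome (no interference). Genotype codes count parent-B
#' alleles; the phenotype is mutant iff the causal genotype is 2 (fully
#' recessive), optionally mislabelled at `misclass_rate`.
#'
#' @param config An [f2_sim_config()].
#' @return An object of class `f2_population` with a genotype matrix
#'   (individuals x markers), the marker table, and a phenotype vector.
#'   Use [tidy()] for a long tibble.
#' @export
#' @examples
#' pop <- simulate_f2(f2_sim_config(n_individuals = 40, seed = 7))
#' table(pop$phenotype)
simulate_f2 <- function(config) {
  stopifnot(inherits(config, "f2_sim_config"))
  markers <- config$markers
  n <- config$n_individuals
  geno <- matrix(0L, nrow = n, ncol = nrow(markers))
  with_seed(config$streams[["meiosis"]], {
    for (chr in names(config$chrom_lengths)) {
      idx <- which(markers$chrom == chr)
      if (length(idx) == 0L) next
      g1 <- simulate_gametes(n, markers$pos[idx], config$chrom_lengths[[chr]],
                             config$genetic_lengths[[chr]])
      g2 <- simulate_gametes(n, markers$pos[idx], config$chrom_lengths[[chr]],
                             config$genetic_lengths[[chr]])
      geno[, idx] <- g1 + g2
    }
  })

  phenotype <- with_seed(config$streams[["phenotype"]], {
    if (is.null(config$causal)) {
      # no segregating locus: phenotype labels independent of genotype
      ifelse(runif(n) < 0.25, "mutant", "wildtype")
    } else {
      ci <- which(markers$chrom == config$causal$chrom &
                    markers$pos == config$causal$pos)
      ph <- ifelse(geno[, ci] == 2L, "mutant", "wildtype")
      if (config$misclass_rate > 0) {
        flip <- runif(n) < config$misclass_rate
        ph[flip] <- ifelse(ph[flip] == "mutant", "wildtype", "mutant")
      }
      ph
    }
  })

  structure(
    list(genotypes = geno, markers = markers, phenotype = phenotype,
         config = config),
    class = "f2_population"
  )
}

#' @export
print.f2_population <- function(x, ...) {
  cat(sprintf("<f2_population> %d individuals x %d markers (%d mutant, %d wildtype)\n",
              nrow(x$genotypes), ncol(x$genotypes),
              sum(x$phenotype == "mutant"), sum(x$phenotype == "wildtype")))
  invisible(x)
}

#' @rdname simulate_f2
#' @param x An `f2_population`.
#' @param ... Unused.
#' @method tidy f2_population
#' @export
tidy.f2_population <- function(x, ...) {
  tidyr::crossing(individual = seq_len(nrow(x$genotypes)),
                  marker = seq_len(ncol(x$genotypes))) |>
    dplyr::mutate(
      chrom = x$markers$chrom[.data$marker],
      pos = x$markers$pos[.data$marker],
      genotype = as.vector(t(x$genotypes)),
      phenotype = x$phenotype[.data$individual]
    ) |>
    dplyr::select(!"marker")
}

#' Select phenotype bulks from an F2 population
#'
#' Draws `bulk_size` plants uniformly at random, without replacement, from
#' each phenotype class.
#'
#' @param population An `f2_population`.
#' @param bulk_size Plants per bulk; defaults to the configured value.
#' @param seed Optional seed; defaults to the config's bulk stream.
#' @return A named list with `mutant` and `wildtype` elements, each an
#'   `f2_population` restricted to the bulked plants.
#' @export
select_bulks <- function(population, bulk_size = NULL, seed = NULL) {
  stopifnot(inherits(population, "f2_population"))
  cfg <- population$config
  bulk_size <- as.integer(bulk_size %||% cfg$bulk_size)
  seed <- seed %||% cfg$streams[["bulks"]]
  classes <- list(mutant = which(population$phenotype == "mutant"),
                  wildtype = which(population$phenotype == "wildtype"))
  for (cls in names(classes)) {
    if (length(classes[[cls]]) < bulk_size) {
      abort(sprintf(
        "Cannot bulk %d plants from the %s class: only %d available.",
        bulk_size, cls, length(classes[[cls]])))
    }
  }
  with_seed(seed, {
    purrr::map(classes, function(idx) {
      keep <- sort(sample(idx, bulk_size))
      structure(
        list(genotypes = population$genotypes[keep, , drop = FALSE],
             markers = population$markers,
             phenotype = population$phenotype[keep],
             config = cfg),
        class = "f2_population"
      )
    })
  })
}

#' Parent-B allele frequency of a bulk at every marker
#'
#' The exact allele frequency in the pooled DNA: `(2 * n_homB + n_het) /
#' (2 * bulk size)`. This is the quantity that read sampling observes with
#' binomial noise.
#'
#' @param bulk An `f2_population` (typically one element of [select_bulks()]).
#' @return A tibble with `chrom`, `pos`, `freq`.
#' @export
bulk_allele_freq <- function(bulk) {
  stopifnot(inherits(bulk, "f2_population"))
  if (nrow(bulk$genotypes) == 0L) abort("Bulk is empty.")
  dplyr::mutate(bulk$markers, freq = colMeans(bulk$genotypes) / 2)
}

#' Sample pooled read depths at given allele frequencies
#'
#' Total depth per site is Poisson(`depth`) (or fixed); the alternate-read
#' count is binomial at the error-adjusted frequency
#' `f' = f (1 - e) + (1 - f) e`.
#'
#' @param true_freq Numeric vector of allele frequencies in `[0, 1]`.
#' @param depth Mean (or fixed) depth per site.
#' @param error_rate Per-base error probability.
#' @param depth_model `"poisson"` or `"fixed"`.
#' @param seed Optional seed.
#' @return A tibble with `ref_depth` and `alt_depth`.
#' @export
#' @examples
#' sample_reads(c(0, 0.5, 1), depth = 80, seed = 1)
sample_reads <- function(true_freq, depth, error_rate = 0,
                         depth_model = c("poisson", "fixed"), seed = NULL) {
  depth_model <- match.arg(depth_model)
  if (any(true_freq < 0 | true_freq > 1, na.rm = TRUE)) {
    abort("`true_freq` must lie in [0, 1].")
  }
  m <- length(true_freq)
  with_seed(seed, {
    total <- if (depth_model == "poisson") rpois(m, depth) else rep(as.integer(round(depth)), m)
    f_obs <- true_freq * (1 - error_rate) + (1 - true_freq) * error_rate
    alt <- rbinom(m, total, f_obs)
    tibble(ref_depth = total - alt, alt_depth = alt)
  })
}

#' Simulate a complete bulk-sequencing data set
#'
#' Runs the whole generative chain: F2 meiosis, phenotype assignment,
#' phenotype-selected bulks, and binomial read sampling per pool, and assigns
#' reference/alternate bases (parent A carries the reference allele at every
#' marker). Sites where both pools drew zero reads are dropped.
#'
#' @param config An [f2_sim_config()].
#' @return A tibble of allele-depth records with columns `chrom`, `pos`,
#'   `ref`, `alt`, `mut_ref`, `mut_alt`, `wt_ref`, `wt_alt`. The population
#'   and bulks are attached as attributes `population` and `bulks`.
#' @export
#' @examples
#' rec <- simulate_bulk_seq(f2_sim_config(n_individuals = 60, bulk_size = 5, seed = 2))
#' head(rec)
simulate_bulk_seq <- function(config) {
  stopifnot(inherits(config, "f2_sim_config"))
  pop <- simulate_f2(config)
  bulks <- select_bulks(pop)
  freq_mut <- bulk_allele_freq(bulks$mutant)$freq
  freq_wt <- bulk_allele_freq(bulks$wildtype)$freq

  bases <- c("A", "C", "G", "T")
  nm <- nrow(config$markers)
  ref_alt <- with_seed(config$streams[["bases"]], {
    ref <- sample(bases, nm, replace = TRUE)
    shift <- sample(1:3, nm, replace = TRUE)
    alt <- bases[(match(ref, bases) - 1L + shift) %% 4L + 1L]
    list(ref = ref, alt = alt)
  })

  mut <- sample_reads(freq_mut, config$depth, config$error_rate,
                      config$depth_model, seed = config$streams[["reads_mut"]])
  wt <- sample_reads(freq_wt, config$depth, config$error_rate,
                     config$depth_model, seed = config$streams[["reads_wt"]])

  rec <- tibble(
    chrom = config$markers$chrom,
    pos = config$markers$pos,
    ref = ref_alt$ref,
    alt = ref_alt$alt,
    mut_ref = mut$ref_depth, mut_alt = mut$alt_depth,
    wt_ref = wt$ref_depth, wt_alt = wt$alt_depth
  )
  rec <- rec[rec$mut_ref + rec$mut_alt + rec$wt_ref + rec$wt_alt > 0, ]
  attr(rec, "population") <- pop
  attr(rec, "bulks") <- bulks
  attr(rec, "config") <- config
  rec
}

#' Write simulated allele-depth records as a minimal VCF
#'
#' Emits a VCF 4.2 file with two samples, `mutant` and `wildtype`, carrying
#' per-sample allele depths in the `AD` FORMAT field (and total depth in
#' `DP`). Output is byte-deterministic for identical inputs and round-trips
#' through [read_variants()].
#'
#' @param records Allele-depth tibble as produced by [simulate_bulk_seq()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_simulated_vcf <- function(records, path) {
  cols <- c("chrom", "pos", "ref", "alt", "mut_ref", "mut_alt", "wt_ref", "wt_alt")
  if (!all(cols %in% names(records))) {
    abort(sprintf("`records` must have columns %s.", paste(cols, collapse = ", ")))
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=bsascan",
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths for the ref and alt alleles">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "mutant", "wildtype", sep = "\t")
  )
  body <- character(0)
  if (nrow(records) > 0) {
    body <- sprintf(
      "%s\t%d\t.\t%s\t%s\t.\t.\t.\tAD:DP\t%d,%d:%d\t%d,%d:%d",
      records$chrom, as.integer(records$pos), records$ref, records$alt,
      records$mut_ref, records$mut_alt, records$mut_ref + records$mut_alt,
      records$wt_ref, records$wt_alt, records$wt_ref + records$wt_alt
    )
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, body), con = con, sep = "\n")
  invisible(path)
}
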