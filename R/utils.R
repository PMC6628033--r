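# Internal helpers shared across modules.

# Derive n reproducible sub-seeds from one master seed. Every stochastic stage
# of the simulator consumes its own stream so that adding a stage never
# perturbs the draws of another.
derive_seeds <- function(master_seed, n, names = NULL) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(master_seed))
  s <- sample.int(.Machine$integer.max - 1L, n)
  if (!is.null(names)) s <- setNames(s, names)
  s
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

# Apply a seed if given, without leaking the change to the caller's RNG.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  force(code)
}

check_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max) {
    abort(sprintf("`%s` must be a single number in [%s, %s].", name, min, max))
  }
  invisible(x)
}

# Total order on sites: chromosome (lexicographic, or a supplied ordering),
# then position.
arrange_sites <- function(x, chrom_order = NULL) {
  if (!is.null(chrom_order)) {
    x$chrom <- factor(x$chrom, levels = chrom_order)
    x <- dplyr::arrange(x, .data$chrom, .data$pos)
    x$chrom <- as.character(x$chrom)
    x
  } else {
    dplyr::arrange(x, .data$chrom, .data$pos)
  }
}
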