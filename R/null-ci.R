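#' Simulate delta SNP-index under the no-QTL null
#'
#' Monte-Carlo draws of the window-free, per-site delta SNP-index when no
#' locus segregates with the phenotype. Per replicate and per bulk
#' independently: `bulk_size` F2 genotypes are drawn at the Mendelian 1:2:1,
#' the bulk allele frequency is formed, an alternate-read count is drawn as
#' Binomial(depth, frequency), and the two resulting indices are differenced.
#'
#' @param bulk_size Plants per bulk (>= 1).
#' @param depth Reads per site per pool (>= 1).
#' @param n_reps Number of replicates (>= 1; thresholds need many more).
#' @param seed Optional seed.
#' @param depth_model `"fixed"` (default: the thresholds condition on depth)
#'   or `"poisson"`; Poisson draws of zero are redrawn so every replicate has
#'   at least one read.
#' @return Numeric vector of `n_reps` delta values in `[-1, 1]`.
#' @export
#' @examples
#' sd(simulate_null_delta(33, 80, n_reps = 5000, seed = 1))
simulate_null_delta <- function(bulk_size, depth, n_reps = 10000, seed = NULL,
                                depth_model = c("fixed", "poisson")) {
  depth_model <- match.arg(depth_model)
  check_scalar_number(bulk_size, "bulk_size", min = 1)
  check_scalar_number(depth, "depth", min = 1)
  check_scalar_number(n_reps, "n_reps", min = 1)
  with_seed(seed, {
    draw_index <- function() {
      counts <- rmultinom(n_reps, bulk_size, prob = c(1, 2, 1) / 4)
      freq <- (counts[2, ] + 2 * counts[3, ]) / (2 * bulk_size)
      d <- if (depth_model == "fixed") {
        rep(as.integer(round(depth)), n_reps)
      } else {
        dd <- rpois(n_reps, depth)
        while (any(dd == 0L)) dd[dd == 0L] <- rpois(sum(dd == 0L), depth)
        dd
      }
      rbinom(n_reps, d, freq) / d
    }
    draw_index() - draw_index()
  })
}

#' Two-sided confidence bounds from a null sample
#'
#' Symmetric two-sided bounds: the `level`-quantile of `|delta|`.
#'
#' @param samples Numeric vector of null delta draws.
#' @param levels Confidence levels, default 0.95 and 0.99.
#' @return Named numeric vector of bounds, one per level.
#' @export
thresholds_from_samples <- function(samples, levels = c(0.95, 0.99)) {
  if (any(levels <= 0 | levels >= 1)) abort("`levels` must lie in (0, 1).")
  need <- ceiling(1 / (1 - max(levels)))
  if (length(samples) < need) {
    abort(sprintf("Need at least %d samples for the %g quantile; got %d.",
                  need, max(levels), length(samples)))
  }
  setNames(quantile(abs(samples), probs = levels, names = FALSE),
           sprintf("ci_%02d", round(levels * 100)))
}

#' Null thresholds over a grid of read depths
#'
#' Precomputes two-sided 95%/99% bounds on `|delta|` for each distinct depth
#' (capped at 200 grid values; downstream lookup snaps to the nearest depth).
#'
#' @param depths Integer vector of per-site depths (duplicates fine), or the
#'   depths column of a variant table.
#' @param bulk_size Plants per bulk.
#' @param n_reps Null replicates per depth (default 10,000).
#' @param levels Confidence levels.
#' @param seed Seed; per-depth streams derive from it.
#' @param max_grid Maximum number of distinct depths simulated.
#' @return A tibble `depth, bulk_size, ci_95, ci_99, n_reps` of class
#'   `null_thresholds`, sorted by depth.
#' @export
#' @examples
#' null_thresholds(80, bulk_size = 33, n_reps = 2000, seed = 1)
null_thresholds <- function(depths, bulk_size, n_reps = 10000,
                            levels = c(0.95, 0.99), seed = 1L,
                            max_grid = 200) {
  depths <- sort(unique(as.integer(round(depths))))
  depths <- depths[depths >= 1]
  if (length(depths) == 0L) abort("No positive depths supplied.")
  if (length(depths) > max_grid) {
    depths <- sort(unique(as.integer(round(
      quantile(depths, probs = seq(0, 1, length.out = max_grid), names = FALSE)))))
  }
  seeds <- derive_seeds(seed, length(depths))
  rows <- purrr::map2_dfr(depths, seeds, function(d, s) {
    b <- thresholds_from_samples(
      simulate_null_delta(bulk_size, d, n_reps = n_reps, seed = s), levels)
    tibble(depth = d, bulk_size = bulk_size, !!!as.list(b), n_reps = n_reps)
  })
  class(rows) <- c("null_thresholds", class(rows))
  rows
}

# Nearest-depth lookup of per-site bounds.
lookup_thresholds <- function(depth, thresholds) {
  grid <- thresholds$depth
  idx <- vapply(depth, function(d) {
    if (is.na(d)) NA_integer_ else which.min(abs(grid - d))
  }, integer(1))
  thresholds[idx, setdiff(names(thresholds), c("depth", "bulk_size", "n_reps"))]
}

#' Attach null bounds to scan windows
#'
#' The null thresholds are built per site at a given depth; a window's bound
#' is the arithmetic mean of the per-site bounds of its contributing sites
#' (each site's bound looked up at the nearest simulated depth to its
#' two-pool mean depth). Empty windows get `NA`.
#'
#' @param windows Window tibble from [sliding_window_mean()].
#' @param sites The site tibble the windows were computed from.
#' @param thresholds A [null_thresholds()] table.
#' @return `windows` with bound columns (`ci_95`, `ci_99`, ...) and logical
#'   `exceeds_95`/`exceeds_99` flags added.
#' @export
window_thresholds <- function(windows, sites, thresholds) {
  sites <- sites[!is.na(sites$index_mut) & !is.na(sites$index_wt), ]
  site_depth <- round((sites$depth_mut + sites$depth_wt) / 2)
  bounds <- lookup_thresholds(site_depth, thresholds)
  lvl_cols <- names(bounds)
  for (col in lvl_cols) windows[[col]] <- NA_real_
  for (chr in unique(windows$chrom)) {
    wi <- which(windows$chrom == chr)
    si <- which(sites$chrom == chr)
    ord <- si[order(sites$pos[si])]
    pos <- sites$pos[ord]
    for (col in lvl_cols) {
      cs <- c(0, cumsum(bounds[[col]][ord]))
      lo <- findInterval(windows$start[wi] - 0.5, pos)
      hi <- findInterval(windows$end[wi] - 0.5, pos)
      n <- hi - lo
      windows[[col]][wi] <- ifelse(n > 0, (cs[hi + 1] - cs[lo + 1]) / n, NA_real_)
    }
  }
  for (col in lvl_cols) {
    flag <- sub("^ci_", "exceeds_", col)
    windows[[flag]] <- !is.na(windows$delta) & !is.na(windows[[col]]) &
      abs(windows$delta) > windows[[col]]
  }
  windows
}

#' Call candidate regions from threshold-exceeding windows
#'
#' A candidate region is a maximal run of consecutive windows (per
#' chromosome, in window order) whose `|delta|` exceeds the window's bound at
#' the requested level. Each region records its peak window.
#'
#' @param windows Window tibble with bounds attached
#'   (see [window_thresholds()]).
#' @param level `"95"` or `"99"`: the bound runs are formed against.
#' @return A tibble with one row per region: `chrom`, `start`, `end`,
#'   `n_windows`, `peak_delta` (signed delta of the peak window), `peak_mid`
#'   (midpoint of the peak window), and `level` (`99` if any window in the
#'   run also exceeds its 99% bound, else `95`).
#' @export
call_candidate_regions <- function(windows, level = c("95", "99")) {
  level <- match.arg(level)
  flag_col <- paste0("exceeds_", level)
  if (!flag_col %in% names(windows)) {
    abort(sprintf("Windows lack an `%s` column; run `window_thresholds()` first.",
                  flag_col))
  }
  empty <- tibble(chrom = character(), start = double(), end = double(),
                  n_windows = integer(), peak_delta = double(),
                  peak_mid = double(), level = integer())
  out <- purrr::map_dfr(unique(windows$chrom), function(chr) {
    w <- windows[windows$chrom == chr, ]
    w <- w[order(w$start), ]
    flag <- w[[flag_col]]
    if (!any(flag)) return(empty)
    r <- rle(flag)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    keep <- which(r$values)
    purrr::map_dfr(keep, function(k) {
      idx <- starts[k]:ends[k]
      peak <- idx[which.max(abs(w$delta[idx]))]
      lvl <- if ("exceeds_99" %in% names(w) && any(w$exceeds_99[idx])) 99L else 95L
      tibble(chrom = chr, start = w$start[idx[1]], end = w$end[idx[length(idx)]],
             n_windows = length(idx), peak_delta = w$delta[peak],
             peak_mid = (w$start[peak] + w$end[peak]) / 2, level = lvl)
    })
  })
  if (nrow(out) == 0) empty else out
}
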