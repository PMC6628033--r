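#' SNP-index of a pool at a site
#'
#' Fraction of reads carrying the non-reference allele: 0 when every read
#' matches the reference, 1 when every read differs. Sites with zero total
#' depth yield `NA` (missing), never 0.
#'
#' @param ref_depth,alt_depth Integer vectors of per-pool read counts.
#' @return Numeric vector of indices in `[0, 1]`, `NA` where depth is zero
#'   or either count is missing.
#' @export
#' @examples
#' snp_index(c(0, 20, 15), c(20, 0, 5))
snp_index <- function(ref_depth, alt_depth) {
  if (any(ref_depth < 0 | alt_depth < 0, na.rm = TRUE)) {
    abort("Read depths must be non-negative.")
  }
  total <- ref_depth + alt_depth
  ifelse(!is.na(total) & total > 0, alt_depth / total, NA_real_)
}

#' Attach per-site SNP-indices and depths to allele-depth records
#'
#' @param records Allele-depth tibble (`chrom, pos, mut_ref, mut_alt,
#'   wt_ref, wt_alt`, plus any other columns, which are kept).
#' @return The records with columns `depth_mut`, `depth_wt`, `index_mut`,
#'   `index_wt`, and `delta` (= `index_mut - index_wt`) added.
#' @export
add_snp_indices <- function(records) {
  dplyr::mutate(
    records,
    depth_mut = .data$mut_ref + .data$mut_alt,
    depth_wt = .data$wt_ref + .data$wt_alt,
    index_mut = snp_index(.data$mut_ref, .data$mut_alt),
    index_wt = snp_index(.data$wt_ref, .data$wt_alt),
    delta = delta_snp_index(.data$index_mut, .data$index_wt)
  )
}

#' Delta SNP-index
#'
#' Difference between the mutant-bulk and wildtype-bulk SNP-indices. With the
#' mutant bulk first, a recessive causal locus shows a positive peak
#' (expected value 2/3 at the locus itself: mutant bulk fixed at 1, wildtype
#' bulk at 1/3).
#'
#' @param mut_index,wt_index Numeric vectors of per-pool SNP-indices.
#' @return `mut_index - wt_index`, in `[-1, 1]`; `NA` if either is missing.
#' @export
delta_snp_index <- function(mut_index, wt_index) {
  mut_index - wt_index
}

#' Filter sites on joint pool extremeness
#'
#' A site is removed when its SNP-index is below `low` in BOTH pools, or
#' above `high` in BOTH pools — the pattern produced by shared artefacts
#' (mis-called reference or fixed non-segregating differences) rather than by
#' a segregating locus. A site extreme in only one pool is kept: at the
#' causal locus of a recessive mutant the mutant pool sits near 1 while the
#' wildtype pool sits near 1/3, and such sites must survive. Sites with a
#' missing index in either pool (zero-depth pool) are removed and counted
#' separately.
#'
#' @param sites Tibble with `index_mut` and `index_wt` (see
#'   [add_snp_indices()]).
#' @param low,high Filter bounds, `low < high`. Defaults 0.3 and 0.7.
#' @param quiet Suppress the removal-count message.
#' @return The retained sites; removal counts by reason are attached as
#'   attribute `filter_counts`.
#' @export
filter_sites <- function(sites, low = 0.3, high = 0.7, quiet = FALSE) {
  if (low >= high) abort("`low` must be smaller than `high`.")
  miss <- is.na(sites$index_mut) | is.na(sites$index_wt)
  both_low <- !miss & sites$index_mut < low & sites$index_wt < low
  both_high <- !miss & sites$index_mut > high & sites$index_wt > high
  counts <- c(missing_pool = sum(miss), both_low = sum(both_low),
              both_high = sum(both_high))
  if (!quiet && sum(counts) > 0) {
    inform(sprintf(
      "Removed %d site(s): %d with a zero-depth pool, %d with both indices < %g, %d with both > %g.",
      sum(counts), counts[["missing_pool"]], counts[["both_low"]], low,
      counts[["both_high"]], high))
  }
  out <- sites[!(miss | both_low | both_high), ]
  attr(out, "filter_counts") <- counts
  out
}

# Window layout for one chromosome: starts at 1, advances by step_bp, keeps
# the final partial window; [start, start + window_bp) half-open.
window_starts <- function(chrom_len, window_bp, step_bp) {
  seq(1, max(1, chrom_len), by = step_bp)
}

#' Sliding-window means of SNP-indices
#'
#' Tiles each chromosome with windows of `window_bp` starting at position 1
#' and advancing by `step_bp` (defaults 1 Mb and 250 kb); a site contributes
#' to every window containing it. Window values are unweighted means of the
#' per-site indices of each pool, with the window delta formed from the two
#' means. Windows with no contributing site are kept with `NA` statistics.
#'
#' @param sites Tibble of per-site indices (see [add_snp_indices()]),
#'   typically after [filter_sites()].
#' @param window_bp Window width in bp.
#' @param step_bp Step between window starts in bp; `window_bp >= step_bp >= 1`.
#' @param chrom_lengths Optional named vector of chromosome lengths; windows
#'   then tile the full chromosome rather than stopping at the last site.
#' @return A tibble with `chrom`, `start`, `end` (half-open), `n_sites`,
#'   `index_mut`, `index_wt`, `delta`, and `mean_depth` (mean over sites of
#'   the two-pool average depth, used for threshold lookup).
#' @export
sliding_window_mean <- function(sites, window_bp = 1e6, step_bp = 250e3,
                                chrom_lengths = NULL) {
  if (step_bp < 1 || window_bp < step_bp) {
    abort("Require `window_bp >= step_bp >= 1`.")
  }
  sites <- arrange_sites(sites, names(chrom_lengths))
  chroms <- if (!is.null(chrom_lengths)) names(chrom_lengths) else unique(sites$chrom)
  purrr::map_dfr(chroms, function(chr) {
    s <- sites[sites$chrom == chr, ]
    # sites with a zero-depth pool carry no index and are excluded outright
    s <- s[!is.na(s$index_mut) & !is.na(s$index_wt), ]
    len <- if (!is.null(chrom_lengths)) chrom_lengths[[chr]] else max(s$pos, 1)
    starts <- window_starts(len, window_bp, step_bp)
    pos <- s$pos
    # prefix sums over sites sorted by position
    cum <- function(v) c(0, cumsum(ifelse(is.na(v), 0, v)))
    cum_mut <- cum(s$index_mut)
    cum_wt <- cum(s$index_wt)
    cum_dep <- cum((s$depth_mut + s$depth_wt) / 2)
    lo <- findInterval(starts - 0.5, pos)       # sites with pos < start
    hi <- findInterval(starts + window_bp - 0.5, pos)  # pos < start + window
    n <- hi - lo
    mean_at <- function(cs) ifelse(n > 0, (cs[hi + 1] - cs[lo + 1]) / n, NA_real_)
    tibble(
      chrom = chr,
      start = starts,
      end = pmin(starts + window_bp, len + 1),
      n_sites = n,
      index_mut = mean_at(cum_mut),
      index_wt = mean_at(cum_wt),
      mean_depth = mean_at(cum_dep),
      delta = delta_snp_index(mean_at(cum_mut), mean_at(cum_wt))
    )
  })
}
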