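#' Run the full bulked-segregant scan
#'
#' Chains the whole analysis on a table of pooled allele depths: per-site
#' SNP-indices, the dual-pool 0.3/0.7 extremeness filter, 1 Mb / 250 kb
#' sliding-window means and window delta SNP-index, Monte-Carlo no-QTL
#' thresholds on the observed depth grid, and candidate-region calls.
#'
#' @param records Allele-depth tibble (`chrom, pos, ref, alt, mut_ref,
#'   mut_alt, wt_ref, wt_alt`), e.g. from [read_variants()] or
#'   [simulate_bulk_seq()].
#' @param bulk_size Plants per bulk, used by the null simulation.
#' @param window_bp,step_bp Window geometry (defaults 1 Mb, 250 kb).
#' @param filter_low,filter_high Dual-pool filter bounds.
#' @param chrom_lengths Optional named chromosome lengths for full tiling.
#' @param n_reps Null replicates per depth.
#' @param thresholds Optionally, a precomputed [null_thresholds()] table
#'   (e.g. shared across replicate scans at a fixed design); otherwise
#'   computed from the observed depths.
#' @param seed Seed for the null simulation.
#' @param quiet Suppress filter messages.
#' @return An object of class `bsa_scan`: a list with tibbles `sites`
#'   (retained, with indices), `windows` (with bounds and exceedance flags),
#'   `regions` (95% candidate regions), the `thresholds` table, and `params`.
#' @export
#' @examples
#' cfg <- f2_sim_config(n_individuals = 60, bulk_size = 10, depth = 40,
#'                      marker_spacing = 1e5, seed = 3)
#' scan <- bsa_scan(simulate_bulk_seq(cfg), bulk_size = 10,
#'                  n_reps = 2000, quiet = TRUE)
#' glance(scan)
bsa_scan <- function(records, bulk_size = 33, window_bp = 1e6,
                     step_bp = 250e3, filter_low = 0.3, filter_high = 0.7,
                     chrom_lengths = NULL, n_reps = 10000, thresholds = NULL,
                     seed = 1L, quiet = FALSE) {
  sites <- add_snp_indices(records)
  kept <- filter_sites(sites, low = filter_low, high = filter_high,
                       quiet = quiet)
  windows <- sliding_window_mean(kept, window_bp = window_bp,
                                 step_bp = step_bp,
                                 chrom_lengths = chrom_lengths)
  if (is.null(thresholds)) {
    depth_grid <- round((kept$depth_mut + kept$depth_wt) / 2)
    thresholds <- null_thresholds(depth_grid, bulk_size = bulk_size,
                                  n_reps = n_reps, seed = seed)
  }
  windows <- window_thresholds(windows, kept, thresholds)
  regions <- call_candidate_regions(windows, level = "95")
  structure(
    list(sites = kept, windows = windows, regions = regions,
         thresholds = thresholds,
         params = list(bulk_size = bulk_size, window_bp = window_bp,
                       step_bp = step_bp, filter_low = filter_low,
                       filter_high = filter_high, n_reps = n_reps,
                       seed = seed,
                       filter_counts = attr(kept, "filter_counts"))),
    class = "bsa_scan"
  )
}

#' @export
print.bsa_scan <- function(x, ...) {
  g <- glance(x)
  cat("<bsa_scan>\n")
  cat(sprintf("  sites retained : %d (removed: %s)\n", g$n_sites,
              paste(sprintf("%s=%d", names(x$params$filter_counts),
                            x$params$filter_counts), collapse = ", ")))
  cat(sprintf("  windows        : %d of %d bp, step %d bp\n", g$n_windows,
              as.integer(x$params$window_bp), as.integer(x$params$step_bp)))
  cat(sprintf("  candidate 95%%  : %d region(s)\n", g$n_regions))
  if (g$n_regions > 0) {
    cat(sprintf("  top region     : %s:%s-%s (peak delta %.3f at %s)\n",
                g$top_chrom, format(g$top_start, big.mark = ","),
                format(g$top_end, big.mark = ","), g$peak_delta,
                format(g$peak_mid, big.mark = ",")))
  }
  invisible(x)
}

#' Tidy the window track of a scan
#'
#' @param x A `bsa_scan`.
#' @param ... Unused.
#' @return The window tibble (one row per sliding window) with indices,
#'   delta, null bounds and exceedance flags.
#' @method tidy bsa_scan
#' @export
tidy.bsa_scan <- function(x, ...) x$windows

#' One-row summary of a scan
#'
#' @param x A `bsa_scan`.
#' @param ... Unused.
#' @return A one-row tibble: retained site and window counts, number of 95%
#'   candidate regions, and the top region's coordinates and peak delta.
#' @method glance bsa_scan
#' @export
glance.bsa_scan <- function(x, ...) {
  top <- if (nrow(x$regions) > 0) {
    x$regions[which.max(abs(x$regions$peak_delta)), ]
  } else {
    tibble(chrom = NA_character_, start = NA_real_, end = NA_real_,
           peak_delta = NA_real_, peak_mid = NA_real_)
  }
  tibble(
    n_sites = nrow(x$sites),
    n_windows = nrow(x$windows),
    n_regions = nrow(x$regions),
    top_chrom = top$chrom, top_start = top$start, top_end = top$end,
    peak_delta = top$peak_delta, peak_mid = top$peak_mid
  )
}

#' Plot the delta SNP-index track of a scan
#'
#' One panel per chromosome: the windowed delta SNP-index with the simulated
#' 95% and 99% null bounds (mirrored) and 95% candidate regions shaded.
#'
#' @param object A `bsa_scan`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot bsa_scan
#' @export
autoplot.bsa_scan <- function(object, ...) {
  w <- object$windows
  w$mid <- (w$start + w$end) / 2
  p <- ggplot2::ggplot(w, ggplot2::aes(x = .data$mid / 1e6))
  if (nrow(object$regions) > 0) {
    p <- p + ggplot2::geom_rect(
      data = object$regions,
      ggplot2::aes(xmin = .data$start / 1e6, xmax = .data$end / 1e6,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "gold", alpha = 0.3)
  }
  p +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_line(ggplot2::aes(y = .data$ci_95), colour = "forestgreen",
                       linetype = "dashed", na.rm = TRUE) +
    ggplot2::geom_line(ggplot2::aes(y = -.data$ci_95), colour = "forestgreen",
                       linetype = "dashed", na.rm = TRUE) +
    ggplot2::geom_line(ggplot2::aes(y = .data$ci_99), colour = "steelblue",
                       linetype = "dotted", na.rm = TRUE) +
    ggplot2::geom_line(ggplot2::aes(y = -.data$ci_99), colour = "steelblue",
                       linetype = "dotted", na.rm = TRUE) +
    ggplot2::geom_line(ggplot2::aes(y = .data$delta), na.rm = TRUE) +
    ggplot2::facet_wrap(ggplot2::vars(.data$chrom), scales = "free_x") +
    ggplot2::labs(x = "Position (Mb)", y = expression(Delta * " SNP-index")) +
    ggplot2::ylim(-1, 1) +
    ggplot2::theme_minimal()
}

#' @export
plot.bsa_scan <- function(x, ...) print(autoplot(x, ...))

#' Write the window track of a scan as TSV
#'
#' Columns: `chrom, start, end, n_sites, index_mut, index_wt, delta, ci_95,
#' ci_99, exceeds_95, exceeds_99`. Byte-deterministic for identical scans.
#'
#' @param scan A `bsa_scan`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_windows_tsv <- function(scan, path) {
  cols <- c("chrom", "start", "end", "n_sites", "index_mut", "index_wt",
            "delta", "ci_95", "ci_99", "exceeds_95", "exceeds_99")
  readr::write_tsv(scan$windows[, intersect(cols, names(scan$windows))], path,
                   progress = FALSE)
  invisible(path)
}
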