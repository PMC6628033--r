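#' Chi-square test of a Mendelian segregation ratio
#'
#' Pearson goodness-of-fit of observed dominant/recessive phenotype counts
#' against a hypothesized integer ratio (default 3:1, the F2 expectation for
#' a single recessive locus), without continuity correction.
#'
#' @param n_dominant,n_recessive Observed class counts.
#' @param ratio Integer ratio `c(dominant, recessive)`, default `c(3, 1)`.
#' @return A one-row tibble: `statistic`, `df`, `p_value`, plus the inputs.
#' @export
#' @examples
#' segregation_test(122, 34)  # statistic 0.855, consistent with 3:1
segregation_test <- function(n_dominant, n_recessive, ratio = c(3, 1)) {
  counts <- c(n_dominant, n_recessive)
  if (any(counts < 0) || sum(counts) < 1) {
    abort("Counts must be non-negative with a positive total.")
  }
  if (length(ratio) != 2 || any(ratio < 1)) {
    abort("`ratio` must be two values >= 1.")
  }
  p <- ratio / sum(ratio)
  ht <- suppressWarnings(chisq.test(counts, p = p))
  tibble(
    statistic = unname(ht$statistic),
    df = unname(ht$parameter),
    p_value = ht$p.value,
    n_dominant = n_dominant,
    n_recessive = n_recessive,
    ratio = paste(ratio, collapse = ":")
  )
}

#' Pigment concentrations from acetone-extract absorbances
#'
#' Spectrophotometric quantification of chlorophyll a, chlorophyll b and
#' total carotenoids from absorbances at 663, 646 and 470 nm (80% acetone):
#' \deqn{C_a = 12.21 A_{663} - 2.81 A_{646}}
#' \deqn{C_b = 20.13 A_{646} - 5.03 A_{663}}
#' \deqn{C_T = C_a + C_b}
#' \deqn{C_{x.c} = (1000 A_{470} - 3.27 C_a - 104 C_b) / 229}
#' Units follow the inputs (mg/L of extract; convert to mg/g fresh weight
#' with the extraction volume and tissue mass). Negative concentrations —
#' possible for absorbance ratios outside the calibration range — are
#' reported as-is with a warning so quality control can catch bad inputs.
#'
#' @param absorbances Data frame with columns `a663`, `a646`, `a470`
#'   (dimensionless, >= 0); other columns are kept.
#' @return The input with `chl_a`, `chl_b`, `chl_total`, `car` added.
#' @export
#' @examples
#' pigment_concentrations(tibble::tibble(a663 = 0.50, a646 = 0.18, a470 = 0.25))
pigment_concentrations <- function(absorbances) {
  need <- c("a663", "a646", "a470")
  missing <- setdiff(need, names(absorbances))
  if (length(missing) > 0) {
    abort(sprintf("`absorbances` lacks column(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  if (any(absorbances$a663 < 0 | absorbances$a646 < 0 | absorbances$a470 < 0,
          na.rm = TRUE)) {
    abort("Absorbances must be non-negative.")
  }
  out <- dplyr::mutate(
    absorbances,
    chl_a = 12.21 * .data$a663 - 2.81 * .data$a646,
    chl_b = 20.13 * .data$a646 - 5.03 * .data$a663,
    chl_total = .data$chl_a + .data$chl_b,
    car = (1000 * .data$a470 - 3.27 * .data$chl_a - 104 * .data$chl_b) / 229
  )
  neg <- sum(out$chl_a < 0, na.rm = TRUE) + sum(out$chl_b < 0, na.rm = TRUE) +
    sum(out$car < 0, na.rm = TRUE)
  if (neg > 0) {
    warn(sprintf("%d negative concentration(s) computed; check the input absorbances.",
                 neg))
  }
  out
}

#' Carotenoid share of total pigment
#'
#' Carotenoid content as a percentage of total measured pigment,
#' `100 * Car / (Chl a + Chl b + Car)`. When applied to per-genotype means,
#' this agrees with published means of per-replicate ratios only to within a
#' few tenths of a percentage point (a ratio of means is not a mean of
#' ratios).
#'
#' @param pigments Data frame with columns `chl_a`, `chl_b`, `car`.
#' @return The input with `car_pig_pct` added.
#' @export
#' @examples
#' car_pig_percent(tibble::tibble(chl_a = 0.76, chl_b = 0.25, car = 0.30))
car_pig_percent <- function(pigments) {
  need <- c("chl_a", "chl_b", "car")
  missing <- setdiff(need, names(pigments))
  if (length(missing) > 0) {
    abort(sprintf("`pigments` lacks column(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  total <- pigments$chl_a + pigments$chl_b + pigments$car
  if (any(total <= 0, na.rm = TRUE)) {
    abort("Total pigment must be positive to form a percentage.")
  }
  dplyr::mutate(pigments, car_pig_pct = 100 * .data$car / total)
}

#' Percent reduction relative to a reference
#'
#' `100 * (reference - value) / reference`; e.g. the chlorophyll loss of a
#' mutant relative to wild type.
#'
#' @param reference Positive reference value(s).
#' @param value Value(s) to compare.
#' @return Percent reduction (negative if `value > reference`).
#' @export
#' @examples
#' percent_reduction(3.70, 1.01)  # 72.7
percent_reduction <- function(reference, value) {
  if (any(reference <= 0, na.rm = TRUE)) {
    abort("`reference` must be positive.")
  }
  100 * (reference - value) / reference
}
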