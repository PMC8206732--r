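#' Water, drought and heat stress indices from the four-run yields
#'
#' The indices are proportional yield losses: `wsi = 1 - yw/yp` (seasonal
#' water limitation, a source-capacity stress), `dsi = 1 - ywd/yw` and
#' `hsi = 1 - ywh/yw` (drought and heat around flowering, sink-capacity
#' stresses acting on grain number). Tiny negative values from floating
#' error are clamped to 0; a genuine ordering violation (ywd or ywh above
#' yw, or yw above yp, beyond tolerance) signals a simulator bug and errors.
#'
#' @param yields A data frame with numeric columns `yp`, `yw`, `ywd`, `ywh`
#'   (t/ha), one row per season. Rows with a `failed` column set to `TRUE`
#'   are dropped with a warning.
#' @param tol Ordering tolerance (fraction) before an invariant violation is
#'   raised.
#' @return The input tibble with `wsi`, `dsi`, `hsi` columns appended, all
#'   in [0, 1].
#' @examples
#' compute_indices(tibble::tibble(yp = 10, yw = 8, ywd = 7.2, ywh = 8))
#' @export
compute_indices <- function(yields, tol = 1e-6) {
  stopifnot(is.data.frame(yields))
  if ("failed" %in% names(yields) && any(yields$failed)) {
    warn(sprintf("dropping %d failed season(s) from index computation",
                 sum(yields$failed)))
    yields <- dplyr::filter(yields, !.data$failed)
  }
  if (nrow(yields) == 0) abort("no successful seasons to compute indices from")
  if (any(yields$yp <= 0) || any(yields$yw <= 0)) {
    abort("indices are undefined when yp or yw is zero")
  }
  clamp01 <- function(x, nm) {
    if (any(x < -tol)) {
      abort(paste0(nm, " violates the yield-ordering invariant; ",
                   "this indicates a simulator bug"))
    }
    pmin(1, pmax(0, x))
  }
  dplyr::mutate(tibble::as_tibble(yields),
    wsi = clamp01(1 - .data$yw / .data$yp, "wsi"),
    dsi = clamp01(1 - .data$ywd / .data$yw, "dsi"),
    hsi = clamp01(1 - .data$ywh / .data$yw, "hsi")
  )
}

#' Empirical percentile with linear interpolation
#'
#' The empirical quantile that interpolates linearly between order
#' statistics at position `1 + q(n-1)` (the convention used for every
#' percentile, boxplot statistic and risk metric in this package).
#'
#' @param sample Non-empty numeric vector.
#' @param q Probability (or vector of probabilities) in [0, 1].
#' @return Numeric quantile(s), monotone in `q`.
#' @examples
#' percentile(1:100, 0.95)
#' @export
percentile <- function(sample, q) {
  if (length(sample) == 0) abort("sample must be non-empty")
  if (any(q < 0 | q > 1)) abort("q must lie in [0, 1]")
  unname(quantile(sample, probs = q, type = 7, names = FALSE))
}

#' Coefficient of variation of yearly yields
#'
#' @param yields Numeric vector of yields (t/ha), length >= 2, positive mean.
#' @return CV in percent: 100 * sample sd (n-1 denominator) / mean.
#' @examples
#' coefficient_of_variation(c(8, 10, 12))
#' @export
coefficient_of_variation <- function(yields) {
  yields <- yields[!is.na(yields)]
  if (length(yields) < 2) abort("need at least 2 yields")
  m <- mean(yields)
  if (m <= 0) abort("mean yield must be positive")
  100 * sd(yields) / m
}

#' Risk percentiles of a yearly stress-index sample
#'
#' Summarizes the yearly distribution of one stress index by its 50th,
#' 75th, 90th and 95th percentiles — the loss levels expected to recur every
#' 2, 4, 10 and 20 years respectively (see [recurrence_interval()]).
#'
#' @param indices A data frame of yearly indices (as from
#'   [compute_indices()]).
#' @param which One of `"wsi"`, `"dsi"`, `"hsi"`.
#' @return A one-row tibble: `index`, `p50`, `p75`, `p90`, `p95`.
#' @examples
#' ix <- compute_indices(tibble::tibble(yp = 10, yw = runif(50, 7, 10),
#'                                      ywd = 7, ywh = 7))
#' index_percentiles(ix, "wsi")
#' @export
index_percentiles <- function(indices, which = c("wsi", "dsi", "hsi")) {
  which <- match.arg(which)
  x <- indices[[which]]
  x <- x[!is.na(x)]
  if (length(x) == 0) abort("no index values")
  if (length(x) < 20) warn("fewer than 20 years; percentiles will be noisy")
  p <- percentile(x, c(0.50, 0.75, 0.90, 0.95))
  tibble::tibble(index = which, p50 = p[1], p75 = p[2], p90 = p[3], p95 = p[4])
}
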