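# Half-up rounding (round() in R rounds half to even); used for the printed
# percentages and ratios in cohort description tables.
round_half_up <- function(x, digits = 1L) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5 + 1e-9) / f
}

#' Prevalence of a clinical feature
#'
#' Percent present among documented cases, rounded half-up to one decimal, as
#' reported in clinical-findings tables ("frequency of presence / total
#' number documented").
#'
#' @param present Count of participants with the feature present.
#' @param documented Count of participants in whom the feature was documented.
#' @return Percentage(s), one decimal.
#' @examples
#' prevalence(22, 29)  # 75.9
#' @export
prevalence <- function(present, documented) {
  if (any(!is.finite(present)) || any(!is.finite(documented)) ||
      any(present < 0) || any(present != round(present)) ||
      any(documented != round(documented)))
    stop("counts must be non-negative integers")
  if (any(documented == 0)) stop("undefined prevalence: documented count is zero")
  if (any(present > documented)) stop("'present' cannot exceed 'documented'")
  round_half_up(100 * present / documented, 1L)
}

#' Ratio of two counts
#'
#' E.g. the female:male ratio of a cohort, rounded half-up to one decimal.
#'
#' @param count_a,count_b Non-negative counts; `count_b` must be positive.
#' @return `count_a / count_b` rounded to one decimal.
#' @examples
#' sex_ratio(56, 35)  # 1.6
#' @export
sex_ratio <- function(count_a, count_b) {
  if (any(!is.finite(count_a)) || any(!is.finite(count_b)) || any(count_a < 0))
    stop("counts must be non-negative numbers")
  if (any(count_b <= 0)) stop("denominator count must be positive")
  round_half_up(count_a / count_b, 1L)
}

#' Median and interquartile range
#'
#' Quartiles by linear interpolation between order statistics (quantile
#' positions `(n - 1) * q + 1`, i.e. type-7).
#'
#' @param values Numeric vector; missing values dropped.
#' @return Named vector `c(median, q1, q3)`.
#' @export
median_iqr <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) stop("no non-missing values")
  q <- stats::quantile(values, probs = c(0.5, 0.25, 0.75),
                       type = 7, names = FALSE)
  c(median = q[1L], q1 = q[2L], q3 = q[3L])
}

#' Convert a normative scaled score to a z-score
#'
#' Age-adjusted normative scaled scores (MOANS convention: mean 10, SD 3)
#' are converted as `z = (scaled - 10) / 3`; a scaled score of 1 maps to
#' z = -3.
#'
#' @param scaled Scaled score(s) on the mean-10 / SD-3 scale.
#' @return z-score(s).
#' @export
moans_to_z <- function(scaled) {
  if (!is.numeric(scaled)) stop("'scaled' must be numeric")
  (scaled - 10) / 3
}

#' Floor coding for timed tests
#'
#' Participants unable to complete a timed test (e.g. Trail Making within the
#' maximum allowed time) are coded at the normative floor, a scaled score of
#' 1, i.e. z = -3; completed tests are converted with [moans_to_z()].
#'
#' @param scaled Scaled score(s); ignored where `completed` is `FALSE`.
#' @param completed Logical: was the test completed in time?
#' @return z-score(s).
#' @export
code_timed_floor <- function(scaled, completed) {
  completed <- rep_len(as.logical(completed), length(scaled))
  ifelse(completed, moans_to_z(scaled), -3)
}

#' Classify a PET SUVR as positive or negative
#'
#' Strict threshold on the standardized uptake value ratio: amyloid > 1.42,
#' tau > 1.23.
#'
#' @param suvr Positive SUVR value(s).
#' @param tracer `"amyloid"` or `"tau"` (scalar).
#' @return Character vector `"positive"` / `"negative"`.
#' @examples
#' suvr_classify(1.43, "amyloid")
#' @export
suvr_classify <- function(suvr, tracer = c("amyloid", "tau")) {
  tracer <- match.arg(tracer)
  if (!is.numeric(suvr) || any(!is.finite(suvr)) || any(suvr <= 0))
    stop("'suvr' must be positive")
  cutoff <- c(amyloid = 1.42, tau = 1.23)[[tracer]]
  ifelse(suvr > cutoff, "positive", "negative")
}
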