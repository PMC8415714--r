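# Group statistics for morphometric measurements expressed as percentages.

#' Arcsine square-root transform of a proportion
#'
#' The variance-stabilizing transform conventionally applied to
#' percentage-valued morphometric data before t-tests:
#' `asin(sqrt(p))`, in radians. Percent inputs must be divided by 100 first.
#'
#' @param p proportion(s) in `[0, 1]`.
#' @return Transformed values in radians, in `[0, pi/2]`.
#' @export
arcsine_transform <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("proportions must lie in [0, 1]", call. = FALSE)
  asin(sqrt(p))
}

#' Compare two groups of percentage measurements
#'
#' Welch two-sample t-test (unequal variances, Welch-Satterthwaite degrees
#' of freedom) on optionally arcsine-transformed proportions. Group means
#' and standard deviations are reported on the original percent scale
#' (the spread reported is the SD, not the SE).
#'
#' @param a,b numeric samples of percentages (each of length >= 2).
#' @param transform apply [arcsine_transform()] to `value / 100` first.
#' @return `list(mean_a, sd_a, mean_b, sd_b, t, df, p_value, transform)`.
#' @export
compare_groups <- function(a, b, transform = TRUE) {
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least two observations", call. = FALSE)
  xa <- if (transform) arcsine_transform(a / 100) else a
  xb <- if (transform) arcsine_transform(b / 100) else b
  if (sd(xa) == 0 && sd(xb) == 0 && mean(xa) == mean(xb)) {
    tt <- list(statistic = c(t = 0), parameter = c(df = length(a) + length(b) - 2),
               p.value = 1)
  } else {
    tt <- t.test(xa, xb, var.equal = FALSE)
  }
  list(mean_a = mean(a), sd_a = sd(a),
       mean_b = mean(b), sd_b = sd(b),
       t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, transform = transform)
}
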