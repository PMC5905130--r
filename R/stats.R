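# Treatment-effect statistics for crossover-frequency series.

#' Normalize a treatment series to its control
#'
#' Divides every value by the mean of the control series so data sets can be
#' combined across batches; the control itself normalizes to mean 1.  Units
#' cancel, so raw fractions and percentages give identical output.
#'
#' @param series Numeric vector of per-plant crossover frequencies.
#' @param control Numeric vector for the control treatment (mean must be
#'   positive).
#' @return Normalized numeric vector.
#' @examples
#' normalize_to_control(c(17), c(10, 10, 10))
#' @export
normalize_to_control <- function(series, control) {
  if (!length(series) || any(!is.finite(series)) || any(!is.finite(control)))
    stop("series must be finite and non-empty", call. = FALSE)
  m <- mean(control)
  if (!is.finite(m) || m <= 0)
    stop("control mean must be positive", call. = FALSE)
  series / m
}

#' Welch's unequal-variance t-test
#'
#' Two-sided two-sample t-test without the equal-variance assumption
#' (Welch-Satterthwaite degrees of freedom), the heteroscedastic t-test
#' conventionally used to compare treatment against control at a 0.05
#' threshold.  Thin wrapper over [stats::t.test()] that enforces the
#' preconditions.
#'
#' @param a,b Numeric samples, each with n >= 2 and nonzero variance.
#' @return List with `t`, `df`, `p` (two-sided), plus the underlying
#'   `htest` object as `test`.
#' @examples
#' welch_t(c(10, 11, 12, 13), c(20, 21, 22, 23))
#' @export
welch_t <- function(a, b) {
  for (s in list(a, b)) {
    if (length(s) < 2L || any(!is.finite(s)))
      stop("each sample needs at least two finite values", call. = FALSE)
    if (stats::var(s) == 0)
      stop("degenerate sample: zero variance", call. = FALSE)
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, test = ht)
}

#' Normality diagnostics for a crossover-frequency series
#'
#' Histogram and normal Q-Q plot side by side, a visual check (not a gate)
#' before t-testing.
#'
#' @param x Numeric vector.
#' @param main Title prefix.
#' @return Invisibly, `x`.
#' @export
plot_normality <- function(x, main = deparse(substitute(x))) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::hist(x, main = paste(main, "- histogram"), xlab = "value")
  stats::qqnorm(x, main = paste(main, "- normal Q-Q"))
  stats::qqline(x)
  invisible(x)
}
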