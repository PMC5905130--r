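# Gamete and seed-class labels used throughout the package.  The reporter
# line carries GFP and RFP transgenes in cis on one parental chromosome
# ("GR"); the other parent contributes the null chromosome ("nn").  A single
# meiotic crossover between the two insertions produces the recombinant
# gametes "Gn" and "nR".
GAMETE_CLASSES <- c("GR", "nn", "Gn", "nR")
SEED_CLASSES <- c("RED_ONLY", "GREEN_ONLY", "BOTH", "NONE")

check_rfrac <- function(r) {
  if (!is.numeric(r) || length(r) != 1L || !is.finite(r) || r < 0 || r > 0.5)
    stop("recombination fraction 'r' must be a single value in [0, 0.5], got ",
         deparse(substitute(r)), " = ", format(r), call. = FALSE)
  invisible(r)
}

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Gamete-class frequencies of an F1 hybrid with two linked markers in cis
#'
#' An F1 plant heterozygous for a chromosome carrying both dominant
#' fluorescence transgenes (GFP and RFP) in coupling phase produces four
#' gamete classes: the two parental configurations (both markers, `GR`;
#' neither, `nn`) each with frequency \eqn{(1-r)/2}, and the two single-marker
#' recombinants (`Gn`, `nR`) each with frequency \eqn{r/2}, where \eqn{r} is
#' the recombination fraction between the insertion sites.
#'
#' @param r Recombination fraction between the two marker loci, in
#'   \eqn{[0, 0.5]}.
#' @return Named numeric vector of the four gamete-class probabilities
#'   (`GR`, `nn`, `Gn`, `nR`), summing to 1, with the input `r` kept as an
#'   attribute.
#' @examples
#' gamete_freqs(0.16)
#' @seealso [seed_class_probs()], [simulate_f2()]
#' @export
gamete_freqs <- function(r) {
  check_rfrac(r)
  p <- c(GR = (1 - r) / 2, nn = (1 - r) / 2, Gn = r / 2, nR = r / 2)
  attr(p, "r") <- r
  p
}

#' Expected F2 seed-class fractions under the coupling-phase model
#'
#' Selfing the F1 pairs two independent gametes per seed.  Both transgenes
#' are dominant at the seed level (seed-storage-protein promoter, embryo
#' expressed), so a seed fluoresces in a channel iff at least one of its two
#' gametes carries the corresponding transgene.  With \eqn{q = (1-r)/2} the
#' expected class fractions are
#' \deqn{p_{none} = q^2,\quad p_{red only} = p_{green only} = 1/4 - q^2,\quad
#'       p_{both} = 1/2 + q^2.}
#'
#' `seed_class_probs()` evaluates this closed form; `seed_class_probs_enum()`
#' obtains the same fractions by brute-force enumeration of all 16 ordered
#' gamete pairs and serves as an independent cross-check.
#'
#' @inheritParams gamete_freqs
#' @return Named numeric vector over `RED_ONLY`, `GREEN_ONLY`, `BOTH`,
#'   `NONE`, summing to 1.
#' @examples
#' seed_class_probs(0.16)
#' all.equal(seed_class_probs(0.3), seed_class_probs_enum(0.3))
#' @export
seed_class_probs <- function(r) {
  check_rfrac(r)
  q <- (1 - r) / 2
  c(RED_ONLY = 0.25 - q^2, GREEN_ONLY = 0.25 - q^2,
    BOTH = 0.5 + q^2, NONE = q^2)
}

#' @rdname seed_class_probs
#' @export
seed_class_probs_enum <- function(r) {
  p <- gamete_freqs(r)
  red <- c(GR = TRUE, nn = FALSE, Gn = FALSE, nR = TRUE)
  green <- c(GR = TRUE, nn = FALSE, Gn = TRUE, nR = FALSE)
  out <- c(RED_ONLY = 0, GREEN_ONLY = 0, BOTH = 0, NONE = 0)
  for (g1 in GAMETE_CLASSES) {
    for (g2 in GAMETE_CLASSES) {
      cls <- classify_genotype(red[g1] || red[g2], green[g1] || green[g2])
      out[cls] <- out[cls] + p[g1] * p[g2]
    }
  }
  out
}

# Seed phenotype from dominant marker presence.
classify_genotype <- function(has_red, has_green) {
  if (has_red && has_green) "BOTH"
  else if (has_red) "RED_ONLY"
  else if (has_green) "GREEN_ONLY"
  else "NONE"
}

#' Seed-class count container
#'
#' Tallies of the four F2 seed phenotype classes for one image or one pooled
#' sample.  Counts may be non-integer (e.g. exact expected counts) but must
#' be non-negative and finite.
#'
#' @param red_only,green_only,both,none Class tallies (single non-negative
#'   numbers).
#' @param x Object to convert: a `seed_counts`, a numeric vector of length 4
#'   (ordered or named `red_only`, `green_only`, `both`, `none`), or a
#'   list/data.frame row with `n_`-prefixed or bare component names.
#' @return A `seed_counts` object: named numeric vector of length 4.
#' @examples
#' seed_counts(736, 736, 6764, 1764)
#' @export
seed_counts <- function(red_only, green_only, both, none) {
  x <- c(red_only = red_only, green_only = green_only,
         both = both, none = none)
  if (!is.numeric(x) || length(x) != 4L || any(!is.finite(x)) || any(x < 0))
    stop("seed counts must be four finite non-negative numbers", call. = FALSE)
  structure(x, class = "seed_counts")
}

#' @rdname seed_counts
#' @export
as_seed_counts <- function(x) {
  if (inherits(x, "seed_counts")) return(x)
  if (is.data.frame(x)) x <- as.list(x[1L, , drop = FALSE])
  if (is.list(x)) {
    nm <- names(x)
    pick <- function(key) {
      hit <- match(c(paste0("n_", key), key), nm)
      hit <- hit[!is.na(hit)]
      if (!length(hit)) stop("missing seed-class component '", key, "'",
                             call. = FALSE)
      as.numeric(x[[hit[1L]]])
    }
    return(seed_counts(pick("red_only"), pick("green_only"),
                       pick("both"), pick("none")))
  }
  x <- as.numeric(x)
  if (length(x) != 4L)
    stop("expected four seed-class counts", call. = FALSE)
  seed_counts(x[1L], x[2L], x[3L], x[4L])
}

#' @export
print.seed_counts <- function(x, ...) {
  cat("F2 seed-class counts (n =", format(sum(x)), "):\n")
  print(unclass(x), ...)
  invisible(x)
}

#' Fit the two-marker F2 segregation model to seed-class counts
#'
#' Estimates the recombination fraction between two dominant, in-cis linked
#' fluorescence markers from the F2 seed phenotype tallies.  Only the
#' single-colored seeds reveal crossovers directly; recombinant chromosomes
#' hidden in double-colored seeds are accounted for by inverting the expected
#' single-color fraction \eqn{f(r) = 1/2 - (1-r)^2/2}:
#' \deqn{\hat r = 1 - \sqrt{1 - 2f},\qquad
#'       f = (n_{red only} + n_{green only}) / n_{total}.}
#' Map distances are reported under the identity (\eqn{100\hat r}), Haldane
#' and Kosambi mapping functions.  The standard error of \eqn{\hat r} follows
#' from the delta method, \eqn{SE(\hat r) = SE(f)/\sqrt{1-2f}} with binomial
#' \eqn{SE(f)}.
#'
#' `f > 0.375` is an error: it implies \eqn{\hat r > 0.5}, outside the model
#' (it is never silently clamped).  Double crossovers between the marker loci
#' are not modelled; they regenerate parental marker configurations and are
#' unidentifiable from two markers.
#'
#' @param counts Seed-class tallies: a [seed_counts] object or anything
#'   [as_seed_counts()] accepts.
#' @return An object of class `"xo_fit"` with components `counts`, `n`,
#'   `f_single`, `r_hat`, `se_r`, `cm` (named vector of identity/Haldane/
#'   Kosambi map distances in cM) and `call`.  Supports `print()`,
#'   `summary()`, `coef()`, `vcov()`, `confint()`, `predict()`,
#'   `residuals()`, `simulate()` and `plot()`.
#' @examples
#' fit <- xo_fit(seed_counts(736, 736, 6764, 1764))
#' fit
#' coef(fit)
#' predict(fit)
#' @export
xo_fit <- function(counts) {
  counts <- as_seed_counts(counts)
  n <- sum(counts)
  if (n <= 0)
    stop("empty input: total seed count is zero", call. = FALSE)
  f <- unname((counts[["red_only"]] + counts[["green_only"]]) / n)
  if (f > 0.375 + 1e-9)
    stop(sprintf(paste0(
      "single-color fraction f = %.4f exceeds the model maximum 0.375 ",
      "(would imply r > 0.5); check thresholds and counts"), f),
      call. = FALSE)
  f <- min(f, 0.375)
  r <- 1 - sqrt(1 - 2 * f)
  se_f <- sqrt(f * (1 - f) / n)
  se_r <- if (f < 0.375) se_f / sqrt(1 - 2 * f) else Inf
  cm <- c(identity = map_distance(r, "identity"),
          haldane = map_distance(r, "haldane"),
          kosambi = map_distance(r, "kosambi"))
  structure(list(counts = counts, n = n, f_single = f, r_hat = r,
                 se_r = se_r, cm = cm, call = match.call()),
            class = "xo_fit")
}

#' Genetic map distance from a recombination fraction
#'
#' Converts a recombination fraction to a map distance in centimorgan under a
#' mapping function of choice: identity (\eqn{100r}), Haldane
#' (\eqn{-50\ln(1-2r)}; no interference) or Kosambi
#' (\eqn{25\ln\frac{1+2r}{1-2r}}; partial interference).  At \eqn{r = 0.5}
#' Haldane and Kosambi distances are infinite; `Inf` is returned.
#'
#' @param r Recombination fraction(s) in \eqn{[0, 0.5]} (vectorized).
#' @param method One of `"identity"`, `"haldane"`, `"kosambi"`.
#' @return Map distance(s) in cM.
#' @examples
#' map_distance(0.16, "haldane")   # 19.283 cM
#' map_distance(0.16, "kosambi")   # 16.582 cM
#' @export
map_distance <- function(r, method = c("identity", "haldane", "kosambi")) {
  method <- match.arg(method)
  if (!is.numeric(r) || any(!is.finite(r)) || any(r < 0) || any(r > 0.5))
    stop("recombination fraction 'r' must be in [0, 0.5]", call. = FALSE)
  switch(method,
    identity = 100 * r,
    haldane = ifelse(r == 0.5, Inf, -50 * log(1 - 2 * r)),
    kosambi = ifelse(r == 0.5, Inf, 25 * log((1 + 2 * r) / (1 - 2 * r))))
}

#' Simulate F2 seed-class counts
#'
#' Draws seed-class tallies for `n` F2 seeds at recombination fraction `r`.
#' The default draws a single multinomial over the four seed classes
#' (statistically identical to pairing two independent gametes per seed and
#' classifying by dominance); `method = "gamete"` performs the explicit
#' per-gamete simulation and is kept as an independent route for testing.
#'
#' @inheritParams gamete_freqs
#' @param n Number of seeds (>= 1).
#' @param seed Optional RNG seed for reproducibility; the caller's RNG state
#'   is left untouched.
#' @param method `"multinomial"` (default) or `"gamete"`.
#' @return A [seed_counts] object summing to `n`.
#' @examples
#' simulate_f2(0.16, 1000, seed = 1)
#' @export
simulate_f2 <- function(r, n, seed = NULL,
                        method = c("multinomial", "gamete")) {
  check_rfrac(r)
  method <- match.arg(method)
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n < 1)
    stop("'n' must be a positive seed count", call. = FALSE)
  n <- as.integer(n)
  with_seed(seed, {
    if (method == "multinomial") {
      x <- as.vector(stats::rmultinom(1L, n, seed_class_probs(r)))
      seed_counts(x[1L], x[2L], x[3L], x[4L])
    } else {
      g <- gamete_freqs(r)
      g1 <- sample.int(4L, n, replace = TRUE, prob = g)
      g2 <- sample.int(4L, n, replace = TRUE, prob = g)
      red <- c(TRUE, FALSE, FALSE, TRUE)
      green <- c(TRUE, FALSE, TRUE, FALSE)
      has_r <- red[g1] | red[g2]
      has_g <- green[g1] | green[g2]
      seed_counts(sum(has_r & !has_g), sum(!has_r & has_g),
                  sum(has_r & has_g), sum(!has_r & !has_g))
    }
  })
}

# ---- xo_fit methods ---------------------------------------------------------

#' @export
print.xo_fit <- function(x, digits = 4, ...) {
  cat("Two-marker F2 segregation fit\n")
  cat(sprintf("  seeds: %s (red-only %s, green-only %s, both %s, none %s)\n",
              format(x$n), format(x$counts[["red_only"]]),
              format(x$counts[["green_only"]]), format(x$counts[["both"]]),
              format(x$counts[["none"]])))
  cat(sprintf("  single-color fraction f = %s\n",
              format(x$f_single, digits = digits)))
  cat(sprintf("  recombination fraction r = %s (SE %s)\n",
              format(x$r_hat, digits = digits),
              format(x$se_r, digits = 3)))
  cat(sprintf("  map distance: %s cM (Haldane), %s cM (Kosambi), %s cM (identity)\n",
              format(x$cm[["haldane"]], digits = digits),
              format(x$cm[["kosambi"]], digits = digits),
              format(x$cm[["identity"]], digits = digits)))
  invisible(x)
}

#' @export
coef.xo_fit <- function(object, ...) c(r = object$r_hat)

#' @export
vcov.xo_fit <- function(object, ...) {
  matrix(object$se_r^2, 1, 1, dimnames = list("r", "r"))
}

#' @export
confint.xo_fit <- function(object, parm = "r", level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  lo <- max(0, object$r_hat - z * object$se_r)
  hi <- min(0.5, object$r_hat + z * object$se_r)
  out <- matrix(c(lo, hi), 1, 2,
                dimnames = list("r", sprintf("%.1f %%", 100 *
                  c((1 - level) / 2, 1 - (1 - level) / 2))))
  out
}

#' Expected seed-class composition at the fitted recombination fraction
#'
#' @param object An [xo_fit] object.
#' @param n Seed total for `type = "count"` (defaults to the fitted total).
#' @param type Return class fractions or expected counts.
#' @param ... Unused.
#' @return Named numeric vector over the four seed classes.
#' @export
predict.xo_fit <- function(object, n = object$n,
                           type = c("fraction", "count"), ...) {
  type <- match.arg(type)
  p <- seed_class_probs(object$r_hat)
  if (type == "fraction") p else p * n
}

#' @export
residuals.xo_fit <- function(object, type = c("raw", "pearson"), ...) {
  type <- match.arg(type)
  obs <- unclass(object$counts)
  names(obs) <- SEED_CLASSES
  exp_ <- seed_class_probs(object$r_hat) * object$n
  res <- obs - exp_
  if (type == "pearson") res <- res / sqrt(pmax(exp_, .Machine$double.eps))
  res
}

#' @export
simulate.xo_fit <- function(object, nsim = 1, seed = NULL, n = object$n,
                            ...) {
  with_seed(seed, {
    out <- t(vapply(seq_len(nsim), function(i)
      unclass(simulate_f2(object$r_hat, n)), numeric(4L)))
    as.data.frame(out)
  })
}

#' @export
summary.xo_fit <- function(object, ...) {
  obs <- unclass(object$counts)
  names(obs) <- SEED_CLASSES
  p <- seed_class_probs(object$r_hat)
  tab <- data.frame(observed = obs, expected = p * object$n,
                    fraction = obs / object$n, model_fraction = p)
  # goodness of fit: 4 classes, 1 estimated parameter -> 2 df
  chi2 <- sum((obs - p * object$n)^2 / pmax(p * object$n,
                                            .Machine$double.eps))
  structure(list(fit = object, table = tab, chisq = chi2, df = 2L,
                 p_gof = stats::pchisq(chi2, 2L, lower.tail = FALSE),
                 ci = confint(object)),
            class = "summary.xo_fit")
}

#' @export
print.summary.xo_fit <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat(sprintf("  95%% CI for r: [%s, %s]\n",
              format(x$ci[1], digits = digits),
              format(x$ci[2], digits = digits)))
  cat("\nObserved vs expected class composition:\n")
  print(round(x$table, digits))
  cat(sprintf("\nGoodness of fit: X-squared = %s, df = %d, p = %s\n",
              format(x$chisq, digits = digits), x$df,
              format.pval(x$p_gof, digits = 3)))
  invisible(x)
}

#' @export
plot.xo_fit <- function(x, ...) {
  obs <- unclass(x$counts) / x$n
  exp_ <- seed_class_probs(x$r_hat)
  m <- rbind(observed = obs, expected = exp_)
  colnames(m) <- c("RedOnly", "GreenOnly", "Both", "None")
  graphics::barplot(m, beside = TRUE, legend.text = rownames(m),
                    ylab = "fraction of seeds",
                    main = sprintf("F2 seed classes (r = %.3f)", x$r_hat),
                    ...)
  invisible(x)
}
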