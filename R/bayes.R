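# Bayes factors: JZS independent-samples t-test (Cauchy prior on the
# standardized effect size) and Pearson-correlation test (stretched-beta
# prior on rho), both by adaptive quadrature, plus prior-width robustness
# curves and the conventional evidence categories.

#' Evidence category for a Bayes factor
#'
#' The conventional scale: anecdotal below 3, moderate [3, 10), strong
#' [10, 30), very strong [30, 100), extreme at or above 100.
#'
#' @param bf a positive Bayes factor (BF10)
#' @return category string
#' @examples
#' evidenceCategory(5.6)   # "moderate"
#' evidenceCategory(2343)  # "extreme"
#' @export
evidenceCategory <- function(bf) {
  stopifnot(is.finite(bf), bf > 0)
  if (bf < 3) "anecdotal"
  else if (bf < 10) "moderate"
  else if (bf < 30) "strong"
  else if (bf < 100) "very_strong"
  else "extreme"
}

# Marginal likelihood ratio for the JZS t-test: integrate the noncentral-t
# likelihood of the observed t over the (possibly truncated) Cauchy prior
# on the standardized effect size delta. dt(., ncp) warns about its ~1e-8
# precision; that is far inside the factor-level tolerances used here.
.jzsBF <- function(t, n1, n2, width, side) {
  df <- n1 + n2 - 2
  neff <- sqrt(n1 * n2 / (n1 + n2))
  f <- function(d) stats::dt(t, df, ncp = d * neff) * stats::dcauchy(d, 0, width)
  m1 <- suppressWarnings(switch(side,
    two_sided = stats::integrate(f, -Inf, Inf, rel.tol = 1e-9,
                                 abs.tol = 0)$value,
    greater = 2 * stats::integrate(f, 0, Inf, rel.tol = 1e-9,
                                   abs.tol = 0)$value,
    less = 2 * stats::integrate(f, -Inf, 0, rel.tol = 1e-9,
                                abs.tol = 0)$value,
    stop("side must be two_sided, greater or less")))
  m1 / stats::dt(t, df)
}

#' JZS Bayesian independent-samples t-test
#'
#' Computes the pooled-variance t statistic, from raw samples or printed
#' group summaries, and evaluates the Bayes factor in favor of a group
#' difference under a Cauchy prior on the standardized effect size
#' (default width 0.707, the common software default). One-sided
#' hypotheses use the truncated prior; `side = "greater"` means the second
#' group's mean exceeds the first's.
#'
#' @param x,y raw samples for the two groups (alternative to summaries)
#' @param m1,sd1,n1,m2,sd2,n2 group summaries (alternative to raw samples)
#' @param width Cauchy prior width on the effect size
#' @param side "two_sided", "greater" or "less"
#' @param robustnessWidths optional width grid to attach a robustness curve
#' @return a [BFResult-class]
#' @examples
#' jzsTtestBF(m1 = -4.93, sd1 = 2.69, n1 = 16, m2 = -0.88, sd2 = 1.27, n2 = 16)
#' @export
jzsTtestBF <- function(x = NULL, y = NULL, m1 = NULL, sd1 = NULL, n1 = NULL,
                       m2 = NULL, sd2 = NULL, n2 = NULL,
                       width = sqrt(2) / 2, side = "two_sided",
                       robustnessWidths = NULL) {
  if (!is.null(x)) {
    if (length(x) < 2 || length(y) < 2) stop("need n >= 2 per group")
    m1 <- mean(x); sd1 <- stats::sd(x); n1 <- length(x)
    m2 <- mean(y); sd2 <- stats::sd(y); n2 <- length(y)
  }
  if (any(vapply(list(m1, sd1, n1, m2, sd2, n2), is.null, TRUE)))
    stop("supply either raw samples or full summaries")
  if (n1 < 2 || n2 < 2) stop("need n >= 2 per group")
  if (!(width > 0)) stop("prior width must be positive")
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
  if (sp2 <= 0) stop("zero pooled variance")
  t <- (m2 - m1) / sqrt(sp2 * (1 / n1 + 1 / n2))
  bf <- .jzsBF(t, n1, n2, width, side)
  rob <- if (is.null(robustnessWidths)) data.frame(width = numeric(),
                                                   bf10 = numeric())
  else data.frame(width = robustnessWidths,
                  bf10 = vapply(robustnessWidths,
                                function(w) .jzsBF(t, n1, n2, w, side), 0))
  new("BFResult", bf10 = bf,
      prior = list(family = "cauchy_on_effect_size", width = width, side = side),
      statistic = list(t = t, df = n1 + n2 - 2, n1 = n1, n2 = n2),
      robustness = rob, category = evidenceCategory(bf))
}

# Log-likelihood of an observed Pearson r given rho, up to rho-free
# constants, via the integral representation of the exact sampling
# density: f(r | rho, n) proportional to
#   (1 - rho^2)^((n-1)/2) * integral_0^inf (cosh(w) - rho * r)^-(n-1) dw.
.corrLogLik <- function(rho, r, n) {
  vapply(rho, function(p) {
    I <- stats::integrate(function(w) (cosh(w) - p * r)^(-(n - 1)),
                          0, Inf, rel.tol = 1e-10)$value
    (n - 1) / 2 * log(1 - p^2) + log(I)
  }, 0)
}

.corrBF <- function(r, n, width, side) {
  l0 <- .corrLogLik(0, r, n)
  prior <- function(p) stats::dbeta((p + 1) / 2, 1 / width, 1 / width) / 2
  f <- function(p) exp(.corrLogLik(p, r, n) - l0) * prior(p)
  switch(side,
    two_sided = stats::integrate(f, -1, 1, rel.tol = 1e-8)$value,
    greater = 2 * stats::integrate(f, 0, 1, rel.tol = 1e-8)$value,
    less = 2 * stats::integrate(f, -1, 0, rel.tol = 1e-8)$value,
    stop("side must be two_sided, greater or less"))
}

#' Bayesian Pearson-correlation test (stretched-beta prior)
#'
#' Bayes factor for a nonzero Pearson correlation under a stretched-beta
#' prior on rho: a beta(1/width, 1/width) distribution rescaled to
#' (-1, 1), the JASP convention, with default width 0.5. One-sided
#' variants truncate the prior.
#'
#' @param r observed Pearson correlation, |r| < 1
#' @param n number of pairs (>= 3)
#' @param width stretched-beta prior width
#' @param side "two_sided", "greater" or "less"
#' @param robustnessWidths optional width grid for a robustness curve
#' @return a [BFResult-class]
#' @examples
#' bayesCorrelationBF(0.55, 16)   # moderate evidence
#' @export
bayesCorrelationBF <- function(r, n, width = 0.5, side = "two_sided",
                               robustnessWidths = NULL) {
  if (abs(r) >= 1) stop("|r| = 1: infinite evidence, not representable")
  if (n < 3) stop("need n >= 3")
  if (!(width > 0)) stop("prior width must be positive")
  bf <- .corrBF(r, n, width, side)
  rob <- if (is.null(robustnessWidths)) data.frame(width = numeric(),
                                                   bf10 = numeric())
  else data.frame(width = robustnessWidths,
                  bf10 = vapply(robustnessWidths,
                                function(w) .corrBF(r, n, w, side), 0))
  new("BFResult", bf10 = bf,
      prior = list(family = "stretched_beta_on_correlation", width = width,
                   side = side),
      statistic = list(r = r, n = as.integer(n)),
      robustness = rob, category = evidenceCategory(bf))
}

#' Prior-width robustness curve for a Bayes factor
#'
#' Recomputes the Bayes factor of an existing result over a grid of prior
#' widths, keeping the statistic and sidedness fixed. The curve value at
#' the original width reproduces the single-call BF.
#'
#' @param bf a [BFResult-class]
#' @param widths width grid (the original width is added if absent)
#' @return the [BFResult-class] with its robustness slot filled
#' @export
bfRobustness <- function(bf, widths = c(0.1, 0.25, 0.5, sqrt(2) / 2, 1, 1.5, 2)) {
  if (!length(widths)) stop("width grid must be non-empty")
  widths <- sort(unique(c(widths, bf@prior$width)))
  st <- bf@statistic
  vals <- if (!is.null(st$t))
    vapply(widths, function(w) .jzsBF(st$t, st$n1, st$n2, w, bf@prior$side), 0)
  else
    vapply(widths, function(w) .corrBF(st$r, st$n, w, bf@prior$side), 0)
  initialize(bf, robustness = data.frame(width = widths, bf10 = vals))
}
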