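# Frequentist summary statistics recomputable from printed group tables.

#' Two-group one-way ANOVA from group summaries
#'
#' For two groups the one-way F equals the squared pooled-variance t, with
#' df (1, n1 + n2 - 2); partial eta squared is F / (F + df_error)
#' (equivalent to the sums-of-squares form in the two-group case).
#'
#' @param m1,sd1,n1,m2,sd2,n2 group means, SDs and sizes
#' @return list: F, df1, df2, etaPSquared, p
#' @examples
#' anovaFromSummary(-4.93, 2.69, 16, -0.88, 1.27, 16)  # F ~ 29.7
#' @export
anovaFromSummary <- function(m1, sd1, n1, m2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop("need n >= 2 per group")
  if (sd1 < 0 || sd2 < 0) stop("negative SD")
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
  if (sp2 <= 0) stop("zero pooled variance")
  t <- (m2 - m1) / sqrt(sp2 * (1 / n1 + 1 / n2))
  Fv <- t^2
  df2 <- n1 + n2 - 2
  list(F = Fv, df1 = 1, df2 = df2, etaPSquared = Fv / (Fv + df2),
       p = stats::pf(Fv, 1, df2, lower.tail = FALSE))
}

#' Pearson chi-squared test for a 2x2 table
#'
#' Reports the Pearson statistic both without and with the Yates
#' continuity correction.
#'
#' @param counts 2x2 matrix of non-negative integer counts
#' @return list: chi2, chi2Corrected, df, p, pCorrected
#' @examples
#' chisq2x2(matrix(c(12, 14, 4, 2), 2))
#' @export
chisq2x2 <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == 2)) stop("counts must be 2x2")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero marginal")
  un <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  co <- suppressWarnings(stats::chisq.test(counts, correct = TRUE))
  list(chi2 = unname(un$statistic), chi2Corrected = unname(co$statistic),
       df = 1, p = un$p.value, pCorrected = co$p.value)
}
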