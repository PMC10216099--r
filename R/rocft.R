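#' Published ROCFT group summaries
#'
#' Group means and standard deviations of the Rey-Osterrieth complex figure
#' test copy and recall z-scores for the NVLD and TD cohorts (n = 16 per
#' group). These printed summaries are the inputs to the summary-statistic
#' inference functions ([jzsTtestBF()], [anovaFromSummary()]) and to
#' [generateRocftScores()].
#'
#' @return data.frame with columns trial, group, mean, sd, n
#' @examples
#' rocftSummaries()
#' @export
rocftSummaries <- function() {
  data.frame(
    trial = rep(c("copy", "recall"), each = 2),
    group = rep(c("NVLD", "TD"), 2),
    mean  = c(-4.93, -0.88, -2.52, -0.56),
    sd    = c(2.69, 1.27, 1.15, 1.21),
    n     = 16L,
    stringsAsFactors = FALSE)
}

#' Simulate ROCFT copy/recall z-scores at the published group summaries
#'
#' Draws Gaussian copy and recall z-scores per group at the published means
#' and SDs, for exercising the Bayesian t-test stage at realistic effect
#' sizes. The composite is the mean of copy and recall, the "Rey index"
#' used as the behavioral prediction target.
#'
#' @param nPerGroup subjects per group (>= 2)
#' @param seed integer RNG seed
#' @param summaries data.frame in the format of [rocftSummaries()]; set an
#'   sd to 0 to make all draws equal the mean
#' @return data.frame: subjectID, group, copyZ, recallZ, composite
#' @examples
#' head(generateRocftScores(4, seed = 1))
#' @export
generateRocftScores <- function(nPerGroup, seed = 1, summaries = rocftSummaries()) {
  if (!(is.numeric(nPerGroup) && nPerGroup >= 2))
    stop("nPerGroup must be >= 2")
  nPerGroup <- as.integer(nPerGroup)
  set.seed(as.integer(seed))
  out <- lapply(c("NVLD", "TD"), function(g) {
    s <- summaries[summaries$group == g, ]
    copy <- stats::rnorm(nPerGroup, s$mean[s$trial == "copy"], s$sd[s$trial == "copy"])
    recall <- stats::rnorm(nPerGroup, s$mean[s$trial == "recall"], s$sd[s$trial == "recall"])
    data.frame(subjectID = sprintf("%s%02d", g, seq_len(nPerGroup)),
               group = g, copyZ = copy, recallZ = recall,
               composite = (copy + recall) / 2, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
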