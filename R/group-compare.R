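# Group inference on graph metric tables: one JZS Bayes factor per
# measure and scope, with direction and figure-style evidence tiers.

.bfOrNA <- function(a, b, width, side) {
  tryCatch(bf10(jzsTtestBF(x = b, y = a, width = width, side = side)),
           error = function(e) NA_real_)
}

#' Bayesian group comparison of graph metrics
#'
#' Runs a JZS independent-samples Bayes-factor t-test (H1: NVLD differs
#' from TD) per hemisphere-graph for the global measures and per node for
#' the nodal measures. Each row carries the group means, the direction of
#' the difference, the evidence category, and a display tier following the
#' convention of coloring strong effects (BF above `tiers[2]`) and
#' null-ish effects (BF below `tiers[1]`).
#'
#' @param tables output of [groupMetricTables()]
#' @param width Cauchy prior width
#' @param side prior sidedness, effect oriented as NVLD minus TD
#' @param tiers two BF thresholds for the display tiers (default 3 and 10)
#' @return list of data.frames `global` and `nodal` with columns scope
#'   descriptors, meanNVLD, meanTD, direction, bf10, evidence, tier
#' @export
compareGroupsGraphMetrics <- function(tables, width = sqrt(2) / 2,
                                      side = "two_sided", tiers = c(3, 10)) {
  compareOne <- function(d, keys) {
    if (length(unique(d$group)) < 2) stop("both groups are required")
    split.keys <- interaction(d[keys], drop = TRUE)
    rows <- lapply(split(d, split.keys), function(s) {
      a <- s$value[s$group == "NVLD"]; b <- s$value[s$group == "TD"]
      if (!length(a) || !length(b)) stop("group missing in a cell")
      bf <- .bfOrNA(a, b, width, side)
      out <- s[1, keys, drop = FALSE]
      out$meanNVLD <- mean(a); out$meanTD <- mean(b)
      out$direction <- if (mean(a) > mean(b)) "NVLD>TD"
                       else if (mean(a) < mean(b)) "NVLD<TD" else "equal"
      out$bf10 <- bf
      out$evidence <- if (is.na(bf)) NA_character_ else evidenceCategory(bf)
      out$tier <- if (is.na(bf)) NA_character_
                  else if (bf > tiers[2]) "red"
                  else if (bf < tiers[1]) "blue" else "intermediate"
      out
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  }
  list(global = compareOne(tables$global,
                           c("network", "hemisphere", "band", "measure")),
       nodal = compareOne(tables$nodal,
                          c("network", "band", "node", "role", "measure")))
}
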