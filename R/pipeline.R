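# Orchestration: simulate -> connectivity -> features -> classify /
# predict -> graphs -> group stats, under one config with stage toggles.

#' Assemble a full-study run configuration
#'
#' @param cohort a [cohortConfig()] describing the cohort (or, for real
#'   data, leave NULL and pass `cohortDir` pointing at a manifest layout
#'   readable by [readCohort()])
#' @param cohortDir directory with a pre-existing cohort (overrides
#'   `cohort` simulation when given)
#' @param windowS,overlap Welch parameters
#' @param retainFraction graph edge retention fraction
#' @param graphBands bands analyzed by the graph stage
#' @param tPriorWidth Cauchy width for the group-comparison t-tests
#' @param corrPriorWidth stretched-beta width for the prediction BFs
#' @param bfThreshold reporting threshold for predictions
#' @param svmCost,svrCost,svrEpsilon machine-learning settings
#' @param stages named logical list enabling classify / predict / graphs
#' @return config list of class "runConfig"
#' @export
runConfig <- function(cohort = demoCohortConfig(), cohortDir = NULL,
                      windowS = 2, overlap = 0.5, retainFraction = 0.10,
                      graphBands = c("beta", "gamma"),
                      tPriorWidth = sqrt(2) / 2, corrPriorWidth = 0.5,
                      bfThreshold = 3, svmCost = 1, svrCost = 1,
                      svrEpsilon = 0.1,
                      stages = list(classify = TRUE, predict = TRUE,
                                    graphs = TRUE)) {
  cfg <- list(cohort = cohort, cohortDir = cohortDir, windowS = windowS,
              overlap = overlap, retainFraction = retainFraction,
              graphBands = graphBands, tPriorWidth = tPriorWidth,
              corrPriorWidth = corrPriorWidth, bfThreshold = bfThreshold,
              svmCost = svmCost, svrCost = svrCost, svrEpsilon = svrEpsilon,
              stages = stages)
  class(cfg) <- "runConfig"
  cfg
}

#' Read a run configuration from YAML
#'
#' Flat keys mirror the [runConfig()] arguments; cohort keys live under
#' `cohort:` (nPerGroup, nRoi, fs, durationS, seed and a `couplings` list
#' of rows with group/network/hemisphere/band/role/a/jitterSD).
#'
#' @param path YAML file
#' @return config list of class "runConfig"
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  cohort <- if (is.null(y$cohort)) demoCohortConfig() else {
    cp <- y$cohort
    coup <- if (is.null(cp$couplings))
      couplingSpec("NVLD", "DAN", "both", "gamma", 0)[0, ]
    else do.call(rbind, lapply(cp$couplings, function(r)
      couplingSpec(r$group, r$network, r$hemisphere %||% "both", r$band,
                   r$a, r$role %||% "all", r$jitterSD %||% 0)))
    cohortConfig(nPerGroup = cp$nPerGroup %||% 16, nRoi = cp$nRoi %||% 24,
                 fs = cp$fs %||% 256, durationS = cp$durationS %||% 240,
                 couplings = coup,
                 behaviorLink = cp$behaviorLink %||%
                   list(network = "DAN", hemisphere = "R", band = "delta"),
                 behaviorBeta = cp$behaviorBeta %||% 0,
                 behaviorNoiseSD = cp$behaviorNoiseSD %||% 1,
                 seed = cp$seed %||% 1)
  }
  args <- y[setdiff(names(y), "cohort")]
  do.call(runConfig, c(list(cohort = cohort), args))
}

#' Run the full resting-state connectivity study
#'
#' Simulates (or loads) the cohort, estimates per-band coherence
#' matrices, and runs the enabled stages: leave-one-subject-out SVM
#' discrimination over the network x hemisphere x band grid, per-group
#' SVR behavior prediction with Bayesian-correlation filtering and
#' robustness curves, and weighted-graph topology metrics with Bayesian
#' group comparison. Deterministic under the cohort seed.
#'
#' @param config a [runConfig()]
#' @param outDir optional directory to write the report bundle to
#' @return report list (meta, scores, accuracy, predictions, graphMetrics,
#'   graphStats)
#' @examples
#' \dontrun{
#' rep <- runFullStudy(runConfig(cohort = demoCohortConfig(seed = 0)))
#' }
#' @export
runFullStudy <- function(config, outDir = NULL) {
  stopifnot(inherits(config, "runConfig"))
  stage <- function(name) isTRUE(config$stages[[name]])
  wrap <- function(name, expr) tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))

  coh <- wrap("simulate", if (!is.null(config$cohortDir))
    readCohort(config$cohortDir) else generateCohort(config$cohort))
  recs <- coh$recordings
  groups <- vapply(recs, function(r) r@group, "")
  bands <- config$cohort$bands %||% defaultBands()
  networks <- networkDefinitions(roiLabels = roiLabels(recs[[1]]))
  seed <- config$cohort$seed %||% 1L

  cmBySubject <- wrap("connectivity", lapply(recs, function(r)
    connectivityMatrices(r, bands = bands, windowS = config$windowS,
                         overlap = config$overlap)))

  netGrid <- expand.grid(network = c("DAN", "VAN"), hemisphere = c("L", "R"),
                         band = names(bands), stringsAsFactors = FALSE)

  accuracy <- NULL
  if (stage("classify")) {
    accuracy <- wrap("classify", {
      res <- lapply(seq_len(nrow(netGrid)), function(i) {
        g <- netGrid[i, ]
        net <- networks[[paste(g$network, g$hemisphere, sep = "_")]]
        ft <- buildFeatures(lapply(cmBySubject, `[[`, g$band), net, groups)
        loocvSvm(ft, cost = config$svmCost)
      })
      accuracyTable(res)
    })
  }

  predictions <- NULL
  if (stage("predict")) {
    predictions <- wrap("predict", {
      res <- list()
      for (grp in c("NVLD", "TD")) {
        ids <- names(groups)[groups == grp]
        for (i in seq_len(nrow(netGrid))) {
          g <- netGrid[i, ]
          net <- networks[[paste(g$network, g$hemisphere, sep = "_")]]
          ft <- buildFeatures(lapply(cmBySubject[ids], `[[`, g$band), net,
                              groups)
          res[[length(res) + 1]] <- loocvSvr(ft, coh$scores,
                                             cost = config$svrCost,
                                             epsilon = config$svrEpsilon)
        }
      }
      grid <- do.call(rbind, lapply(res, function(r) data.frame(
        roi = paste(r$provenance$network, r$provenance$hemisphere, sep = "-"),
        band = r$provenance$band, group = r$group, n = r$n, r = r$pearsonR,
        stringsAsFactors = FALSE)))
      reported <- reportPredictions(res, bfThreshold = config$bfThreshold,
                                    priorWidth = config$corrPriorWidth)
      robustness <- if (nrow(reported)) do.call(rbind, lapply(
        seq_len(nrow(reported)), function(i) {
          rb <- bfRobustness(bayesCorrelationBF(reported$r[i], reported$n[i],
                                                width = config$corrPriorWidth))
          cbind(reported[i, c("roi", "band", "group")],
                rb@robustness, row.names = NULL)
        })) else NULL
      list(grid = grid, reported = reported, robustness = robustness)
    })
  }

  graphMetrics <- NULL; graphStats <- NULL
  if (stage("graphs")) {
    graphMetrics <- wrap("graphs", groupMetricTables(
      cmBySubject, groups, networks, bands = config$graphBands,
      retainFraction = config$retainFraction, seed = seed))
    graphStats <- wrap("stats", compareGroupsGraphMetrics(
      graphMetrics, width = config$tPriorWidth))
  }

  report <- list(
    meta = list(seed = seed, nSubjects = length(recs),
                nPerGroup = config$cohort$nPerGroup,
                fs = config$cohort$fs, durationS = config$cohort$durationS,
                windowS = config$windowS, overlap = config$overlap,
                retainFraction = config$retainFraction,
                graphBands = config$graphBands,
                tPriorWidth = config$tPriorWidth,
                corrPriorWidth = config$corrPriorWidth,
                bfThreshold = config$bfThreshold,
                stages = config$stages),
    scores = coh$scores, accuracy = accuracy, predictions = predictions,
    graphMetrics = graphMetrics, graphStats = graphStats)
  validateReport(report)
  if (!is.null(outDir)) writeReport(report, outDir)
  report
}
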