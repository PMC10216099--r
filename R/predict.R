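# Leave-one-subject-out SVR brain-to-behavior prediction within groups,
# evaluated by Pearson correlation on the pooled held-out predictions.

#' Leave-one-subject-out SVR behavior prediction
#'
#' Within one group, predicts the behavioral composite from connectivity
#' features by epsilon-SVR (linear kernel, C = 1, epsilon = 0.1); features
#' are standardized and the target centered per training fold. Held-out
#' predictions are pooled across folds and summarized by their Pearson
#' correlation with the observed composites.
#'
#' @param ft a [FeatureTable-class] restricted to one group
#' @param scores data.frame with subjectID and composite covering all
#'   subjects in `ft`
#' @param cost,epsilon SVR parameters
#' @param standardize per-fold feature standardization
#' @return list of class "cvRegression": predicted, observed, pearsonR,
#'   group, n, provenance
#' @export
loocvSvr <- function(ft, scores, cost = 1, epsilon = 0.1, standardize = TRUE) {
  X <- ft@X
  n <- nrow(X)
  if (n < 4) stop("need at least 4 subjects per group")
  if (length(unique(ft@groups)) != 1)
    stop("feature table must be restricted to one group")
  obs <- scores$composite[match(rownames(X), scores$subjectID)]
  if (anyNA(obs)) stop("subject/score mismatch: missing composite for ",
                       paste(rownames(X)[is.na(obs)], collapse = ", "))
  if (stats::sd(obs) < 1e-12) stop("zero variance in observed scores")
  pred <- numeric(n)
  for (i in seq_len(n)) {
    trX <- X[-i, , drop = FALSE]; teX <- X[i, ]
    trY <- obs[-i]
    if (standardize) {
      fs <- .foldScale(trX, teX)
      trX <- fs$train; teX <- fs$test
    }
    mu <- mean(trY)
    fit <- e1071::svm(trX, trY - mu, type = "eps-regression",
                      kernel = "linear", cost = cost, epsilon = epsilon,
                      scale = FALSE)
    pred[i] <- stats::predict(fit, matrix(teX, 1)) + mu
  }
  names(pred) <- rownames(X)
  structure(list(predicted = pred, observed = stats::setNames(obs, rownames(X)),
                 pearsonR = stats::cor(pred, obs), group = ft@groups[1], n = n,
                 provenance = ft@provenance),
            class = "cvRegression")
}

#' @export
print.cvRegression <- function(x, ...) {
  p <- x$provenance
  cat(sprintf("LOOCV SVR %s-%s %s (%s, n = %d): r = %.3f\n", p$network,
              p$hemisphere, p$band, x$group, x$n, x$pearsonR))
  invisible(x)
}

#' Filtered brain-to-behavior prediction report
#'
#' Attaches a stretched-beta Bayesian correlation Bayes factor to each
#' cross-validated prediction and keeps only the rows with a positive
#' correlation (negative correlations index a failed fit) and
#' BF10 at or above the evidence threshold. Filtering is idempotent.
#'
#' @param results list of "cvRegression" results
#' @param bfThreshold minimum BF10 to report (default 3, "moderate")
#' @param priorWidth stretched-beta prior width (default 0.5)
#' @param side prior sidedness for the correlation BF
#' @return data.frame: roi (network-hemisphere), band, group, n, r, bf10,
#'   evidence — empty when nothing survives
#' @export
reportPredictions <- function(results, bfThreshold = 3, priorWidth = 0.5,
                              side = "two_sided") {
  rows <- lapply(results, function(r) {
    p <- r$provenance
    bf <- if (is.finite(r$pearsonR) && abs(r$pearsonR) < 1)
      bf10(bayesCorrelationBF(r$pearsonR, r$n, width = priorWidth, side = side))
    else NA_real_
    data.frame(roi = paste(p$network, p$hemisphere, sep = "-"), band = p$band,
               group = r$group, n = r$n, r = r$pearsonR, bf10 = bf,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab)) return(data.frame(roi = character(), band = character(),
                                      group = character(), n = integer(),
                                      r = numeric(), bf10 = numeric(),
                                      evidence = character()))
  keep <- !is.na(tab$bf10) & tab$r > 0 & tab$bf10 >= bfThreshold
  tab <- tab[keep, , drop = FALSE]
  tab$evidence <- vapply(tab$bf10, evidenceCategory, "")
  rownames(tab) <- NULL
  tab
}
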