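# Leave-one-subject-out linear SVM group discrimination.

# Per-fold standardization: train-fold mean/SD applied to the held-out
# subject; constant features get unit scale (warned once upstream).
.foldScale <- function(train, test) {
  mu <- colMeans(train)
  s <- apply(train, 2, stats::sd)
  s[s < 1e-12] <- 1
  list(train = scale(train, mu, s), test = (test - mu) / s)
}

#' Leave-one-subject-out linear SVM classification
#'
#' For each held-out subject a linear soft-margin SVM (cost C = 1, the
#' library default) is fit on the remaining subjects and used to predict
#' the held-out group label; accuracy is the fraction of correct held-out
#' predictions (chance level 50% for balanced groups). Features are
#' standardized per training fold by default. A decision value of exactly
#' zero resolves to the majority class of the training fold, then to
#' "NVLD" — deterministic.
#'
#' @param ft a [FeatureTable-class]
#' @param cost SVM box constraint
#' @param standardize per-fold feature standardization (default TRUE)
#' @return list of class "cvClassification": predicted (named character),
#'   labels, accuracy, correct, n, provenance
#' @export
loocvSvm <- function(ft, cost = 1, standardize = TRUE) {
  X <- ft@X; y <- ft@groups
  n <- nrow(X)
  if (n < 4) stop("need at least 4 subjects")
  if (any(table(y) < 2)) stop("both classes need at least 2 subjects")
  if (any(apply(X, 2, stats::sd) < 1e-12))
    warning("degenerate constant feature(s); proceeding")
  lev <- sort(unique(y))
  pred <- character(n)
  for (i in seq_len(n)) {
    trX <- X[-i, , drop = FALSE]; trY <- y[-i]
    if (length(unique(trY)) < 2) stop("single-class training fold")
    teX <- X[i, ]
    if (standardize) {
      fs <- .foldScale(trX, teX)
      trX <- fs$train; teX <- fs$test
    }
    fit <- e1071::svm(trX, factor(trY, levels = lev), kernel = "linear",
                      cost = cost, scale = FALSE)
    pr <- stats::predict(fit, matrix(teX, 1), decision.values = TRUE)
    dv <- attr(pr, "decision.values")[1]
    if (identical(unname(dv), 0)) {
      tab <- table(trY)
      pred[i] <- if (length(unique(tab)) > 1) names(which.max(tab)) else "NVLD"
    } else pred[i] <- as.character(pr)
  }
  names(pred) <- rownames(X)
  correct <- sum(pred == y)
  structure(list(predicted = pred, labels = y, accuracy = correct / n,
                 correct = correct, n = n, provenance = ft@provenance),
            class = "cvClassification")
}

#' @export
print.cvClassification <- function(x, ...) {
  p <- x$provenance
  cat(sprintf("LOOCV linear SVM %s-%s %s: accuracy %.2f%% (%d/%d)\n",
              p$network, p$hemisphere, p$band, 100 * x$accuracy, x$correct,
              x$n))
  invisible(x)
}

#' Accuracy grid and per-band summary
#'
#' Assembles the network x hemisphere x band accuracy grid and summarizes
#' each band by the mean and standard error of its accuracies across the
#' four network x hemisphere cells; bands with mean accuracy above the
#' 50% chance level are flagged informative.
#'
#' @param results list of "cvClassification" results covering the full grid
#' @return list with `byCell` (network, hemisphere, band, n, accuracy,
#'   correctCount) and `byBand` (band, mean, se, informative)
#' @export
accuracyTable <- function(results) {
  byCell <- do.call(rbind, lapply(results, function(r) {
    p <- r$provenance
    data.frame(network = p$network, hemisphere = p$hemisphere, band = p$band,
               n = r$n, accuracy = r$accuracy, correctCount = r$correct,
               stringsAsFactors = FALSE)
  }))
  rownames(byCell) <- NULL
  if (anyDuplicated(byCell[c("network", "hemisphere", "band")]))
    stop("duplicate grid cells")
  byBand <- do.call(rbind, lapply(split(byCell, byCell$band), function(d) {
    data.frame(band = d$band[1], nCells = nrow(d), mean = mean(d$accuracy),
               se = if (nrow(d) > 1) stats::sd(d$accuracy) / sqrt(nrow(d)) else 0,
               stringsAsFactors = FALSE)
  }))
  byBand$informative <- byBand$mean > 0.5
  rownames(byBand) <- NULL
  list(byCell = byCell, byBand = byBand)
}
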