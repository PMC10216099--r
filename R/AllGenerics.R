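# Accessors and show methods for the S4 containers.

#' ROI labels of an object
#' @param x a SubjectRecording, CrossSpectra, ConnectivityMatrix or
#'   WeightedGraph
#' @return character vector of ROI labels
#' @export
setGeneric("roiLabels", function(x) standardGeneric("roiLabels"))

#' @rdname roiLabels
#' @export
setMethod("roiLabels", "SubjectRecording", function(x) colnames(x@series))
#' @rdname roiLabels
#' @export
setMethod("roiLabels", "CrossSpectra", function(x) x@roiLabels)
#' @rdname roiLabels
#' @export
setMethod("roiLabels", "ConnectivityMatrix", function(x) rownames(x@values))
#' @rdname roiLabels
#' @export
setMethod("roiLabels", "WeightedGraph", function(x) rownames(x@adjacency))
#' @rdname roiLabels
#' @export
setMethod("roiLabels", "NetworkDefinition", function(x) x@nodes$label)

#' Coherence values of a ConnectivityMatrix
#' @param x a ConnectivityMatrix
#' @return symmetric numeric matrix
#' @export
setGeneric("msc", function(x) standardGeneric("msc"))
#' @rdname msc
#' @export
setMethod("msc", "ConnectivityMatrix", function(x) x@values)

#' Adjacency matrix of a WeightedGraph
#' @param x a WeightedGraph
#' @export
setGeneric("adjacency", function(x) standardGeneric("adjacency"))
#' @rdname adjacency
#' @export
setMethod("adjacency", "WeightedGraph", function(x) x@adjacency)

#' Bayes factor value
#' @param x a BFResult
#' @export
setGeneric("bf10", function(x) standardGeneric("bf10"))
#' @rdname bf10
#' @export
setMethod("bf10", "BFResult", function(x) x@bf10)

setMethod("show", "SubjectRecording", function(object) {
  cat(sprintf("SubjectRecording %s (%s): %d ROIs x %d samples @ %g Hz (%.1f s)\n",
              object@subjectID, object@group, ncol(object@series),
              nrow(object@series), object@fs, nrow(object@series) / object@fs))
})

setMethod("show", "CrossSpectra", function(object) {
  wp <- object@welchParams
  cat(sprintf("CrossSpectra: %d channels, %d frequency bins (%.2f-%.2f Hz)\n",
              length(object@roiLabels), length(object@freqs),
              min(object@freqs), max(object@freqs)))
  cat(sprintf("  Welch: %d-sample %s windows, overlap %.2f, K = %d segments\n",
              wp$windowSamples, wp$taper, wp$overlap, wp$K))
})

setMethod("show", "ConnectivityMatrix", function(object) {
  cat(sprintf("ConnectivityMatrix [%s %g-%g Hz]: %d ROIs, mean off-diagonal MSC %.4f\n",
              object@band@name, object@band@fLo, object@band@fHi,
              nrow(object@values), mean(object@values[upper.tri(object@values)])))
})

setMethod("show", "NetworkDefinition", function(object) {
  cat(sprintf("NetworkDefinition %s (%s): %d nodes [%s]\n", object@name,
              object@hemisphere, nrow(object@nodes),
              paste(unique(object@nodes$role), collapse = "/")))
})

setMethod("show", "FeatureTable", function(object) {
  p <- object@provenance
  cat(sprintf("FeatureTable %s-%s %s: %d subjects x %d features (%s)\n",
              p$network, p$hemisphere, p$band, nrow(object@X), ncol(object@X),
              paste(names(table(object@groups)), table(object@groups),
                    sep = "=", collapse = ", ")))
})

setMethod("show", "WeightedGraph", function(object) {
  m <- object@meta
  cat(sprintf("WeightedGraph: %d nodes, %d edges retained (fraction %.2f)%s\n",
              nrow(object@adjacency), m$nRetained, m$retainedFraction,
              if (isTRUE(m$normalized)) ", max-weight normalized" else ""))
})

setMethod("show", "BFResult", function(object) {
  st <- object@statistic
  stat <- if (!is.null(st$t)) sprintf("t = %.3f, df = %g", st$t, st$df)
          else sprintf("r = %.3f, n = %d", st$r, st$n)
  cat(sprintf("BF10 = %.4g (%s evidence; %s prior, width %g, %s; %s)\n",
              object@bf10, object@category, object@prior$family,
              object@prior$width, object@prior$side, stat))
  if (nrow(object@robustness))
    cat(sprintf("  robustness over %d widths in [%g, %g]: BF10 range [%.4g, %.4g]\n",
                nrow(object@robustness), min(object@robustness$width),
                max(object@robustness$width), min(object@robustness$bf10),
                max(object@robustness$bf10)))
})
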