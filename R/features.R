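#' Build a connectivity feature table for one network and band
#'
#' Row i is the strict upper triangle (row-major node order) of subject
#' i's network submatrix, giving n(n-1)/2 features for an n-node network.
#'
#' @param cmList named list of per-subject [ConnectivityMatrix-class]
#'   (full matrices, all for the same band)
#' @param net a [NetworkDefinition-class]
#' @param groups named character vector of group labels keyed by subject id
#' @return a [FeatureTable-class]
#' @examples
#' # see buildFeatures examples in the vignette pipeline
#' @export
buildFeatures <- function(cmList, net, groups) {
  ids <- names(cmList)
  if (is.null(ids)) stop("cmList must be named by subject id")
  bands <- vapply(cmList, function(x) x@band@name, "")
  if (length(unique(bands)) != 1) stop("all subjects must share the band")
  rows <- lapply(cmList, function(cm) {
    sub <- extractSubnetwork(cm, net)
    if (!identical(roiLabels(sub), net@nodes$label))
      stop("inconsistent node sets across subjects")
    upperTriRowMajor(sub@values)
  })
  X <- do.call(rbind, rows)
  rownames(X) <- ids
  n <- nrow(net@nodes)
  colnames(X) <- paste(net@nodes$label[rep(seq_len(n - 1), (n - 1):1)],
                       net@nodes$label[unlist(lapply(2:n, function(i) i:n))],
                       sep = "~")
  new("FeatureTable", X = X, groups = unname(groups[ids]),
      provenance = list(network = net@name, hemisphere = net@hemisphere,
                        band = bands[[1]], nodeLabels = net@nodes$label))
}
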