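# Weighted graph construction (top-fraction edge retention, no
# binarization, max-weight normalization) and topology metrics.

#' Build a weighted graph by retaining the strongest connections
#'
#' Keeps the m = ceiling(retainFraction * n(n-1)/2) largest off-diagonal
#' weights with their values (no binarization) and zeroes everything else,
#' including the diagonal. Ties at the cutoff weight are all kept, so the
#' retained count can exceed m; this is recorded in the metadata.
#'
#' @param cm a [ConnectivityMatrix-class] (or plain symmetric matrix)
#' @param retainFraction fraction of connections to keep, in (0, 1]
#' @param network,hemisphere optional provenance strings for the metadata
#' @return a [WeightedGraph-class]
#' @examples
#' C <- symmetricFromUpperTri(c(.9, .8, .7, .6, .5, .4), letters[1:4])
#' g <- buildGraph(new("ConnectivityMatrix", band = bandSpec("beta", 13, 29),
#'                     values = C), retainFraction = 0.10)
#' @export
buildGraph <- function(cm, retainFraction = 0.10, network = NA_character_,
                       hemisphere = NA_character_) {
  W <- if (is(cm, "ConnectivityMatrix")) cm@values else as.matrix(cm)
  band <- if (is(cm, "ConnectivityMatrix")) cm@band@name else NA_character_
  n <- nrow(W)
  if (n < 2) stop("graph needs at least 2 nodes")
  if (!isSymmetricTol(W)) stop("input must be symmetric")
  if (!(retainFraction > 0 && retainFraction <= 1))
    stop("retainFraction must lie in (0, 1]")
  up <- upper.tri(W)
  vals <- W[up]
  m <- ceiling(retainFraction * length(vals))
  cutoff <- sort(vals, decreasing = TRUE)[m]
  keep <- up & W >= cutoff
  A <- matrix(0, n, n, dimnames = dimnames(W))
  A[keep] <- W[keep]
  A <- A + t(A)
  nRetained <- sum(keep)
  new("WeightedGraph", adjacency = A,
      meta = list(retainedFraction = retainFraction, normalized = FALSE,
                  nRetained = as.integer(nRetained),
                  ties = nRetained > m, band = band, network = network,
                  hemisphere = hemisphere))
}

#' Normalize graph weights by the maximum weight
#'
#' Scales all weights to [0, 1] by dividing by the maximal weight, so the
#' strongest connection becomes exactly 1. The zero pattern is unchanged
#' and the operation is idempotent. Must precede the metric computations.
#'
#' @param g a [WeightedGraph-class] with at least one positive weight
#' @return normalized [WeightedGraph-class]
#' @export
normalizeWeights <- function(g) {
  mx <- max(g@adjacency)
  if (mx <= 0) stop("cannot normalize an all-zero graph")
  meta <- g@meta
  meta$normalized <- TRUE
  new("WeightedGraph", adjacency = g@adjacency / mx, meta = meta)
}

.assertNormalized <- function(g) {
  if (!isTRUE(g@meta$normalized))
    stop("graph must be max-weight normalized first (see normalizeWeights)")
}

#' Nodal graph metrics: degree, strength, Onnela clustering
#'
#' Degree is the number of retained connections incident on the node;
#' strength the sum of their (normalized) weights; the clustering
#' coefficient is Onnela's weighted variant
#' C_i = (2 / (k_i (k_i - 1))) * sum_{j<h} (w_ij w_ih w_jh)^(1/3) over
#' neighbor pairs, with C_i = 0 for degree < 2.
#'
#' @param g a normalized [WeightedGraph-class]
#' @return data.frame: node, degree, strength, clustering
#' @export
nodalMetrics <- function(g) {
  .assertNormalized(g)
  A <- g@adjacency
  k <- colSums(A > 0)
  s <- colSums(A)
  W3 <- A^(1/3)
  tri <- diag(W3 %*% W3 %*% W3)   # 2 * sum over neighbor pairs of the cube-root product
  cl <- ifelse(k >= 2, tri / (k * (k - 1)), 0)
  data.frame(node = colnames(A) %||% as.character(seq_along(k)),
             degree = as.integer(k), strength = s, clustering = cl,
             stringsAsFactors = FALSE)
}

#' Global graph metrics: efficiency, assortativity, modularity
#'
#' Global efficiency is the mean inverse shortest-path length over ordered
#' node pairs, with edge lengths 1/w and disconnected pairs contributing
#' zero. Assortativity is the Pearson correlation of endpoint strengths
#' over edges (NA when degenerate). Modularity is the best Louvain
#' partition quality Q over `restarts` seeded restarts at resolution 1.
#'
#' @param g a normalized [WeightedGraph-class]
#' @param seed RNG seed for the Louvain restarts (fixed for reproducibility)
#' @param restarts number of Louvain restarts
#' @return list: globalEfficiency, assortativity, modularityQ, partition
#' @export
globalMetrics <- function(g, seed = 1, restarts = 100) {
  .assertNormalized(g)
  A <- g@adjacency
  n <- nrow(A)
  ig <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                            weighted = TRUE, diag = FALSE)
  w <- igraph::E(ig)$weight
  D <- igraph::distances(ig, weights = 1 / w)
  inv <- 1 / D
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  eff <- sum(inv) / (n * (n - 1))

  el <- igraph::as_edgelist(ig, names = FALSE)
  s <- colSums(A)
  assort <- NA_real_
  if (nrow(el) >= 2) {
    x <- c(s[el[, 1]], s[el[, 2]])
    y <- c(s[el[, 2]], s[el[, 1]])
    if (stats::sd(x) > 1e-12) assort <- stats::cor(x, y)
  }

  set.seed(seed)
  bestQ <- -Inf; bestPart <- rep(1L, n)
  for (i in seq_len(restarts)) {
    cl <- igraph::cluster_louvain(ig, weights = w)
    q <- max(cl$modularity)
    if (q > bestQ) {
      bestQ <- q
      bestPart <- igraph::membership(cl)
    }
  }
  list(globalEfficiency = eff, assortativity = assort, modularityQ = bestQ,
       partition = stats::setNames(as.integer(bestPart),
                                   colnames(A) %||% as.character(seq_len(n))))
}

#' Cohort-wide graph metric tables
#'
#' Computes, for every subject and requested band, the global measures on
#' the single-hemisphere graphs (L and R separately) and the nodal
#' measures on the bilateral graphs, producing long tables ready for
#' group inference.
#'
#' @param cmBySubject list (by subject id) of named band lists of
#'   [ConnectivityMatrix-class], as produced by [connectivityMatrices()]
#' @param groups named character vector of group labels by subject id
#' @param networks network definitions (see [networkDefinitions()])
#' @param bands character vector of band names to analyze
#' @param retainFraction edge retention fraction for [buildGraph()]
#' @param seed Louvain seed
#' @return list of long data.frames: `global` (subjectID, group, network,
#'   hemisphere, band, measure, value) and `nodal` (subjectID, group,
#'   network, band, node, role, measure, value)
#' @export
groupMetricTables <- function(cmBySubject, groups, networks = networkDefinitions(),
                              bands = c("beta", "gamma"),
                              retainFraction = 0.10, seed = 1) {
  ids <- names(cmBySubject)
  if (is.null(ids) || !all(ids %in% names(groups)))
    stop("missing subjects in group vector")
  netNames <- unique(vapply(networks, function(n) n@name, ""))
  globalRows <- list(); nodalRows <- list()
  for (id in ids) for (b in bands) {
    cm <- cmBySubject[[id]][[b]]
    if (is.null(cm)) stop("missing band ", b, " for subject ", id)
    for (nn in netNames) {
      for (h in c("L", "R")) {
        net <- networks[[paste(nn, h, sep = "_")]]
        gm <- globalMetrics(normalizeWeights(buildGraph(
          extractSubnetwork(cm, net), retainFraction, nn, h)), seed = seed)
        globalRows[[length(globalRows) + 1]] <- data.frame(
          subjectID = id, group = groups[[id]], network = nn, hemisphere = h,
          band = b,
          measure = c("global_efficiency", "assortativity", "modularity"),
          value = c(gm$globalEfficiency, gm$assortativity, gm$modularityQ),
          stringsAsFactors = FALSE)
      }
      net <- networks[[paste(nn, "bilateral", sep = "_")]]
      nm <- nodalMetrics(normalizeWeights(buildGraph(
        extractSubnetwork(cm, net), retainFraction, nn, "bilateral")))
      nodalRows[[length(nodalRows) + 1]] <- data.frame(
        subjectID = id, group = groups[[id]], network = nn, band = b,
        node = rep(nm$node, 3), role = rep(net@nodes$role, 3),
        measure = rep(c("degree", "strength", "clustering"), each = nrow(nm)),
        value = c(nm$degree, nm$strength, nm$clustering),
        stringsAsFactors = FALSE)
    }
  }
  g <- do.call(rbind, globalRows); rownames(g) <- NULL
  nd <- do.call(rbind, nodalRows); rownames(nd) <- NULL
  list(global = g, nodal = nd)
}
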