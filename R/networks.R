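# DAN/VAN network definitions over Destrieux-style parcel labels, and
# extraction of network submatrices from connectivity matrices.

#' Default attention-network parcel table
#'
#' The shipped convention assigning six Destrieux-style parcels per network
#' per hemisphere: superior frontal / precentral parcels for the frontal
#' eye fields (FEF) and intraparietal/superior-parietal parcels for the
#' IPS in the dorsal attention network; opercular inferior-frontal parcels
#' for the ventral prefrontal cortex (VPFC) and supramarginal /
#' superior-temporal parcels for the temporo-parietal junction (TPJ) in
#' the ventral attention network. This is an editable convention, not an
#' anatomical ground truth: real analyses can supply their own mapping via
#' [loadNetworkDefinitions()].
#'
#' @return data.frame with columns label, hemisphere, network, role
#' @export
defaultNetworkTable <- function() {
  spec <- list(
    DAN = list(FEF = c("G_front_sup", "G_precentral", "S_precentral-sup-part"),
               IPS = c("G_pariet_inf-Angular", "G_parietal_sup",
                       "S_intrapariet_and_P_trans")),
    VAN = list(VPFC = c("G_front_inf-Opercular", "G_front_inf-Orbital",
                        "G_front_inf-Triangul"),
               TPJ = c("G_pariet_inf-Supramar", "G_temp_sup-Lateral",
                       "S_temporal_sup")))
  out <- NULL
  for (net in names(spec)) for (role in names(spec[[net]]))
    for (h in c("L", "R"))
      out <- rbind(out, data.frame(
        label = paste(sort(spec[[net]][[role]]), h, sep = "_"),
        hemisphere = h, network = net, role = role, stringsAsFactors = FALSE))
  out[order(match(out$network, c("DAN", "VAN")),
            match(out$role, c("FEF", "IPS", "VPFC", "TPJ")),
            match(out$hemisphere, c("L", "R")), out$label), ]
}

# Fixed node ordering inside a definition: anterior roles (FEF/VPFC) before
# posterior (IPS/TPJ), left before right, alphabetical within role, so
# feature vectors are reproducible.
.orderNodes <- function(nd) {
  nd[order(match(nd$role, c("FEF", "VPFC", "IPS", "TPJ")),
           match(nd$hemisphere, c("L", "R")), nd$label), , drop = FALSE]
}

.makeNetworkDefinition <- function(name, hemisphere, nd) {
  nd <- .orderNodes(nd)
  rownames(nd) <- NULL
  new("NetworkDefinition", name = name, hemisphere = hemisphere,
      nodes = nd[, c("label", "index", "role", "hemisphere")])
}

#' Load network definitions from JSON
#'
#' Reads per-hemisphere node sets ({name, hemisphere, nodes:[{label,
#' index, role}]}), resolves labels against the ROI label set, validates
#' them, and derives the bilateral definitions as the union of L and R.
#'
#' @param path JSON file; defaults to the shipped DAN/VAN convention
#' @param roiLabels ROI label set to resolve node labels against; when
#'   NULL the indices stored in the file are used as-is
#' @return named list of [NetworkDefinition-class]:
#'   DAN_L, DAN_R, DAN_bilateral, VAN_L, VAN_R, VAN_bilateral
#' @examples
#' nets <- networkDefinitions()
#' nrow(nets$DAN_bilateral@nodes)  # 12
#' @export
loadNetworkDefinitions <- function(path = system.file("extdata",
                                     "attention_networks.json",
                                     package = "eegnets"),
                                   roiLabels = NULL) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  defs <- list()
  for (i in seq_len(nrow(raw$networks))) {
    entry <- raw$networks[i, ]
    nd <- entry$nodes[[1]]
    nd$hemisphere <- entry$hemisphere
    if (!is.null(roiLabels)) {
      miss <- setdiff(nd$label, roiLabels)
      if (length(miss))
        stop("unknown label in network definition: ",
             paste(miss, collapse = ", "))
      nd$index <- match(nd$label, roiLabels)
    }
    suffix <- sub(".*_", "", nd$label)
    if (entry$hemisphere %in% c("L", "R") && !all(suffix == entry$hemisphere))
      stop("hemisphere mismatch in ", entry$name, "_", entry$hemisphere,
           ": label(s) ", paste(nd$label[suffix != entry$hemisphere],
                                collapse = ", "))
    defs[[paste(entry$name, entry$hemisphere, sep = "_")]] <-
      .makeNetworkDefinition(entry$name, entry$hemisphere, nd)
  }
  for (net in unique(raw$networks$name)) {
    l <- defs[[paste0(net, "_L")]]; r <- defs[[paste0(net, "_R")]]
    if (is.null(l) || is.null(r)) next
    both <- rbind(l@nodes, r@nodes)
    if (anyDuplicated(both$index))
      stop("L and R node sets of ", net, " are not disjoint")
    defs[[paste0(net, "_bilateral")]] <-
      .makeNetworkDefinition(net, "bilateral", both)
  }
  defs
}

#' Default network definitions resolved against an ROI layout
#'
#' @param roiLabels ROI labels of the recording layout (default: the
#'   24-parcel DAN/VAN layout)
#' @return named list of [NetworkDefinition-class]
#' @export
networkDefinitions <- function(roiLabels = cohortRoiLabels(24)) {
  loadNetworkDefinitions(roiLabels = roiLabels)
}

#' Extract a network submatrix from a connectivity matrix
#'
#' Principal submatrix of the coherence matrix restricted to the network's
#' nodes, in the definition's node order. Symmetry and the unit diagonal
#' are preserved. Nodes are matched by label when the parent matrix carries
#' the labels, falling back to indices otherwise.
#'
#' @param cm a [ConnectivityMatrix-class]
#' @param net a [NetworkDefinition-class]
#' @return a [ConnectivityMatrix-class] restricted to the network
#' @export
extractSubnetwork <- function(cm, net) {
  C <- cm@values
  if (all(net@nodes$label %in% rownames(C))) {
    idx <- match(net@nodes$label, rownames(C))
  } else {
    idx <- net@nodes$index
    if (any(idx < 1 | idx > nrow(C))) stop("network index out of range")
  }
  new("ConnectivityMatrix", band = cm@band, values = C[idx, idx, drop = FALSE])
}
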