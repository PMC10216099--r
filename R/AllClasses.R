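#' @import methods
NULL

#' Frequency band specification
#'
#' A named frequency band with lower and upper edges in Hz. The five
#' canonical resting-state bands are returned by [defaultBands()].
#'
#' @slot name band name, e.g. "alpha"
#' @slot fLo lower edge in Hz (exclusive of 0)
#' @slot fHi upper edge in Hz
#' @export
setClass("BandSpec",
  representation(name = "character", fLo = "numeric", fHi = "numeric"),
  validity = function(object) {
    if (length(object@name) != 1 || !nzchar(object@name))
      return("band needs a single non-empty name")
    if (!(object@fLo > 0 && object@fHi > object@fLo))
      return("band edges must satisfy 0 < fLo < fHi")
    TRUE
  })

#' Per-subject source-level recording
#'
#' Multichannel ROI time series for one subject. Samples are rows, ROIs are
#' columns (column names are the ROI labels).
#'
#' @slot subjectID subject identifier
#' @slot group group label, "NVLD" or "TD"
#' @slot series numeric matrix [n_samples x n_roi], finite values
#' @slot fs sampling rate in Hz
#' @export
setClass("SubjectRecording",
  representation(subjectID = "character", group = "character",
                 series = "matrix", fs = "numeric"),
  validity = function(object) {
    if (!all(is.finite(object@series))) return("series contains non-finite values")
    lab <- colnames(object@series)
    if (is.null(lab) || anyDuplicated(lab)) return("ROI labels must be present and unique")
    if (!(length(object@fs) == 1 && object@fs > 0)) return("fs must be a positive scalar")
    if (!object@group %in% c("NVLD", "TD")) return("group must be 'NVLD' or 'TD'")
    TRUE
  })

#' Welch cross-spectral estimates
#'
#' One-sided cross-spectra S[i, j, f] averaged over K tapered segments,
#' Hermitian at each frequency with real non-negative auto-spectra.
#'
#' @slot freqs bin center frequencies in Hz
#' @slot S complex array [n_roi x n_roi x n_freq]
#' @slot welchParams list: windowSamples, overlap, taper, K, fs
#' @slot roiLabels channel labels
#' @export
setClass("CrossSpectra",
  representation(freqs = "numeric", S = "array", welchParams = "list",
                 roiLabels = "character"),
  validity = function(object) {
    d <- dim(object@S)
    if (length(d) != 3 || d[1] != d[2]) return("S must be [n x n x n_freq]")
    if (d[3] != length(object@freqs)) return("freq dimension mismatch")
    if (d[1] != length(object@roiLabels)) return("label/channel mismatch")
    TRUE
  })

#' Band-averaged magnitude squared coherence matrix
#'
#' Symmetric matrix of MSC values in [0, 1] with unit diagonal, for one
#' frequency band. Row/column names are the ROI labels.
#'
#' @slot band the [BandSpec-class] the values were averaged over
#' @slot values numeric matrix of coherence values
#' @export
setClass("ConnectivityMatrix",
  representation(band = "BandSpec", values = "matrix"),
  validity = function(object) {
    C <- object@values
    if (!isSymmetricTol(C)) return("C must be symmetric")
    if (is.null(rownames(C))) return("C must carry ROI labels as dimnames")
    if (max(abs(diag(C) - 1)) > 1e-12) return("diagonal must be exactly 1")
    if (min(C) < -1e-12 || max(C) > 1 + 1e-9) return("entries must lie in [0, 1]")
    TRUE
  })

#' Attention-network node set
#'
#' Maps anatomical labels to ROI indices for one network (DAN or VAN) and
#' hemisphere scope, with an anatomical role (FEF/IPS for DAN, VPFC/TPJ for
#' VAN) per node.
#'
#' @slot name "DAN" or "VAN"
#' @slot hemisphere "L", "R" or "bilateral"
#' @slot nodes data.frame with columns label, index, role
#' @export
setClass("NetworkDefinition",
  representation(name = "character", hemisphere = "character", nodes = "data.frame"),
  validity = function(object) {
    if (!object@name %in% c("DAN", "VAN")) return("name must be DAN or VAN")
    if (!object@hemisphere %in% c("L", "R", "bilateral"))
      return("hemisphere must be L, R or bilateral")
    nd <- object@nodes
    if (!all(c("label", "index", "role") %in% names(nd)))
      return("nodes needs columns label, index, role")
    if (anyDuplicated(nd$index)) return("duplicate ROI index in network definition")
    if (anyDuplicated(nd$label)) return("duplicate ROI label in network definition")
    if (!all(nd$role %in% c("FEF", "IPS", "VPFC", "TPJ")))
      return("roles must be FEF, IPS, VPFC or TPJ")
    TRUE
  })

#' Connectivity feature table
#'
#' One row per subject; columns are the strict upper triangle (row-major
#' node order) of the network submatrix for one band.
#'
#' @slot X numeric matrix [n_subjects x n_features], rownames = subject ids
#' @slot groups group label per subject ("NVLD"/"TD")
#' @slot provenance list: network, hemisphere, band, nodeLabels
#' @export
setClass("FeatureTable",
  representation(X = "matrix", groups = "character", provenance = "list"),
  validity = function(object) {
    if (anyNA(object@X)) return("missing values in feature matrix")
    if (nrow(object@X) != length(object@groups)) return("group/subject mismatch")
    n <- length(object@provenance$nodeLabels)
    if (ncol(object@X) != n * (n - 1) / 2)
      return("n_features must equal n(n-1)/2 for the network's node count")
    TRUE
  })

#' Thresholded weighted graph
#'
#' Symmetric non-negative adjacency with zero diagonal, produced by
#' retaining the strongest fraction of connections ([buildGraph()]) and,
#' after [normalizeWeights()], scaled so the maximum weight is 1.
#'
#' @slot adjacency symmetric numeric matrix, zero diagonal
#' @slot meta list: retainedFraction, normalized, nRetained, ties, band,
#'   network, hemisphere
#' @export
setClass("WeightedGraph",
  representation(adjacency = "matrix", meta = "list"),
  validity = function(object) {
    A <- object@adjacency
    if (!isSymmetricTol(A)) return("adjacency must be symmetric")
    if (any(diag(A) != 0)) return("diagonal must be zero")
    if (min(A) < 0) return("weights must be non-negative")
    if (isTRUE(object@meta$normalized) && max(A) > 0 &&
        abs(max(A) - 1) > 1e-12) return("normalized graph must have max weight 1")
    TRUE
  })

#' Bayes factor result
#'
#' BF10 with its prior specification, the test statistic it was computed
#' from, an optional prior-width robustness curve, and the evidence
#' category on the conventional scale (anecdotal < 3, moderate [3,10),
#' strong [10,30), very strong [30,100), extreme >= 100).
#'
#' @slot bf10 Bayes factor in favor of H1
#' @slot prior list: family, width, side
#' @slot statistic list, either (t, df, n1, n2) or (r, n)
#' @slot robustness data.frame with columns width, bf10 (may be empty)
#' @slot category evidence category string
#' @export
setClass("BFResult",
  representation(bf10 = "numeric", prior = "list", statistic = "list",
                 robustness = "data.frame", category = "character"),
  validity = function(object) {
    if (!(length(object@bf10) == 1 && is.finite(object@bf10) && object@bf10 > 0))
      return("bf10 must be a positive finite scalar")
    if (!object@prior$side %in% c("two_sided", "greater", "less"))
      return("side must be two_sided, greater or less")
    if (object@category != evidenceCategory(object@bf10))
      return("category inconsistent with bf10")
    TRUE
  })
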