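# Synthetic cohort generator: ROI-level oscillatory recordings with known
# band-specific coherence structure, group effects injected only through
# coupling coefficients, and behavior linked to the true coupling statistic.

.h2cache <- new.env(parent = emptyenv())

# Squared-magnitude response of a digital 4th-order Butterworth band-pass,
# evaluated at the N DFT bin frequencies. This is the amplitude response of
# the zero-phase (forward-backward) application of the filter.
.bandAmplitude <- function(fs, N, fLo, fHi, order = 4) {
  key <- paste(fs, N, fLo, fHi, order, sep = "|")
  if (!is.null(.h2cache[[key]])) return(.h2cache[[key]])
  bt <- signal::butter(order, c(fLo, fHi) / (fs / 2), type = "pass")
  z <- exp(-1i * 2 * pi * (0:(N - 1)) / N)
  num <- outer(z, seq_along(bt$b) - 1, "^") %*% bt$b
  den <- outer(z, seq_along(bt$a) - 1, "^") %*% bt$a
  h2 <- as.vector(Mod(num / den)^2)
  .h2cache[[key]] <- h2
  h2
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies the squared-magnitude response of a digital Butterworth
#' band-pass in the frequency domain: the same transfer function a
#' forward-backward (filtfilt) pass applies, with exactly zero phase and
#' circular edge handling. Operates column-wise on matrices.
#'
#' @param x numeric vector or matrix (samples in rows)
#' @param fLo,fHi band edges in Hz
#' @param fs sampling rate in Hz
#' @param order Butterworth order of the underlying one-pass filter
#' @return filtered vector or matrix of the same shape
#' @examples
#' y <- zerophaseBandpass(rnorm(1024), 8, 12, fs = 256)
#' @export
zerophaseBandpass <- function(x, fLo, fHi, fs, order = 4) {
  v <- is.null(dim(x))
  if (v) x <- matrix(x, ncol = 1)
  h2 <- .bandAmplitude(fs, nrow(x), fLo, fHi, order)
  y <- Re(stats::mvfft(stats::mvfft(x) * h2, inverse = TRUE)) / nrow(x)
  if (v) y[, 1] else y
}

#' Specify one shared-source coupling
#'
#' One row of the coupling table consumed by [cohortConfig()]. Each row
#' spawns an independent band-limited shared source mixed into the covered
#' ROIs as x = a * s + sqrt(1 - a^2) * noise, so a pair of covered ROIs has
#' asymptotic band MSC of a^4 (for a single row). `a` is jittered per
#' subject with SD `jitterSD` (truncated to [0, 0.98]) to create
#' inter-subject variability.
#'
#' @param group "NVLD" or "TD"
#' @param network "DAN" or "VAN"
#' @param hemisphere "L", "R" or "both"
#' @param band band name (must exist in the config's band list)
#' @param a mixing coefficient in [0, 1)
#' @param role restrict the source to nodes of one anatomical role
#'   ("FEF", "IPS", "VPFC", "TPJ") or "all"
#' @param jitterSD per-subject SD of the mixing coefficient
#' @return one-row data.frame
#' @export
couplingSpec <- function(group, network, hemisphere = "both", band, a,
                         role = "all", jitterSD = 0) {
  if (!(a >= 0 && a < 1)) stop("coupling must lie in [0, 1)")
  if (!group %in% c("NVLD", "TD")) stop("group must be NVLD or TD")
  data.frame(group = group, network = network, hemisphere = hemisphere,
             band = band, role = role, a = a, jitterSD = jitterSD,
             stringsAsFactors = FALSE)
}

#' Configure a synthetic cohort
#'
#' Collects the simulation knobs: cohort size, ROI layout, sampling rate
#' and duration matching an eyes-closed resting recording (256 Hz, 240 s),
#' the coupling table, and the behavior linkage. Each ROI series is a sum
#' over bands of unit-variance band-limited processes, so its variance
#' target is the number of bands.
#'
#' @param nPerGroup subjects per group (>= 2)
#' @param nRoi number of ROIs; the default 24 is the DAN/VAN node set
#'   (6 per network per hemisphere); larger layouts append filler ROIs
#' @param fs sampling rate in Hz
#' @param durationS recording duration in seconds
#' @param bands named list of [BandSpec-class]
#' @param couplings data.frame of [couplingSpec()] rows (may be empty)
#' @param behaviorLink list(network, hemisphere, band): the scope whose
#'   true mean pairwise coherence drives the behavioral composite
#' @param behaviorBeta linear weight of the true coherence statistic
#' @param behaviorNoiseSD SD of the Gaussian noise on the composite
#' @param seed master integer seed; per-subject substreams are derived
#'   from it so adding subjects does not perturb existing ones
#' @return a validated config list of class "cohortConfig"
#' @examples
#' cfg <- cohortConfig(nPerGroup = 2, durationS = 20)
#' @export
cohortConfig <- function(nPerGroup = 16, nRoi = 24, fs = 256, durationS = 240,
                         bands = defaultBands(),
                         couplings = couplingSpec("NVLD", "DAN", "both", "gamma", 0)[0, ],
                         behaviorLink = list(network = "DAN", hemisphere = "R",
                                             band = "delta"),
                         behaviorBeta = 0, behaviorNoiseSD = 1, seed = 1) {
  if (nPerGroup < 2) stop("nPerGroup must be >= 2")
  if (durationS <= 0) stop("duration must be positive")
  if (durationS * fs < 4 * 2 * fs)
    stop("duration must cover at least 4 Welch windows (8 s)")
  if (nRoi < 1) stop("nRoi must be positive")
  if (nrow(couplings)) {
    if (!all(couplings$band %in% names(bands)))
      stop("invalid band name in couplings: ",
           paste(setdiff(couplings$band, names(bands)), collapse = ", "))
    if (!all(couplings$a >= 0 & couplings$a < 1))
      stop("coupling must lie in [0, 1)")
  }
  roiLabels <- cohortRoiLabels(nRoi)
  networks <- networkDefinitions(roiLabels = roiLabels)
  cfg <- list(nPerGroup = as.integer(nPerGroup), nRoi = as.integer(nRoi),
              fs = fs, durationS = durationS, bands = bands,
              couplings = couplings, behaviorLink = behaviorLink,
              behaviorBeta = behaviorBeta, behaviorNoiseSD = behaviorNoiseSD,
              seed = as.integer(seed), roiLabels = roiLabels,
              networks = networks)
  class(cfg) <- "cohortConfig"
  cfg
}

#' ROI labels for a cohort layout
#'
#' The first 24 labels are the DAN/VAN parcels of the default network
#' definitions; layouts up to 148 ROIs append generic filler parcels.
#' @param nRoi number of ROIs
#' @return character vector of labels
#' @export
cohortRoiLabels <- function(nRoi = 24) {
  base <- defaultNetworkTable()$label
  if (nRoi <= length(base)) return(base[seq_len(nRoi)])
  c(base, sprintf("Parcel_%03d_%s", seq_len(nRoi - length(base)),
                  rep_len(c("L", "R"), nRoi - length(base))))
}

# ROI indices covered by one coupling row.
.couplingNodes <- function(row, networks) {
  hemis <- if (row$hemisphere == "both") "bilateral" else row$hemisphere
  net <- networks[[paste(row$network, hemis, sep = "_")]]
  if (is.null(net)) stop("unknown network scope: ", row$network, "_", hemis)
  nd <- net@nodes
  if (row$role != "all") nd <- nd[nd$role == row$role, ]
  if (!nrow(nd)) stop("coupling row covers no nodes (role ", row$role, ")")
  nd$index
}

# Per-subject node-by-source coupling matrix for one band, after jitter and
# the per-node total-power cap sum_r a_r^2 <= 0.98.
.couplingMatrix <- function(rows, aJ, bandName, networks, nRoi) {
  sel <- which(rows$band == bandName)
  A <- matrix(0, nRoi, length(sel))
  for (j in seq_along(sel)) {
    r <- sel[j]
    A[.couplingNodes(rows[r, , drop = FALSE], networks), j] <- aJ[r]
  }
  ss <- rowSums(A^2)
  over <- ss > 0.98
  if (any(over)) A[over, ] <- A[over, , drop = FALSE] * sqrt(0.98 / ss[over])
  A
}

#' Generate a synthetic cohort
#'
#' Draws per-subject ROI time series with the configured band-specific
#' shared-source structure, plus behavioral composites linked to the true
#' coupling-derived coherence statistic. Identical config and seed give
#' byte-identical output; group effects enter only through couplings,
#' never through amplitude.
#'
#' @param config a [cohortConfig()]
#' @return list with elements
#'   \item{recordings}{list of [SubjectRecording-class]}
#'   \item{scores}{data.frame subjectID, group, copyZ, recallZ, composite}
#'   \item{truth}{ground truth: jittered couplings per subject, the true
#'     behavior statistic per subject, and the variance target}
#' @examples
#' coh <- generateCohort(cohortConfig(nPerGroup = 2, durationS = 20, seed = 7))
#' length(coh$recordings)
#' @export
generateCohort <- function(config) {
  stopifnot(inherits(config, "cohortConfig"))
  cfg <- config
  N <- round(cfg$durationS * cfg$fs)
  bandNames <- names(cfg$bands)

  # per-band spectral shaping: amplitude response, truncated support, and
  # the deterministic scale that makes each band component unit variance
  shape <- lapply(cfg$bands, function(b) {
    if (b@fHi >= cfg$fs / 2) stop("band ", b@name, " reaches Nyquist")
    h2 <- .bandAmplitude(cfg$fs, N, b@fLo, b@fHi)
    supp <- which(h2 > 1e-8 * max(h2))
    g <- h2[supp] * N / sqrt(sum(h2^2))
    list(supp = supp, g = g)
  })

  link <- cfg$behaviorLink
  linkRow <- data.frame(network = link$network,
                        hemisphere = link$hemisphere %||% "both",
                        role = "all", stringsAsFactors = FALSE)
  linkNodes <- .couplingNodes(linkRow, cfg$networks)

  recordings <- list()
  scores <- NULL
  aJitterTruth <- NULL
  statTruth <- NULL

  for (g in c("NVLD", "TD")) {
    rows <- cfg$couplings[cfg$couplings$group == g, , drop = FALSE]
    for (k in seq_len(cfg$nPerGroup)) {
      sid <- sprintf("%s%02d", g, k)
      set.seed(subjectSeed(cfg$seed, g, k))
      aJ <- if (nrow(rows))
        pmin(pmax(rows$a + stats::rnorm(nrow(rows)) * rows$jitterSD, 0), 0.98)
      else numeric(0)

      Fspec <- matrix(0 + 0i, N, cfg$nRoi)
      Alink <- NULL
      for (b in bandNames) {
        sh <- shape[[b]]
        ns <- length(sh$supp)
        A <- .couplingMatrix(rows, aJ, b, cfg$networks, cfg$nRoi)
        if (b == link$band) Alink <- A
        ss <- rowSums(A^2)
        Zn <- matrix(complex(real = stats::rnorm(ns * cfg$nRoi),
                             imaginary = stats::rnorm(ns * cfg$nRoi)), ns)
        Fb <- sweep(Zn, 2, sqrt(1 - ss), "*")
        if (ncol(A)) {
          Zs <- matrix(complex(real = stats::rnorm(ns * ncol(A)),
                               imaginary = stats::rnorm(ns * ncol(A))), ns)
          Fb <- Fb + Zs %*% t(A)
        }
        Fspec[sh$supp, ] <- Fspec[sh$supp, ] + Fb * sh$g
      }
      series <- Re(stats::mvfft(Fspec, inverse = TRUE)) / N
      colnames(series) <- cfg$roiLabels
      recordings[[sid]] <- new("SubjectRecording", subjectID = sid, group = g,
                               series = series, fs = cfg$fs)

      # true coherence statistic over the linked scope: pairwise
      # (sum_r a_ri a_rj)^2, the asymptotic band MSC
      stat <- if (is.null(Alink) || !ncol(Alink)) 0 else {
        cross <- tcrossprod(Alink[linkNodes, , drop = FALSE])
        mean((cross[upper.tri(cross)])^2)
      }
      comp <- cfg$behaviorBeta * stat + stats::rnorm(1) * cfg$behaviorNoiseSD
      scores <- rbind(scores, data.frame(
        subjectID = sid, group = g, copyZ = comp, recallZ = comp,
        composite = comp, stringsAsFactors = FALSE))
      statTruth <- rbind(statTruth, data.frame(
        subjectID = sid, group = g, stat = stat, stringsAsFactors = FALSE))
      if (nrow(rows))
        aJitterTruth <- rbind(aJitterTruth, data.frame(
          subjectID = sid, network = rows$network, hemisphere = rows$hemisphere,
          band = rows$band, role = rows$role, a = aJ, stringsAsFactors = FALSE))
    }
  }
  list(recordings = recordings, scores = scores,
       truth = list(couplings = aJitterTruth, behaviorStat = statTruth,
                    behaviorBeta = cfg$behaviorBeta,
                    varianceTarget = length(bandNames), seed = cfg$seed))
}

#' Demonstration cohort configuration
#'
#' The study-condition demo: 16 + 16 subjects, 24 DAN/VAN ROIs, 256 Hz,
#' 240 s. The NVLD-like group carries (i) a gamma-band DAN shared source
#' with squared coupling 0.30 absent in the TD-like group, concentrated
#' further on IPS nodes so parietal hubs emerge, and (ii) a delta-band
#' right-DAN source whose per-subject strength drives the behavioral
#' composite (the right-DAN/delta brain-to-behavior linkage).
#'
#' @param seed master seed
#' @param nPerGroup subjects per group
#' @return a [cohortConfig()]
#' @export
demoCohortConfig <- function(seed = 0, nPerGroup = 16) {
  cohortConfig(
    nPerGroup = nPerGroup, seed = seed,
    couplings = rbind(
      couplingSpec("NVLD", "DAN", "both", "gamma", sqrt(0.30), jitterSD = 0.05),
      couplingSpec("NVLD", "DAN", "both", "gamma", 0.45, role = "IPS", jitterSD = 0.05),
      couplingSpec("NVLD", "DAN", "R", "delta", 0.55, jitterSD = 0.15)),
    behaviorLink = list(network = "DAN", hemisphere = "R", band = "delta"),
    behaviorBeta = 10, behaviorNoiseSD = 0.3)
}
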