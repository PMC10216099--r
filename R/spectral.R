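# Welch cross-spectra and band-averaged magnitude squared coherence.

#' Welch cross-spectral density matrix
#'
#' Estimates the full cross-spectral matrix S[i, j, f] as the average over
#' K overlapping, mean-removed, Hann-tapered segments of
#' X_i(f) * conj(X_j(f)). Auto-spectra equal the standard Welch PSD up to
#' a common scale constant (which cancels in coherence).
#'
#' @param rec a [SubjectRecording-class] (or numeric matrix, samples x
#'   channels, with `fs` supplied)
#' @param windowS segment length in seconds (default 2)
#' @param overlap fractional overlap in [0, 1) (default 0.5)
#' @param fs sampling rate, only needed when `rec` is a bare matrix
#' @return a [CrossSpectra-class]
#' @examples
#' x <- matrix(rnorm(2048 * 2), ncol = 2, dimnames = list(NULL, c("a", "b")))
#' cs <- welchCrossSpectra(x, fs = 256)
#' @export
welchCrossSpectra <- function(rec, windowS = 2, overlap = 0.5, fs = NULL) {
  if (is(rec, "SubjectRecording")) {
    X <- rec@series; fs <- rec@fs
  } else {
    X <- as.matrix(rec)
    if (is.null(fs)) stop("fs is required for a bare matrix")
    if (is.null(colnames(X))) colnames(X) <- sprintf("ch%02d", seq_len(ncol(X)))
  }
  if (!all(is.finite(X))) stop("non-finite samples in recording")
  if (!(overlap >= 0 && overlap < 1)) stop("overlap must lie in [0, 1)")
  wl <- round(windowS * fs)
  step <- max(1L, round(wl * (1 - overlap)))
  N <- nrow(X); nch <- ncol(X)
  K <- floor((N - wl) / step) + 1
  if (wl < 2 || N < wl + step) stop("recording shorter than two Welch windows")

  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(wl) / wl)  # periodic Hann taper
  nf <- floor(wl / 2) + 1
  A <- array(0 + 0i, c(nf, nch, K))
  for (k in seq_len(K)) {
    seg <- X[((k - 1) * step + 1):((k - 1) * step + wl), , drop = FALSE]
    seg <- sweep(seg, 2, colMeans(seg)) * w
    Ff <- stats::mvfft(seg)
    A[, , k] <- Ff[seq_len(nf), , drop = FALSE]
  }
  scale <- 1 / (fs * sum(w^2) * K)
  S <- array(0 + 0i, c(nch, nch, nf),
             dimnames = list(colnames(X), colnames(X), NULL))
  for (f in seq_len(nf)) {
    Xf <- matrix(A[f, , ], nch, K)
    S[, , f] <- Xf %*% Conj(t(Xf)) * scale
  }
  new("CrossSpectra", freqs = (seq_len(nf) - 1) * fs / wl, S = S,
      welchParams = list(windowSamples = wl, overlap = overlap,
                         taper = "hann", K = as.integer(K), fs = fs),
      roiLabels = colnames(X))
}

#' Band-averaged magnitude squared coherence
#'
#' Per-bin MSC_ij(f) = |S_ij(f)|^2 / (S_ii(f) S_jj(f)), averaged
#' arithmetically over the bins whose center frequency falls inside the
#' band (closed at both edges). The result is symmetric with a unit
#' diagonal and all entries in [0, 1] without clipping.
#'
#' @param cs a [CrossSpectra-class]
#' @param band a [BandSpec-class] or band name from [defaultBands()]
#' @return a [ConnectivityMatrix-class]
#' @examples
#' x <- matrix(rnorm(61440 * 2), ncol = 2, dimnames = list(NULL, c("a", "b")))
#' m <- mscBand(welchCrossSpectra(x, fs = 256), "alpha")
#' @export
mscBand <- function(cs, band) {
  band <- resolveBand(band)
  fs <- cs@welchParams$fs
  if (band@fHi >= fs / 2 + 1e-9) stop("band not fully below Nyquist")
  bins <- which(cs@freqs >= band@fLo & cs@freqs <= band@fHi)
  if (!length(bins)) stop("no frequency bins fall inside band ", band@name)
  nch <- length(cs@roiLabels)
  M <- matrix(0, nch, nch)
  for (f in bins) {
    d <- Re(diag(cs@S[, , f]))
    if (any(d <= 0))
      stop("zero auto-spectrum in band ", band@name, " (silent channel: ",
           paste(cs@roiLabels[d <= 0], collapse = ", "), ")")
    M <- M + Mod(cs@S[, , f])^2 / outer(d, d)
  }
  M <- M / length(bins)
  M[lower.tri(M)] <- t(M)[lower.tri(M)]  # enforce exact symmetry
  diag(M) <- 1
  dimnames(M) <- list(cs@roiLabels, cs@roiLabels)
  new("ConnectivityMatrix", band = band, values = M)
}

#' Per-band connectivity matrices for one recording
#'
#' Convenience wrapper: one Welch cross-spectral estimation, one MSC
#' matrix per band.
#'
#' @inheritParams welchCrossSpectra
#' @param bands named list of [BandSpec-class]
#' @return named list of [ConnectivityMatrix-class]
#' @export
connectivityMatrices <- function(rec, bands = defaultBands(), windowS = 2,
                                 overlap = 0.5) {
  cs <- welchCrossSpectra(rec, windowS = windowS, overlap = overlap)
  lapply(bands, function(b) mscBand(cs, b))
}
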