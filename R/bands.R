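#' Create a frequency band
#'
#' @param name band name
#' @param fLo,fHi band edges in Hz, 0 < fLo < fHi
#' @return a [BandSpec-class]
#' @examples
#' bandSpec("alpha", 8, 12)
#' @export
bandSpec <- function(name, fLo, fHi) {
  new("BandSpec", name = name, fLo = as.numeric(fLo), fHi = as.numeric(fHi))
}

#' The five canonical resting-state frequency bands
#'
#' Delta 2-4, theta 5-7, alpha 8-12, beta 13-29 and gamma 30-59 Hz.
#' Band membership elsewhere in the package is by bin center frequency,
#' closed at both edges.
#'
#' @return named list of [BandSpec-class] objects
#' @examples
#' names(defaultBands())
#' @export
defaultBands <- function() {
  list(delta = bandSpec("delta", 2, 4),
       theta = bandSpec("theta", 5, 7),
       alpha = bandSpec("alpha", 8, 12),
       beta  = bandSpec("beta", 13, 29),
       gamma = bandSpec("gamma", 30, 59))
}

# Resolve a band given either a BandSpec or a name in `bands`.
resolveBand <- function(band, bands = defaultBands()) {
  if (is(band, "BandSpec")) return(band)
  if (is.character(band) && band %in% names(bands)) return(bands[[band]])
  stop("unknown band: ", band)
}
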