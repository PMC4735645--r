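#' Canonical EEG frequency bands
#'
#' The eight resting-state bands used throughout the pipeline: delta
#' (2-3.5 Hz), theta (4-7.5 Hz), alpha1 (8-10 Hz), alpha2 (10-12 Hz),
#' beta1 (13-18 Hz), beta2 (18.5-21 Hz), beta3 (21.5-30 Hz) and gamma
#' (30.5-44 Hz). With the default 2 s epochs (0.5 Hz resolution) no
#' Fourier bin falls on two bands at once.
#'
#' @return A data frame with columns `name`, `f_lo`, `f_hi` (Hz).
#' @export
#' @examples
#' canonical_bands()
canonical_bands <- function() {
  data.frame(
    name = c("delta", "theta", "alpha1", "alpha2",
             "beta1", "beta2", "beta3", "gamma"),
    f_lo = c(2, 4, 8, 10, 13, 18.5, 21.5, 30.5),
    f_hi = c(3.5, 7.5, 10, 12, 18, 21, 30, 44),
    stringsAsFactors = FALSE
  )
}

#' Define a frequency band
#'
#' @param name Band label.
#' @param f_lo,f_hi Band edges in Hz, `0 < f_lo < f_hi`.
#' @return A `band_definition` object (named list).
#' @export
band_definition <- function(name, f_lo, f_hi) {
  stopifnot(is.character(name), length(name) == 1)
  if (!(is.finite(f_lo) && is.finite(f_hi) && f_lo > 0 && f_lo < f_hi)) {
    stop("band edges must satisfy 0 < f_lo < f_hi")
  }
  structure(list(name = name, f_lo = f_lo, f_hi = f_hi),
            class = "band_definition")
}

# Coerce a band given as band_definition, c(lo, hi), or a canonical name.
as_band <- function(band) {
  if (inherits(band, "band_definition")) return(band)
  if (is.character(band) && length(band) == 1) {
    cb <- canonical_bands()
    i <- match(band, cb$name)
    if (is.na(i)) stop("unknown band name: ", band)
    return(band_definition(cb$name[i], cb$f_lo[i], cb$f_hi[i]))
  }
  if (is.numeric(band) && length(band) == 2) {
    return(band_definition(paste0(band[1], "-", band[2], "Hz"),
                           band[1], band[2]))
  }
  stop("band must be a band_definition, a canonical band name, or c(f_lo, f_hi)")
}

# Low/high band split used by the cross-frequency analysis.
low_bands  <- function() c("delta", "theta", "alpha1", "alpha2")
high_bands <- function() c("beta1", "beta2", "beta3", "gamma")
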