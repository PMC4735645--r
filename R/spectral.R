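#' Band-pass filter and resample a recording
#'
#' Standard preprocessing for resting-state analysis: zero-phase
#' band-pass (default 2-44 Hz) followed by Fourier resampling to the
#' processing rate (default 128 Hz). Both steps run in the frequency
#' domain; the filter has raised-cosine transition skirts of 0.5 Hz. The
#' resampled length is `floor(n * target_rate / rate)` samples.
#'
#' @param rec A `recording`.
#' @param target_rate Output rate in Hz; must not exceed `rec$rate`.
#' @param band Passband `c(f_lo, f_hi)` in Hz, inside `(0, target_rate/2)`.
#' @return The filtered, resampled `recording`.
#' @export
preprocess <- function(rec, target_rate = 128, band = c(2, 44)) {
  stopifnot(inherits(rec, "recording"))
  if (target_rate > rec$rate) {
    stop("target_rate (", target_rate, ") exceeds the recording rate (",
         rec$rate, ")")
  }
  if (band[1] <= 0 || band[2] >= target_rate / 2) {
    stop("passband must lie inside (0, target_rate/2) = (0, ",
         target_rate / 2, ")")
  }
  n <- ncol(rec$data)
  m <- floor(n * target_rate / rec$rate)
  out <- t(apply(rec$data, 1, function(x) {
    fft_resample(fft_bandpass(x, rec$rate, band[1], band[2]), m)
  }))
  recording(out, target_rate, rec$labels, rec$coords)
}

#' Cut a recording into fixed-length epochs
#'
#' @param rec A `recording`.
#' @param epoch_length_s Epoch length in seconds (default 2 s, giving
#'   0.5 Hz spectral resolution).
#' @param overlap Fractional overlap between consecutive epochs, in
#'   `[0, 1)`.
#' @return An `epoch_set`: list of channels x epoch-samples matrices plus
#'   rate and epoch length. The trailing remainder is dropped.
#' @export
epoch_recording <- function(rec, epoch_length_s = 2, overlap = 0) {
  stopifnot(inherits(rec, "recording"))
  if (overlap < 0 || overlap >= 1) stop("overlap must lie in [0, 1)")
  len <- round(epoch_length_s * rec$rate)
  if (len < 2) stop("epoch too short: need epoch_length_s * rate >= 2")
  n <- ncol(rec$data)
  if (n < len) {
    stop("recording (", n, " samples) is shorter than one epoch (",
         len, " samples)")
  }
  step <- max(1L, round(len * (1 - overlap)))
  starts <- seq(1L, n - len + 1L, by = step)
  epochs <- lapply(starts, function(s) rec$data[, s:(s + len - 1L), drop = FALSE])
  structure(list(epochs = epochs, rate = rec$rate,
                 epoch_length_s = epoch_length_s,
                 labels = rec$labels, coords = rec$coords),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d epochs of %g s, %d channels @ %g Hz\n",
              length(x$epochs), x$epoch_length_s, nrow(x$epochs[[1]]), x$rate))
  invisible(x)
}

# Hann-tapered one-sided periodogram of one epoch (channels x samples).
# Returns channels x n_freq power, bins k = 1 .. floor(L/2) (DC dropped).
epoch_periodogram <- function(ep_mat, rate) {
  L <- ncol(ep_mat)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, L - 1) / L)
  U <- sum(w^2)
  half <- floor(L / 2)
  X <- t(apply(ep_mat * rep(w, each = nrow(ep_mat)), 1, stats::fft))
  P <- (2 / (rate * U)) * Mod(X[, 1 + seq_len(half), drop = FALSE])^2
  if (L %% 2 == 0) P[, half] <- P[, half] / 2 # Nyquist bin not doubled
  P
}

#' Epoch-averaged power spectrum
#'
#' Per-channel Hann-tapered periodograms averaged over epochs
#' (Welch/Bartlett estimate at the epoch segmentation). Power is
#' one-sided density in units^2/Hz; the DC bin is dropped.
#'
#' @param ep An `epoch_set` with at least 2 epochs.
#' @return A `spectral_estimate`: `PS` (channels x frequencies), `freqs`
#'   (Hz), `rate`, `n_epochs`, `labels`.
#' @export
power_spectrum <- function(ep) {
  stopifnot(inherits(ep, "epoch_set"))
  if (length(ep$epochs) < 2) stop("need at least 2 epochs")
  L <- ncol(ep$epochs[[1]])
  half <- floor(L / 2)
  acc <- matrix(0, nrow(ep$epochs[[1]]), half)
  for (e in ep$epochs) acc <- acc + epoch_periodogram(e, ep$rate)
  PS <- acc / length(ep$epochs)
  structure(list(PS = PS, freqs = seq_len(half) * ep$rate / L,
                 rate = ep$rate, n_epochs = length(ep$epochs),
                 labels = ep$labels),
            class = "spectral_estimate")
}

# OLS of log(PS) on log(f); returns c(alpha, beta) with the sign
# convention alpha > 0 for decaying spectra (alpha = -slope).
loglog_fit <- function(ps_vals, freqs) {
  lx <- log(freqs); ly <- log(ps_vals)
  slope <- stats::cov(lx, ly) / stats::var(lx)
  c(alpha = -slope, beta = mean(ly) - slope * mean(lx))
}

#' Fit the 1/f spectral exponent
#'
#' Ordinary least squares of log(PS) on log(f) over the requested
#' frequency range, per channel. The exponent alpha is the negated
#' regression coefficient, so white noise gives alpha ~ 0, pink noise
#' alpha ~ 1 and Brownian noise alpha ~ 2. The default range is
#' 2-43 Hz — the printed 1-43 Hz window clipped to the 2-44 Hz passband,
#' since log-power below the passband is unstable; pass
#' `f_lo = 1` explicitly to use the full window.
#'
#' @param ps A `spectral_estimate`.
#' @param f_lo,f_hi Fit range in Hz (at least 3 bins).
#' @param pooled If `TRUE`, fit one slope to the channel-mean log
#'   spectrum instead of per-channel slopes.
#' @return A `spectral_slope`: data frame with `channel`, `alpha`,
#'   `beta`, plus attribute `f_range`.
#' @export
fit_slope <- function(ps, f_lo = 2, f_hi = 43, pooled = FALSE) {
  stopifnot(inherits(ps, "spectral_estimate"))
  sel <- ps$freqs >= f_lo & ps$freqs <= f_hi
  if (sum(sel) < 3) stop("need at least 3 frequency bins in [", f_lo,
                         ", ", f_hi, "] Hz")
  P <- ps$PS[, sel, drop = FALSE]
  if (any(P <= 0)) stop("nonpositive power in the fit range; cannot take log")
  f <- ps$freqs[sel]
  if (pooled) {
    fit <- loglog_fit(exp(colMeans(log(P))), f)
    out <- data.frame(channel = "pooled", alpha = fit["alpha"],
                      beta = fit["beta"], row.names = NULL)
  } else {
    fits <- t(apply(P, 1, loglog_fit, freqs = f))
    out <- data.frame(channel = ps$labels, alpha = fits[, "alpha"],
                      beta = fits[, "beta"], row.names = NULL)
  }
  structure(out, f_range = c(f_lo, f_hi), class = c("spectral_slope",
                                                    "data.frame"))
}

#' Per-epoch spectral exponents, averaged
#'
#' Fits the log-log slope separately in every epoch's periodogram and
#' averages the exponents per channel — the per-epoch variant of
#' [fit_slope()] for workflows that fit each artifact-free epoch and
#' average afterwards. For log-linear spectra both estimators agree in
#' expectation.
#'
#' @inheritParams fit_slope
#' @param ep An `epoch_set`.
#' @return Data frame `channel`, `alpha` (epoch-mean exponent), with the
#'   per-epoch exponents as attribute `per_epoch`.
#' @export
epoch_slopes <- function(ep, f_lo = 2, f_hi = 43) {
  stopifnot(inherits(ep, "epoch_set"))
  L <- ncol(ep$epochs[[1]])
  freqs <- seq_len(floor(L / 2)) * ep$rate / L
  sel <- freqs >= f_lo & freqs <= f_hi
  if (sum(sel) < 3) stop("need at least 3 frequency bins in the fit range")
  per <- vapply(ep$epochs, function(e) {
    P <- epoch_periodogram(e, ep$rate)[, sel, drop = FALSE]
    apply(P, 1, function(p) loglog_fit(p, freqs[sel])["alpha"])
  }, numeric(nrow(ep$epochs[[1]])))
  per <- matrix(per, nrow = nrow(ep$epochs[[1]]))
  out <- data.frame(channel = ep$labels, alpha = rowMeans(per))
  attr(out, "per_epoch") <- per
  out
}

#' Compare 1/f slopes between two groups
#'
#' Pools the log-log points of both groups (every channel x frequency
#' bin) into one regression `log(PS) ~ log(f) * group` and tests the
#' group x log(f) interaction with a t-test. A positive t means group A
#' has the steeper (larger-alpha) spectrum.
#'
#' @param psA,psB `spectral_estimate` objects for the two groups
#'   (channels are the units).
#' @param f_lo,f_hi Fit range in Hz.
#' @return List with `t`, `p` (two-sided), `df`, `alpha_diff`
#'   (alpha_A - alpha_B implied by the interaction).
#' @export
compare_slopes <- function(psA, psB, f_lo = 2, f_hi = 43) {
  build <- function(ps, g) {
    sel <- ps$freqs >= f_lo & ps$freqs <= f_hi
    P <- ps$PS[, sel, drop = FALSE]
    if (nrow(P) < 2) stop("need at least 2 units (channels) per group")
    if (any(P <= 0)) stop("nonpositive power in the fit range")
    data.frame(ly = as.vector(log(P)),
               lx = rep(log(ps$freqs[sel]), each = nrow(P)),
               group = g)
  }
  df <- rbind(build(psA, "A"), build(psB, "B"))
  df$group <- factor(df$group, levels = c("A", "B"))
  fit <- stats::lm(ly ~ lx * group, data = df)
  sm <- summary(fit)$coefficients
  if (!("lx:groupB" %in% rownames(sm))) stop("singular design")
  # interaction coefficient = slope_B - slope_A = alpha_A - alpha_B
  list(t = unname(sm["lx:groupB", "t value"]),
       p = unname(sm["lx:groupB", "Pr(>|t|)"]),
       df = fit$df.residual,
       alpha_diff = unname(sm["lx:groupB", "Estimate"]))
}

#' Epoch-averaged cross-spectral matrix for one band
#'
#' For every epoch, each channel is Hann-tapered and Fourier
#' transformed; the outer-product cross-spectra are averaged over epochs
#' and over the Fourier bins falling inside the band (a bin belongs to
#' the band iff `f_lo <= f <= f_hi`). Alongside the raw cross-spectrum
#' `S`, the phase-only coherency matrix `rho` is formed from
#' unit-modulus coefficients; `rho` is what the lagged phase coherence
#' estimator consumes, making it invariant to per-channel amplitude
#' scaling.
#'
#' @param ep An `epoch_set`.
#' @param band A band (name, `band_definition`, or `c(f_lo, f_hi)`).
#' @return List with `band`, `S` (complex Hermitian), `rho` (phase-only
#'   coherency, unit diagonal), `n_epochs`, `n_bins`, `labels`.
#' @export
band_cross_spectrum <- function(ep, band) {
  stopifnot(inherits(ep, "epoch_set"))
  band <- as_band(band)
  L <- ncol(ep$epochs[[1]])
  nch <- nrow(ep$epochs[[1]])
  freqs <- seq_len(floor(L / 2)) * ep$rate / L
  sel <- which(freqs >= band$f_lo & freqs <= band$f_hi)
  if (length(sel) == 0) {
    stop("band ", band$name, " contains no Fourier bin at ",
         ep$rate / L, " Hz resolution; use epochs of at least ",
         ceiling(1 / (band$f_hi - band$f_lo)), " s")
  }
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, L - 1) / L)
  S <- matrix(0 + 0i, nch, nch)
  R <- matrix(0 + 0i, nch, nch)
  for (e in ep$epochs) {
    X <- t(apply(e * rep(w, each = nch), 1, stats::fft))[, 1 + sel,
                                                         drop = FALSE]
    Z <- X / Mod(X)
    Z[!is.finite(Z)] <- 0 # zero-power coefficient carries no phase
    S <- S + X %*% Conj(t(X))
    R <- R + Z %*% Conj(t(Z))
  }
  m <- length(ep$epochs) * length(sel)
  dimnames(S) <- dimnames(R) <- list(ep$labels, ep$labels)
  list(band = band, S = S / m, rho = R / m,
       n_epochs = length(ep$epochs), n_bins = length(sel),
       labels = ep$labels)
}

#' Cross-spectral matrices for a set of bands
#'
#' @param ep An `epoch_set`.
#' @param bands Data frame as returned by [canonical_bands()] (default)
#'   or a list of bands.
#' @return A named list of [band_cross_spectrum()] results, class
#'   `cross_spectral_set`.
#' @export
cross_spectral_set <- function(ep, bands = canonical_bands()) {
  if (is.data.frame(bands)) {
    bands <- lapply(seq_len(nrow(bands)), function(i) {
      band_definition(bands$name[i], bands$f_lo[i], bands$f_hi[i])
    })
  }
  out <- lapply(bands, function(b) band_cross_spectrum(ep, b))
  names(out) <- vapply(out, function(x) x$band$name, character(1))
  structure(out, class = "cross_spectral_set")
}
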