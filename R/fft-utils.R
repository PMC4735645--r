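# Internal FFT utilities shared by the simulator and the spectral stage.
# All filtering/resampling is done in the frequency domain: zero-phase by
# construction, no external signal-processing dependency.

# Assemble a real signal of length n from its positive-frequency Fourier
# coefficients (index k = 1 .. floor(n/2); DC forced to 0, Nyquist bin
# made real when n is even).
real_signal_from_spectrum <- function(pos, n) {
  half <- length(pos)
  stopifnot(half == floor(n / 2))
  full <- complex(n)
  if (n %% 2 == 0) pos[half] <- complex(real = Re(pos[half]), imaginary = 0)
  kmax <- if (n %% 2 == 0) half - 1 else half
  full[1 + seq_len(half)] <- pos
  full[n + 1 - seq_len(kmax)] <- Conj(pos[seq_len(kmax)])
  Re(stats::fft(full, inverse = TRUE)) / n
}

# Frequency axis of an n-point FFT folded to [0, rate/2].
folded_freqs <- function(n, rate) {
  k <- 0:(n - 1)
  pmin(k, n - k) * rate / n
}

# Zero-phase band-pass by frequency-domain masking with raised-cosine
# transition skirts (width `transition` Hz on each side).
fft_bandpass <- function(x, rate, f_lo, f_hi, transition = 0.5) {
  n <- length(x)
  f <- folded_freqs(n, rate)
  mask <- numeric(n)
  mask[f >= f_lo & f <= f_hi] <- 1
  lo_ramp <- f > f_lo - transition & f < f_lo
  mask[lo_ramp] <- 0.5 - 0.5 * cos(pi * (f[lo_ramp] - (f_lo - transition)) /
                                     transition)
  hi_ramp <- f > f_hi & f < f_hi + transition
  mask[hi_ramp] <- 0.5 + 0.5 * cos(pi * (f[hi_ramp] - f_hi) / transition)
  Re(stats::fft(stats::fft(x) * mask, inverse = TRUE)) / n
}

# Fourier resampling of a real signal to m samples (ideal low-pass when
# downsampling). Matches the classical FFT resample: truncate/zero-pad
# the spectrum, rescale by m/n.
fft_resample <- function(x, m) {
  n <- length(x)
  if (m == n) return(x)
  X <- stats::fft(x)
  Y <- complex(m)
  half <- floor(min(n, m) / 2)
  kmax <- if (min(n, m) %% 2 == 0) half - 1 else half
  Y[1] <- X[1]
  Y[1 + seq_len(kmax)] <- X[1 + seq_len(kmax)]
  Y[m + 1 - seq_len(kmax)] <- X[n + 1 - seq_len(kmax)]
  if (min(n, m) %% 2 == 0) {
    ny <- X[half + 1]
    if (m < n) ny <- complex(real = Re(ny), imaginary = 0)
    Y[half + 1] <- ny
    if (m > n) Y[m - half + 1] <- Conj(ny)
  }
  Re(stats::fft(Y, inverse = TRUE)) * (1 / n)
}
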