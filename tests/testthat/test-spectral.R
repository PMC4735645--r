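test_that("preprocess resamples to floor(n * ratio) samples and errors sanely", {
  set.seed(1)
  m <- bundled_montage("1020-19")
  n <- 5000
  rec <- recording(matrix(rnorm(3 * n), 3, n), 500, m$labels[1:3],
                   m$coords[1:3, ])
  pp <- preprocess(rec, 128, c(2, 44))
  expect_identical(ncol(pp$data), as.integer(floor(n * 128 / 500)))
  expect_equal(pp$rate, 128)
  expect_error(preprocess(pp, 500), "exceeds")
  expect_error(preprocess(rec, 128, c(2, 80)), "Nyquist|passband")
})

test_that("a 1 Hz tone is strongly attenuated by the 2-44 Hz band-pass", {
  m <- bundled_montage("1020-19")
  t <- seq(0, 10 - 1 / 500, by = 1 / 500)
  x <- sin(2 * pi * 1 * t)
  rec <- recording(rbind(x, x), 500, m$labels[1:2], m$coords[1:2, ])
  pp <- preprocess(rec, 128, c(2, 44))
  expect_lt(stats::sd(pp$data[1, ]), 0.1 * stats::sd(x))
  # and a passband tone survives essentially intact
  x10 <- sin(2 * pi * 10 * t)
  rec10 <- recording(rbind(x10, x10), 500, m$labels[1:2], m$coords[1:2, ])
  pp10 <- preprocess(rec10, 128, c(2, 44))
  expect_gt(stats::sd(pp10$data[1, ]), 0.9 * stats::sd(x10))
})

test_that("epoching yields the expected counts and drops the remainder", {
  m <- bundled_montage("1020-19")
  rec <- recording(matrix(rnorm(2 * 1280), 2, 1280), 128, m$labels[1:2],
                   m$coords[1:2, ]) # 10 s
  expect_length(epoch_recording(rec, 2, 0)$epochs, 5)
  expect_length(epoch_recording(rec, 2, 0.5)$epochs, 9)
  rec1s <- recording(matrix(rnorm(2 * 256), 2, 256), 128, m$labels[1:2],
                     m$coords[1:2, ]) # 2 s exactly: one epoch of 2 s fits
  expect_length(epoch_recording(rec1s, 2, 0)$epochs, 1)
  expect_error(epoch_recording(rec1s, 4, 0), "shorter")
  expect_error(epoch_recording(rec, 2, 1), "overlap")
})

test_that("power spectrum concentrates a bin-frequency sinusoid and scales quadratically", {
  m <- bundled_montage("1020-19")
  t <- seq(0, 20 - 1 / 128, by = 1 / 128)
  x <- sin(2 * pi * 10 * t) # 10 Hz falls on a bin for 2 s epochs
  rec <- recording(rbind(x, 2 * x), 128, m$labels[1:2], m$coords[1:2, ])
  ps <- power_spectrum(epoch_recording(rec))
  peak <- which.max(ps$PS[1, ])
  expect_equal(ps$freqs[peak], 10)
  # Hann main lobe spans the peak bin and its two neighbours
  lobe <- sum(ps$PS[1, (peak - 1):(peak + 1)])
  expect_gt(lobe / sum(ps$PS[1, ]), 0.9)
  expect_equal(ps$PS[2, ], 4 * ps$PS[1, ], tolerance = 1e-12)
})

test_that("fit_slope recovers exact power-law grids to machine precision", {
  f <- seq(2, 43, by = 0.5)
  for (a in c(0, 0.5, 1, 2)) {
    ps <- structure(list(PS = matrix(3.7 * f^(-a), 1), freqs = f,
                         rate = 128, n_epochs = 2, labels = "ch"),
                    class = "spectral_estimate")
    fit <- fit_slope(ps, 2, 43)
    expect_lt(abs(fit$alpha - a), 1e-10)
    expect_lt(abs(fit$beta - log(3.7)), 1e-10)
  }
  flat <- structure(list(PS = matrix(1, 1, length(f)), freqs = f,
                         rate = 128, n_epochs = 2, labels = "ch"),
                    class = "spectral_estimate")
  expect_equal(fit_slope(flat)$alpha, 0)
  bad <- structure(list(PS = matrix(c(1, 0, rep(1, length(f) - 2)), 1),
                        freqs = f, rate = 128, n_epochs = 2, labels = "ch"),
                   class = "spectral_estimate")
  expect_error(fit_slope(bad), "nonpositive")
})

test_that("per-epoch slope fitting agrees with the averaged-spectrum fit", {
  cfg <- simulation_config(2, 40, alpha_exponent = 1, noise_sd = 0, seed = 21)
  ep <- epoch_recording(generate_recording(cfg))
  a1 <- mean(fit_slope(power_spectrum(ep))$alpha)
  a2 <- mean(epoch_slopes(ep)$alpha)
  expect_lt(abs(a1 - a2), 0.2)
  expect_identical(dim(attr(epoch_slopes(ep), "per_epoch")),
                   c(2L, length(ep$epochs)))
})

test_that("compare_slopes is symmetric, null at equality, and detects a planted difference", {
  cfg <- simulation_config(3, 60, alpha_exponent = 1, noise_sd = 0, seed = 31)
  psA <- power_spectrum(epoch_recording(generate_recording(cfg)))
  eq <- compare_slopes(psA, psA)
  expect_equal(eq$t, 0, tolerance = 1e-8)
  cfgB <- simulation_config(3, 60, alpha_exponent = 1.5, noise_sd = 0,
                            seed = 32)
  psB <- power_spectrum(epoch_recording(generate_recording(cfgB)))
  ab <- compare_slopes(psA, psB)
  ba <- compare_slopes(psB, psA)
  expect_equal(ab$t, -ba$t, tolerance = 1e-10)
  expect_equal(ab$p, ba$p, tolerance = 1e-10)
  expect_lt(ab$p, 0.01)
  expect_lt(ab$t, 0) # group B is steeper, so alpha_A - alpha_B < 0
  expect_lt(ab$alpha_diff, 0)
})

test_that("band cross-spectra are Hermitian with unit phase-only diagonal", {
  ep <- toy_epochs(n_channels = 4, n_epochs = 10, seed = 8)
  cs <- band_cross_spectrum(ep, "alpha1")
  expect_lt(max(Mod(cs$S - Conj(t(cs$S)))), 1e-12)
  expect_true(all(abs(Im(diag(cs$S))) < 1e-12))
  expect_true(all(Re(diag(cs$S)) >= 0))
  expect_equal(unname(Re(diag(cs$rho))), rep(1, 4), tolerance = 1e-12)
  expect_identical(cs$n_epochs, 10L)
  expect_identical(cs$n_bins, 5L) # 8, 8.5, 9, 9.5, 10 Hz at 0.5 Hz resolution
})

test_that("cross-spectral averaging is invariant to epoch order", {
  ep <- toy_epochs(n_channels = 3, n_epochs = 6, seed = 9)
  ep_rev <- ep
  ep_rev$epochs <- rev(ep$epochs)
  a <- band_cross_spectrum(ep, "beta1")
  b <- band_cross_spectrum(ep_rev, "beta1")
  expect_equal(a$S, b$S, tolerance = 1e-12)
  expect_equal(a$rho, b$rho, tolerance = 1e-12)
})

test_that("an empty band names the required epoch length", {
  ep <- toy_epochs(n_channels = 2, n_epochs = 4, L = 64, seed = 2) # 2 Hz resolution
  expect_error(band_cross_spectrum(ep, band_definition("narrow", 8.2, 9.1)),
               "no Fourier bin")
})

test_that("identical channels give coherency magnitude 1 in every band", {
  set.seed(10)
  m <- bundled_montage("1020-19")
  x <- rnorm(1280)
  rec <- recording(rbind(x, x), 128, m$labels[1:2], m$coords[1:2, ])
  cs <- band_cross_spectrum(epoch_recording(rec), "theta")
  expect_equal(Mod(cs$rho[1, 2]), 1, tolerance = 1e-12)
})

test_that("phase-only off-diagonals of independent noise shrink with epochs", {
  offdiag <- function(n_ep, seed) {
    ep <- toy_epochs(n_channels = 2, n_epochs = n_ep, seed = seed)
    Mod(band_cross_spectrum(ep, "alpha1")$rho[1, 2])
  }
  few <- mean(vapply(1:6, function(s) offdiag(4, s), numeric(1)))
  many <- mean(vapply(1:6, function(s) offdiag(64, s), numeric(1)))
  expect_lt(many, few)
  expect_lt(many, 0.1)
})
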