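test_that("lagged phase coherence follows the closed formula", {
  expect_equal(lagged_phase_coherence(0.3 + 0.4i), 0.16 / 0.91,
               tolerance = 1e-12)
  expect_equal(lagged_phase_coherence(0 + 0i), 0)
  expect_equal(lagged_phase_coherence(0.7 + 0i), 0) # purely instantaneous
  expect_warning(v <- lagged_phase_coherence(1 + 0i), "instantaneous")
  expect_equal(v, 0)
  expect_error(lagged_phase_coherence(1.2 + 0.2i), "exceed")
  # always in [0, 1)
  set.seed(4)
  th <- runif(200, -pi, pi); r <- runif(200)
  vals <- lagged_phase_coherence(complex(modulus = r, argument = th))
  expect_true(all(vals >= 0 & vals < 1))
})

test_that("identical signals have zero lagged phase coherence", {
  set.seed(11)
  m <- bundled_montage("1020-19")
  x <- rnorm(2560)
  rec <- recording(rbind(x, x), 128, m$labels[1:2], m$coords[1:2, ])
  W <- suppressWarnings(
    connectivity_matrix(epoch_recording(rec), "alpha1")$W)
  expect_lt(W[1, 2], 1e-10)
})

test_that("a quarter-cycle lag in a clean narrowband pair drives LPC towards 1", {
  cfg <- simulation_config(2, 60, alpha_exponent = 0, noise_sd = 0,
                           couplings = list(list(i = 1, j = 2,
                                                 band = c(9.5, 10.5),
                                                 lag = pi / 2,
                                                 amplitude = 20)),
                           seed = 17)
  W <- connectivity_matrix(epoch_recording(generate_recording(cfg)),
                           band_definition("alpha10", 9.5, 10.5))$W
  expect_gt(W[1, 2], 0.9)
})

test_that("zero-lag coupling is suppressed below the significance threshold", {
  cfg <- simulation_config(4, 60, alpha_exponent = 1, noise_sd = 0.3,
                           couplings = list(list(i = 1, j = 2,
                                                 band = c(8, 10),
                                                 lag = 0, amplitude = 2)),
                           seed = 23)
  cm <- connectivity_matrix(epoch_recording(generate_recording(cfg)),
                            "alpha1")
  thr <- significance_threshold(cm$n_epochs, 0.05, n_pairs = 6,
                                n_bins = cm$n_bins)
  expect_lt(cm$W[1, 2], thr)
})

test_that("connectivity matrices have the right structure and edge counts", {
  cfg <- simulation_config(19, 20, alpha_exponent = 1, noise_sd = 0.5,
                           seed = 13)
  cm <- connectivity_matrix(epoch_recording(generate_recording(cfg)),
                            "theta")
  W <- cm$W
  expect_identical(dim(W), c(19L, 19L))
  expect_identical(sum(upper.tri(W)), 171L)
  expect_equal(W, t(W))
  expect_true(all(diag(W) == 0))
  expect_true(all(W >= 0 & W < 1))
})

test_that("permuting channels permutes the matrix consistently", {
  cfg <- simulation_config(5, 20, alpha_exponent = 1, noise_sd = 0.4,
                           couplings = list(list(i = 1, j = 3,
                                                 band = c(13, 18),
                                                 lag = 1.2, amplitude = 2)),
                           seed = 29)
  rec <- generate_recording(cfg)
  perm <- c(3, 1, 5, 2, 4)
  rec2 <- recording(rec$data[perm, ], rec$rate, rec$labels[perm],
                    rec$coords[perm, ])
  W1 <- connectivity_matrix(epoch_recording(rec), "beta1")$W
  W2 <- connectivity_matrix(epoch_recording(rec2), "beta1")$W
  expect_equal(unname(W2), unname(W1[perm, perm]), tolerance = 1e-12)
})

test_that("matrix LPC agrees with the closed formula applied to stored rho", {
  ep <- toy_epochs(n_channels = 5, n_epochs = 12, seed = 37)
  cs <- band_cross_spectrum(ep, "alpha2")
  cm <- connectivity_matrix(cs)
  direct <- suppressWarnings(
    Im(cs$rho)^2 / (1 - Re(cs$rho)^2))
  diag(direct) <- 0
  expect_equal(cm$W, direct, tolerance = 1e-10)
})

test_that("end-to-end LPC matches an independent re-implementation", {
  # brute-force route: plain loops, no package cross-spectral code
  ep <- toy_epochs(n_channels = 3, n_epochs = 6, L = 256, rate = 128,
                   seed = 41)
  L <- 256
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, L - 1) / L)
  freqs <- seq_len(L / 2) * 128 / L
  sel <- which(freqs >= 8 & freqs <= 10)
  acc <- matrix(0 + 0i, 3, 3)
  cnt <- 0
  for (e in ep$epochs) {
    for (k in sel) {
      coefs <- complex(3)
      for (ch in 1:3) {
        coefs[ch] <- sum(e[ch, ] * w * exp(-2i * pi * k * seq(0, L - 1) / L))
      }
      z <- coefs / Mod(coefs)
      acc <- acc + z %*% Conj(t(z))
      cnt <- cnt + 1
    }
  }
  rho <- acc / cnt
  expected <- Im(rho)^2 / (1 - Re(rho)^2)
  diag(expected) <- 0
  W <- connectivity_matrix(ep, "alpha1")$W
  expect_equal(unname(W), unname(expected), tolerance = 1e-10)
})

test_that("significance threshold arithmetic and monotonicity", {
  # Bonferroni per-test level for 171 edges at 0.05
  expect_equal(0.05 / 171, 2.923977e-4, tolerance = 1e-6)
  t1 <- significance_threshold(20, 0.05, n_pairs = 171, n_bins = 4)
  t2 <- significance_threshold(40, 0.05, n_pairs = 171, n_bins = 4)
  expect_lt(t2, t1)
  t3 <- significance_threshold(20, 0.05, n_pairs = 1, n_bins = 4)
  expect_lt(t3, t1) # fewer comparisons, lower cutoff
  expect_error(significance_threshold(1, 0.05), "n_epochs")
})

test_that("thresholding zeroes exactly the sub-threshold edges", {
  cfg <- simulation_config(6, 40, alpha_exponent = 1, noise_sd = 0.3,
                           couplings = list(list(i = 2, j = 5,
                                                 band = c(8, 10),
                                                 lag = pi / 2,
                                                 amplitude = 2.5)),
                           seed = 43)
  cm <- connectivity_matrix(epoch_recording(generate_recording(cfg)),
                            "alpha1")
  th <- threshold_matrix(cm, 0.05)
  expect_true(all(th$W[th$W > 0] >= th$threshold))
  expect_gt(th$W[2, 5], 0) # the planted edge survives
  expect_lt(sum(th$W[upper.tri(th$W)] > 0), sum(cm$W[upper.tri(cm$W)] > 0))
})

test_that("connectivity matrices round-trip through TSV + sidecar", {
  cfg <- simulation_config(4, 20, seed = 47)
  cm <- connectivity_matrix(epoch_recording(generate_recording(cfg)),
                            "gamma")
  path <- file.path(withr::local_tempdir(), "conn.tsv")
  write_connectivity(cm, path)
  back <- read_connectivity(path)
  expect_equal(back$W, cm$W, tolerance = 1e-12)
  expect_equal(back$band$f_lo, cm$band$f_lo)
  expect_identical(back$n_epochs, cm$n_epochs)
  expect_identical(back$labels, cm$labels)
})
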