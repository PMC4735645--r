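#' Lagged phase coherence from a coherency value
#'
#' Given the band-averaged phase-only coherency `rho` between two
#' signals, the lagged phase coherence is
#' `LPC = Im(rho)^2 / (1 - Re(rho)^2)`.
#' The real (instantaneous, zero-lag) component — the part that volume
#' conduction can produce — is partialled out, so only time-lagged
#' synchronization contributes: identical signals give 0, a quarter-cycle
#' lag in a clean narrowband pair drives the value towards 1. At 10 Hz a
#' quarter-cycle lag corresponds to a 25 ms delay, at 20 Hz to 12.5 ms.
#'
#' @param rho Complex coherency (scalar, vector or matrix), `|rho| <= 1`.
#' @return Values in `[0, 1)`, same shape as `rho`. Perfect instantaneous
#'   coherence (`Re(rho)^2 = 1`) has no lagged component and returns 0
#'   with a warning.
#' @export
#' @examples
#' lagged_phase_coherence(0.3 + 0.4i) # 0.16 / 0.91
lagged_phase_coherence <- function(rho) {
  if (any(Mod(rho) > 1 + 1e-9)) stop("|rho| must not exceed 1")
  re2 <- Re(rho)^2
  out <- Im(rho)^2 / (1 - re2)
  degen <- re2 >= 1 - 1e-15
  if (any(degen)) {
    warning("perfect instantaneous coherence: no lagged component, LPC set to 0")
    out[degen] <- 0
  }
  out
}

#' Band-wise lagged phase coherence matrix
#'
#' Applies the lagged phase coherence estimator to every unordered
#' channel pair of one band's phase-only coherency matrix. A 19-node
#' matrix carries 171 undirected edges, an 84-node matrix 3486.
#'
#' @param x An `epoch_set` (together with `band`) or the result of
#'   [band_cross_spectrum()].
#' @param band Band specification, required when `x` is an `epoch_set`.
#' @return A `connectivity_matrix`: symmetric `W` with zero diagonal and
#'   entries in `[0, 1)`, plus band, epoch/bin counts and labels.
#' @export
connectivity_matrix <- function(x, band = NULL) {
  if (inherits(x, "epoch_set")) {
    if (length(x$epochs) < 2) stop("need at least 2 epochs")
    if (nrow(x$epochs[[1]]) < 2) stop("need at least 2 channels")
    x <- band_cross_spectrum(x, band)
  }
  stopifnot(is.list(x), !is.null(x$rho))
  W <- suppressWarnings(lagged_phase_coherence(x$rho))
  W <- (W + t(W)) / 2 # enforce exact symmetry against rounding
  diag(W) <- 0
  dimnames(W) <- list(x$labels, x$labels)
  structure(list(W = W, band = x$band, n_epochs = x$n_epochs,
                 n_bins = x$n_bins, labels = x$labels),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  n <- nrow(x$W)
  cat(sprintf("<connectivity_matrix> band %s: %d nodes, %d edges, %d epochs\n",
              x$band$name, n, n * (n - 1) / 2, x$n_epochs))
  invisible(x)
}

#' Connectivity matrices for all bands
#'
#' @param ep An `epoch_set`.
#' @param bands Band table, default [canonical_bands()].
#' @return Named list of `connectivity_matrix` objects, one per band.
#' @export
connectivity_matrices <- function(ep, bands = canonical_bands()) {
  css <- cross_spectral_set(ep, bands)
  lapply(css, connectivity_matrix)
}

#' Significance threshold for lagged phase coherence
#'
#' Asymptotic null cutoff: under independence the scaled statistic
#' `n_epochs * n_bins * LPC` is referred to a chi-square distribution
#' with 1 df, and the test level is Bonferroni-corrected for the number
#' of simultaneous edges. The scaling is conservative (family-wise
#' false-positive rate at or below nominal), which the packaged
#' Monte-Carlo calibration test verifies.
#'
#' @param n_epochs Number of epochs entering the coherency average.
#' @param alpha_level Family-wise significance level, in (0, 1).
#' @param n_pairs Number of simultaneous comparisons (171 for 19 nodes).
#' @param n_bins Number of Fourier bins averaged inside the band.
#' @return LPC cutoff; values above it are declared significant.
#' @export
significance_threshold <- function(n_epochs, alpha_level = 0.05,
                                   n_pairs = 1, n_bins = 1) {
  stopifnot(n_epochs >= 2, alpha_level > 0, alpha_level < 1, n_pairs >= 1)
  stats::qchisq(1 - alpha_level / n_pairs, df = 1) / (n_epochs * n_bins)
}

#' Zero sub-threshold edges of a connectivity matrix
#'
#' Optional thresholding step: weighted analyses run on the full matrix
#' by default, but a Bonferroni-corrected cutoff can be applied to keep
#' only significant edges.
#'
#' @param cm A `connectivity_matrix`.
#' @param alpha_level Family-wise level passed to
#'   [significance_threshold()] with `n_pairs` = number of edges.
#' @return The thresholded `connectivity_matrix`.
#' @export
threshold_matrix <- function(cm, alpha_level = 0.05) {
  stopifnot(inherits(cm, "connectivity_matrix"))
  n <- nrow(cm$W)
  thr <- significance_threshold(cm$n_epochs, alpha_level,
                                n_pairs = n * (n - 1) / 2,
                                n_bins = cm$n_bins)
  cm$W[cm$W < thr] <- 0
  cm$threshold <- thr
  cm
}

#' Write / read a connectivity matrix as TSV + JSON sidecar
#'
#' The square matrix is stored as TSV with a header row of node labels;
#' band definition and epoch bookkeeping go to a JSON sidecar.
#'
#' @param cm A `connectivity_matrix`.
#' @param path TSV path (sidecar derived by swapping the extension).
#' @return Invisibly, the paths written.
#' @export
write_connectivity <- function(cm, path) {
  stopifnot(inherits(cm, "connectivity_matrix"))
  utils::write.table(cm$W, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  meta <- list(band = cm$band[c("name", "f_lo", "f_hi")],
               n_epochs = cm$n_epochs, n_bins = cm$n_bins,
               labels = cm$labels)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(c(data = path, sidecar = sidecar_path(path)))
}

#' @rdname write_connectivity
#' @param path TSV path previously written by [write_connectivity()].
#' @export
read_connectivity <- function(path) {
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  W <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                   check.names = FALSE))
  dimnames(W) <- list(meta$labels, meta$labels)
  structure(list(W = W,
                 band = band_definition(meta$band$name, meta$band$f_lo,
                                        meta$band$f_hi),
                 n_epochs = meta$n_epochs, n_bins = meta$n_bins,
                 labels = meta$labels),
            class = "connectivity_matrix")
}
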