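#' Construct a multichannel recording
#'
#' A recording bundles a channels x samples data matrix with its sampling
#' rate, channel labels and per-channel MNI coordinates (mm). All
#' downstream stages (preprocessing, spectra, connectivity) consume this
#' container.
#'
#' @param data Numeric matrix, channels in rows, samples in columns.
#' @param rate Sampling frequency in Hz (> 0).
#' @param labels Character vector of channel identifiers, one per row.
#' @param coords Numeric matrix (channels x 3) of (x, y, z) MNI
#'   coordinates in millimetres.
#' @return An object of class `recording`.
#' @export
recording <- function(data, rate, labels, coords) {
  data <- as.matrix(data)
  coords <- as.matrix(coords)
  if (!is.numeric(data) || !all(is.finite(data))) {
    stop("recording data must be a finite numeric matrix")
  }
  if (!is.numeric(rate) || length(rate) != 1 || rate <= 0) {
    stop("rate must be a single positive number (Hz)")
  }
  if (nrow(data) != length(labels)) {
    stop("number of labels (", length(labels),
         ") does not match number of channels (", nrow(data), ")")
  }
  if (nrow(coords) != nrow(data) || ncol(coords) != 3) {
    stop("coords must be a channels x 3 matrix")
  }
  if (ncol(data) < 2 * rate) {
    stop("recording must contain at least 2 s of data (", 2 * rate,
         " samples at ", rate, " Hz)")
  }
  rownames(data) <- labels
  rownames(coords) <- labels
  colnames(coords) <- c("x", "y", "z")
  structure(list(data = data, rate = rate,
                 labels = as.character(labels), coords = coords),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$rate, ncol(x$data) / x$rate))
  cat("  channels:", paste(utils::head(x$labels, 8), collapse = ", "),
      if (length(x$labels) > 8) "..." else "", "\n")
  invisible(x)
}

#' Write a recording to CSV plus JSON sidecar
#'
#' The data matrix is stored as headerless CSV with one row per channel
#' (samples in columns); rate, labels, coordinates and any simulation
#' provenance go to a JSON sidecar. `read_recording()` restores the
#' object losslessly.
#'
#' @param rec A `recording`.
#' @param path Output CSV path.
#' @param sidecar Sidecar path; default replaces the extension with `.json`.
#' @param extra Named list merged into the sidecar (e.g. seed, config).
#' @return Invisibly, the two paths written.
#' @export
write_recording <- function(rec, path, sidecar = NULL, extra = list()) {
  stopifnot(inherits(rec, "recording"))
  if (is.null(sidecar)) sidecar <- sidecar_path(path)
  utils::write.table(format(rec$data, digits = 17, trim = TRUE,
                            scientific = TRUE),
                     path, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  meta <- c(list(rate = rec$rate, labels = rec$labels,
                 coords = unname(apply(rec$coords, 1, as.numeric,
                                       simplify = FALSE))),
            extra)
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(c(data = path, sidecar = sidecar))
}

#' Read a recording from CSV plus JSON sidecar
#'
#' @param path CSV path (channels in rows, samples in columns; no header).
#' @param sidecar Sidecar JSON path; default derived from `path`.
#' @return A validated `recording`.
#' @export
read_recording <- function(path, sidecar = NULL) {
  if (is.null(sidecar)) sidecar <- sidecar_path(path)
  if (!file.exists(path)) stop("recording file not found: ", path)
  if (!file.exists(sidecar)) stop("sidecar not found: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(meta$rate)) stop("sidecar is missing the sampling rate")
  dat <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  dimnames(dat) <- NULL
  if (any(!is.finite(dat))) stop("recording contains non-finite values")
  labels <- as.character(meta$labels)
  if (length(labels) != nrow(dat)) {
    stop("sidecar lists ", length(labels), " labels but the matrix has ",
         nrow(dat), " rows")
  }
  coords <- meta$coords
  if (is.list(coords)) coords <- do.call(rbind, coords)
  recording(dat, meta$rate, labels, coords)
}

sidecar_path <- function(path) sub("\\.[^.]+$", ".json", path)
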