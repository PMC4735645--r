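#' Bundled electrode / region montages
#'
#' Two static coordinate tables ship with the package:
#' \describe{
#'   \item{`"1020-19"`}{The 19 scalp electrodes of the international
#'     10-20 placement (Fp1, Fp2, F7, F3, Fz, F4, F8, T7, C3, Cz, C4, T8,
#'     P7, P3, Pz, P4, P8, O1, O2) with approximate MNI positions (mm).}
#'   \item{`"ba-84"`}{84 Brodmann-area centroids (42 areas x 2
#'     hemispheres, ordered by area number with left before right). The
#'     coordinates are a plausible synthetic stand-in for an
#'     atlas-derived centroid table, adequate for distance-based
#'     analyses on simulated data; they are not atlas output.}
#' }
#' Row order is fixed: the table is returned exactly as packaged.
#'
#' @param name Montage identifier, `"1020-19"` or `"ba-84"`.
#' @return A list with `labels` (character) and `coords`
#'   (n x 3 numeric matrix, MNI mm).
#' @export
#' @examples
#' m <- bundled_montage("1020-19")
#' m$labels[1] # "Fp1"
bundled_montage <- function(name) {
  file <- switch(name,
    "1020-19" = "montage_1020_19.tsv",
    "ba-84"   = "montage_ba84_synthetic.tsv",
    stop("unknown montage: '", name, "' (available: \"1020-19\", \"ba-84\")")
  )
  path <- system.file("extdata", file, package = "lpcnet", mustWork = TRUE)
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  coords <- as.matrix(tab[, c("x", "y", "z")])
  rownames(coords) <- tab$label
  list(labels = tab$label, coords = coords)
}
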