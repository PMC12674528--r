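#' Build compartment-aware training labels from scene ground truth
#'
#' Implements the compartment-aware labelling rule at the heart of the
#' method: for cytoplasmic and membranous markers the entire cell region of
#' every truth-positive cell is labelled positive -- including the nucleus,
#' whatever its own staining -- so that extranuclear positivity is carried
#' onto the nuclear area; for nuclear markers only the nuclei themselves
#' are labelled. Everything else is background (0).
#'
#' @param scene a \linkS4class{SyntheticScene}.
#' @param markerName marker present in the scene.
#' @return A binary \linkS4class{LabelMask} (provenance "annotation",
#'   values 0/1).
#' @export
buildTrainingLabels <- function(scene, markerName) {
  truth <- scene@truth
  comp <- attr(truth, "compartments")
  if (!markerName %in% names(comp))
    stop("unknown marker '", markerName, "'; scene has: ",
         paste(names(comp), collapse = ", "))
  src <- if (comp[[markerName]] == "nuclear")
    scene@nucleusMask@labels else scene@cellMask@labels
  posIds <- truth$object_id[truth[[markerName]]]
  lab <- matrix(0L, nrow(src), ncol(src))
  lab[src %in% posIds] <- 1L
  LabelMask(lab, "annotation")
}

#' Load a hand-drawn annotation mask from a TIFF file
#'
#' Real-data path: a freehand annotation exported as a TIFF where nonzero
#' pixels mark positive regions.
#'
#' @param path TIFF path.
#' @return A binary \linkS4class{LabelMask} (provenance "annotation").
#' @export
loadAnnotationMask <- function(path) {
  m <- readLabelMask(path, "annotation")
  lab <- m@labels
  lab[lab != 0L] <- 1L
  LabelMask(lab, "annotation")
}

#' Tile an image/label pair into training patches
#'
#' Reflect-pads image and labels on the bottom/right to a stride-aligned
#' size and emits every \code{patch x patch} window at the given stride.
#' The union of patch footprints covers the padded image exactly.
#'
#' @param image a single-plane \linkS4class{MultichannelImage} or a matrix.
#' @param labels a binary \linkS4class{LabelMask} of the same shape.
#' @param patch patch side in pixels (receptive-field size; default 512).
#' @param stride step between window origins; defaults to \code{patch}
#'   (non-overlapping).
#' @return List of training patches; each is a list with elements
#'   \code{image} (matrix), \code{labels} (0/1 matrix), \code{marker}, and
#'   \code{offset} -- the 0-based (row, col) origin in the padded image.
#' @export
tilePatches <- function(image, labels, patch = 512L, stride = patch) {
  if (is(image, "MultichannelImage")) {
    mk <- image@channelNames[1]
    img <- image@planes[[1]]
  } else {
    mk <- NA_character_
    img <- image
  }
  lab <- if (is(labels, "LabelMask")) labels@labels else labels
  stopifnot(identical(dim(img), dim(lab)))
  if (!all(lab %in% c(0L, 1L))) stop("labels must be binary {0, 1}")
  if (stride <= 0) stop("stride must be positive")
  patch <- as.integer(patch); stride <- as.integer(stride)

  padTo <- function(n) {
    if (n <= patch) patch else patch + stride * ceiling((n - patch) / stride)
  }
  H <- padTo(nrow(img)); W <- padTo(ncol(img))
  ri <- reflectIndex(nrow(img), H)
  ci <- reflectIndex(ncol(img), W)
  imgP <- img[ri, ci, drop = FALSE]
  labP <- lab[ri, ci, drop = FALSE]

  starts <- function(n) seq.int(1L, n - patch + 1L, by = stride)
  out <- list()
  for (r0 in starts(H)) for (c0 in starts(W)) {
    rr <- r0:(r0 + patch - 1L); cc <- c0:(c0 + patch - 1L)
    out[[length(out) + 1L]] <- list(
      image = imgP[rr, cc, drop = FALSE],
      labels = labP[rr, cc, drop = FALSE],
      marker = mk, offset = c(r0 - 1L, c0 - 1L))
  }
  out
}

# mirror-reflection indices (no edge duplication) extending 1..n to 1..total
reflectIndex <- function(n, total) {
  if (n == 1L) return(rep(1L, total))
  period <- 2L * (n - 1L)
  k <- (seq_len(total) - 1L) %% period
  ifelse(k < n, k + 1L, period - k + 1L)
}
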