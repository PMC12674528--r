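#' @import methods
NULL

#' MultichannelImage: pixel planes with channel names and physical scale
#'
#' Container for a multiplex immunofluorescence (mIF) image: one 2-D
#' intensity plane per marker channel, an ordered vector of channel names,
#' and the physical pixel size in micrometres.
#'
#' @slot planes list of numeric matrices (row = image row, column = image
#'   column), all with identical dimensions; intensities are non-negative.
#' @slot channelNames character vector, one unique name per plane.
#' @slot umPerPixel single positive numeric, micrometres per pixel.
#'
#' @examples
#' img <- MultichannelImage(list(matrix(0, 4, 4)), "DAPI", umPerPixel = 0.5)
#' channelNames(img)
#' @export
setClass("MultichannelImage",
  representation(planes = "list", channelNames = "character",
                 umPerPixel = "numeric"))

setValidity("MultichannelImage", function(object) {
  p <- object@planes
  if (length(p) == 0L) return("at least one plane is required")
  if (!all(vapply(p, is.matrix, logical(1))))
    return("planes must be matrices")
  d <- vapply(p, dim, integer(2))
  if (any(d[1, ] != d[1, 1]) || any(d[2, ] != d[2, 1]))
    return("all planes must share identical height/width")
  if (length(object@channelNames) != length(p))
    return("channelNames length must equal number of planes")
  if (anyDuplicated(object@channelNames))
    return("channel names must be unique")
  if (length(object@umPerPixel) != 1L || is.na(object@umPerPixel) ||
      object@umPerPixel <= 0)
    return("umPerPixel must be a single positive number")
  TRUE
})

#' @rdname MultichannelImage-class
#' @param planes list of numeric matrices, or a single matrix.
#' @param channelNames character vector of marker names; defaults to
#'   \code{"ch0" ... "chN-1"}.
#' @param umPerPixel physical pixel size in micrometres.
#' @return A \code{MultichannelImage}.
#' @export
MultichannelImage <- function(planes, channelNames = NULL, umPerPixel) {
  if (is.matrix(planes)) planes <- list(planes)
  if (is.null(channelNames))
    channelNames <- paste0("ch", seq_along(planes) - 1L)
  new("MultichannelImage", planes = planes,
      channelNames = as.character(channelNames),
      umPerPixel = as.numeric(umPerPixel))
}

#' LabelMask: integer object map
#'
#' A 2-D raster of non-negative integer object ids; 0 denotes background.
#' Object ids are positive and need not be contiguous. Provenance records
#' whether the mask holds segmented nuclei, training annotations, or an
#' object-size variant.
#'
#' @slot labels integer matrix, values >= 0.
#' @slot provenance one of \code{"nuclei"}, \code{"annotation"},
#'   \code{"variant"}.
#' @export
setClass("LabelMask",
  representation(labels = "matrix", provenance = "character"))

setValidity("LabelMask", function(object) {
  l <- object@labels
  if (!is.numeric(l)) return("labels must be numeric")
  if (any(l < 0) || any(l != round(l)))
    return("labels must be non-negative integers")
  if (!object@provenance %in% c("nuclei", "annotation", "variant"))
    return("provenance must be one of nuclei/annotation/variant")
  TRUE
})

#' @rdname LabelMask-class
#' @param labels integer matrix (0 = background).
#' @param provenance character, see slots.
#' @return A \code{LabelMask}.
#' @export
LabelMask <- function(labels, provenance = "nuclei") {
  storage.mode(labels) <- "integer"
  new("LabelMask", labels = labels, provenance = provenance)
}

#' ProbabilityHeatmap: per-pixel positive-class probability for one marker
#'
#' The pixel classifier is two-class (Positive vs Background) with a
#' per-pixel softmax, so background probability is \code{1 - probs} and
#' only the positive plane is stored.
#'
#' @slot probs numeric matrix with values in [0, 1].
#' @slot marker marker name the heatmap belongs to.
#' @export
setClass("ProbabilityHeatmap",
  representation(probs = "matrix", marker = "character"))

setValidity("ProbabilityHeatmap", function(object) {
  p <- object@probs
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    return("probabilities must lie in [0, 1]")
  if (length(object@marker) != 1L) return("marker must be a single name")
  TRUE
})

#' @rdname ProbabilityHeatmap-class
#' @param probs numeric matrix in [0, 1].
#' @param marker marker name.
#' @return A \code{ProbabilityHeatmap}.
#' @export
ProbabilityHeatmap <- function(probs, marker) {
  new("ProbabilityHeatmap", probs = probs, marker = as.character(marker))
}

#' SyntheticScene: simulated mIF scene with known per-cell ground truth
#'
#' Holds the generative geometry of a synthetic tissue scene -- nucleus,
#' whole-cell and membrane label masks sharing object ids -- together with
#' the per-cell marker truth table the scene was drawn from. All fixtures
#' and benchmark experiments derive from this class, so downstream logic is
#' testable against exact ground truth.
#'
#' @slot nucleusMask,cellMask,membraneMask \code{LabelMask}s with shared ids.
#' @slot truth data.frame: \code{object_id}, \code{x}, \code{y} (nucleus
#'   centroid, pixel units, 0-based), and one logical column per marker
#'   (TRUE = positive); marker names and compartments are carried in the
#'   \code{"markers"} and \code{"compartments"} attributes.
#' @slot params the \code{SceneParams} list the scene was generated from.
#' @export
setClass("SyntheticScene",
  representation(nucleusMask = "LabelMask", cellMask = "LabelMask",
                 membraneMask = "LabelMask", truth = "data.frame",
                 params = "list"))

setValidity("SyntheticScene", function(object) {
  dn <- dim(object@nucleusMask@labels)
  if (!identical(dn, dim(object@cellMask@labels)) ||
      !identical(dn, dim(object@membraneMask@labels)))
    return("all masks must share dimensions")
  nl <- object@nucleusMask@labels
  cl <- object@cellMask@labels
  inside <- nl == 0L | nl == cl
  if (!all(inside))
    return("every nucleus pixel must belong to the same cell's pixel set")
  TRUE
})

#' PixelModel: a trained single-channel two-class U-Net pixel classifier
#'
#' @slot config the \code{trainConfig} list used for training.
#' @slot weights named list of parameter arrays.
#' @slot log data.frame of (iteration, loss) pairs recorded during training.
#' @export
setClass("PixelModel",
  representation(config = "list", weights = "list", log = "data.frame"))
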