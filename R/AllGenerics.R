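#' Accessors for pixphen classes
#'
#' @param object a pixphen object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("channelNames", function(object) standardGeneric("channelNames"))
#' @rdname accessors
#' @export
setGeneric("umPerPixel", function(object) standardGeneric("umPerPixel"))
#' @rdname accessors
#' @export
setGeneric("imgPlanes", function(object) standardGeneric("imgPlanes"))
#' @rdname accessors
#' @export
setGeneric("maskLabels", function(object) standardGeneric("maskLabels"))
#' @rdname accessors
#' @export
setGeneric("provenance", function(object) standardGeneric("provenance"))
#' @rdname accessors
#' @export
setGeneric("probs", function(object) standardGeneric("probs"))
#' @rdname accessors
#' @export
setGeneric("marker", function(object) standardGeneric("marker"))
#' @rdname accessors
#' @export
setGeneric("sceneTruth", function(object) standardGeneric("sceneTruth"))
#' @rdname accessors
#' @export
setGeneric("nucleusMask", function(object) standardGeneric("nucleusMask"))
#' @rdname accessors
#' @export
setGeneric("cellMask", function(object) standardGeneric("cellMask"))
#' @rdname accessors
#' @export
setGeneric("membraneMask", function(object) standardGeneric("membraneMask"))
#' @rdname accessors
#' @export
setGeneric("sceneConfig", function(object) standardGeneric("sceneConfig"))
#' @rdname accessors
#' @export
setGeneric("trainingLog", function(object) standardGeneric("trainingLog"))

#' @rdname accessors
setMethod("channelNames", "MultichannelImage",
          function(object) object@channelNames)
#' @rdname accessors
setMethod("umPerPixel", "MultichannelImage",
          function(object) object@umPerPixel)
#' @rdname accessors
setMethod("imgPlanes", "MultichannelImage", function(object) object@planes)
#' @rdname accessors
setMethod("maskLabels", "LabelMask", function(object) object@labels)
#' @rdname accessors
setMethod("provenance", "LabelMask", function(object) object@provenance)
#' @rdname accessors
setMethod("probs", "ProbabilityHeatmap", function(object) object@probs)
#' @rdname accessors
setMethod("marker", "ProbabilityHeatmap", function(object) object@marker)
#' @rdname accessors
setMethod("sceneTruth", "SyntheticScene", function(object) object@truth)
#' @rdname accessors
setMethod("nucleusMask", "SyntheticScene", function(object) object@nucleusMask)
#' @rdname accessors
setMethod("cellMask", "SyntheticScene", function(object) object@cellMask)
#' @rdname accessors
setMethod("membraneMask", "SyntheticScene",
          function(object) object@membraneMask)
#' @rdname accessors
setMethod("sceneConfig", "SyntheticScene", function(object) object@params)
#' @rdname accessors
setMethod("trainingLog", "PixelModel", function(object) object@log)

setMethod("show", "MultichannelImage", function(object) {
  d <- dim(object@planes[[1]])
  cat(sprintf("MultichannelImage: %d x %d px, %d channel(s), %.3g um/px\n",
              d[1], d[2], length(object@planes), object@umPerPixel))
  cat("  channels:", paste(object@channelNames, collapse = ", "), "\n")
})

setMethod("show", "LabelMask", function(object) {
  d <- dim(object@labels)
  ids <- setdiff(unique(as.vector(object@labels)), 0L)
  cat(sprintf("LabelMask (%s): %d x %d px, %d object(s)\n",
              object@provenance, d[1], d[2], length(ids)))
})

setMethod("show", "ProbabilityHeatmap", function(object) {
  d <- dim(object@probs)
  cat(sprintf("ProbabilityHeatmap [%s]: %d x %d px, range [%.3f, %.3f]\n",
              object@marker, d[1], d[2], min(object@probs),
              max(object@probs)))
})

setMethod("show", "SyntheticScene", function(object) {
  d <- dim(object@nucleusMask@labels)
  mk <- attr(object@truth, "markers")
  cat(sprintf("SyntheticScene: %d x %d px, %d cell(s)\n",
              d[1], d[2], nrow(object@truth)))
  if (!is.null(mk)) cat("  markers:", paste(mk, collapse = ", "), "\n")
})

setMethod("show", "PixelModel", function(object) {
  np <- sum(vapply(object@weights, length, integer(1)))
  cat(sprintf(
    "PixelModel: U-Net depth %d, base width %d, %d parameters, %d iteration(s)\n",
    object@config$depth, object@config$base_width, np,
    if (nrow(object@log)) max(object@log$iteration) else 0L))
})
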