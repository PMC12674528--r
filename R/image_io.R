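#' Read a multichannel TIFF / OME-TIFF image
#'
#' Reads all planes of a TIFF into a \linkS4class{MultichannelImage}.
#' Channel names and physical pixel size are taken, in order of preference,
#' from OME-XML in the TIFF ImageDescription tag, from a YAML sidecar
#' written by \code{\link{writeMultichannel}} (\code{<path>.meta.yaml}),
#' or from the arguments. Without any metadata, channels are named
#' \code{"ch0" ... "chN-1"} and \code{umPerPixel} must be supplied.
#'
#' @param path path to a TIFF file with >= 1 plane.
#' @param umPerPixel physical pixel size in micrometres; required when the
#'   file carries no pixel-size metadata.
#' @param channelNames optional explicit channel names overriding metadata.
#' @return A \linkS4class{MultichannelImage}.
#' @examples
#' tf <- tempfile(fileext = ".tif")
#' img <- MultichannelImage(list(matrix(1, 8, 8), matrix(2, 8, 8)),
#'                          c("DAPI", "CD8"), umPerPixel = 0.5)
#' writeMultichannel(img, tf)
#' readMultichannel(tf)
#' @export
readMultichannel <- function(path, umPerPixel = NULL, channelNames = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  pl <- tiff::readTIFF(path, all = TRUE, info = TRUE, as.is = FALSE)
  if (!is.list(pl)) pl <- list(pl)
  pl <- lapply(pl, .collapseGray)
  d <- vapply(pl, dim, integer(2))
  if (any(d[1, ] != d[1, 1]) || any(d[2, ] != d[2, 1]))
    stop("planes of differing shapes in ", path)
  meta <- .readImageMeta(path, attr(pl[[1]], "description"))
  nm <- channelNames %||% meta$channel_names %||%
    paste0("ch", seq_along(pl) - 1L)
  um <- umPerPixel %||% meta$um_per_pixel
  if (is.null(um))
    stop("no pixel-size metadata in ", path,
         "; supply umPerPixel explicitly")
  if (um <= 0) stop("umPerPixel must be positive")
  if (!is.null(meta$intensity_scale) && meta$intensity_scale != 1)
    pl <- lapply(pl, function(p) p * meta$intensity_scale)
  MultichannelImage(lapply(pl, .stripAttrs), nm, um)
}

#' Write a multichannel image as a multipage 32-bit TIFF
#'
#' Pixel data are stored one plane per TIFF page at 32-bit depth.
#' TIFF samples live on a normalized [0, 1] grid, so intensities are
#' divided by a common scale factor on write and multiplied back on read;
#' the scale, channel names and pixel size go to a YAML sidecar
#' (\code{<path>.meta.yaml}) that \code{\link{readMultichannel}} picks
#' up, since baseline TIFF has no channel-name tag. Round trips are exact
#' to the 32-bit quantization (relative error below 1e-9).
#'
#' @param img a \linkS4class{MultichannelImage}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeMultichannel <- function(img, path) {
  stopifnot(is(img, "MultichannelImage"))
  if (min(vapply(img@planes, min, numeric(1))) < 0)
    stop("negative intensities cannot be stored")
  scale <- max(1, vapply(img@planes, max, numeric(1)))
  tiff::writeTIFF(lapply(img@planes, function(p) p / scale), path,
                  bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  yaml::write_yaml(list(channel_names = as.list(img@channelNames),
                        um_per_pixel = img@umPerPixel,
                        intensity_scale = scale),
                   .sidecarPath(path))
  invisible(path)
}

#' Extract one channel from a multichannel image
#'
#' @param img a \linkS4class{MultichannelImage}.
#' @param markerName a channel name present in \code{channelNames(img)}.
#' @return A single-plane \linkS4class{MultichannelImage} with the same
#'   physical pixel size; pixel values unchanged.
#' @export
extractChannel <- function(img, markerName) {
  stopifnot(is(img, "MultichannelImage"))
  i <- match(markerName, img@channelNames)
  if (is.na(i))
    stop("unknown marker '", markerName, "'; available: ",
         paste(img@channelNames, collapse = ", "))
  MultichannelImage(img@planes[i], img@channelNames[i], img@umPerPixel)
}

# object ids are stored on the TIFF [0, 1] grid as id / 2^24, which the
# 32-bit samples represent without integer loss
.LABEL_SCALE <- 2^24

#' Read and write label masks as TIFF
#'
#' Label masks are written as 32-bit TIFF with object ids mapped onto the
#' normalized sample grid; the round trip is exact for ids below 2^24.
#'
#' @param mask a \linkS4class{LabelMask}.
#' @param path file path.
#' @param provenance provenance tag for the mask read back.
#' @return \code{writeLabelMask}: \code{path}, invisibly;
#'   \code{readLabelMask}: a \linkS4class{LabelMask}.
#' @export
writeLabelMask <- function(mask, path) {
  stopifnot(is(mask, "LabelMask"))
  m <- mask@labels
  if (max(m) >= .LABEL_SCALE) stop("object ids must be below 2^24")
  storage.mode(m) <- "double"
  tiff::writeTIFF(m / .LABEL_SCALE, path, bits.per.sample = 32L,
                  compression = "none", reduce = FALSE)
  invisible(path)
}

#' @rdname writeLabelMask
#' @export
readLabelMask <- function(path, provenance = "nuclei") {
  if (!file.exists(path)) stop("file not found: ", path)
  m <- tiff::readTIFF(path)
  LabelMask(round(.collapseGray(m) * .LABEL_SCALE), provenance)
}

#' Read and write probability heatmaps as 32-bit float TIFF
#'
#' @param heatmap a \linkS4class{ProbabilityHeatmap}.
#' @param path file path.
#' @param markerName marker name to attach on read.
#' @return \code{writeHeatmap}: \code{path}, invisibly;
#'   \code{readHeatmap}: a \linkS4class{ProbabilityHeatmap}.
#' @export
writeHeatmap <- function(heatmap, path) {
  stopifnot(is(heatmap, "ProbabilityHeatmap"))
  tiff::writeTIFF(heatmap@probs, path, bits.per.sample = 32L,
                  compression = "none", reduce = FALSE)
  invisible(path)
}

#' @rdname writeHeatmap
#' @export
readHeatmap <- function(path, markerName) {
  if (!file.exists(path)) stop("file not found: ", path)
  p <- .collapseGray(tiff::readTIFF(path))
  ProbabilityHeatmap(pmin(pmax(.stripAttrs(p), 0), 1), markerName)
}

#' Read and write per-cell tables as CSV
#'
#' A cell table is a data.frame with columns \code{object_id}, \code{x},
#' \code{y} (centroid, pixel units, 0-based \code{(x, y) = (column, row)}),
#' one call column per marker (values \code{"positive"}/\code{"negative"}),
#' and \code{phenotype}. Rows are written in ascending \code{object_id}
#' order.
#'
#' @param table a cell-table data.frame.
#' @param path file path.
#' @return \code{writeCellTable}: \code{path}, invisibly;
#'   \code{readCellTable}: a data.frame.
#' @export
writeCellTable <- function(table, path) {
  stopifnot(is.data.frame(table))
  if (nrow(table) && anyDuplicated(table$object_id))
    stop("object_id must be unique")
  if (nrow(table)) table <- table[order(table$object_id), , drop = FALSE]
  utils::write.csv(table, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname writeCellTable
#' @export
readCellTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}

#' Read and write YAML run configs
#'
#' @param config a named list.
#' @param path file path.
#' @return \code{readConfig}: a named list; \code{writeConfig}:
#'   \code{path}, invisibly.
#' @export
readConfig <- function(path) yaml::read_yaml(path)

#' @rdname readConfig
#' @export
writeConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.sidecarPath <- function(path) paste0(path, ".meta.yaml")

.stripAttrs <- function(m) {
  attributes(m) <- list(dim = dim(m))
  m
}

# readTIFF returns H x W x S arrays for multi-sample pages; collapse
# grayscale-with-alpha or RGB-identical planes to a matrix
.collapseGray <- function(m) {
  if (length(dim(m)) == 3L) m <- m[, , 1L, drop = TRUE]
  m
}

.readImageMeta <- function(path, description = NULL) {
  if (!is.null(description) && grepl("<OME", description, fixed = TRUE)) {
    ome <- tryCatch(.parseOmeDescription(description),
                    error = function(e) NULL)
    if (!is.null(ome)) return(ome)
  }
  sc <- .sidecarPath(path)
  if (file.exists(sc)) {
    y <- yaml::read_yaml(sc)
    return(list(channel_names = unlist(y$channel_names),
                um_per_pixel = y$um_per_pixel,
                intensity_scale = y$intensity_scale))
  }
  list(channel_names = NULL, um_per_pixel = NULL)
}

# Minimal OME-XML reader: Channel Name attributes and PhysicalSizeX
.parseOmeDescription <- function(description) {
  doc <- xml2::read_xml(description)
  ns <- xml2::xml_ns_strip(doc)
  px <- xml2::xml_find_first(doc, ".//Pixels")
  um <- as.numeric(xml2::xml_attr(px, "PhysicalSizeX"))
  ch <- xml2::xml_find_all(doc, ".//Channel")
  nm <- xml2::xml_attr(ch, "Name")
  list(channel_names = if (length(nm) && !all(is.na(nm))) nm else NULL,
       um_per_pixel = if (is.finite(um) && um > 0) um else NULL)
}
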