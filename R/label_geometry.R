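#' Dilate labelled objects by a Euclidean radius with collision handling
#'
#' Each object grows to all background pixels within Euclidean distance
#' \code{k} of its original pixels. Pixels claimed by two or more objects
#' go to the object whose original pixel set is nearest; exact distance
#' ties go to the smaller object id. Originally labelled pixels are never
#' reassigned and the object count is preserved.
#'
#' @param mask a \linkS4class{LabelMask}.
#' @param k dilation radius in pixels (>= 0).
#' @return A \linkS4class{LabelMask} (provenance "variant").
#' @examples
#' m <- matrix(0L, 7, 7); m[4, 4] <- 1L
#' maskLabels(dilateLabels(LabelMask(m), 1))[3:5, 3:5]
#' @export
dilateLabels <- function(mask, k) {
  stopifnot(is(mask, "LabelMask"))
  if (k < 0) stop("dilation radius k must be non-negative")
  lab <- mask@labels
  if (k == 0) return(LabelMask(lab, "variant"))
  ids <- setdiff(sort(unique(as.vector(lab))), 0L)
  out <- lab
  h <- nrow(lab); w <- ncol(lab)
  bestD <- matrix(Inf, h, w)
  kc <- as.integer(ceiling(k))
  for (id in ids) {
    px <- which(lab == id, arr.ind = TRUE)
    r0 <- max(1L, min(px[, 1]) - kc); r1 <- min(h, max(px[, 1]) + kc)
    c0 <- max(1L, min(px[, 2]) - kc); c1 <- min(w, max(px[, 2]) + kc)
    win <- lab[r0:r1, c0:c1]
    # distance of every window pixel to the nearest pixel of this object
    d <- EBImage::imageData(EBImage::distmap((win != id) * 1))
    d <- matrix(d, nrow(win))
    cand <- d <= k & win == 0L
    if (!any(cand)) next
    bw <- bestD[r0:r1, c0:c1]
    takeNew <- cand & d < bw - 1e-9  # ties keep the earlier (smaller) id
    ow <- out[r0:r1, c0:c1]
    ow[takeNew] <- id
    bw[takeNew] <- d[takeNew]
    out[r0:r1, c0:c1] <- ow
    bestD[r0:r1, c0:c1] <- bw
  }
  LabelMask(out, "variant")
}

#' Reduce each object to a single centre-of-mass pixel
#'
#' The unweighted pixel centroid of each object, rounded to the nearest
#' pixel (halves round up). If the rounded pixel falls outside the object
#' (non-convex shapes), the in-object pixel nearest the exact centroid is
#' used, with row-major tie-breaking. Object ids are preserved; the output
#' has exactly one pixel per object.
#'
#' @param mask a \linkS4class{LabelMask}.
#' @return A \linkS4class{LabelMask} (provenance "variant").
#' @export
centreOfMassPixel <- function(mask) {
  stopifnot(is(mask, "LabelMask"))
  lab <- mask@labels
  out <- matrix(0L, nrow(lab), ncol(lab))
  for (id in setdiff(sort(unique(as.vector(lab))), 0L)) {
    px <- which(lab == id, arr.ind = TRUE)
    cr <- mean(px[, 1]); cc <- mean(px[, 2])
    rr <- floor(cr + 0.5); rc <- floor(cc + 0.5)
    if (rr >= 1 && rr <= nrow(lab) && rc >= 1 && rc <= ncol(lab) &&
        lab[rr, rc] == id) {
      out[rr, rc] <- id
    } else {
      d2 <- (px[, 1] - cr)^2 + (px[, 2] - cc)^2
      near <- which(d2 <= min(d2) + 1e-9)
      pick <- near[order(px[near, 1], px[near, 2])][1]
      out[px[pick, 1], px[pick, 2]] <- id
    }
  }
  LabelMask(out, "variant")
}

#' Object-size variants of a nuclear label mask
#'
#' The five label geometries of the object-size study: whole nuclei,
#' nuclei dilated by 3 or 8 px, the single centre-of-mass pixel, and the
#' centre pixel dilated by 3 px.
#'
#' @param nuclei a \linkS4class{LabelMask} of nuclei.
#' @param variant one of \code{"nuclear"}, \code{"nuclear_dilate_3"},
#'   \code{"nuclear_dilate_8"}, \code{"com_pixel"},
#'   \code{"com_pixel_dilate_3"}, or the group number 1--5.
#' @return A \linkS4class{LabelMask}.
#' @export
makeVariant <- function(nuclei, variant) {
  kinds <- c("nuclear", "nuclear_dilate_3", "nuclear_dilate_8",
             "com_pixel", "com_pixel_dilate_3")
  if (is.numeric(variant)) {
    if (!variant %in% 1:5) stop("variant group must be 1..5")
    variant <- kinds[variant]
  }
  switch(match.arg(variant, kinds),
         nuclear = LabelMask(nuclei@labels, "variant"),
         nuclear_dilate_3 = dilateLabels(nuclei, 3),
         nuclear_dilate_8 = dilateLabels(nuclei, 8),
         com_pixel = centreOfMassPixel(nuclei),
         com_pixel_dilate_3 = dilateLabels(centreOfMassPixel(nuclei), 3))
}

#' @rdname makeVariant
#' @export
variantKinds <- function() c("nuclear", "nuclear_dilate_3",
                             "nuclear_dilate_8", "com_pixel",
                             "com_pixel_dilate_3")

#' Classical nuclear detection on a DAPI-like channel
#'
#' Gaussian smoothing, Otsu thresholding, distance-transform watershed
#' splitting and an object-area filter. A simple, dependency-light stand-in
#' for a learned nuclear segmenter; any method that labels nuclei can feed
#' the phenotyping stage.
#'
#' @param dapi single-plane \linkS4class{MultichannelImage} or matrix.
#' @param minArea,maxArea object area bounds in pixels.
#' @param sigma smoothing SD in pixels.
#' @param tolerance watershed tolerance.
#' @return A \linkS4class{LabelMask} (provenance "nuclei"); empty for a
#'   blank image.
#' @export
detectNuclei <- function(dapi, minArea = 20, maxArea = Inf, sigma = 2,
                         tolerance = 1) {
  img <- if (is(dapi, "MultichannelImage")) dapi@planes[[1]] else dapi
  h <- nrow(img); w <- ncol(img)
  if (max(img) <= min(img))
    return(LabelMask(matrix(0L, h, w), "nuclei"))
  sm <- EBImage::imageData(EBImage::gblur(img, sigma = sigma))
  sm <- matrix(sm, h)
  rng <- range(sm)
  smn <- (sm - rng[1]) / (rng[2] - rng[1])
  th <- EBImage::otsu(EBImage::Image(smn), range = c(0, 1))
  bin <- smn > th
  if (!any(bin)) return(LabelMask(matrix(0L, h, w), "nuclei"))
  d <- EBImage::distmap(bin * 1)
  wl <- EBImage::imageData(EBImage::watershed(d, tolerance = tolerance))
  wl <- matrix(as.integer(wl), h)
  sizes <- tabulate(wl[wl > 0L])
  drop <- which(sizes < minArea | sizes > maxArea)
  if (length(drop)) wl[wl %in% drop] <- 0L
  LabelMask(wl, "nuclei")
}

#' Centroids of labelled objects
#'
#' @param mask a \linkS4class{LabelMask}.
#' @return data.frame with \code{object_id}, \code{x}, \code{y} (0-based
#'   pixel coordinates, \code{(x, y) = (column, row)}).
#' @export
labelCentroids <- function(mask) {
  lab <- mask@labels
  ids <- setdiff(sort(unique(as.vector(lab))), 0L)
  if (!length(ids))
    return(data.frame(object_id = integer(0), x = numeric(0),
                      y = numeric(0)))
  px <- which(lab > 0L)
  rr <- (px - 1L) %% nrow(lab) + 1L
  cc <- (px - 1L) %/% nrow(lab) + 1L
  v <- lab[px]
  data.frame(object_id = ids,
             x = as.numeric(tapply(cc, v, mean))[match(ids, sort(ids))] - 1,
             y = as.numeric(tapply(rr, v, mean))[match(ids, sort(ids))] - 1)
}
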