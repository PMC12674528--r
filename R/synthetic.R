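#' Marker specification for the synthetic mIF simulator
#'
#' Describes one marker channel: its subcellular compartment and the mean
#' staining intensity of positive and negative cells. The negative mean
#' models bleed-through / endogenous low-level signal and defaults to 0.
#'
#' @param name marker name.
#' @param compartment one of \code{"nuclear"}, \code{"cytoplasmic"},
#'   \code{"membranous"}.
#' @param meanPositive mean intensity added over the marker's compartment
#'   pixels in positive cells (arbitrary fluorescence units; images are
#'   rendered on a [0, 1]-ish scale).
#' @param meanNegative mean intensity in negative cells; must be smaller
#'   than \code{meanPositive}.
#' @param positiveFraction probability that a cell is truth-positive for
#'   this marker.
#' @return A named list of class \code{"markerSpec"}.
#' @export
markerSpec <- function(name, compartment = c("nuclear", "cytoplasmic",
                                             "membranous"),
                       meanPositive = 0.6, meanNegative = 0,
                       positiveFraction = 0.4) {
  compartment <- match.arg(compartment)
  if (meanPositive <= meanNegative || meanNegative < 0)
    stop("need meanPositive > meanNegative >= 0")
  if (positiveFraction < 0 || positiveFraction > 1)
    stop("positiveFraction must be in [0, 1]")
  structure(list(name = name, compartment = compartment,
                 meanPositive = meanPositive, meanNegative = meanNegative,
                 positiveFraction = positiveFraction),
            class = "markerSpec")
}

#' Parameters of a synthetic mIF scene
#'
#' The defaults describe a moderately dense field of roundish cells at the
#' scale of a 20x mIF acquisition (0.5 um/px): nuclei of 5--8 px radius,
#' cytoplasm 3--6 px thick, a 2 px membrane band, lognormal per-cell
#' brightness variation and additive Gaussian sensor noise over a constant
#' background.
#'
#' @param height,width scene size in pixels.
#' @param nCells number of cells to place.
#' @param nucleusRadiusRange,cytoplasmThicknessRange min/max in pixels.
#' @param membraneWidth membrane band width in pixels.
#' @param markerSpecs list of \code{\link{markerSpec}} objects.
#' @param spindleFraction fraction of elongated (axis ratio 4) cells.
#' @param noise list with \code{background_level} (constant offset),
#'   \code{gaussian_sigma} (additive pixel noise SD) and
#'   \code{intensity_cv} (lognormal per-cell brightness CV).
#' @param dapiIntensity mean nuclear counterstain intensity.
#' @param umPerPixel physical pixel size for rendered images.
#' @param seed integer seed; every render derived from the scene is
#'   deterministic given this seed.
#' @return A named list of class \code{"sceneParams"}.
#' @export
sceneParams <- function(height = 512L, width = 512L, nCells = 60L,
                        nucleusRadiusRange = c(5, 8),
                        cytoplasmThicknessRange = c(3, 6),
                        membraneWidth = 2L,
                        markerSpecs = defaultMarkerPanel(),
                        spindleFraction = 0,
                        noise = list(background_level = 0.05,
                                     gaussian_sigma = 0.02,
                                     intensity_cv = 0.3),
                        dapiIntensity = 0.8, umPerPixel = 0.5,
                        seed = 1L) {
  stopifnot(nCells >= 0, height > 0, width > 0,
            all(nucleusRadiusRange > 0), all(cytoplasmThicknessRange > 0),
            membraneWidth >= 1, spindleFraction >= 0, spindleFraction <= 1)
  nm <- vapply(markerSpecs, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("marker names must be unique")
  structure(list(height = as.integer(height), width = as.integer(width),
                 nCells = as.integer(nCells),
                 nucleusRadiusRange = nucleusRadiusRange,
                 cytoplasmThicknessRange = cytoplasmThicknessRange,
                 membraneWidth = as.integer(membraneWidth),
                 markerSpecs = markerSpecs,
                 spindleFraction = spindleFraction, noise = noise,
                 dapiIntensity = dapiIntensity, umPerPixel = umPerPixel,
                 seed = as.integer(seed)),
            class = "sceneParams")
}

#' Default three-marker panel: one marker per compartment
#'
#' A nuclear, a cytoplasmic and a membranous marker with mutually exclusive
#' usage in the default lineage scheme (see
#' \code{\link{defaultPhenotypeScheme}}).
#'
#' @param meanPositive,meanNegative,positiveFraction passed to each
#'   \code{\link{markerSpec}}.
#' @return List of three \code{markerSpec}s (FOXP3 nuclear, panCK
#'   cytoplasmic, PDL1 membranous).
#' @export
defaultMarkerPanel <- function(meanPositive = 0.6, meanNegative = 0,
                               positiveFraction = 0.35) {
  list(markerSpec("FOXP3", "nuclear", meanPositive, meanNegative,
                  positiveFraction),
       markerSpec("panCK", "cytoplasmic", meanPositive, meanNegative,
                  positiveFraction),
       markerSpec("PDL1", "membranous", meanPositive, meanNegative,
                  positiveFraction))
}

#' Simulate a synthetic mIF scene with known ground truth
#'
#' Places \code{nCells} cells by rejection sampling so that nuclei never
#' overlap (cytoplasm may touch). Each cell is a nuclear ellipse (circular
#' by default; elongated with axis ratio 4 for the spindle fraction) inside
#' a concentric cell ellipse; contested cytoplasm pixels go to the cell
#' whose normalized ellipse metric is smallest. The membrane band of each
#' cell is its painted region minus its morphological erosion by a disc of
#' radius \code{membraneWidth}. Per-marker truth is drawn i.i.d. with the
#' marker's \code{positiveFraction}. Deterministic given
#' \code{params$seed}.
#'
#' @param params a \code{\link{sceneParams}} list.
#' @param maxTries placement attempts per cell before giving up.
#' @return A \linkS4class{SyntheticScene}.
#' @examples
#' sc <- simulateScene(sceneParams(height = 128, width = 128, nCells = 8,
#'                                 seed = 7))
#' head(sceneTruth(sc))
#' @export
simulateScene <- function(params, maxTries = 200L) {
  stopifnot(inherits(params, "sceneParams"))
  withr::with_seed(params$seed, .simulateSceneImpl(params, maxTries))
}

.simulateSceneImpl <- function(params, maxTries) {
  h <- params$height; w <- params$width; n <- params$nCells
  rr <- params$nucleusRadiusRange; tr <- params$cytoplasmThicknessRange

  cen <- matrix(0, n, 2)  # (row, col)
  nucA <- nucB <- cellA <- cellB <- theta <- numeric(n)
  placed <- 0L
  if (n > 0) {
    for (i in seq_len(n)) {
      r <- stats::runif(1, rr[1], rr[2])
      t <- stats::runif(1, tr[1], tr[2])
      spindle <- stats::runif(1) < params$spindleFraction
      na <- if (spindle) 2 * r else r
      nb <- if (spindle) r / 2 else r
      th <- stats::runif(1, 0, pi)
      ca <- na + t; cb <- nb + t
      margin <- ca + 1
      if (2 * margin >= min(h, w))
        stop("scene too small for the requested cell size")
      ok <- FALSE
      for (try in seq_len(maxTries)) {
        p <- c(stats::runif(1, margin, h - margin),
               stats::runif(1, margin, w - margin))
        if (placed == 0L) { ok <- TRUE; break }
        jj <- seq_len(placed)
        d <- sqrt((cen[jj, 1] - p[1])^2 + (cen[jj, 2] - p[2])^2)
        # conservative circumscribed-circle test keeps nuclei disjoint
        if (all(d > max(na, nb) + pmax(nucA[jj], nucB[jj]) + 1.5)) {
          ok <- TRUE; break
        }
      }
      if (!ok) stop("scene too crowded: nucleus placement failed after ",
                    maxTries, " tries (cell ", i, ")")
      placed <- placed + 1L
      cen[placed, ] <- p
      nucA[placed] <- na; nucB[placed] <- nb
      cellA[placed] <- ca; cellB[placed] <- cb
      theta[placed] <- th
    }
  }

  nucLab <- matrix(0L, h, w)
  cellLab <- matrix(0L, h, w)
  bestMetric <- matrix(Inf, h, w)
  for (i in seq_len(n)) {
    bb <- .ellipseBBox(cen[i, ], cellA[i], h, w)
    rows <- bb$rows; cols <- bb$cols
    dR <- outer(rows - cen[i, 1], rep(1, length(cols)))
    dC <- outer(rep(1, length(rows)), cols - cen[i, 2])
    u <- dR * cos(theta[i]) + dC * sin(theta[i])
    v <- -dR * sin(theta[i]) + dC * cos(theta[i])
    mCell <- (u / cellA[i])^2 + (v / cellB[i])^2
    mNuc <- (u / nucA[i])^2 + (v / nucB[i])^2
    win <- bestMetric[rows, cols]
    take <- mCell <= 1 & mCell < win
    cl <- cellLab[rows, cols]
    cl[take] <- i
    cellLab[rows, cols] <- cl
    win[take] <- mCell[take]
    bestMetric[rows, cols] <- win
    nl <- nucLab[rows, cols]
    nl[mNuc <= 1] <- i
    nucLab[rows, cols] <- nl
  }
  cellLab[nucLab > 0L] <- nucLab[nucLab > 0L]

  memLab <- .membraneBand(cellLab, params$membraneWidth)

  truth <- data.frame(object_id = seq_len(n))
  if (n > 0) {
    truth$x <- cen[, 2] - 1  # 0-based (x, y) = (column, row)
    truth$y <- cen[, 1] - 1
  } else {
    truth$x <- numeric(0); truth$y <- numeric(0)
  }
  comp <- character(0)
  for (ms in params$markerSpecs) {
    truth[[ms$name]] <- if (n > 0)
      stats::runif(n) < ms$positiveFraction else logical(0)
    comp <- c(comp, ms$compartment)
  }
  mk <- vapply(params$markerSpecs, `[[`, character(1), "name")
  attr(truth, "markers") <- mk
  attr(truth, "compartments") <- stats::setNames(comp, mk)

  new("SyntheticScene",
      nucleusMask = LabelMask(nucLab, "nuclei"),
      cellMask = LabelMask(cellLab, "nuclei"),
      membraneMask = LabelMask(memLab, "variant"),
      truth = truth, params = unclass(params))
}

.ellipseBBox <- function(center, radius, h, w) {
  r0 <- max(1L, floor(center[1] - radius - 1))
  r1 <- min(h, ceiling(center[1] + radius + 1))
  c0 <- max(1L, floor(center[2] - radius - 1))
  c1 <- min(w, ceiling(center[2] + radius + 1))
  list(rows = r0:r1, cols = c0:c1)
}

# membrane band = painted cell region minus its erosion by a disc
.membraneBand <- function(cellLab, width) {
  mem <- matrix(0L, nrow(cellLab), ncol(cellLab))
  ids <- setdiff(sort(unique(as.vector(cellLab))), 0L)
  if (!length(ids)) return(mem)
  brush <- EBImage::makeBrush(2L * width + 1L, shape = "disc")
  for (i in ids) {
    px <- which(cellLab == i, arr.ind = TRUE)
    r0 <- max(1L, min(px[, 1]) - 1L); r1 <- min(nrow(cellLab), max(px[, 1]) + 1L)
    c0 <- max(1L, min(px[, 2]) - 1L); c1 <- min(ncol(cellLab), max(px[, 2]) + 1L)
    bin <- (cellLab[r0:r1, c0:c1] == i) * 1
    er <- EBImage::erode(bin, brush)
    band <- bin > 0 & !(er > 0)
    sub <- mem[r0:r1, c0:c1]
    sub[band] <- i
    mem[r0:r1, c0:c1] <- sub
  }
  mem
}

# deterministic per-(scene, channel) sub-seed below 2^31
.channelSeed <- function(seed, markerName) {
  hsh <- sum(utf8ToInt(markerName) * seq_along(utf8ToInt(markerName)))
  as.integer((as.numeric(seed) * 10007 + hsh * 97) %% 2147483647)
}

#' Render one marker channel of a synthetic scene
#'
#' Positive cells receive the marker's \code{meanPositive} intensity over
#' its compartment pixels (nuclear = nucleus, cytoplasmic = whole cell
#' interior, membranous = membrane band); negative cells receive
#' \code{meanNegative}. Each cell's intensity is multiplied by a lognormal
#' factor with coefficient of variation \code{noise$intensity_cv}; the
#' constant \code{noise$background_level} and i.i.d. Gaussian noise with SD
#' \code{noise$gaussian_sigma} are added, and the result is clipped at 0.
#' Deterministic given the scene seed and marker name.
#'
#' @param scene a \linkS4class{SyntheticScene}.
#' @param markerName a marker present in the scene.
#' @return A single-plane \linkS4class{MultichannelImage}.
#' @export
renderChannel <- function(scene, markerName) {
  p <- scene@params
  ms <- NULL
  for (m in p$markerSpecs) if (m$name == markerName) ms <- m
  if (is.null(ms))
    stop("unknown marker '", markerName, "'; scene has: ",
         paste(vapply(p$markerSpecs, `[[`, character(1), "name"),
               collapse = ", "))
  compMask <- switch(ms$compartment,
                     nuclear = scene@nucleusMask@labels,
                     cytoplasmic = scene@cellMask@labels,
                     membranous = scene@membraneMask@labels)
  pos <- scene@truth[[markerName]]
  means <- ifelse(pos, ms$meanPositive, ms$meanNegative)
  withr::with_seed(.channelSeed(p$seed, markerName),
                   .renderCompartment(compMask, means, p, p$umPerPixel,
                                      markerName))
}

#' Render the DAPI-like nuclear counterstain of a synthetic scene
#'
#' All nuclei are bright regardless of marker truth; same noise model as
#' \code{\link{renderChannel}}.
#'
#' @param scene a \linkS4class{SyntheticScene}.
#' @return A single-plane \linkS4class{MultichannelImage} named "DAPI".
#' @export
renderDapi <- function(scene) {
  p <- scene@params
  n <- nrow(scene@truth)
  withr::with_seed(.channelSeed(p$seed, "DAPI"),
                   .renderCompartment(scene@nucleusMask@labels,
                                      rep(p$dapiIntensity, n), p,
                                      p$umPerPixel, "DAPI"))
}

.renderCompartment <- function(compMask, cellMeans, p, umPerPixel, name) {
  img <- matrix(0, nrow(compMask), ncol(compMask))
  n <- length(cellMeans)
  cv <- p$noise$intensity_cv
  if (n > 0) {
    if (cv > 0) {
      s2 <- log(1 + cv^2)
      fac <- stats::rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))
    } else fac <- rep(1, n)
    amp <- cellMeans * fac
    inObj <- compMask > 0L
    img[inObj] <- amp[compMask[inObj]]
  }
  img <- img + p$noise$background_level
  if (p$noise$gaussian_sigma > 0)
    img <- img + matrix(stats::rnorm(length(img), 0, p$noise$gaussian_sigma),
                        nrow(img))
  img[img < 0] <- 0
  MultichannelImage(list(img), name, umPerPixel)
}

#' Render every channel of a scene as one multichannel image
#'
#' DAPI first, then all markers in panel order.
#'
#' @param scene a \linkS4class{SyntheticScene}.
#' @return A \linkS4class{MultichannelImage}.
#' @export
renderScene <- function(scene) {
  mk <- attr(scene@truth, "markers")
  imgs <- c(list(renderDapi(scene)),
            lapply(mk, function(m) renderChannel(scene, m)))
  MultichannelImage(lapply(imgs, function(i) i@planes[[1]]),
                    c("DAPI", mk), scene@params$umPerPixel)
}
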