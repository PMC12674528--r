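#' Positivity rule: confidence and coverage thresholds
#'
#' An object is marker-positive when at least \code{coverage} of its pixels
#' have positive probability at or above \code{confidence}; both bounds
#' are inclusive. Defaults are 50\% confidence and 80\% coverage. A
#' mean-probability mode (positive when the object's mean heatmap
#' probability is at least \code{confidence}) is available as an
#' alternative.
#'
#' @param confidence probability threshold in [0, 1].
#' @param coverage minimum fraction of object pixels at or above the
#'   confidence threshold.
#' @param mode \code{"coverage"} (default) or \code{"mean"}.
#' @return A named list of class \code{"positivityRule"}.
#' @export
positivityRule <- function(confidence = 0.5, coverage = 0.8,
                           mode = c("coverage", "mean")) {
  mode <- match.arg(mode)
  stopifnot(confidence >= 0, confidence <= 1,
            coverage >= 0, coverage <= 1)
  structure(list(confidence = confidence, coverage = coverage, mode = mode),
            class = "positivityRule")
}

#' Call per-object marker positivity from a probability heatmap
#'
#' For every object, the coverage fraction is the share of its pixels with
#' heatmap probability at or above the rule's confidence; the object is
#' positive when that fraction is at or above the rule's coverage (both
#' inclusive). Nuclear labels suffice as objects: the compartment-aware
#' training transfers whole-cell positivity onto nuclear pixels.
#'
#' @param heatmap a \linkS4class{ProbabilityHeatmap}.
#' @param objects a \linkS4class{LabelMask} of the same shape.
#' @param rule a \code{\link{positivityRule}}.
#' @return data.frame with \code{object_id}, \code{coverage} (or
#'   \code{mean_prob} in mean mode), and \code{call}
#'   (\code{"positive"}/\code{"negative"}); empty for an empty mask.
#' @export
assignPositivity <- function(heatmap, objects, rule = positivityRule()) {
  stopifnot(is(heatmap, "ProbabilityHeatmap"), is(objects, "LabelMask"))
  p <- heatmap@probs
  lab <- objects@labels
  if (!identical(dim(p), dim(lab)))
    stop("heatmap and object mask shapes differ")
  inObj <- lab > 0L
  ids <- sort(unique(lab[inObj]))
  if (!length(ids))
    return(data.frame(object_id = integer(0), coverage = numeric(0),
                      call = character(0)))
  v <- lab[inObj]
  pv <- p[inObj]
  npix <- as.vector(rowsum(rep(1, length(v)), v))
  if (rule$mode == "mean") {
    stat <- as.vector(rowsum(pv, v)) / npix
    call <- ifelse(stat >= rule$confidence, "positive", "negative")
    out <- data.frame(object_id = ids, mean_prob = stat, call = call)
  } else {
    hit <- as.vector(rowsum(as.numeric(pv >= rule$confidence), v))
    stat <- hit / npix
    call <- ifelse(stat >= rule$coverage, "positive", "negative")
    out <- data.frame(object_id = ids, coverage = stat, call = call)
  }
  rownames(out) <- NULL
  out
}

#' Sweep positivity calls across confidence thresholds
#'
#' Runs \code{\link{assignPositivity}} at each confidence with a fixed
#' coverage. The default sweep is 10\%, 25\%, 50\%, 75\% and 90\%.
#' Positive sets are nested: every object positive at a higher confidence
#' is positive at any lower one.
#'
#' @param heatmap a \linkS4class{ProbabilityHeatmap}.
#' @param objects a \linkS4class{LabelMask}.
#' @param confidences numeric vector of thresholds in [0, 1].
#' @param coverage coverage threshold shared across the sweep.
#' @param mode rule mode, as \code{\link{positivityRule}}.
#' @return Long data.frame with columns \code{confidence} plus the
#'   \code{assignPositivity} columns.
#' @export
confidenceSweep <- function(heatmap, objects,
                            confidences = c(0.10, 0.25, 0.50, 0.75, 0.90),
                            coverage = 0.8, mode = "coverage") {
  stopifnot(all(confidences >= 0), all(confidences <= 1))
  out <- lapply(confidences, function(cf) {
    r <- assignPositivity(heatmap, objects,
                          positivityRule(cf, coverage, mode))
    if (nrow(r)) cbind(confidence = cf, r)
    else cbind(r, confidence = numeric(0))[, c(3, 1, 2)]
  })
  do.call(rbind, out)
}

#' Phenotype scheme: ordered lineage definitions
#'
#' Each definition names the markers an object must be positive for and
#' (optionally) negative for. With exclusivity on (the default), an object
#' matching two or more definitions -- i.e. co-positive for mutually
#' exclusive lineage markers -- is reclassified as the conflict label
#' ("unclassifiable"); an object matching none gets the fallback label.
#' With exclusivity off, the first matching definition in order wins.
#'
#' @param definitions list of lists with \code{name}, \code{positive}
#'   (character vector of required-positive markers) and optional
#'   \code{negative}.
#' @param exclusive logical.
#' @param fallback label for objects matching no definition.
#' @param conflictLabel label for exclusivity conflicts.
#' @return A named list of class \code{"phenotypeScheme"}.
#' @export
phenotypeScheme <- function(definitions, exclusive = TRUE,
                            fallback = "negative",
                            conflictLabel = "unclassifiable") {
  nms <- vapply(definitions, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("phenotype names must be unique")
  markers <- unique(unlist(lapply(definitions, function(d)
    c(d$positive, d$negative))))
  structure(list(definitions = definitions, exclusive = exclusive,
                 fallback = fallback, conflictLabel = conflictLabel,
                 markers = markers, names = nms),
            class = "phenotypeScheme")
}

#' Default single-marker lineage scheme for the built-in panel
#'
#' One exclusive lineage per marker of \code{\link{defaultMarkerPanel}}.
#'
#' @return A \code{\link{phenotypeScheme}}.
#' @export
defaultPhenotypeScheme <- function() {
  phenotypeScheme(list(
    list(name = "Treg", positive = "FOXP3"),
    list(name = "epithelial", positive = "panCK"),
    list(name = "PDL1pos", positive = "PDL1")))
}

#' Resolve per-marker calls into a phenotype label per object
#'
#' @param calls data.frame with \code{object_id} and one column per scheme
#'   marker holding \code{"positive"}/\code{"negative"}.
#' @param scheme a \code{\link{phenotypeScheme}}.
#' @return Character vector of phenotype labels, one per row of
#'   \code{calls}.
#' @export
resolvePhenotype <- function(calls, scheme) {
  stopifnot(inherits(scheme, "phenotypeScheme"))
  missing <- setdiff(scheme$markers, names(calls))
  if (length(missing))
    stop("calls are missing scheme marker(s): ",
         paste(missing, collapse = ", "))
  n <- nrow(calls)
  if (!n) return(character(0))
  match1 <- vapply(scheme$definitions, function(d) {
    ok <- rep(TRUE, n)
    for (m in d$positive) ok <- ok & calls[[m]] == "positive"
    for (m in d$negative) ok <- ok & calls[[m]] == "negative"
    ok
  }, logical(n))
  match1 <- matrix(match1, nrow = n)
  nm <- rowSums(match1)
  out <- rep(scheme$fallback, n)
  one <- nm == 1L
  if (any(one))
    out[one] <- scheme$names[apply(match1[one, , drop = FALSE], 1, which)]
  multi <- nm >= 2L
  if (any(multi))
    out[multi] <- if (scheme$exclusive) scheme$conflictLabel else
      scheme$names[apply(match1[multi, , drop = FALSE], 1, which.max)]
  out
}

#' Full segmentation-free phenotyping pipeline
#'
#' Per scheme marker, obtains a probability heatmap (from a supplied
#' heatmap, or by running a trained model on the marker's channel), calls
#' per-object positivity over the nuclear labels, and resolves phenotypes.
#' No whole-cell segmentation is used at any point.
#'
#' @param heatmaps named list of \linkS4class{ProbabilityHeatmap}s, one
#'   per scheme marker; alternatively NULL to compute them from
#'   \code{models} and \code{image}.
#' @param nuclei a \linkS4class{LabelMask} of nuclear labels.
#' @param rule a \code{\link{positivityRule}}.
#' @param scheme a \code{\link{phenotypeScheme}}.
#' @param models named list of \linkS4class{PixelModel}s (one per marker),
#'   used when \code{heatmaps} is NULL.
#' @param image a \linkS4class{MultichannelImage} holding the marker
#'   channels, used with \code{models}.
#' @param tile,overlap tiling parameters for \code{\link{predictHeatmap}}.
#' @return A cell table: \code{object_id}, \code{x}, \code{y}, one call
#'   column per marker, \code{phenotype}.
#' @export
phenotypePipeline <- function(heatmaps = NULL, nuclei, rule, scheme,
                              models = NULL, image = NULL, tile = 512L,
                              overlap = NULL) {
  stopifnot(is(nuclei, "LabelMask"), inherits(scheme, "phenotypeScheme"))
  if (is.null(heatmaps)) {
    if (is.null(models) || is.null(image))
      stop("supply either heatmaps or models + image")
    missing <- setdiff(scheme$markers, names(models))
    if (length(missing))
      stop("no model for scheme marker(s): ",
           paste(missing, collapse = ", "))
    heatmaps <- lapply(stats::setNames(scheme$markers, scheme$markers),
                       function(m) predictHeatmap(models[[m]],
                                                  extractChannel(image, m),
                                                  tile = tile,
                                                  overlap = overlap))
  }
  missing <- setdiff(scheme$markers, names(heatmaps))
  if (length(missing))
    stop("no heatmap for scheme marker(s): ",
         paste(missing, collapse = ", "))
  tab <- labelCentroids(nuclei)
  for (m in scheme$markers) {
    r <- assignPositivity(heatmaps[[m]], nuclei, rule)
    tab[[m]] <- r$call[match(tab$object_id, r$object_id)]
  }
  tab$phenotype <- resolvePhenotype(tab, scheme)
  tab
}
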