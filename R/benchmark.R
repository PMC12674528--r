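#' Mean-intensity marker positivity (classical baseline)
#'
#' Per-object arithmetic mean of pixel intensities, thresholded
#' inclusively: positive when mean >= threshold, as in intensity-gated
#' phenotyping built into most commercial platforms.
#'
#' @param image single-plane \linkS4class{MultichannelImage} or matrix.
#' @param objects a \linkS4class{LabelMask} of the same shape.
#' @param threshold positivity threshold on the mean intensity.
#' @return data.frame with \code{object_id}, \code{mean_intensity},
#'   \code{call}.
#' @export
meanIntensityPositivity <- function(image, objects, threshold) {
  img <- if (is(image, "MultichannelImage")) image@planes[[1]] else image
  stopifnot(is(objects, "LabelMask"))
  lab <- objects@labels
  if (!identical(dim(img), dim(lab)))
    stop("image and object mask shapes differ")
  inObj <- lab > 0L
  ids <- sort(unique(lab[inObj]))
  if (!length(ids))
    return(data.frame(object_id = integer(0), mean_intensity = numeric(0),
                      call = character(0)))
  v <- lab[inObj]
  mi <- as.vector(rowsum(img[inObj], v)) /
    as.vector(rowsum(rep(1, length(v)), v))
  data.frame(object_id = ids, mean_intensity = mi,
             call = ifelse(mi >= threshold, "positive", "negative"))
}

#' Nuclear expansion followed by mean-intensity gating
#'
#' The classical whole-cell approximation this method replaces: dilate the
#' nuclear labels by \code{k} pixels, then gate on the mean intensity over
#' the expanded objects.
#'
#' @param image single-plane image or matrix.
#' @param nuclei nuclear \linkS4class{LabelMask}.
#' @param k expansion radius in pixels.
#' @param threshold mean-intensity threshold.
#' @return As \code{\link{meanIntensityPositivity}}.
#' @export
expandAndMeasure <- function(image, nuclei, k, threshold) {
  meanIntensityPositivity(image, dilateLabels(nuclei, k), threshold)
}

#' Weighted multiclass classification metrics
#'
#' Support-weighted precision, recall and F1 over the truth classes,
#' overall accuracy, and the confusion matrix (rows = truth, columns =
#' predicted). Optionally a support-weighted one-vs-rest AUC-ROC when
#' per-class scores are supplied.
#'
#' @param truth character vector of true labels.
#' @param predicted character vector of predicted labels (may contain
#'   labels absent from truth, e.g. "unclassifiable").
#' @param classes optional class order for the confusion matrix; defaults
#'   to the union of observed labels.
#' @param scores optional numeric matrix (objects x classes, named
#'   columns) of per-class scores for AUC.
#' @param normalize one of \code{"none"}, \code{"prediction"} (column) or
#'   \code{"truth"} (row) normalization of the reported confusion matrix;
#'   the raw matrix is always kept in \code{confusion_counts}.
#' @return A list of class \code{"MetricsReport"}: \code{f1},
#'   \code{accuracy}, \code{precision}, \code{recall}, optional
#'   \code{auc}, \code{confusion}, \code{confusion_counts},
#'   \code{per_class}, \code{n}.
#' @examples
#' weightedMetrics(c("A", "A", "B", "B"), c("A", "B", "B", "B"))$f1
#' @export
weightedMetrics <- function(truth, predicted, classes = NULL,
                            scores = NULL,
                            normalize = c("none", "prediction", "truth")) {
  normalize <- match.arg(normalize)
  if (length(truth) != length(predicted))
    stop("truth and predicted must have equal length")
  if (!length(truth)) stop("empty input")
  truth <- as.character(truth); predicted <- as.character(predicted)
  if (is.null(classes)) classes <- sort(unique(c(truth, predicted)))
  else classes <- unique(c(classes, setdiff(unique(c(truth, predicted)),
                                            classes)))
  tf <- factor(truth, levels = classes)
  pf <- factor(predicted, levels = classes)
  cm <- table(truth = tf, predicted = pf)
  n <- length(truth)

  support <- rowSums(cm)
  tp <- diag(cm)
  prec <- ifelse(colSums(cm) > 0, tp / colSums(cm), 0)
  rec <- ifelse(support > 0, tp / support, 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  wts <- support / n  # weights over truth classes (zero-support excluded)

  perClass <- data.frame(class = classes, support = as.vector(support),
                         precision = as.vector(prec),
                         recall = as.vector(rec), f1 = as.vector(f1))
  res <- list(
    f1 = sum(wts * f1), accuracy = mean(truth == predicted),
    precision = sum(wts * prec), recall = sum(wts * rec),
    per_class = perClass, confusion_counts = cm, n = n)
  res$confusion <- switch(normalize,
    none = cm,
    prediction = sweep(cm, 2, pmax(colSums(cm), 1), "/"),
    truth = sweep(cm, 1, pmax(rowSums(cm), 1), "/"))
  if (!is.null(scores)) {
    aucs <- vapply(classes, function(cl) {
      if (!cl %in% colnames(scores) || !any(truth == cl) ||
          all(truth == cl)) return(NA_real_)
      rankAUC(scores[, cl], truth == cl)
    }, numeric(1))
    ok <- !is.na(aucs) & support > 0
    res$auc <- if (any(ok)) sum(wts[ok] * aucs[ok]) / sum(wts[ok]) else NA_real_
    res$per_class$auc <- as.vector(aucs)
  }
  class(res) <- "MetricsReport"
  res
}

#' @export
print.MetricsReport <- function(x, ...) {
  cat(sprintf(
    "MetricsReport (n = %d): F1 %.4f | accuracy %.4f | precision %.4f | recall %.4f%s\n",
    x$n, x$f1, x$accuracy, x$precision, x$recall,
    if (!is.null(x$auc) && is.finite(x$auc))
      sprintf(" | AUC %.4f", x$auc) else ""))
  invisible(x)
}

#' Mann-Whitney AUC of a score against a binary truth
#'
#' @param score numeric scores (higher = more positive).
#' @param positive logical vector, same length.
#' @return AUC in [0, 1].
#' @export
rankAUC <- function(score, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score, ties.method = "average")
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Serialize a metrics report to a plain list / JSON-ready structure
#'
#' @param report a \code{MetricsReport}.
#' @return A named list of plain vectors and matrices-as-data.frames.
#' @export
reportToList <- function(report) {
  list(n = report$n, f1 = report$f1, accuracy = report$accuracy,
       precision = report$precision, recall = report$recall,
       auc = if (!is.null(report$auc)) report$auc else NULL,
       per_class = report$per_class,
       confusion_counts = as.data.frame.matrix(report$confusion_counts))
}

#' Object-size experiment: phenotype accuracy across label geometries
#'
#' Runs positivity assignment for each of the five object-size groups
#' (whole nuclei; +3 px; +8 px; centre pixel; centre pixel +3 px) against
#' the same heatmap and ground truth, reporting weighted metrics per
#' group.
#'
#' @param heatmap a \linkS4class{ProbabilityHeatmap} for one marker.
#' @param nuclei nuclear \linkS4class{LabelMask}.
#' @param truthCalls data.frame with \code{object_id} and \code{call}
#'   (\code{"positive"}/\code{"negative"}) -- the ground truth.
#' @param rule a \code{\link{positivityRule}}.
#' @param groups subset of 1:5.
#' @return List with \code{reports} (per-group \code{MetricsReport}) and
#'   \code{summary} (data.frame: group, kind, f1, accuracy, precision,
#'   recall) -- bar-plot-ready.
#' @export
objectSizeExperiment <- function(heatmap, nuclei, truthCalls,
                                 rule = positivityRule(), groups = 1:5) {
  kinds <- variantKinds()
  reports <- list()
  rows <- list()
  for (g in groups) {
    vm <- makeVariant(nuclei, g)
    calls <- assignPositivity(heatmap, vm, rule)
    m <- match(calls$object_id, truthCalls$object_id)
    if (any(is.na(m))) stop("truthCalls missing object ids")
    res <- weightedMetrics(truthCalls$call[m], calls$call,
                           classes = c("negative", "positive"))
    reports[[kinds[g]]] <- res
    rows[[length(rows) + 1L]] <- data.frame(
      group = g, kind = kinds[g], f1 = res$f1, accuracy = res$accuracy,
      precision = res$precision, recall = res$recall)
  }
  list(reports = reports, summary = do.call(rbind, rows))
}

#' Choose a mean-intensity threshold maximizing balanced accuracy
#'
#' Automated stand-in for an expert-chosen staining threshold: scans the
#' midpoints between consecutive sorted object means on a calibration
#' subset and keeps the threshold with the best balanced accuracy.
#'
#' @param means per-object mean intensities.
#' @param positive logical ground truth for the same objects.
#' @return A single threshold value.
#' @export
calibrateThreshold <- function(means, positive) {
  if (all(positive) || !any(positive)) return(stats::median(means))
  s <- sort(unique(means))
  cand <- if (length(s) > 1) (s[-1] + s[-length(s)]) / 2 else s
  cand <- c(min(s) - 1e-9, cand, max(s) + 1e-9)
  ba <- vapply(cand, function(th) {
    call <- means >= th
    (mean(call[positive]) + mean(!call[!positive])) / 2
  }, numeric(1))
  cand[which.max(ba)]
}

#' Three-way benchmark: heatmap phenotyping vs mean-intensity baseline
#'
#' On one synthetic scene, phenotypes every nucleus twice -- from marker
#' probability heatmaps over the nuclear labels alone, and from the
#' classical nuclear-expansion + mean-intensity baseline -- and scores
#' both against the scene's generative ground truth on identical nuclei
#' and coordinates. Both reports are always emitted, whatever the
#' ordering. A confidence sweep of the heatmap route is included.
#'
#' @param scene a \linkS4class{SyntheticScene}.
#' @param heatmaps named list of \linkS4class{ProbabilityHeatmap}s per
#'   scheme marker (trained-model or oracle).
#' @param rule a \code{\link{positivityRule}}.
#' @param scheme a \code{\link{phenotypeScheme}}.
#' @param nuclei optional nuclear \linkS4class{LabelMask}; defaults to the
#'   scene's true nuclei.
#' @param expansion baseline expansion radius in pixels.
#' @param thresholds optional named per-marker mean-intensity thresholds;
#'   when NULL they are calibrated on a split of the objects
#'   (\code{\link{calibrateThreshold}}), and the report says so.
#' @param calibrationFraction fraction of objects used for calibration.
#' @param confidences sweep thresholds.
#' @param seed seed for the calibration split.
#' @return List with \code{pixel} and \code{baseline}
#'   (\code{MetricsReport}s), \code{tables} (both cell tables),
#'   \code{sweep}, \code{thresholds}, \code{threshold_source}.
#' @export
benchmarkExperiment <- function(scene, heatmaps, rule = positivityRule(),
                                scheme = defaultPhenotypeScheme(),
                                nuclei = NULL, expansion = 5L,
                                thresholds = NULL,
                                calibrationFraction = 0.5,
                                confidences = c(0.10, 0.25, 0.50, 0.75,
                                                0.90),
                                seed = 1L) {
  truth <- scene@truth
  if (is.null(nuclei)) nuclei <- scene@nucleusMask

  truthCalls <- truth
  for (m in scheme$markers)
    truthCalls[[m]] <- ifelse(truth[[m]], "positive", "negative")
  truthPheno <- resolvePhenotype(truthCalls, scheme)

  # heatmap route: nuclear labels only
  pixTab <- phenotypePipeline(heatmaps, nuclei, rule, scheme)

  # baseline route: expansion + mean intensity on the raw channels
  expanded <- dilateLabels(nuclei, expansion)
  thSource <- if (is.null(thresholds)) "calibrated" else "user"
  baseCalls <- data.frame(object_id = pixTab$object_id)
  usedTh <- numeric(0)
  for (m in scheme$markers) {
    img <- renderChannel(scene, m)
    mi <- meanIntensityPositivity(img, expanded, threshold = -Inf)
    idm <- match(mi$object_id, truth$object_id)
    th <- thresholds[[m]]
    if (is.null(th)) {
      nCal <- max(2L, floor(calibrationFraction * nrow(mi)))
      cal <- withr::with_seed(seed, sample.int(nrow(mi), nCal))
      th <- calibrateThreshold(mi$mean_intensity[cal],
                               truth[[m]][idm[cal]])
    }
    usedTh[m] <- th
    cl <- ifelse(mi$mean_intensity >= th, "positive", "negative")
    baseCalls[[m]] <- cl[match(baseCalls$object_id, mi$object_id)]
  }
  baseCalls$phenotype <- resolvePhenotype(baseCalls, scheme)

  mTruth <- match(pixTab$object_id, truth$object_id)
  if (any(is.na(mTruth)))
    stop("nuclei mask contains object ids absent from scene truth")
  classes <- c(scheme$names, scheme$fallback)
  pixRep <- weightedMetrics(truthPheno[mTruth], pixTab$phenotype, classes)
  baseRep <- weightedMetrics(truthPheno[mTruth], baseCalls$phenotype,
                             classes)

  sweep <- lapply(stats::setNames(scheme$markers, scheme$markers),
                  function(m) confidenceSweep(heatmaps[[m]], nuclei,
                                              confidences, rule$coverage,
                                              rule$mode))
  list(pixel = pixRep, baseline = baseRep,
       tables = list(pixel = pixTab, baseline = baseCalls),
       sweep = sweep, thresholds = usedTh, threshold_source = thSource)
}

#' Ground-truth marker calls for an arbitrary nuclei mask
#'
#' Matches each object of a (possibly detector-derived) nuclei mask to a
#' scene cell by majority overlap with the true cell mask, falling back to
#' the nearest true nucleus centroid, and returns the matched cell's truth
#' call for one marker. Objects matching no cell are dropped.
#'
#' @param scene a \linkS4class{SyntheticScene}.
#' @param markerName marker in the scene.
#' @param mask a \linkS4class{LabelMask} (e.g. from
#'   \code{\link{detectNuclei}}).
#' @return data.frame with \code{object_id}, \code{cell_id}, \code{call}.
#' @export
truthCallsForMask <- function(scene, markerName, mask) {
  truth <- scene@truth
  if (!markerName %in% names(truth))
    stop("unknown marker '", markerName, "'")
  lab <- mask@labels
  cellLab <- scene@cellMask@labels
  ids <- setdiff(sort(unique(as.vector(lab))), 0L)
  cent <- labelCentroids(mask)
  out <- data.frame(object_id = integer(0), cell_id = integer(0),
                    call = character(0))
  for (id in ids) {
    sel <- lab == id
    over <- cellLab[sel]
    over <- over[over > 0L]
    cid <- if (length(over)) {
      tb <- tabulate(over)
      which.max(tb)
    } else {
      ci <- cent[cent$object_id == id, ]
      d2 <- (truth$x - ci$x)^2 + (truth$y - ci$y)^2
      if (!length(d2)) next
      truth$object_id[which.min(d2)]
    }
    out <- rbind(out, data.frame(
      object_id = id, cell_id = cid,
      call = if (truth[[markerName]][truth$object_id == cid])
        "positive" else "negative"))
  }
  out
}
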