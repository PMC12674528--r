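#' Training configuration for the pixel classifier
#'
#' Defaults follow the published training recipe where one exists
#' (learning rate 1e-06, mini-batch size 2, 512 px receptive field); the
#' network itself is a standard U-Net with a configurable depth and base
#' width so that CPU training on synthetic patches finishes in minutes.
#' For small synthetic problems a higher learning rate (e.g. 1e-3 with
#' Adam) and a smaller patch/network are the practical choice.
#'
#' @param learning_rate optimizer step size.
#' @param batch_size patches per iteration.
#' @param iterations training iterations.
#' @param patch_size expected square patch side; must be divisible by
#'   \code{2^(depth-1)}.
#' @param depth number of resolution levels including the bottleneck.
#' @param base_width channels at the top level; doubled per level.
#' @param optimizer \code{"adam"} or \code{"sgd"}.
#' @param augment random flips / 90-degree rotations during training.
#' @param normalize apply \code{\link{normalizeImage}}-style percentile
#'   scaling, pooled over the patch set.
#' @param freeze_schedule optional list of \code{c(iteration, depth)}
#'   pairs; from each iteration on, encoder levels up to that depth are
#'   frozen.
#' @param validation_fraction fraction of patches held out; their loss is
#'   logged alongside the training loss when positive.
#' @param seed RNG seed for weight init, batch sampling and augmentation.
#' @param log_every record the loss every this many iterations.
#' @return A named list of class \code{"trainConfig"}.
#' @export
trainConfig <- function(learning_rate = 1e-06, batch_size = 2L,
                        iterations = 1000L, patch_size = 512L,
                        depth = 4L, base_width = 16L,
                        optimizer = c("adam", "sgd"), augment = TRUE,
                        normalize = TRUE, freeze_schedule = NULL,
                        validation_fraction = 0, seed = 1L,
                        log_every = 50L) {
  optimizer <- match.arg(optimizer)
  stopifnot(learning_rate > 0, batch_size >= 1, iterations >= 1,
            depth >= 1, base_width >= 1,
            patch_size %% 2L^(depth - 1L) == 0L,
            validation_fraction >= 0, validation_fraction < 1)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 iterations = as.integer(iterations),
                 patch_size = as.integer(patch_size),
                 depth = as.integer(depth),
                 base_width = as.integer(base_width),
                 optimizer = optimizer, augment = augment,
                 normalize = normalize, freeze_schedule = freeze_schedule,
                 validation_fraction = validation_fraction,
                 seed = as.integer(seed), log_every = as.integer(log_every)),
            class = "trainConfig")
}

#' Percentile-normalize an image to [0, 1]
#'
#' Scales the 1st--99.9th intensity percentiles to [0, 1] and clips.
#' Applied at image level before inference, and with percentiles pooled
#' over the whole patch set before training, so training and inference see
#' the same transform. The high upper anchor keeps the scaling stable for
#' sparse markers whose positive pixels are a small fraction of the image
#' (e.g. a nuclear marker at low prevalence).
#'
#' @param m numeric matrix.
#' @param lower,upper percentile bounds in [0, 1].
#' @return Matrix with values in [0, 1].
#' @export
normalizeImage <- function(m, lower = 0.01, upper = 0.999) {
  q <- stats::quantile(m, c(lower, upper), names = FALSE)
  .affineClip(m, q)
}

.affineClip <- function(m, q) {
  if (q[2] <= q[1]) return(matrix(0, nrow(m), ncol(m)))
  out <- (m - q[1]) / (q[2] - q[1])
  out[out < 0] <- 0; out[out > 1] <- 1
  out
}

#' Train the single-channel two-class U-Net pixel classifier
#'
#' Minimizes per-pixel cross-entropy over \{Positive, Background\} on the
#' supplied training patches. Deterministic given \code{cfg$seed} and a
#' fixed BLAS.
#'
#' @param patches list of training patches from \code{\link{tilePatches}}
#'   (each a list with \code{image} and binary \code{labels} matrices).
#' @param cfg a \code{\link{trainConfig}}.
#' @return A \linkS4class{PixelModel} with the training log attached.
#' @export
trainPixelClassifier <- function(patches, cfg) {
  stopifnot(inherits(cfg, "trainConfig"), length(patches) >= 1)
  both <- vapply(patches, function(p)
    length(unique(as.vector(p$labels))) > 1L, logical(1))
  if (!any(both))
    stop("degenerate training set: no patch contains both classes")
  d <- dim(patches[[1]]$image)
  if (d[1] != d[2] || d[1] %% 2L^(cfg$depth - 1L) != 0L)
    stop("patches must be square with side divisible by 2^(depth-1)")
  imgs <- lapply(patches, `[[`, "image")
  if (cfg$normalize) {
    # one affine transform pooled over the whole patch set, matching the
    # image-level normalization used at inference
    q <- stats::quantile(unlist(imgs), c(0.01, 0.999), names = FALSE)
    imgs <- lapply(imgs, .affineClip, q = q)
  }
  labs <- lapply(patches, function(p) {
    l <- p$labels; storage.mode(l) <- "integer"; l
  })
  withr::with_seed(cfg$seed, .trainLoop(imgs, labs, cfg))
}

.trainLoop <- function(imgs, labs, cfg) {
  nTrain <- length(imgs)
  valIdx <- integer(0)
  if (cfg$validation_fraction > 0 && nTrain > 1) {
    nVal <- max(1L, floor(cfg$validation_fraction * nTrain))
    valIdx <- sample.int(nTrain, nVal)
  }
  trIdx <- setdiff(seq_len(nTrain), valIdx)
  wts <- .initWeights(cfg)
  opt <- .optimInit(wts)
  logIt <- integer(0); logLoss <- numeric(0); logVal <- numeric(0)

  for (it in seq_len(cfg$iterations)) {
    frozen <- .frozenLayers(cfg, it)
    bi <- trIdx[sample.int(length(trIdx), cfg$batch_size, replace = TRUE)]
    gsum <- NULL; lsum <- 0
    for (i in bi) {
      x <- imgs[[i]]; y <- labs[[i]]
      if (cfg$augment) {
        tf <- sample.int(8L, 1L)
        x <- .dihedral(x, tf); y <- .dihedral(y, tf)
      }
      fw <- .forwardUnet(wts, x, cfg, keepCache = TRUE)
      bk <- .backwardUnet(wts, cfg, fw, as.vector(y))
      lsum <- lsum + bk$loss
      gsum <- if (is.null(gsum)) bk$grads else .gradAdd(gsum, bk$grads)
    }
    loss <- lsum / cfg$batch_size
    if (!is.finite(loss))
      stop("NaN/Inf loss at iteration ", it,
           "; lower the learning rate or check the inputs")
    upd <- .optimStep(wts, gsum, opt, cfg, it, frozen)
    wts <- upd$wts; opt <- upd$opt
    if (it == 1L || it %% cfg$log_every == 0L || it == cfg$iterations) {
      logIt <- c(logIt, it); logLoss <- c(logLoss, loss)
      if (length(valIdx))
        logVal <- c(logVal, mean(vapply(valIdx, function(i)
          .pixelLoss(wts, imgs[[i]], labs[[i]], cfg), numeric(1))))
    }
  }
  log <- data.frame(iteration = logIt, loss = logLoss)
  if (length(valIdx)) log$val_loss <- logVal
  new("PixelModel", config = unclass(cfg), weights = wts, log = log)
}

.pixelLoss <- function(wts, x, y, cfg) {
  fw <- .forwardUnet(wts, x, cfg, keepCache = FALSE)
  p <- .softmax2(fw$logits)
  yv <- as.vector(y)
  -mean(log(pmax(p[cbind(seq_along(yv), yv + 1L)], 1e-12)))
}

.frozenLayers <- function(cfg, it) {
  fs <- cfg$freeze_schedule
  if (is.null(fs)) return(character(0))
  depth <- 0L
  for (p in fs) if (it >= p[1]) depth <- max(depth, as.integer(p[2]))
  if (depth == 0L) return(character(0))
  paste0("enc", rep(seq_len(min(depth, cfg$depth)), each = 2), c("a", "b"))
}

.gradAdd <- function(a, b) {
  for (nm in names(a)) {
    a[[nm]]$W <- a[[nm]]$W + b[[nm]]$W
    a[[nm]]$b <- a[[nm]]$b + b[[nm]]$b
  }
  a
}

.optimInit <- function(wts) {
  st <- list()
  for (nm in names(wts))
    st[[nm]] <- list(mW = wts[[nm]]$W * 0, vW = wts[[nm]]$W * 0,
                     mb = wts[[nm]]$b * 0, vb = wts[[nm]]$b * 0)
  st
}

.optimStep <- function(wts, grads, opt, cfg, it, frozen,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  lr <- cfg$learning_rate
  bs <- cfg$batch_size
  for (nm in names(wts)) {
    if (nm %in% frozen) next
    gW <- grads[[nm]]$W / bs
    gb <- grads[[nm]]$b / bs
    if (cfg$optimizer == "sgd") {
      wts[[nm]]$W <- wts[[nm]]$W - lr * gW
      wts[[nm]]$b <- wts[[nm]]$b - lr * gb
    } else {
      o <- opt[[nm]]
      o$mW <- beta1 * o$mW + (1 - beta1) * gW
      o$vW <- beta2 * o$vW + (1 - beta2) * gW^2
      o$mb <- beta1 * o$mb + (1 - beta1) * gb
      o$vb <- beta2 * o$vb + (1 - beta2) * gb^2
      c1 <- 1 - beta1^it; c2 <- 1 - beta2^it
      wts[[nm]]$W <- wts[[nm]]$W - lr * (o$mW / c1) / (sqrt(o$vW / c2) + eps)
      wts[[nm]]$b <- wts[[nm]]$b - lr * (o$mb / c1) / (sqrt(o$vb / c2) + eps)
      opt[[nm]] <- o
    }
  }
  list(wts = wts, opt = opt)
}

# the 8 square-dihedral transforms (identity, rotations, flips)
.dihedral <- function(m, k) {
  rot90 <- function(x) t(x)[ncol(x):1, , drop = FALSE]
  if (k > 4L) { m <- m[nrow(m):1, , drop = FALSE]; k <- k - 4L }
  for (i in seq_len(k - 1L)) m <- rot90(m)
  m
}

#' Predict a probability heatmap by tiled U-Net inference
#'
#' The image is percentile-normalized, reflect-padded, and processed in
#' overlapping square tiles. A margin of \code{\link{unetMargin}} pixels --
#' the network's receptive-field half-width -- is discarded from every tile
#' border, and the remaining interiors are blended with a raised-cosine
#' crossfade, so tiled and whole-image prediction agree to floating-point
#' precision.
#'
#' @param model a \linkS4class{PixelModel}.
#' @param image single-plane \linkS4class{MultichannelImage} or matrix.
#' @param tile tile side in pixels; must exceed twice the margin.
#' @param overlap overlap between consecutive tiles; at least twice the
#'   margin (the default).
#' @param markerName marker name for the returned heatmap; defaults to the
#'   image's channel name.
#' @return A \linkS4class{ProbabilityHeatmap} of the positive class.
#' @export
predictHeatmap <- function(model, image, tile = 512L, overlap = NULL,
                           markerName = NULL) {
  stopifnot(is(model, "PixelModel"))
  if (is(image, "MultichannelImage")) {
    if (length(image@planes) != 1L)
      stop("predictHeatmap needs a single-plane image; use extractChannel()")
    markerName <- markerName %||% image@channelNames[1]
    img <- image@planes[[1]]
  } else {
    img <- image
    markerName <- markerName %||% "marker"
  }
  cfg <- model@config
  g <- 2L^(cfg$depth - 1L)
  m <- unetMargin(cfg)
  tile <- as.integer(tile)
  if (tile %% g != 0L) stop("tile must be a multiple of ", g)
  if (tile <= 2L * m)
    stop("tile (", tile, ") must exceed twice the receptive-field margin (",
         m, ")")
  overlap <- as.integer(overlap %||% (2L * m))
  if (overlap < 2L * m) stop("overlap must be at least 2 * margin = ", 2 * m)
  stride <- tile - overlap
  stride <- max(g, (stride %/% g) * g)

  if (cfg$normalize) img <- normalizeImage(img)
  H <- nrow(img); W <- ncol(img)
  padSize <- function(n) {
    need <- n + 2L * m
    if (need <= tile) tile else
      tile + stride * as.integer(ceiling((need - tile) / stride))
  }
  PH <- padSize(H); PW <- padSize(W)
  ri <- .mirrorIdx(H, m, PH - H - m)
  ci <- .mirrorIdx(W, m, PW - W - m)
  imgP <- img[ri, ci, drop = FALSE]

  wv <- .tileWeights(tile, m, overlap - 2L * m)
  Wtile <- outer(wv, wv)
  acc <- matrix(0, PH, PW); wacc <- matrix(0, PH, PW)
  for (r0 in seq.int(1L, PH - tile + 1L, by = stride))
    for (c0 in seq.int(1L, PW - tile + 1L, by = stride)) {
      rr <- r0:(r0 + tile - 1L); cc <- c0:(c0 + tile - 1L)
      fw <- .forwardUnet(model@weights, imgP[rr, cc], cfg,
                         keepCache = FALSE)
      p <- matrix(.softmax2(fw$logits)[, 2], tile, tile)
      acc[rr, cc] <- acc[rr, cc] + p * Wtile
      wacc[rr, cc] <- wacc[rr, cc] + Wtile
    }
  out <- acc[m + seq_len(H), m + seq_len(W)] /
    wacc[m + seq_len(H), m + seq_len(W)]
  ProbabilityHeatmap(pmin(pmax(out, 0), 1), markerName)
}

# mirror-padding index for `left` and `right` extra pixels around 1..n
.mirrorIdx <- function(n, left, right) {
  p <- seq.int(1L - left, n + right)
  if (n == 1L) return(rep(1L, length(p)))
  period <- 2L * (n - 1L)
  q <- (abs(p - 1L)) %% period
  ifelse(q < n, q + 1L, period + 1L - q) + 0L
}

# per-axis blending weight: zero on the discarded margin, raised-cosine
# crossfade of width `ramp`, flat 1 in the middle
.tileWeights <- function(tile, margin, ramp) {
  w <- numeric(tile)
  lo <- margin + 1L; hi <- tile - margin
  w[lo:hi] <- 1
  if (ramp > 0L) {
    t <- seq_len(ramp)
    up <- 0.5 - 0.5 * cos(pi * t / (ramp + 1))
    w[margin + t] <- up
    w[tile - margin + 1L - t] <- up
  }
  w
}

#' Ideal-classifier heatmap from scene ground truth
#'
#' Probability 1 on the compartment-aware training-label support of the
#' marker, 0 elsewhere, optionally Gaussian-blurred (then clipped to
#' [0, 1]). Stands in for a perfectly trained pixel classifier, so that
#' assignment logic can be tested in the ideal limit.
#'
#' @param scene a \linkS4class{SyntheticScene}.
#' @param markerName marker in the scene.
#' @param blurSigma Gaussian blur SD in pixels; 0 = binary heatmap.
#' @return A \linkS4class{ProbabilityHeatmap}.
#' @export
oracleHeatmap <- function(scene, markerName, blurSigma = 0) {
  lab <- buildTrainingLabels(scene, markerName)
  p <- lab@labels * 1.0
  if (blurSigma > 0) {
    p <- EBImage::imageData(EBImage::gblur(p, sigma = blurSigma))
    p <- matrix(p, nrow(lab@labels))
  }
  ProbabilityHeatmap(pmin(pmax(p, 0), 1), markerName)
}

#' Save and load pixel-classifier checkpoints
#'
#' A checkpoint is a single RDS archive holding the architecture config,
#' weights and training log.
#'
#' @param model a \linkS4class{PixelModel}.
#' @param path file path.
#' @return \code{saveModel}: \code{path}, invisibly; \code{loadModel}: a
#'   \linkS4class{PixelModel}.
#' @export
saveModel <- function(model, path) {
  stopifnot(is(model, "PixelModel"))
  saveRDS(list(config = model@config, weights = model@weights,
               log = model@log), path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  x <- readRDS(path)
  new("PixelModel", config = x$config, weights = x$weights, log = x$log)
}
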