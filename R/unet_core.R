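# U-Net primitives on a (npix x channels) activation layout.
#
# An activation is a matrix with h*w rows (column-major pixel order of the
# underlying h x w raster) and one column per feature channel. 3x3
# convolutions are computed as im2col gathers followed by a single BLAS
# matmul; the gather/scatter index tables are cached per (h, w, channels).

.unetCache <- new.env(parent = emptyenv())

.convIndex <- function(h, w, C) {
  key <- paste(h, w, C, sep = "x")
  got <- .unetCache[[key]]
  if (!is.null(got)) return(got)
  hp <- h + 2L
  npad <- hp * (w + 2L)
  r <- rep(seq_len(h), times = w)
  cc <- rep(seq_len(w), each = h)
  idx9 <- matrix(0L, h * w, 9L)
  k <- 0L
  for (dc in -1:1) for (dr in -1:1) {
    k <- k + 1L
    idx9[, k] <- (cc + dc) * hp + (r + 1L + dr)
  }
  IDX <- matrix(0L, h * w, 9L * C)
  for (ch in seq_len(C))
    IDX[, (ch - 1L) * 9L + 1:9] <- idx9 + (ch - 1L) * npad
  # linear indices of the unpadded raster inside the padded one
  core <- as.vector(outer(seq_len(h) + 1L, seq_len(w) * hp, `+`))
  out <- list(IDX = IDX, idx9 = idx9, core = core, npad = npad, hp = hp,
              C = C)
  .unetCache[[key]] <- out
  out
}

# zero-pad each channel column of A (h*w x C) into a (h+2)*(w+2) x C matrix
.padChannels <- function(A, ci) {
  P <- matrix(0, ci$npad, ncol(A))
  P[ci$core, ] <- A
  P
}

.convForward <- function(A, h, w, layer) {
  C <- ncol(A)
  ci <- .convIndex(h, w, C)
  P <- .padChannels(A, ci)
  X <- matrix(P[ci$IDX], nrow(A), 9L * C)
  Y <- X %*% layer$W
  Y <- Y + rep(layer$b, each = nrow(Y))
  list(Y = Y, X = X)
}

.convBackward <- function(dY, X, layer, h, w, Cin) {
  dW <- crossprod(X, dY)
  db <- colSums(dY)
  dXcol <- tcrossprod(dY, layer$W)  # npix x 9C
  ci <- .convIndex(h, w, Cin)
  dP <- matrix(0, ci$npad, Cin)
  # per-offset scatter: for a fixed kernel tap the target indices are
  # distinct, so plain indexed addition accumulates correctly
  for (k in 1:9) {
    cols <- seq.int(k, by = 9L, length.out = Cin)
    dP[ci$idx9[, k], ] <- dP[ci$idx9[, k], ] +
      dXcol[, cols, drop = FALSE]
  }
  list(dA = dP[ci$core, , drop = FALSE], dW = dW, db = db)
}

.poolIndex <- function(h, w) {
  key <- paste("pool", h, w, sep = "x")
  got <- .unetCache[[key]]
  if (!is.null(got)) return(got)
  h2 <- h %/% 2L; w2 <- w %/% 2L
  r <- rep(seq_len(h2) * 2L - 1L, times = w2)
  cc <- rep(seq_len(w2) * 2L - 1L, each = h2)
  lin <- function(rr, ccc) (ccc - 1L) * h + rr
  out <- list(i00 = lin(r, cc), i10 = lin(r + 1L, cc),
              i01 = lin(r, cc + 1L), i11 = lin(r + 1L, cc + 1L),
              h2 = h2, w2 = w2)
  .unetCache[[key]] <- out
  out
}

.maxpool <- function(A, h, w) {
  pi <- .poolIndex(h, w)
  a <- A[pi$i00, , drop = FALSE]; b <- A[pi$i10, , drop = FALSE]
  cc <- A[pi$i01, , drop = FALSE]; d <- A[pi$i11, , drop = FALSE]
  m1 <- pmax(a, b); t1 <- a >= b
  m2 <- pmax(cc, d); t2 <- cc >= d
  M <- pmax(m1, m2); tt <- m1 >= m2
  list(Y = M, h = pi$h2, w = pi$w2,
       cache = list(t1 = t1, t2 = t2, tt = tt, pi = pi, n = nrow(A)))
}

.maxpoolBackward <- function(dY, cache, C) {
  dA <- matrix(0, cache$n, C)
  pi <- cache$pi
  dA[pi$i00, ] <- dY * (cache$tt & cache$t1)
  dA[pi$i10, ] <- dY * (cache$tt & !cache$t1)
  dA[pi$i01, ] <- dY * (!cache$tt & cache$t2)
  dA[pi$i11, ] <- dY * (!cache$tt & !cache$t2)
  dA
}

.upIndex <- function(h2, w2) {
  key <- paste("up", h2, w2, sep = "x")
  got <- .unetCache[[key]]
  if (!is.null(got)) return(got)
  h <- 2L * h2
  rf <- rep(seq_len(h), times = 2L * w2)
  cf <- rep(seq_len(2L * w2), each = h)
  idx <- ((cf + 1L) %/% 2L - 1L) * h2 + (rf + 1L) %/% 2L
  .unetCache[[key]] <- idx
  idx
}

.upsample <- function(A, h2, w2) {
  idx <- .upIndex(h2, w2)
  list(Y = A[idx, , drop = FALSE], h = 2L * h2, w = 2L * w2, idx = idx)
}

.upsampleBackward <- function(dY, h2, w2) {
  # sum each 2x2 fine block into its coarse pixel
  pi <- .poolIndex(2L * h2, 2L * w2)
  dY[pi$i00, , drop = FALSE] + dY[pi$i10, , drop = FALSE] +
    dY[pi$i01, , drop = FALSE] + dY[pi$i11, , drop = FALSE]
}

.relu <- function(Y) pmax(Y, 0)

# architecture bookkeeping -------------------------------------------------

.levelChannels <- function(cfg) cfg$base_width * 2L^(seq_len(cfg$depth) - 1L)

.layerNames <- function(cfg) {
  D <- cfg$depth
  c(paste0("enc", rep(seq_len(D), each = 2), c("a", "b")),
    if (D > 1) paste0("dec", rep(seq_len(D - 1), each = 2), c("a", "b")),
    "out")
}

.layerShapes <- function(cfg) {
  D <- cfg$depth
  ch <- .levelChannels(cfg)
  sh <- list()
  for (l in seq_len(D)) {
    cin <- if (l == 1L) 1L else ch[l - 1L]
    sh[[paste0("enc", l, "a")]] <- c(9L * cin, ch[l])
    sh[[paste0("enc", l, "b")]] <- c(9L * ch[l], ch[l])
  }
  for (l in seq_len(D - 1L)) {
    cin <- ch[l] + ch[l + 1L]
    sh[[paste0("dec", l, "a")]] <- c(9L * cin, ch[l])
    sh[[paste0("dec", l, "b")]] <- c(9L * ch[l], ch[l])
  }
  sh[["out"]] <- c(ch[1], 2L)
  sh
}

.initWeights <- function(cfg) {
  sh <- .layerShapes(cfg)
  wts <- list()
  for (nm in names(sh)) {
    s <- sh[[nm]]
    fanIn <- s[1]
    wts[[nm]] <- list(W = matrix(stats::rnorm(s[1] * s[2], 0,
                                              sqrt(2 / fanIn)),
                                 s[1], s[2]),
                      b = numeric(s[2]))
  }
  wts
}

# receptive-field half-width of the network (all 3x3 convs, stride by
# level), aligned up to the pooling grid: predictions further than this
# from a tile border are unaffected by the tile's zero padding
#' U-Net receptive-field margin
#'
#' Half-width of the receptive field of the configured network, rounded up
#' to the pooling grid. Tiled inference discards a border of this width
#' from every tile, which makes tiled and whole-image prediction agree
#' exactly away from floating-point blending error.
#'
#' @param cfg a \code{\link{trainConfig}} list (only \code{depth} is used).
#' @return Integer margin in pixels.
#' @export
unetMargin <- function(cfg) {
  D <- cfg$depth
  m <- 3L * 2L^D - 4L
  g <- 2L^(D - 1L)
  as.integer(g * ceiling(m / g))
}

# full forward pass; keepCache=TRUE retains everything backward needs
.forwardUnet <- function(wts, x, cfg, keepCache = FALSE) {
  D <- cfg$depth
  ch <- .levelChannels(cfg)
  h <- nrow(x); w <- ncol(x)
  A <- matrix(as.vector(x), ncol = 1L)
  cache <- if (keepCache) list(dims = list(), conv = list(), relu = list(),
                               pool = list(), up = list(), skipC = integer(0))
           else NULL
  skips <- vector("list", D - 1L)
  for (l in seq_len(D)) {
    for (ab in c("a", "b")) {
      nm <- paste0("enc", l, ab)
      cv <- .convForward(A, h, w, wts[[nm]])
      Y <- .relu(cv$Y)
      if (keepCache) {
        cache$conv[[nm]] <- cv$X
        cache$relu[[nm]] <- cv$Y > 0
        cache$dims[[nm]] <- c(h, w, ncol(A))
      }
      A <- Y
    }
    if (l < D) {
      skips[[l]] <- list(A = A, h = h, w = w)
      pl <- .maxpool(A, h, w)
      if (keepCache) cache$pool[[l]] <- pl$cache
      A <- pl$Y; h <- pl$h; w <- pl$w
    }
  }
  for (l in rev(seq_len(D - 1L))) {
    up <- .upsample(A, h, w)
    if (keepCache) cache$up[[l]] <- c(h, w)
    A <- cbind(skips[[l]]$A, up$Y)
    h <- up$h; w <- up$w
    for (ab in c("a", "b")) {
      nm <- paste0("dec", l, ab)
      cv <- .convForward(A, h, w, wts[[nm]])
      Y <- .relu(cv$Y)
      if (keepCache) {
        cache$conv[[nm]] <- cv$X
        cache$relu[[nm]] <- cv$Y > 0
        cache$dims[[nm]] <- c(h, w, ncol(A))
      }
      A <- Y
    }
  }
  logits <- A %*% wts$out$W
  logits <- logits + rep(wts$out$b, each = nrow(logits))
  if (keepCache) {
    cache$preOut <- A
    cache$hw <- c(h, w)
  }
  list(logits = logits, cache = cache)
}

.softmax2 <- function(logits) {
  m <- pmax(logits[, 1], logits[, 2])
  e1 <- exp(logits[, 1] - m); e2 <- exp(logits[, 2] - m)
  s <- e1 + e2
  cbind(e1 / s, e2 / s)
}

# backward pass; y is 0/1 vector over pixels; returns grads + loss
.backwardUnet <- function(wts, cfg, fw, y) {
  D <- cfg$depth
  ch <- .levelChannels(cfg)
  p <- .softmax2(fw$logits)
  n <- nrow(p)
  pick <- cbind(seq_len(n), y + 1L)
  loss <- -mean(log(pmax(p[pick], 1e-12)))
  dL <- p
  dL[pick] <- dL[pick] - 1
  dL <- dL / n

  grads <- list()
  cache <- fw$cache
  grads$out <- list(W = crossprod(cache$preOut, dL), b = colSums(dL))
  dA <- tcrossprod(dL, wts$out$W)

  # decoder levels unwind in reverse application order: level 1 was last
  dSkips <- vector("list", max(D - 1L, 0L))
  for (l in seq_len(D - 1L)) {
    for (ab in c("b", "a")) {
      nm <- paste0("dec", l, ab)
      dY <- dA * cache$relu[[nm]]
      dm <- cache$dims[[nm]]
      bk <- .convBackward(dY, cache$conv[[nm]], wts[[nm]], dm[1], dm[2], dm[3])
      grads[[nm]] <- list(W = bk$dW, b = bk$db)
      dA <- bk$dA
    }
    # split concat: [skip (ch[l]) | upsampled (ch[l+1])]
    dSkips[[l]] <- dA[, seq_len(ch[l]), drop = FALSE]
    dUp <- dA[, ch[l] + seq_len(ch[l + 1L]), drop = FALSE]
    up <- cache$up[[l]]
    dA <- .upsampleBackward(dUp, up[1], up[2])
  }

  for (l in rev(seq_len(D))) {
    for (ab in c("b", "a")) {
      nm <- paste0("enc", l, ab)
      dY <- dA * cache$relu[[nm]]
      dm <- cache$dims[[nm]]
      bk <- .convBackward(dY, cache$conv[[nm]], wts[[nm]], dm[1], dm[2], dm[3])
      grads[[nm]] <- list(W = bk$dW, b = bk$db)
      dA <- bk$dA
    }
    if (l > 1L) {
      pooled <- .maxpoolBackward(dA, cache$pool[[l - 1L]], ncol(dA))
      dA <- pooled + dSkips[[l - 1L]]
    }
  }
  list(grads = grads, loss = loss)
}
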