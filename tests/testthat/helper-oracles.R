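# Independent brute-force oracles used to validate the fast implementations.
# These are deliberately naive (pixel loops, direct definitions) and share
# no code with the package internals.

# random label mask with n non-overlapping rectangular-ish blobs
randomMask <- function(h, w, nObj, seed) {
  withr::with_seed(seed, {
    lab <- matrix(0L, h, w)
    for (i in seq_len(nObj)) {
      for (try in 1:50) {
        rh <- sample(1:4, 1); rw <- sample(1:4, 1)
        r0 <- sample(seq_len(h - rh), 1); c0 <- sample(seq_len(w - rw), 1)
        win <- lab[r0:(r0 + rh), c0:(c0 + rw)]
        if (all(win == 0L)) {
          lab[r0:(r0 + rh), c0:(c0 + rw)] <- i
          break
        }
      }
    }
    lab
  })
}

# exhaustive per-object coverage counting
bruteCoverage <- function(p, lab, confidence, coverage) {
  ids <- setdiff(sort(unique(as.vector(lab))), 0L)
  out <- data.frame(object_id = integer(0), coverage = numeric(0),
                    call = character(0))
  for (id in ids) {
    hits <- 0L; tot <- 0L
    for (r in seq_len(nrow(lab))) for (c in seq_len(ncol(lab))) {
      if (lab[r, c] == id) {
        tot <- tot + 1L
        if (p[r, c] >= confidence) hits <- hits + 1L
      }
    }
    cov <- hits / tot
    out <- rbind(out, data.frame(
      object_id = id, coverage = cov,
      call = if (cov >= coverage) "positive" else "negative"))
  }
  out
}

# exhaustive per-object mean intensity
bruteMeanIntensity <- function(img, lab, threshold) {
  ids <- setdiff(sort(unique(as.vector(lab))), 0L)
  out <- data.frame(object_id = integer(0), mean_intensity = numeric(0),
                    call = character(0))
  for (id in ids) {
    v <- img[lab == id]
    m <- sum(v) / length(v)
    out <- rbind(out, data.frame(
      object_id = id, mean_intensity = m,
      call = if (m >= threshold) "positive" else "negative"))
  }
  out
}

# exhaustive nearest-object dilation with ties to the smaller id
bruteDilate <- function(lab, k) {
  ids <- setdiff(sort(unique(as.vector(lab))), 0L)
  out <- lab
  h <- nrow(lab); w <- ncol(lab)
  for (r in seq_len(h)) for (c in seq_len(w)) {
    if (lab[r, c] != 0L) next
    bestD <- Inf; bestId <- 0L
    for (id in ids) {
      px <- which(lab == id, arr.ind = TRUE)
      d2 <- min((px[, 1] - r)^2 + (px[, 2] - c)^2)
      if (d2 < bestD - 1e-9) { bestD <- d2; bestId <- id }
    }
    if (bestD <= k^2 + 1e-9) out[r, c] <- bestId
  }
  out
}

# exhaustive centre-of-mass pixel with the documented tie rules
bruteCom <- function(lab) {
  ids <- setdiff(sort(unique(as.vector(lab))), 0L)
  out <- matrix(0L, nrow(lab), ncol(lab))
  for (id in ids) {
    px <- which(lab == id, arr.ind = TRUE)
    cr <- mean(px[, 1]); cc <- mean(px[, 2])
    rr <- floor(cr + 0.5); rc <- floor(cc + 0.5)
    if (rr >= 1 && rr <= nrow(lab) && rc >= 1 && rc <= ncol(lab) &&
        lab[rr, rc] == id) {
      out[rr, rc] <- id
    } else {
      d <- (px[, 1] - cr)^2 + (px[, 2] - cc)^2
      near <- which(d <= min(d) + 1e-9)
      near <- near[order(px[near, 1], px[near, 2])]  # row-major tie-break
      out[px[near[1], 1], px[near[1], 2]] <- id
    }
  }
  out
}

# weighted multiclass metrics straight from the definitions
bruteMetrics <- function(truth, predicted) {
  classes <- sort(unique(c(truth, predicted)))
  n <- length(truth)
  wf1 <- wp <- wr <- 0
  for (cl in classes) {
    sup <- sum(truth == cl)
    if (sup == 0) next
    tp <- sum(truth == cl & predicted == cl)
    fp <- sum(truth != cl & predicted == cl)
    fn <- sum(truth == cl & predicted != cl)
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    wf1 <- wf1 + sup / n * f
    wp <- wp + sup / n * p
    wr <- wr + sup / n * r
  }
  list(f1 = wf1, precision = wp, recall = wr,
       accuracy = mean(truth == predicted))
}

# small standard scene used across tests
testScene <- function(seed = 1, nCells = 12, side = 192, ...) {
  simulateScene(sceneParams(height = side, width = side, nCells = nCells,
                            seed = seed, ...))
}

# compact training setup shared by classifier tests
smallTrainConfig <- function(iterations = 200, seed = 1, ...) {
  trainConfig(learning_rate = 2e-3, iterations = iterations,
              patch_size = 64L, depth = 3L, base_width = 8L,
              seed = seed, log_every = 50L, ...)
}

sceneTruthCalls <- function(scene, markerName) {
  tr <- sceneTruth(scene)
  data.frame(object_id = tr$object_id,
             call = ifelse(tr[[markerName]], "positive", "negative"))
}
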