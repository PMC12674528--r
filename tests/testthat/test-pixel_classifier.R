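test_that("analytic gradients agree with finite differences", {
  cfg <- trainConfig(depth = 3, base_width = 4, patch_size = 16,
                     learning_rate = 1e-3)
  wts <- withr::with_seed(5, pixphen:::.initWeights(cfg))
  x <- withr::with_seed(6, matrix(runif(256), 16, 16))
  y <- withr::with_seed(7, matrix(rbinom(256, 1, 0.5), 16, 16))
  fw <- pixphen:::.forwardUnet(wts, x, cfg, keepCache = TRUE)
  bk <- pixphen:::.backwardUnet(wts, cfg, fw, as.vector(y))
  lossAt <- function(w) {
    f <- pixphen:::.forwardUnet(w, x, cfg, keepCache = FALSE)
    p <- pixphen:::.softmax2(f$logits)
    yv <- as.vector(y)
    -mean(log(pmax(p[cbind(seq_along(yv), yv + 1L)], 1e-12)))
  }
  eps <- 1e-6
  set.seed(8)
  for (nm in c("enc1a", "enc3b", "dec1b", "out")) {
    i <- sample(length(wts[[nm]]$W), 1)
    wp <- wts; wp[[nm]]$W[i] <- wp[[nm]]$W[i] + eps
    wm <- wts; wm[[nm]]$W[i] <- wm[[nm]]$W[i] - eps
    num <- (lossAt(wp) - lossAt(wm)) / (2 * eps)
    expect_equal(bk$grads[[nm]]$W[i], num, tolerance = 1e-4,
                 label = paste("grad", nm))
  }
})

test_that("a centred identity kernel reproduces its input", {
  A <- matrix(as.numeric(1:30), 30, 1)
  layer <- list(W = matrix(0, 9, 1), b = 0)
  layer$W[5, 1] <- 1
  out <- pixphen:::.convForward(A, 6, 5, layer)
  expect_equal(out$Y, A)
})

test_that("softmax probabilities are normalized everywhere", {
  cfg <- trainConfig(depth = 2, base_width = 4, patch_size = 16)
  wts <- withr::with_seed(1, pixphen:::.initWeights(cfg))
  x <- withr::with_seed(2, matrix(runif(16 * 16), 16, 16))
  fw <- pixphen:::.forwardUnet(wts, x, cfg)
  p <- pixphen:::.softmax2(fw$logits)
  expect_true(all(abs(rowSums(p) - 1) < 1e-12))
  expect_true(all(p >= 0 & p <= 1))
})

makeTrainingSet <- function(seed, nCells = 20, side = 256, marker = "panCK",
                            noise = list(background_level = 0.05,
                                         gaussian_sigma = 0.02,
                                         intensity_cv = 0.2)) {
  sc <- simulateScene(sceneParams(height = side, width = side,
                                  nCells = nCells, seed = seed,
                                  noise = noise))
  img <- imgPlanes(renderChannel(sc, marker))[[1]]
  lab <- buildTrainingLabels(sc, marker)
  list(scene = sc, img = img,
       patches = tilePatches(img, lab, patch = 64, stride = 64))
}

test_that("training reduces the loss and is seed-reproducible", {
  ts <- makeTrainingSet(seed = 51)
  cfg <- smallTrainConfig(iterations = 60, seed = 9)
  m1 <- trainPixelClassifier(ts$patches, cfg)
  expect_lt(tail(trainingLog(m1)$loss, 1), trainingLog(m1)$loss[1])
  m2 <- trainPixelClassifier(ts$patches, cfg)
  expect_identical(trainingLog(m1), trainingLog(m2))
  expect_identical(m1@weights$out$W, m2@weights$out$W)
})

test_that("degenerate single-class training sets are rejected", {
  blank <- list(list(image = matrix(0, 64, 64),
                     labels = matrix(0L, 64, 64), marker = "m",
                     offset = c(0L, 0L)))
  expect_error(trainPixelClassifier(blank, smallTrainConfig()),
               "degenerate")
})

test_that("short training on separable data reaches the oracle heatmap", {
  ts <- makeTrainingSet(seed = 52)
  m <- trainPixelClassifier(ts$patches, smallTrainConfig(iterations = 250,
                                                         seed = 10))
  hm <- predictHeatmap(m, ts$img, tile = 128)
  oracle <- oracleHeatmap(ts$scene, "panCK", 0)
  agree <- mean((probs(hm) >= 0.5) == (probs(oracle) >= 0.5))
  expect_gte(agree, 0.95)
  # held-out pixel accuracy on a fresh scene from the same conditions
  held <- makeTrainingSet(seed = 53)
  hm2 <- predictHeatmap(m, held$img, tile = 128)
  oracle2 <- oracleHeatmap(held$scene, "panCK", 0)
  expect_gte(mean((probs(hm2) >= 0.5) == (probs(oracle2) >= 0.5)), 0.95)
})

test_that("a constant image yields a spatially constant heatmap", {
  cfg <- smallTrainConfig()
  model <- new("PixelModel", config = unclass(cfg),
               weights = withr::with_seed(3, pixphen:::.initWeights(cfg)),
               log = data.frame())
  hm <- predictHeatmap(model, matrix(0.3, 96, 96), tile = 64)
  expect_lt(diff(range(probs(hm))), 1e-9)
  expect_true(all(probs(hm) >= 0 & probs(hm) <= 1))
})

test_that("tiled inference with overlap matches whole-image prediction", {
  ts <- makeTrainingSet(seed = 54, nCells = 10, side = 160)
  m <- trainPixelClassifier(ts$patches, smallTrainConfig(iterations = 40,
                                                         seed = 11))
  whole <- predictHeatmap(m, ts$img, tile = 256)  # single tile
  tiled <- predictHeatmap(m, ts$img, tile = 96, overlap = 48)
  expect_lt(max(abs(probs(whole) - probs(tiled))), 1e-3)
  expect_error(predictHeatmap(m, ts$img, tile = 32), "margin")
})

test_that("oracle heatmaps are binary at zero blur and bounded under blur", {
  sc <- testScene(seed = 13, nCells = 10)
  hm0 <- oracleHeatmap(sc, "panCK", 0)
  lab <- maskLabels(buildTrainingLabels(sc, "panCK"))
  expect_identical(unname(probs(hm0)), unname(lab * 1.0))
  hm2 <- oracleHeatmap(sc, "panCK", 2)
  expect_true(all(probs(hm2) >= 0 & probs(hm2) <= 1))
  # positive-cell centroids stay confidently positive under moderate blur
  tr <- sceneTruth(sc)
  pos <- tr[tr$panCK, ]
  for (i in seq_len(nrow(pos))) {
    expect_gte(probs(hm2)[round(pos$y[i]) + 1, round(pos$x[i]) + 1], 0.5)
  }
})

test_that("model checkpoints round-trip through disk", {
  ts <- makeTrainingSet(seed = 55, nCells = 8, side = 128)
  m <- trainPixelClassifier(ts$patches, smallTrainConfig(iterations = 20,
                                                         seed = 12))
  tf <- withr::local_tempfile(fileext = ".rds")
  saveModel(m, tf)
  m2 <- loadModel(tf)
  expect_identical(m@weights, m2@weights)
  expect_identical(trainingLog(m), trainingLog(m2))
  h1 <- probs(predictHeatmap(m, ts$img, tile = 128))
  h2 <- probs(predictHeatmap(m2, ts$img, tile = 128))
  expect_identical(h1, h2)
})

test_that("staged encoder freezing leaves frozen weights untouched", {
  ts <- makeTrainingSet(seed = 56, nCells = 8, side = 128)
  cfg <- smallTrainConfig(iterations = 30, seed = 13,
                          freeze_schedule = list(c(1, 1)))
  m <- trainPixelClassifier(ts$patches, cfg)
  init <- withr::with_seed(cfg$seed, pixphen:::.initWeights(cfg))
  expect_identical(m@weights$enc1a$W, init$enc1a$W)
  expect_false(identical(m@weights$enc2a$W, init$enc2a$W))
})
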