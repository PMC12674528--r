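test_that("mean-intensity gating is inclusive and matches brute force", {
  lab <- matrix(0L, 3, 3); lab[1, 1:3] <- 1L
  img <- matrix(0, 3, 3); img[1, 1:3] <- c(10, 20, 30)
  r <- meanIntensityPositivity(img, LabelMask(lab), threshold = 20)
  expect_equal(r$mean_intensity, 20)
  expect_identical(r$call, "positive")

  r0 <- meanIntensityPositivity(img, LabelMask(lab), threshold = 0)
  expect_identical(r0$call, "positive")

  for (seed in 1:10) {
    lab <- randomMask(24, 24, nObj = 6, seed = seed)
    img <- withr::with_seed(seed + 50, matrix(runif(576, 0, 100), 24, 24))
    th <- withr::with_seed(seed + 80, runif(1, 20, 80))
    got <- meanIntensityPositivity(img, LabelMask(lab), th)
    want <- bruteMeanIntensity(img, lab, th)
    expect_equal(got$mean_intensity, want$mean_intensity)
    expect_identical(got$call, want$call)
  }
  expect_error(meanIntensityPositivity(matrix(0, 2, 2),
                                       LabelMask(matrix(0L, 3, 3)), 1),
               "shape")
})

test_that("expansion into the membrane raises positive-cell means", {
  sc <- simulateScene(sceneParams(height = 192, width = 192, nCells = 10,
                                  seed = 14,
                                  noise = list(background_level = 0,
                                               gaussian_sigma = 0,
                                               intensity_cv = 0)))
  img <- imgPlanes(renderChannel(sc, "PDL1"))[[1]]
  tr <- sceneTruth(sc)
  k0 <- expandAndMeasure(img, nucleusMask(sc), 0, threshold = 0.1)
  k6 <- expandAndMeasure(img, nucleusMask(sc), 6, threshold = 0.1)
  expect_equal(k0$mean_intensity,
               meanIntensityPositivity(img, nucleusMask(sc),
                                       0.1)$mean_intensity)
  posIds <- tr$object_id[tr$PDL1]
  m0 <- k0$mean_intensity[k0$object_id %in% posIds]
  m6 <- k6$mean_intensity[k6$object_id %in% posIds]
  expect_true(all(m6 > m0))

  # composing the two component oracles reproduces the calls
  lab <- randomMask(24, 24, nObj = 4, seed = 99)
  rimg <- withr::with_seed(7, matrix(runif(576), 24, 24))
  got <- expandAndMeasure(rimg, LabelMask(lab), 2, threshold = 0.5)
  want <- bruteMeanIntensity(rimg, bruteDilate(lab, 2), 0.5)
  expect_equal(got$mean_intensity, want$mean_intensity)
  expect_identical(got$call, want$call)
})

test_that("weighted metrics match hand-computed and brute-force values", {
  r <- weightedMetrics(c("A", "A", "B", "B"), c("A", "B", "B", "B"))
  expect_equal(r$accuracy, 0.75)
  expect_equal(r$recall, 0.75)
  expect_equal(r$precision, 5 / 6)
  expect_equal(r$f1, 0.5 * (2 * 1 * 0.5 / 1.5) + 0.5 * (2 * (2/3) / (5/3)))
  expect_equal(unname(diag(r$confusion_counts)), c(1, 2))

  perfect <- weightedMetrics(c("A", "B", "A"), c("A", "B", "A"))
  expect_equal(perfect$f1, 1.0)
  expect_equal(perfect$accuracy, 1.0)
  expect_true(all(r$confusion_counts >= 0))
  expect_equal(sum(r$confusion_counts), r$n)

  single <- weightedMetrics(rep("A", 5), rep("A", 5))
  expect_equal(single$f1, 1.0)

  for (seed in 1:10) {
    classes <- c("a", "b", "c", "unclassifiable")
    tr <- withr::with_seed(seed, sample(classes[1:3], 30, replace = TRUE))
    pr <- withr::with_seed(seed + 9, sample(classes, 30, replace = TRUE))
    got <- weightedMetrics(tr, pr)
    want <- bruteMetrics(tr, pr)
    expect_equal(got$f1, want$f1)
    expect_equal(got$precision, want$precision)
    expect_equal(got$recall, want$recall)
    expect_equal(got$accuracy, want$accuracy)
  }
  expect_error(weightedMetrics("a", c("a", "b")), "length")
  expect_error(weightedMetrics(character(0), character(0)), "empty")
})

test_that("prediction-normalized confusion matrices have unit columns", {
  r <- weightedMetrics(c("A", "A", "B"), c("A", "B", "B"),
                       normalize = "prediction")
  expect_equal(unname(colSums(r$confusion)), c(1, 1))
})

test_that("rank AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  for (seed in 1:5) {
    y <- withr::with_seed(seed, rbinom(40, 1, 0.4) == 1)
    if (!any(y) || all(y)) next
    s <- withr::with_seed(seed + 5, rnorm(40) + y)
    got <- rankAUC(s, y)
    want <- as.numeric(suppressMessages(pROC::auc(pROC::roc(y, s,
                                                            quiet = TRUE))))
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("object-size experiment is perfect in the ideal sharp limit", {
  # cytoplasm thicker than the largest (8 px) dilation so every group's
  # label stays inside the whole-cell support of the sharp oracle
  sc <- testScene(seed = 15, nCells = 8, side = 224,
                  cytoplasmThicknessRange = c(9, 11))
  hm <- oracleHeatmap(sc, "panCK", 0)
  res <- objectSizeExperiment(hm, nucleusMask(sc),
                              sceneTruthCalls(sc, "panCK"))
  expect_identical(nrow(res$summary), 5L)
  expect_true(all(res$summary$f1 == 1.0))
  # reproducible under identical inputs
  res2 <- objectSizeExperiment(hm, nucleusMask(sc),
                               sceneTruthCalls(sc, "panCK"))
  expect_identical(res$summary, res2$summary)
})

test_that("benchmark harness emits both reports and round-trips them", {
  sc <- testScene(seed = 16, nCells = 15)
  scheme <- defaultPhenotypeScheme()
  hms <- lapply(stats::setNames(scheme$markers, scheme$markers),
                function(m) oracleHeatmap(sc, m, 0))
  res <- benchmarkExperiment(sc, hms, scheme = scheme, seed = 3)
  expect_s3_class(res$pixel, "MetricsReport")
  expect_s3_class(res$baseline, "MetricsReport")
  expect_equal(res$pixel$f1, 1.0)  # ideal classifier, true nuclei
  expect_identical(res$threshold_source, "calibrated")
  expect_named(res$sweep, scheme$markers)

  tf <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(reportToList(res$pixel), tf, auto_unbox = TRUE,
                       digits = NA)
  back <- jsonlite::read_json(tf)
  expect_equal(back$f1, res$pixel$f1)
  expect_equal(back$n, res$pixel$n)
})

test_that("detected nuclei map back to scene truth by overlap", {
  p <- sceneParams(height = 192, width = 192, nCells = 10, seed = 17,
                   noise = list(background_level = 0.02,
                                gaussian_sigma = 0.01, intensity_cv = 0.1))
  sc <- simulateScene(p)
  det <- detectNuclei(renderDapi(sc))
  tc <- truthCallsForMask(sc, "panCK", det)
  expect_identical(nrow(tc), nrow(labelCentroids(det)))
  tr <- sceneTruth(sc)
  want <- ifelse(tr$panCK[match(tc$cell_id, tr$object_id)],
                 "positive", "negative")
  expect_identical(tc$call, want)
})
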