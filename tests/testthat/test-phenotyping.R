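test_that("coverage rule bounds are inclusive at both ends", {
  lab <- matrix(0L, 10, 10); lab[1:10, 1:10] <- 1L
  p <- matrix(1, 10, 10)
  r <- assignPositivity(ProbabilityHeatmap(p, "m"), LabelMask(lab),
                        positivityRule(0.5, 0.8))
  expect_identical(r$call, "positive")
  expect_equal(r$coverage, 1.0)

  # exactly 80 of 100 pixels at p = 0.6, the rest at 0.1
  p2 <- matrix(0.1, 10, 10); p2[1:80] <- 0.6
  r2 <- assignPositivity(ProbabilityHeatmap(p2, "m"), LabelMask(lab),
                         positivityRule(0.5, 0.8))
  expect_identical(r2$call, "positive")
  expect_equal(r2$coverage, 0.8)

  # one pixel less fails
  p3 <- p2; p3[80] <- 0.1
  r3 <- assignPositivity(ProbabilityHeatmap(p3, "m"), LabelMask(lab),
                         positivityRule(0.5, 0.8))
  expect_identical(r3$call, "negative")

  # p exactly at the confidence threshold counts
  p4 <- matrix(0.5, 10, 10)
  r4 <- assignPositivity(ProbabilityHeatmap(p4, "m"), LabelMask(lab),
                         positivityRule(0.5, 0.8))
  expect_identical(r4$call, "positive")
})

test_that("positivity calls match the exhaustive counting oracle", {
  for (seed in 1:10) {
    lab <- randomMask(20, 20, nObj = 5, seed = seed)
    p <- withr::with_seed(seed + 100, matrix(runif(400), 20, 20))
    conf <- c(0.3, 0.5, 0.7)[seed %% 3 + 1]
    cov <- c(0.5, 0.8)[seed %% 2 + 1]
    got <- assignPositivity(ProbabilityHeatmap(p, "m"), LabelMask(lab),
                            positivityRule(conf, cov))
    want <- bruteCoverage(p, lab, conf, cov)
    expect_equal(got$object_id, want$object_id)
    expect_equal(got$coverage, want$coverage)
    expect_identical(got$call, want$call)
  }
})

test_that("empty object sets and shape mismatches are handled", {
  hm <- ProbabilityHeatmap(matrix(0.5, 4, 4), "m")
  expect_identical(nrow(assignPositivity(hm, LabelMask(matrix(0L, 4, 4)))),
                   0L)
  expect_error(assignPositivity(hm, LabelMask(matrix(0L, 5, 5))), "shape")
})

test_that("mean-probability mode gates on the object mean", {
  lab <- matrix(0L, 4, 4); lab[1:2, 1:2] <- 1L
  p <- matrix(0, 4, 4); p[1:2, 1:2] <- c(0.2, 0.4, 0.6, 0.8)
  r <- assignPositivity(ProbabilityHeatmap(p, "m"), LabelMask(lab),
                        positivityRule(0.5, mode = "mean"))
  expect_equal(r$mean_prob, 0.5)
  expect_identical(r$call, "positive")
})

test_that("confidence sweep produces nested positive sets", {
  confs <- c(0.10, 0.25, 0.50, 0.75, 0.90)
  for (seed in 1:6) {
    lab <- randomMask(24, 24, nObj = 6, seed = seed)
    p <- withr::with_seed(seed, matrix(runif(576), 24, 24))
    sw <- confidenceSweep(ProbabilityHeatmap(p, "m"), LabelMask(lab),
                          confidences = confs, coverage = 0.5)
    posAt <- lapply(confs, function(cf)
      sw$object_id[sw$confidence == cf & sw$call == "positive"])
    for (i in seq_len(length(confs) - 1)) {
      expect_true(all(posAt[[i + 1]] %in% posAt[[i]]))
    }
    counts <- vapply(posAt, length, integer(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("a one-point sweep equals a single assignment call", {
  lab <- randomMask(16, 16, nObj = 3, seed = 42)
  p <- withr::with_seed(1, matrix(runif(256), 16, 16))
  sw <- confidenceSweep(ProbabilityHeatmap(p, "m"), LabelMask(lab),
                        confidences = 0.5, coverage = 0.8)
  single <- assignPositivity(ProbabilityHeatmap(p, "m"), LabelMask(lab),
                             positivityRule(0.5, 0.8))
  expect_identical(sw$call, single$call)
  expect_equal(sw$coverage, single$coverage)
})

lineageScheme <- function() {
  phenotypeScheme(list(
    list(name = "epithelial", positive = "panCK"),
    list(name = "CD8 T cell", positive = "CD8"),
    list(name = "macrophage", positive = "CD68")))
}

test_that("phenotype resolution: single match, fallback, and conflicts", {
  calls <- data.frame(
    object_id = 1:4,
    panCK = c("positive", "positive", "negative", "negative"),
    CD8 = c("negative", "positive", "negative", "negative"),
    CD68 = c("negative", "negative", "negative", "positive"))
  got <- resolvePhenotype(calls, lineageScheme())
  # co-positivity for exclusive lineages is reclassified as unclassifiable
  expect_identical(got, c("epithelial", "unclassifiable", "negative",
                          "macrophage"))

  first <- phenotypeScheme(lineageScheme()$definitions, exclusive = FALSE)
  expect_identical(resolvePhenotype(calls, first)[2], "epithelial")

  expect_error(resolvePhenotype(calls[, 1:3], lineageScheme()), "CD68")
})

test_that("oracle heatmaps drive exact end-to-end phenotype recovery", {
  sc <- testScene(seed = 12, nCells = 15)
  scheme <- defaultPhenotypeScheme()
  tr <- sceneTruth(sc)
  truthCalls <- tr
  for (m in scheme$markers)
    truthCalls[[m]] <- ifelse(tr[[m]], "positive", "negative")
  want <- resolvePhenotype(truthCalls, scheme)

  for (blur in c(0, 1)) {
    hms <- lapply(stats::setNames(scheme$markers, scheme$markers),
                  function(m) oracleHeatmap(sc, m, blur))
    tab <- phenotypePipeline(hms, nucleusMask(sc), positivityRule(), scheme)
    expect_identical(tab$phenotype, want, label = paste("blur", blur))
    expect_equal(tab$object_id, tr$object_id)
    expect_equal(tab$x, tr$x, tolerance = 1)  # pixelized centroid
  }
})

test_that("an empty nuclei mask gives an empty cell table", {
  sc <- testScene(seed = 12, nCells = 6)
  scheme <- defaultPhenotypeScheme()
  hms <- lapply(stats::setNames(scheme$markers, scheme$markers),
                function(m) oracleHeatmap(sc, m, 0))
  empty <- LabelMask(matrix(0L, 192, 192))
  tab <- phenotypePipeline(hms, empty, positivityRule(), scheme)
  expect_identical(nrow(tab), 0L)
})

test_that("pipeline demands a heatmap for every scheme marker", {
  sc <- testScene(seed = 12, nCells = 6)
  hms <- list(panCK = oracleHeatmap(sc, "panCK", 0))
  expect_error(
    phenotypePipeline(hms, nucleusMask(sc), positivityRule(),
                      defaultPhenotypeScheme()),
    "FOXP3")
})
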