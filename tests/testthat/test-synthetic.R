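test_that("simulated experiment honors the shape contract", {
  cfg <- smallConfig()
  tce <- simulateTimeCourse(cfg)
  expect_s4_class(tce, "TimeCourseExperiment")
  expect_equal(dim(tce), c(500L, 16L * 6L))
  expect_equal(hours(tce), c(0, 2, 4, 8, 12, 24))
  expect_equal(cellLines(tce), sprintf("L%02d", 1:16))
  # emitted z-scored per gene
  m <- SummarizedExperiment::assay(tce, "exprs")
  expect_equal(unname(rowMeans(m)), rep(0, nrow(m)), tolerance = 1e-12)
  expect_equal(unname(apply(m, 1, sd)), rep(1, nrow(m)), tolerance = 1e-12)
})

test_that("invalid configurations are rejected", {
  expect_error(simulationConfig(nGenes = 10, nSignature = 10), "smaller")
  expect_error(simulationConfig(timepointsH = c(0, 4, 2)), "increasing")
  expect_error(simulationConfig(noiseSd = -1), "non-negative")
  expect_error(simulationConfig(nProfiles = 60, libSize = 50), "libSize")
})

test_that("zero noise reproduces the planted temporal archetypes exactly", {
  cfg <- smallConfig(noiseSd = 0, sf2NoiseSd = 0)
  tce <- simulateTimeCourse(cfg)
  truth <- radiosig:::planTruth(cfg)
  lib <- buildProfileLibrary(6, 2, 50)
  m <- SummarizedExperiment::assay(tce, "exprs")
  cd <- SummarizedExperiment::colData(tce)
  for (g in truth@signatureGenes[1:5]) {
    curve <- profileMatrix(lib)[truth@profileId[g], ]
    for (l in cfg@cellLines[1:3]) {
      series <- m[g, cd$cell_line == l][order(cd$hour[cd$cell_line == l])]
      # z-scoring is affine per gene, so the series is the curve exactly
      # up to a positive linear map
      expect_equal(cor(series, curve), 1, tolerance = 1e-9)
    }
  }
})

test_that("SF2 follows the SGLQ law exactly without noise", {
  cfg <- smallConfig(sf2NoiseSd = 0)
  tce <- simulateTimeCourse(cfg)
  B <- baselineMatrix(tce)
  sf2 <- simulateSF2(cfg, B)
  truth <- radiosig:::planTruth(cfg)
  E <- B[truth@signatureGenes, cfg@cellLines]
  expected <- pmin(exp(colMeans(truth@alpha * E - truth@beta * E^2)), 1)
  expect_equal(sf2Values(sf2), expected, tolerance = 1e-12)
  expect_true(all(sf2Values(sf2) > 0 & sf2Values(sf2) <= 1))
})

test_that("SGLQ generator evaluates the stated formula on a single gene", {
  # alpha = 0.2, beta = 0.3, one signature gene with E = 1 in one line:
  # that line's SF2 is e^(0.2 - 0.3) = e^(-0.1)
  cfg <- simulationConfig(nGenes = 2, nSignature = 1, nResponsive = 0,
                          nBlocks = 0, cellLines = c("A", "B", "C"),
                          sglqAlpha = 0.2, sglqBeta = 0.3, sf2NoiseSd = 0,
                          seed = 3)
  truth <- radiosig:::planTruth(cfg)
  B <- matrix(0, 2, 3, dimnames = list(sprintf("G%04d", 1:2),
                                       c("A", "B", "C")))
  B[truth@signatureGenes, "A"] <- 1
  sf2 <- simulateSF2(cfg, B)
  expect_equal(unname(sf2Values(sf2)["A"]), exp(-0.1), tolerance = 1e-12)
  expect_equal(unname(sf2Values(sf2)[c("B", "C")]), c(1, 1))

  # a positive exponent is clipped to the survival ceiling of 1
  cfgPos <- simulationConfig(nGenes = 2, nSignature = 1, nResponsive = 0,
                             nBlocks = 0, cellLines = c("A", "B", "C"),
                             sglqAlpha = 0.2, sglqBeta = 0.1,
                             sf2NoiseSd = 0, seed = 3)
  sf2Pos <- simulateSF2(cfgPos, B)   # exponent 0.1 at line A
  expect_equal(unname(sf2Values(sf2Pos)["A"]), 1)

  # alpha = beta = 0 gives SF2 = 1 everywhere
  cfg0 <- simulationConfig(nGenes = 2, nSignature = 1, nResponsive = 0,
                           nBlocks = 0, cellLines = c("A", "B", "C"),
                           sglqAlpha = 0, sglqBeta = 0, sf2NoiseSd = 0,
                           seed = 3)
  expect_equal(unname(sf2Values(simulateSF2(cfg0, B))), rep(1, 3))
})

test_that("SF2 generation requires a planted signature", {
  cfg <- smallConfig(nSignature = 0)
  B <- matrix(0, 2, 16, dimnames = list(c("G0001", "G0002"),
                                        cfg@cellLines))
  expect_error(simulateSF2(cfg, B), "empty signature")
})

test_that("one-way ANOVA is calibrated on null synthetic genes", {
  cfg <- simulationConfig(nGenes = 2000, nSignature = 0, nResponsive = 0,
                          nBlocks = 0, cellLines = sprintf("L%02d", 1:8),
                          seed = 31)
  tce <- simulateTimeCourse(cfg)
  rate <- mean(anovaFilter(tce)$p < 0.05)
  expect_gt(rate, 0.03)
  expect_lt(rate, 0.07)
})

test_that("signature subgraph density one yields a clique", {
  cfg <- smallConfig(signatureDensity = 1)
  layers <- simulateNetworkLayers(cfg)
  truth <- radiosig:::planTruth(cfg)
  ed <- layerEdges(layers$protein)
  sig <- truth@signatureGenes
  within <- ed$from %in% sig & ed$to %in% sig
  expect_equal(sum(within), choose(length(sig), 2))
})

test_that("heat elevation behaves multiplicatively", {
  # factor 1: signature heats indistinguishable from background
  ratios1 <- vapply(1:30, function(s) {
    truth <- radiosig:::planTruth(smallConfig(seed = s, heatFactor = 1))
    mean(truth@mutationHeat[truth@signatureGenes]) /
      mean(truth@mutationHeat[setdiff(names(truth@mutationHeat),
                                      truth@signatureGenes)])
  }, numeric(1))
  expect_equal(mean(ratios1), 1, tolerance = 0.05)
  # configured factor recovered in the mean over seeds
  ratios5 <- vapply(1:30, function(s) {
    truth <- radiosig:::planTruth(smallConfig(seed = s, heatFactor = 5))
    mean(truth@mutationHeat[truth@signatureGenes]) /
      mean(truth@mutationHeat[setdiff(names(truth@mutationHeat),
                                      truth@signatureGenes)])
  }, numeric(1))
  expect_equal(mean(ratios5), 5, tolerance = 0.25)
})

test_that("a disconnected planted subgraph is a generation error", {
  cfg <- smallConfig(signatureDensity = 0, meanDegree = 0.01)
  expect_error(simulateNetworkLayers(cfg), "disconnected")
})

test_that("fixture bundles round-trip and are seed-deterministic", {
  b <- smallBundle()
  d1 <- file.path(tempdir(), "bundle1")
  d2 <- file.path(tempdir(), "bundle2")
  m1 <- writeFixtureBundle(b, d1)
  m2 <- writeFixtureBundle(simulateBundle(smallConfig()), d2)
  # identical seed, bit-identical files
  for (f in names(m1$files))
    expect_identical(m1$files[[f]]$md5, m2$files[[f]]$md5)

  rb <- readFixtureBundle(d1)
  expect_equal(SummarizedExperiment::assay(rb$tce, "exprs"),
               SummarizedExperiment::assay(b$tce, "exprs"),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(sf2Values(rb$sf2), sf2Values(b$sf2), tolerance = 1e-12)
  expect_equal(nodeHeat(rb$layers$mutation), nodeHeat(b$layers$mutation),
               tolerance = 1e-12)
  ea <- layerEdges(rb$layers$protein)
  eb <- layerEdges(b$layers$protein)
  expect_equal(ea$from, eb$from)
  expect_equal(ea$weight, eb$weight, tolerance = 1e-12)
  expect_identical(rb$geneSets$PLANTED_SIGNATURE,
                   b$geneSets$PLANTED_SIGNATURE)
  # truth genes are contained in the expression universe
  expect_true(all(signatureGenes(rb$truth) %in% rownames(rb$tce)))
  expect_identical(signatureGenes(rb$truth), signatureGenes(b$truth))
})

test_that("every signature gene appears in all emitted data layers", {
  b <- smallBundle()
  sig <- signatureGenes(b$truth)
  expect_true(all(sig %in% rownames(b$tce)))
  expect_true(all(sig %in% names(nodeHeat(b$layers$mutation))))
  expect_true(all(sig %in% names(nodeHeat(b$layers$cna))))
  expect_true(all(sig %in% b$layers$protein@nodes))
  expect_true(all(sig %in% b$geneSets$PLANTED_SIGNATURE))
})
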