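test_that("identical config including seed reproduces the collection exactly", {
  cfg <- simConfig(nDatasets = 3, nBackgroundGenes = 30,
                   samplesPerDataset = c(10, 12, 14),
                   planted = plantedModule("P1", "PINK1", 0.8), seed = 42)
  t1 <- simulateCollection(cfg)
  t2 <- simulateCollection(cfg)
  for (i in 1:3)
    expect_identical(exprs(simDatasets(t1)[[i]]), exprs(simDatasets(t2)[[i]]))
})

test_that("per-dataset streams are derived by index: extending the collection leaves earlier datasets unchanged", {
  cfgSmall <- simConfig(nDatasets = 2, nBackgroundGenes = 20,
                        samplesPerDataset = c(10, 12), seed = 9)
  cfgBig <- simConfig(nDatasets = 4, nBackgroundGenes = 20,
                      samplesPerDataset = c(10, 12, 9, 11), seed = 9)
  small <- simulateCollection(cfgSmall)
  big <- simulateCollection(cfgBig)
  for (i in 1:2)
    expect_identical(exprs(simDatasets(small)[[i]]),
                     exprs(simDatasets(big)[[i]]))
})

test_that("empty planted set and zero background give datasets of exactly the anchors", {
  cfg <- simConfig(nDatasets = 2, nBackgroundGenes = 0,
                   samplesPerDataset = c(8, 8), seed = 1)
  truth <- simulateCollection(cfg)
  for (ds in simDatasets(truth))
    expect_identical(rownames(ds), anchorSymbols(defaultAnchors()))
})

test_that("planted correlation is consistent: empirical r at n = 1000 approaches rho for each target anchor", {
  # single target at rho = 0.99 (tight check) and a 3-target gene at 0.85
  cfg <- simConfig(
    nDatasets = 1, samplesPerDataset = 1000, nBackgroundGenes = 0,
    planted = plantedModule(c("P1", "P2"),
                            list("SCNA", c("LRRK2", "PINK1", "DJ1")),
                            c(0.99, 0.85)),
    dropoutProb = 0, seed = 5)
  v <- exprs(simDatasets(simulateCollection(cfg))[[1]])
  expect_equal(oraclePearson(v["P1", ], v["SCNA", ]), 0.99, tolerance = 0.011)
  for (a in c("LRRK2", "PINK1", "DJ1"))
    expect_equal(oraclePearson(v["P2", ], v[a, ]), 0.85, tolerance = 0.025)
})

test_that("rho = 0 decouples a planted gene from its anchor (null-distributed r over seeds)", {
  rs <- vapply(1:40, function(s) {
    cfg <- simConfig(nDatasets = 1, samplesPerDataset = 30,
                     nBackgroundGenes = 0,
                     planted = plantedModule("P1", "SCNA", 0),
                     dropoutProb = 0, seed = s)
    v <- exprs(simDatasets(simulateCollection(cfg))[[1]])
    oraclePearson(v["P1", ], v["SCNA", ])
  }, numeric(1))
  # null r at n = 30 has mean 0 and sd ~ 1/sqrt(n - 1) ~ 0.186
  expect_lt(abs(mean(rs)), 3 * 0.186 / sqrt(40))
  expect_lt(max(abs(rs)), 0.75)
})

test_that("background genes are independent of anchors (null-scale correlations)", {
  cfg <- simConfig(nDatasets = 1, samplesPerDataset = 500,
                   nBackgroundGenes = 200, dropoutProb = 0, seed = 13)
  v <- exprs(simDatasets(simulateCollection(cfg))[[1]])
  bg <- grep("^BG", rownames(v), value = TRUE)
  rs <- as.vector(cor(t(v[bg, ]), t(v[anchorSymbols(defaultAnchors()), ])))
  # 200 x 7 null correlations at n = 500: sd ~ 1/sqrt(499)
  expect_lt(abs(mean(rs)), 0.01)
  expect_lt(max(abs(rs)), 6 / sqrt(499))
})

test_that("dropout removes non-anchor genes per dataset but never anchors", {
  cfg <- simConfig(nDatasets = 8, nBackgroundGenes = 100,
                   samplesPerDataset = rep(10, 8), dropoutProb = 0.4,
                   planted = plantedModule("P1", "SCNA", 0.5), seed = 3)
  truth <- simulateCollection(cfg)
  counts <- vapply(simDatasets(truth), nrow, integer(1))
  anchors <- anchorSymbols(defaultAnchors())
  for (ds in simDatasets(truth))
    expect_true(all(anchors %in% rownames(ds)))
  # some background genes must actually be absent somewhere at p = 0.4
  expect_true(any(counts < 7 + 1 + 100))
  # and the planted gene survives somewhere (SimTruth invariant)
  expect_true(any(vapply(simDatasets(truth), function(d)
    "P1" %in% rownames(d), logical(1))))
})

test_that("config invariants are enforced with the offending field named", {
  expect_error(simConfig(nDatasets = 2, samplesPerDataset = c(10, 3),
                         seed = 1), "samplesPerDataset")
  expect_error(simConfig(planted = plantedModule("P1", "NOPE", 0.5),
                         seed = 1), "P1")
  expect_error(simConfig(planted = plantedModule("SCNA", "PINK1", 0.5),
                         seed = 1), "disjoint")
  expect_error(simConfig(planted = plantedModule("P1", "PINK1", 1.2),
                         seed = 1), "rho")
  expect_error(simConfig(dropoutProb = 1, seed = 1), "dropoutProb")
  # unattainable per-anchor rho given the anchor correlation structure
  expect_error(
    simConfig(anchorCor = 0,
              planted = plantedModule("P1", c("SCNA", "PINK1"), 0.9),
              seed = 1),
    "attainable")
})

test_that("written collections round-trip losslessly at 6 decimals with a manifest and ground-truth TSV", {
  cfg <- simConfig(nDatasets = 2, nBackgroundGenes = 15,
                   samplesPerDataset = c(8, 10),
                   planted = plantedModule(c("P1", "P2"), "DJ1", 0.7),
                   seed = 21)
  truth <- simulateCollection(cfg)
  dir <- withr::local_tempdir()
  manifest <- writeCollection(truth, dir)
  expect_true(file.exists(manifest))
  m <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  expect_identical(nrow(m$datasets), 2L)
  back <- suppressMessages(loadCollection(manifest))
  for (i in 1:2) {
    orig <- exprs(simDatasets(truth)[[i]])
    expect_identical(dimnames(exprs(back[[i]])), dimnames(orig))
    expect_equal(exprs(back[[i]]), orig, tolerance = 1e-6)
    expect_true(max(abs(exprs(back[[i]]) - orig)) <= 5e-7)
    expect_identical(idLevel(back[[i]]), "symbol")
  }
  tr <- readTruth(file.path(dir, "truth.tsv"))
  expect_identical(tr$gene, c("P1", "P2"))
  expect_identical(tr$anchors[[1]], "DJ1")
  expect_equal(tr$rho, c(0.7, 0.7))
})

test_that("an empty planted set writes a header-only ground-truth TSV", {
  cfg <- simConfig(nDatasets = 1, nBackgroundGenes = 2,
                   samplesPerDataset = 6, seed = 2)
  dir <- withr::local_tempdir()
  writeCollection(simulateCollection(cfg), dir)
  lines <- readLines(file.path(dir, "truth.tsv"))
  expect_identical(lines, "gene\tanchors\trho")
  expect_identical(nrow(readTruth(file.path(dir, "truth.tsv"))), 0L)
})

test_that("the default 11-dataset configuration writes an 11-file manifest", {
  cfg <- simConfig(nBackgroundGenes = 5, seed = 8)
  expect_identical(cfg@nDatasets, 11L)
  expect_true(all(cfg@samplesPerDataset >= 10 & cfg@samplesPerDataset <= 50))
  dir <- withr::local_tempdir()
  m <- jsonlite::read_json(writeCollection(simulateCollection(cfg), dir),
                           simplifyVector = TRUE)
  expect_identical(nrow(m$datasets), 11L)
})
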