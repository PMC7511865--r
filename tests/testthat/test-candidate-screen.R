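# Build a SupportMatrix directly from a named support specification:
# spec = list(G1 = c(A1 = 6, A2 = 5, ...), ...)
supportFromSpec <- function(spec, nDatasets = 11L, cfg = screenConfig()) {
  recs <- do.call(rbind, lapply(names(spec), function(g) {
    counts <- spec[[g]]
    do.call(rbind, lapply(names(counts), function(a) {
      k <- counts[[a]]
      if (k == 0) return(NULL)
      makeRecords(g, a, sprintf("d%02d", seq_len(k)), r = 0.99)
    }))
  }))
  anchors <- sort(unique(unlist(lapply(spec, names))), method = "radix")
  supportCounts(recs, cfg, nDatasetsTotal = nDatasets, anchors = anchors)
}

test_that("pair-support rule reproduces the enumerated example: {A1:6, A2:5, A3:5, A4:2} with D=5, A=3 gives N=3", {
  sup <- supportFromSpec(list(G1 = c(A1 = 6, A2 = 5, A3 = 5, A4 = 2)))
  tbl <- candidateCall(sup)
  rec <- records(tbl)
  expect_identical(rec$gene, "G1")
  expect_identical(rec$N, 3L)
  expect_true(rec$candidate)
  expect_identical(rec$anchors, "A1:6;A2:5;A3:5;A4:2")
})

test_that("a gene supported everywhere for every anchor is maximal", {
  sup <- supportFromSpec(list(G1 = setNames(rep(11, 7), paste0("A", 1:7))))
  rec <- records(candidateCall(sup))
  expect_identical(rec$N, 7L)
  expect_true(rec$candidate)
})

test_that("candidate calls match exhaustive enumeration on random support instances", {
  set.seed(404)
  for (i in 1:20) {
    rec <- randomRecords(sample(10:60, 1))
    cfg <- screenConfig(tau = runif(1, 0.3, 0.9),
                        minAnchors = sample(1:5, 1),
                        minDatasets = sample(2:8, 1))
    sup <- supportCounts(rec, cfg)
    got <- records(candidateCall(sup))
    oracle <- oracleCandidates(support(sup), cfg@minAnchors,
                               cfg@minDatasets)
    expect_identical(setNames(got$N, got$gene)[names(oracle$N)], oracle$N)
    expect_setequal(got$gene[got$candidate], oracle$candidates)
  }
})

test_that("anchors themselves never appear as candidates", {
  rec <- rbind(makeRecords("A1", "A2", sprintf("d%02d", 1:8), r = 0.95),
               makeRecords("G1", "A2", sprintf("d%02d", 1:8), r = 0.95))
  sup <- supportCounts(rec, screenConfig(minAnchors = 1L),
                       anchors = c("A1", "A2"))
  tbl <- candidateCall(sup)
  expect_identical(records(tbl)$gene, "G1")
})

test_that("per-dataset joint semantics require A anchors passing simultaneously within each supporting dataset", {
  anchors <- c("A1", "A2", "A3")
  # G1 passes all 3 anchors together in 5 datasets -> joint candidate, N = 3
  recJoint <- makeRecords("G1", anchors, sprintf("d%02d", 1:5), r = 0.95)
  # G2 passes each anchor in 5 *different* datasets (15 distinct datasets):
  # pair support is 5 per anchor, but never 3 anchors in one dataset
  recSplit <- do.call(rbind, lapply(1:3, function(k)
    makeRecords("G2", anchors[k], sprintf("e%02d", (k - 1) * 5 + 1:5),
                r = 0.95)))
  rec <- rbind(recJoint, recSplit)
  cfgJoint <- screenConfig(semantics = "per_dataset_joint")
  supJ <- supportCounts(rec, cfgJoint, nDatasetsTotal = 20L)
  tblJ <- candidateCall(supJ)
  rj <- records(tblJ)
  expect_true(rj$candidate[rj$gene == "G1"])
  expect_identical(rj$N[rj$gene == "G1"], 3L)
  expect_false(rj$candidate[rj$gene == "G2"])
  # under pair-support semantics both genes qualify
  cfgPair <- screenConfig()
  tblP <- candidateCall(supportCounts(rec, cfgPair, nDatasetsTotal = 20L))
  expect_setequal(candidates(tblP)$gene, c("G1", "G2"))
})

test_that("the candidate set is anti-monotone in tau, A and D on simulated collections", {
  sizes <- function(tbl) nrow(candidates(tbl))
  for (seed in 1:3) {
    cfg <- simConfig(nDatasets = 8, nBackgroundGenes = 100,
                     samplesPerDataset = rep(15, 8),
                     planted = plantedModule(
                       sprintf("P%d", 1:6),
                       list("SCNA", c("SCNA", "DJ1"), c("LRRK2", "PINK1"),
                            c("SCNA", "DJ1", "PINK1"), "HTR2A",
                            c("ATP13A2", "PARKIN", "DJ1", "SCNA")),
                       c(0.95, 0.9, 0.85, 0.8, 0.7, 0.9)),
                     seed = seed)
    truth <- simulateCollection(cfg)
    rec <- suppressMessages(
      anchorCorrelations(simDatasets(truth), defaultAnchors()))
    sz <- function(tau, A, D) {
      c0 <- screenConfig(tau = tau, minAnchors = A, minDatasets = D)
      sizes(candidateCall(supportCounts(rec, c0, nDatasetsTotal = 8L)))
    }
    for (A in c(2, 3)) for (D in c(4, 6))
      expect_true(all(diff(sapply(c(0.6, 0.75, 0.9), sz, A = A, D = D)) <= 0))
    for (tau in c(0.7, 0.85)) for (D in c(4, 6))
      expect_true(all(diff(sapply(2:4, function(A) sz(tau, A, D))) <= 0))
    for (tau in c(0.7, 0.85)) for (A in c(2, 3))
      expect_true(all(diff(sapply(c(3, 5, 7), function(D) sz(tau, A, D))) <= 0))
  }
})

test_that("genes measured in fewer than D datasets are flagged untestable rather than silently omitted", {
  rec <- rbind(makeRecords("G1", "A1", sprintf("d%02d", 1:6), r = 0.95),
               makeRecords("G2", "A1", c("d01", "d02"), r = 0.95))
  sup <- supportCounts(rec, screenConfig(), nDatasetsTotal = 6L)
  recs <- records(candidateCall(sup))
  expect_true(recs$testable[recs$gene == "G1"])
  expect_false(recs$testable[recs$gene == "G2"])
  expect_true("G2" %in% recs$gene)
})

test_that("tables are sorted (N desc, gene asc) and written byte-deterministically with tier summary", {
  sup <- supportFromSpec(list(
    Gb = c(A1 = 6, A2 = 6, A3 = 6),
    Ga = c(A1 = 6, A2 = 6, A3 = 6),
    Gz = c(A1 = 7, A2 = 7, A3 = 7, A4 = 7),
    Gn = c(A1 = 2)))
  tbl <- candidateCall(sup)
  expect_identical(records(tbl)$gene, c("Gz", "Ga", "Gb", "Gn"))
  ts <- tierSummary(tbl)
  expect_identical(ts$N, c(4L, 3L))
  expect_identical(ts$genes, c(1L, 2L))
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  writeCandidateTable(tbl, f1)
  writeCandidateTable(tbl, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_true(any(grepl("^# N=4\t1$", readLines(f1))))
})

test_that("written candidate tables round-trip through readCandidateTable", {
  sup <- supportFromSpec(list(G1 = c(A1 = 6, A2 = 5, A3 = 5),
                              G2 = c(A1 = 9, A2 = 9, A3 = 2)))
  tbl <- candidateCall(sup)
  f <- withr::local_tempfile()
  writeCandidateTable(tbl, f)
  back <- readCandidateTable(f)
  cand <- candidates(tbl)
  expect_identical(records(back)$gene, cand$gene)
  expect_identical(records(back)$N, cand$N)
  expect_identical(records(back)$anchors, cand$anchors)
})

test_that("an empty table writes a header plus empty summary", {
  sup <- supportFromSpec(list(G1 = c(A1 = 1)))
  tbl <- candidateCall(sup)
  f <- withr::local_tempfile()
  writeCandidateTable(tbl, f)
  lines <- readLines(f)
  expect_true("gene\tN\tanchors" %in% lines)
  expect_identical(sum(!grepl("^#", lines)), 1L)  # header only
  expect_identical(nrow(records(readCandidateTable(f))), 0L)
})

test_that("candidateCall refuses a config whose pass rule differs from the tally's", {
  sup <- supportFromSpec(list(G1 = c(A1 = 6)))
  expect_error(candidateCall(sup, screenConfig(tau = 0.9)), "rebuild")
  # changing only A/D is allowed: the tally does not depend on them
  expect_silent(candidateCall(sup, screenConfig(minAnchors = 1L,
                                                minDatasets = 2L)))
})

test_that("the packaged published table has the printed tier structure", {
  tbl <- loadTable1Fixture()
  rec <- records(tbl)
  expect_identical(nrow(rec), 32L)            # headline candidate count
  expect_identical(anyDuplicated(rec$gene), 0L)
  expect_identical(rec$gene[rec$N == 5L], "SMARCA4")
  expect_identical(sum(rec$N == 4L), 7L)
  expect_identical(sum(rec$N == 3L), 24L)
  expect_true("PRDX2" %in% rec$gene[rec$N == 4L])
  expect_true("BLVRA" %in% rec$gene[rec$N == 3L])
  ts <- tierSummary(tbl)
  expect_identical(ts$N, c(5L, 4L, 3L))
  expect_identical(sum(ts$genes), 32L)
})

test_that("the default anchor set and dataset manifest match the reference screen", {
  a <- defaultAnchors()
  expect_length(anchorSymbols(a), 7)
  expect_identical(anchorAliases(a)$SCNA, "SNCA")
  expect_true("HTRA2" %in% anchorAliases(a)$HTR2A)
  expect_length(pdDatasetManifest(), 11)
  expect_identical(anyDuplicated(pdDatasetManifest()), 0L)
})
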