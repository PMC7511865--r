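#' Planted-gene recovery metrics
#'
#' Compares a candidate table against the ground truth of the simulated
#' collection it was computed from: sensitivity is the fraction of planted
#' genes called candidate; false calls are candidates that are neither
#' planted nor anchors.
#'
#' @param truth the [SimTruth-class] the screen ran on.
#' @param tbl the resulting [CandidateTable-class].
#' @return A [RecoveryReport-class].
#' @examples
#' truth <- simulateCollection(recoverySimConfig(seed = 1, nPlanted = 3))
#' \donttest{
#' rep <- evaluateRecovery(truth, runScreen(simDatasets(truth)))
#' sensitivity(rep)
#' }
#' @export
evaluateRecovery <- function(truth, tbl) {
  planted <- truth@planted
  cand <- candidates(tbl)$gene
  recs <- records(tbl)
  called <- planted$gene %in% cand
  nByGene <- stats::setNames(recs$N, recs$gene)
  perGene <- data.frame(
    gene = planted$gene,
    called = called,
    N = ifelse(planted$gene %in% names(nByGene),
               as.integer(nByGene[planted$gene]), 0L),
    rho = planted$rho
  )
  false <- setdiff(cand, c(planted$gene, truth@config@anchorNames))
  new("RecoveryReport",
      sensitivity = if (nrow(planted)) mean(called) else NA_real_,
      falseCalls = as.numeric(length(false)),
      perGene = perGene, replicates = 1L,
      seed = truth@config@seed, candidateCounts = integer(0))
}

#' Null calibration of the screen
#'
#' Simulates planted-free collections and counts how many candidates the
#' screen emits in each replicate. Under the default rule (tau = 0.8 on at
#' least ~20 samples per dataset) the per-pair null pass probability is the
#' two-sided t tail at `t = r sqrt(n - 2) / sqrt(1 - r^2)`, so joint passage
#' in >= D datasets for >= A anchors is astronomically rare and the expected
#' candidate count is 0.
#'
#' @param config a [SimConfig-class] with an empty planted set; replicate
#'   `i` reuses it with seed `config@seed + i - 1`.
#' @param screen a [ScreenConfig-class] (default [screenConfig()]).
#' @param replicates number of replicates (>= 1).
#' @return A [RecoveryReport-class] with `sensitivity = NA`,
#'   `candidateCounts` holding the per-replicate counts and `falseCalls`
#'   their sum.
#' @examples
#' cfg <- simConfig(nDatasets = 5, nBackgroundGenes = 50,
#'                  samplesPerDataset = rep(20, 5), seed = 4)
#' \donttest{
#' candidateCounts(nullCalibration(cfg, replicates = 2))
#' }
#' @export
nullCalibration <- function(config, screen = screenConfig(),
                            replicates = 20L) {
  replicates <- as.integer(replicates)
  if (replicates < 1L)
    stop("replicates must be >= 1")
  if (nrow(config@planted))
    stop("null calibration requires an empty planted set")
  anchors <- anchorSet(config@anchorNames)
  counts <- vapply(seq_len(replicates), function(i) {
    cfg <- config
    cfg@seed <- as.integer(config@seed + i - 1L)
    truth <- simulateCollection(cfg)
    nrow(candidates(runScreen(simDatasets(truth), anchors, screen)))
  }, integer(1))
  new("RecoveryReport", sensitivity = NA_real_,
      falseCalls = as.numeric(sum(counts)),
      perGene = data.frame(gene = character(0), called = logical(0),
                           N = integer(0), rho = numeric(0)),
      replicates = replicates, seed = config@seed,
      candidateCounts = counts)
}

#' Monte-Carlo recovery over several seeds
#'
#' Runs the simulate -> screen -> evaluate loop over `seeds` under the
#' default recovery regime (see [recoverySimConfig()]) and averages the
#' metrics.
#'
#' @param seeds integer vector of master seeds, one replicate each.
#' @param screen a [ScreenConfig-class].
#' @param ... passed on to [recoverySimConfig()] (e.g. `rho`, `nPlanted`).
#' @return list with `meanSensitivity`, `meanFalseCalls`, and the
#'   per-replicate [RecoveryReport-class] objects.
#' @export
recoveryStudy <- function(seeds, screen = screenConfig(), ...) {
  reports <- lapply(seeds, function(s) {
    truth <- simulateCollection(recoverySimConfig(seed = s, ...))
    tbl <- runScreen(simDatasets(truth),
                     anchorSet(truth@config@anchorNames), screen)
    evaluateRecovery(truth, tbl)
  })
  list(meanSensitivity = mean(vapply(reports, sensitivity, numeric(1))),
       meanFalseCalls = mean(vapply(reports, falseCalls, numeric(1))),
       reports = reports)
}
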