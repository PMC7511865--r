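setMethod("show", "ExpressionDataset", function(object) {
  cat(sprintf("ExpressionDataset '%s' (%s level): %d x %d, %.1f%% missing\n",
              object@datasetId, object@idLevel, nrow(object), ncol(object),
              100 * mean(is.na(assay(object, "exprs")))))
})

setMethod("show", "AnchorSet", function(object) {
  cat(sprintf("AnchorSet of %d: %s\n", length(object@symbols),
              paste(object@symbols, collapse = ", ")))
  if (length(object@aliases)) {
    al <- vapply(names(object@aliases), function(s)
      sprintf("%s=%s", s, paste(object@aliases[[s]], collapse = "/")),
      character(1))
    cat("  aliases:", paste(al, collapse = ", "), "\n")
  }
})

setMethod("show", "ScreenConfig", function(object) {
  cat(sprintf(
    "ScreenConfig: tau=%g (%s), A=%d anchors, D=%d datasets, min n=%d, %s%s\n",
    object@tau, object@mode, object@minAnchors, object@minDatasets,
    object@minSamples, object@semantics,
    if (is.na(object@pCut)) "" else sprintf(", p<=%g", object@pCut)))
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(
    "SimConfig: %d datasets (n %d-%d), %d anchors (cor %.2f), %d background, %d planted, dropout %.2f, seed %d\n",
    object@nDatasets, min(object@samplesPerDataset),
    max(object@samplesPerDataset), length(object@anchorNames),
    object@anchorCor, object@nBackgroundGenes, nrow(object@planted),
    object@dropoutProb, object@seed))
})

setMethod("show", "SimTruth", function(object) {
  cat(sprintf("SimTruth: %d datasets, %d planted genes\n",
              length(object@datasets), nrow(object@planted)))
  for (d in object@datasets[seq_len(min(3L, length(object@datasets)))])
    cat("  ", sprintf("%s: %d genes x %d samples\n", datasetId(d),
                      nrow(d), ncol(d)))
  if (length(object@datasets) > 3L) cat("   ...\n")
})

setMethod("show", "SupportMatrix", function(object) {
  cat(sprintf(
    "SupportMatrix: %d genes x %d anchors over %d datasets (%d passing records)\n",
    nrow(object@support), ncol(object@support), object@nDatasets,
    nrow(object@passes)))
  show(object@config)
})

setMethod("show", "CandidateTable", function(object) {
  cand <- candidates(object)
  cat(sprintf("CandidateTable: %d candidates of %d screened genes\n",
              nrow(cand), nrow(object@records)))
  ts <- tierSummary(object)
  if (nrow(ts))
    cat(paste(sprintf("  N=%d: %d gene(s)", ts$N, ts$genes), collapse = "\n"),
        "\n")
})

setMethod("show", "RecoveryReport", function(object) {
  cat(sprintf(
    "RecoveryReport: sensitivity %s, false calls %g (%d replicate(s), seed %d)\n",
    ifelse(is.na(object@sensitivity), "NA",
           sprintf("%.3f", object@sensitivity)),
    object@falseCalls, object@replicates, object@seed))
  if (length(object@candidateCounts))
    cat("  per-replicate candidates:",
        paste(object@candidateCounts, collapse = " "), "\n")
})
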