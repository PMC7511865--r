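# Independent oracles and small fixture builders. These deliberately use
# naive formulas / exhaustive loops, never the package's own code paths.

# Definitional Pearson correlation: sum of cross-deviations over the product
# of root sums of squared deviations.
oraclePearson <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  dx <- x - mean(x); dy <- y - mean(y)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# Brute-force support tally: explicit triple loop gene x anchor x dataset
# (subsets narrowed level by level so large random instances stay tractable).
oracleSupport <- function(rec, tau, mode = "absolute", minSamples = 6L) {
  genes <- sort(unique(rec$gene), method = "radix")
  anchors <- sort(unique(rec$anchor), method = "radix")
  datasets <- unique(rec$dataset_id)
  out <- matrix(0L, length(genes), length(anchors),
                dimnames = list(genes, anchors))
  for (g in genes) {
    recG <- rec[rec$gene == g, , drop = FALSE]
    for (a in anchors) {
      recA <- recG[recG$anchor == a & recG$n_pairs >= minSamples, ,
                   drop = FALSE]
      for (d in datasets) {
        rows <- recA[recA$dataset_id == d, , drop = FALSE]
        if (!nrow(rows)) next
        pass <- if (mode == "absolute") any(abs(rows$r) >= tau)
                else any(rows$r >= tau)
        if (pass) out[g, a] <- out[g, a] + 1L
      }
    }
  }
  out
}

# Exhaustive pair-support candidate enumeration from a support tally.
oracleCandidates <- function(sup, A, D) {
  N <- integer(nrow(sup))
  names(N) <- rownames(sup)
  for (g in rownames(sup)) {
    n <- 0L
    for (a in colnames(sup)) if (sup[g, a] >= D) n <- n + 1L
    N[g] <- n
  }
  list(N = N, candidates = names(N)[N >= A])
}

# Record table for a fully crossed (gene, anchor, dataset) design with given
# correlations (recycled).
makeRecords <- function(genes, anchors, datasets, r, n_pairs = 20L) {
  grid <- expand.grid(gene = genes, anchor = anchors,
                      dataset_id = datasets, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  grid$r <- rep_len(r, nrow(grid))
  grid$n_pairs <- rep_len(as.integer(n_pairs), nrow(grid))
  grid
}

# Random screen instance: support-style records with uniform correlations.
randomRecords <- function(nGenes, nAnchors = 7L, nDatasets = 11L) {
  makeRecords(sprintf("g%03d", seq_len(nGenes)),
              sprintf("A%d", seq_len(nAnchors)),
              sprintf("d%02d", seq_len(nDatasets)),
              r = runif(nGenes * nAnchors * nDatasets, -1, 1),
              n_pairs = sample(4:40, nGenes * nAnchors * nDatasets,
                               replace = TRUE))
}

# Tiny symbol-level dataset from a matrix (pads to >= 4 samples done by
# caller).
toyDataset <- function(values, id = "TOY", level = "symbol") {
  ExpressionDataset(values, id, level)
}

quietScreen <- function(datasets, anchors = defaultAnchors(),
                        cfg = screenConfig()) {
  suppressMessages(suppressWarnings(runScreen(datasets, anchors, cfg)))
}
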