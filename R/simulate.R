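#' Build a planted-gene manifest
#'
#' Convenience constructor for the `planted` slot of a [SimConfig-class]:
#' each planted gene is generated to have population Pearson correlation
#' `rho` with each of its target anchors.
#'
#' @param genes character vector of planted gene symbols.
#' @param anchors either a single character vector of target anchors applied
#'   to every gene, or a list of per-gene target anchor vectors.
#' @param rho per-anchor target correlation(s) in `[0, 1)`; recycled to
#'   `length(genes)`.
#' @return data.frame with columns `gene`, `anchors` (list column), `rho`.
#' @examples
#' plantedModule(c("P1", "P2"), c("SCNA", "PINK1"), 0.9)
#' @export
plantedModule <- function(genes, anchors, rho) {
  genes <- as.character(genes)
  if (!length(genes))
    return(data.frame(gene = character(0), anchors = I(list()),
                      rho = numeric(0)))
  if (is.character(anchors))
    anchors <- rep(list(anchors), length(genes))
  if (length(anchors) != length(genes))
    stop("`anchors` must be one vector or one entry per gene")
  rho <- rep_len(as.numeric(rho), length(genes))
  data.frame(gene = genes, anchors = I(anchors), rho = rho)
}

#' Default planted-recovery simulation regime
#'
#' The standing configuration used to validate the screen: 11 datasets with
#' 20-40 samples each, 2,000 background genes, and 20 planted genes each
#' correlated at `rho = 0.9` with 4 of the 7 anchors (targets drawn per gene).
#' Everything is a deterministic function of `seed`.
#'
#' @param seed master integer seed.
#' @param nPlanted number of planted genes.
#' @param rho per-anchor planted correlation.
#' @param nTargets number of target anchors per planted gene.
#' @return A [SimConfig-class].
#' @examples
#' recoverySimConfig(seed = 1)
#' @export
recoverySimConfig <- function(seed, nPlanted = 20L, rho = 0.9,
                              nTargets = 4L) {
  anchors <- anchorSymbols(defaultAnchors())
  parts <- withSeed(seed, function() {
    list(sizes = sample(20:40, 11L, replace = TRUE),
         targets = lapply(seq_len(nPlanted), function(i)
           sample(anchors, nTargets)))
  })
  simConfig(nDatasets = 11L, samplesPerDataset = parts$sizes,
            nBackgroundGenes = 2000L, anchorNames = anchors,
            planted = plantedModule(sprintf("PL%02d", seq_len(nPlanted)),
                                    parts$targets, rho),
            seed = seed)
}

# One dataset's full (pre-dropout) matrix plus its dropout mask. The RNG
# stream is seeded from (master seed, dataset index) so earlier datasets are
# invariant to extending the collection.
simulateDatasetRaw <- function(config, index) {
  n <- config@samplesPerDataset[index]
  dsId <- sprintf("SIM%03d", index)
  K <- length(config@anchorNames)
  np <- nrow(config@planted)
  nb <- config@nBackgroundGenes
  b <- config@anchorCor
  mu <- config@baselineMean
  sdv <- config@noiseSd
  withSeed(deriveSeed(config@seed, index), function() {
    f <- rnorm(n)                                   # shared anchor module
    U <- matrix(rnorm(K * n), K, n)
    A <- mu + sqrt(b) * matrix(f, K, n, byrow = TRUE) + sqrt(1 - b) * U
    rownames(A) <- config@anchorNames
    P <- matrix(numeric(0), 0, n)
    if (np) {
      P <- t(vapply(seq_len(np), function(i) {
        tgt <- config@planted$anchors[[i]]
        m <- length(tgt)
        mT <- colMeans(A[tgt, , drop = FALSE])
        zT <- (mT - mean(mT)) / stats::sd(mT)
        cc <- config@planted$rho[i] / sqrt(b + (1 - b) / m)
        mu + sdv * (cc * zT + sqrt(1 - cc^2) * rnorm(n))
      }, numeric(n)))
      rownames(P) <- config@planted$gene
    }
    B <- matrix(numeric(0), 0, n)
    if (nb) {
      B <- matrix(rnorm(nb * n, mean = mu, sd = sdv), nb, n)
      rownames(B) <- sprintf("BG%04d", seq_len(nb))
    }
    keep <- stats::runif(np + nb) >= config@dropoutProb
    vals <- rbind(A, P, B)
    colnames(vals) <- sprintf("%s_S%02d", dsId, seq_len(n))
    list(id = dsId, values = vals,
         keep = c(rep(TRUE, K), keep))             # anchors exempt
  })
}

#' Simulate a collection of expression datasets with planted structure
#'
#' Generates `config@nDatasets` independent datasets. In each, anchor
#' profiles share a latent module factor giving pairwise anchor correlation
#' `anchorCor`; every planted gene is a linear mix of the standardized mean
#' of its target anchors and fresh Gaussian noise, with the mixing
#' coefficient scaled so the population correlation with each target anchor
#' is exactly its `rho`. Background genes are i.i.d. Gaussian. Non-anchor
#' genes are independently absent from each dataset with probability
#' `dropoutProb` (if a planted gene would be dropped from every dataset it is
#' retained in the first, so ground truth stays evaluable). Identical config
#' (including seed) gives identical output.
#'
#' @param config a valid [SimConfig-class].
#' @return A [SimTruth-class] pairing the datasets with the planted manifest.
#' @examples
#' truth <- simulateCollection(simConfig(nDatasets = 2, nBackgroundGenes = 5,
#'                                       samplesPerDataset = c(10, 12),
#'                                       seed = 7))
#' simDatasets(truth)[[1]]
#' @export
simulateCollection <- function(config) {
  validObject(config)
  raw <- lapply(seq_len(config@nDatasets), simulateDatasetRaw,
                config = config)
  np <- nrow(config@planted)
  if (np) {
    K <- length(config@anchorNames)
    present <- Reduce(`|`, lapply(raw, function(r)
      r$keep[K + seq_len(np)]))
    if (any(!present)) {
      idx <- K + which(!present)
      raw[[1L]]$keep[idx] <- TRUE
    }
  }
  datasets <- lapply(raw, function(r)
    ExpressionDataset(r$values[r$keep, , drop = FALSE], r$id, "symbol"))
  new("SimTruth", datasets = datasets, planted = config@planted,
      config = config)
}

#' Write a simulated collection to disk
#'
#' One series-matrix-dialect file per dataset (values at 6 decimal places,
#' lossless through [readSeriesMatrix()] at that precision), a ground-truth
#' TSV `truth.tsv` (columns `gene`, `anchors` comma-joined, `rho`; header
#' always present), and a JSON manifest listing the dataset files.
#'
#' @param truth a [SimTruth-class].
#' @param dir output directory (created if needed).
#' @return Path of the written manifest (`manifest.json`), invisibly usable
#'   by [loadCollection()].
#' @examples
#' truth <- simulateCollection(simConfig(nDatasets = 2, nBackgroundGenes = 5,
#'                                       samplesPerDataset = c(10, 12),
#'                                       seed = 7))
#' manifest <- writeCollection(truth, tempfile("sim"))
#' @export
writeCollection <- function(truth, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- vapply(truth@datasets, function(ds) {
    f <- paste0(datasetId(ds), ".txt")
    writeSeriesMatrix(ds, file.path(dir, f))
    f
  }, character(1))
  pl <- truth@planted
  truthDf <- data.frame(
    gene = pl$gene,
    anchors = vapply(pl$anchors, paste, character(1), collapse = ","),
    rho = vapply(pl$rho, format, character(1), digits = 15)
  )
  utils::write.table(truthDf, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest <- list(
    datasets = data.frame(
      id = vapply(truth@datasets, datasetId, character(1)),
      file = files,
      n_samples = vapply(truth@datasets, ncol, integer(1)),
      n_genes = vapply(truth@datasets, nrow, integer(1))
    ),
    anchors = truth@config@anchorNames,
    truth = "truth.tsv",
    seed = truth@config@seed
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  path
}

#' Read back a ground-truth TSV
#'
#' @param path path to a `truth.tsv` written by [writeCollection()].
#' @return data.frame (`gene`, `anchors` list column, `rho`).
#' @export
readTruth <- function(path) {
  df <- utils::read.delim(path, colClasses = c("character", "character",
                                               "numeric"))
  plantedModule(df$gene, strsplit(df$anchors, ",", fixed = TRUE), df$rho)
}
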