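#' Pearson correlation of two expression profiles
#'
#' Pairwise-complete Pearson correlation, `r = cov(x, y) / (sd(x) sd(y))`,
#' clamped to `[-1, 1]` against floating-point rounding. Either profile
#' being constant over the complete pairs leaves the correlation undefined
#' and is an error here; the screen skips such pairs upstream with a log
#' entry.
#'
#' @param x,y numeric vectors of equal length; `NA`s are removed pairwise.
#' @param minPairs minimum complete pairs required (default 3).
#' @return single numeric in `[-1, 1]`.
#' @examples
#' pearsonCor(c(1, 2, 3), c(2, 4, 6))      #  1
#' pearsonCor(c(1, 2, 3), c(3, 2, 1))      # -1
#' pearsonCor(c(1, 2, 3, 4), c(1, 3, 2, 4))  # 0.8
#' @export
pearsonCor <- function(x, y, minPairs = 3L) {
  if (length(x) != length(y))
    stop(sprintf("length mismatch: %d vs %d", length(x), length(y)))
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < minPairs)
    stop(sprintf("fewer than %d complete pairs (%d)", minPairs, sum(ok)))
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a constant profile")
  r <- stats::cor(x, y)
  max(-1, min(1, r))
}

# Correlation records for one symbol-level dataset: one row per
# (gene, anchor) with enough complete pairs and a defined correlation.
datasetRecords <- function(ds, anchors, minSamples, includeAnchorPairs) {
  anchorRows <- matchAnchorRows(ds, anchors)
  empty <- data.frame(gene = character(0), anchor = character(0),
                      dataset_id = character(0), r = numeric(0),
                      n_pairs = integer(0))
  if (!length(anchorRows)) {
    warning(sprintf("dataset %s contains none of the anchors; it contributes no records",
                    datasetId(ds)))
    return(empty)
  }
  absent <- setdiff(anchorSymbols(anchors), names(anchorRows))
  if (length(absent))
    message(sprintf("%s: anchor(s) absent: %s", datasetId(ds),
                    paste(absent, collapse = ", ")))
  vals <- exprs(ds)
  geneRows <- setdiff(rownames(vals), unname(anchorRows))
  if (includeAnchorPairs)
    geneRows <- rownames(vals)
  if (!length(geneRows))
    return(empty)
  X <- t(vals[geneRows, , drop = FALSE])
  Y <- t(vals[unname(anchorRows), , drop = FALSE])
  R <- suppressWarnings(stats::cor(X, Y, use = "pairwise.complete.obs"))
  NP <- crossprod((!is.na(X)) * 1, (!is.na(Y)) * 1)
  keep <- !is.na(R) & NP >= minSamples
  nSkipped <- sum(is.na(R) & NP >= minSamples)
  if (nSkipped)
    message(sprintf("%s: %d pair(s) skipped (constant profile, correlation undefined)",
                    datasetId(ds), nSkipped))
  idx <- which(keep, arr.ind = TRUE)
  if (!nrow(idx))
    return(empty)
  out <- data.frame(
    gene = geneRows[idx[, 1L]],
    anchor = names(anchorRows)[idx[, 2L]],
    dataset_id = datasetId(ds),
    r = pmax(-1, pmin(1, R[keep])),
    n_pairs = as.integer(NP[keep])
  )
  out <- out[out$gene != out$anchor, , drop = FALSE]
  out[radixOrder(out$gene, out$anchor), , drop = FALSE]
}

#' Gene-versus-anchor correlations within each dataset
#'
#' Computes one correlation record per (gene, anchor, dataset) where both
#' profiles are present with at least `minSamples` pairwise-complete
#' observations and neither is constant. Anchors are matched by canonical
#' symbol or alias and reported under the canonical symbol; anchors absent
#' from a dataset simply yield no records (logged). A dataset containing no
#' anchors contributes nothing (warning, not fatal).
#'
#' @param x a symbol-level [ExpressionDataset-class], or a list of them (e.g.
#'   [simDatasets()] output).
#' @param anchors an [AnchorSet-class].
#' @param minSamples minimum complete sample pairs per record (default 6:
#'   below that a high-correlation cut is nearly uninformative).
#' @param includeAnchorPairs also compute anchor-versus-anchor records
#'   (default `FALSE`; gene == anchor rows are always excluded).
#' @return data.frame with columns `gene`, `anchor`, `dataset_id`, `r`,
#'   `n_pairs`.
#' @examples
#' truth <- simulateCollection(
#'   simConfig(nDatasets = 2, nBackgroundGenes = 5,
#'             samplesPerDataset = c(12, 15), seed = 3))
#' head(anchorCorrelations(simDatasets(truth), defaultAnchors()))
#' @export
anchorCorrelations <- function(x, anchors, minSamples = 6L,
                               includeAnchorPairs = FALSE) {
  if (is(x, "ExpressionDataset"))
    x <- list(x)
  if (!length(x))
    stop("no datasets supplied")
  bad <- vapply(x, function(d) idLevel(d) != "symbol", logical(1))
  if (any(bad))
    stop("all datasets must be at symbol level (collapse probes first): ",
         paste(vapply(x[bad], datasetId, character(1)), collapse = ", "))
  out <- do.call(rbind, lapply(x, datasetRecords, anchors = anchors,
                               minSamples = as.integer(minSamples),
                               includeAnchorPairs = includeAnchorPairs))
  rownames(out) <- NULL
  out
}

#' Cross-dataset support counts
#'
#' Converts correlation records into the per-(gene, anchor) tally the
#' frequent co-expression rule consumes: a pair gains one unit of support per
#' dataset in which its correlation passes the configured threshold
#' (`|r| >= tau` in absolute mode, `r >= tau` in positive mode; or the
#' optional significance rule when `pCut` is set), at most one unit per
#' dataset per pair. Records with fewer than `minSamples` complete pairs
#' never contribute.
#'
#' @param rec record data.frame from [anchorCorrelations()].
#' @param cfg a [ScreenConfig-class].
#' @param nDatasetsTotal total datasets screened; defaults to the number of
#'   distinct `dataset_id`s in `rec`.
#' @param anchors optional character vector fixing the anchor columns (by
#'   default the anchors observed in `rec`).
#' @return A [SupportMatrix-class].
#' @examples
#' rec <- data.frame(gene = "G1", anchor = "A1",
#'                   dataset_id = c("d1", "d2", "d3"),
#'                   r = c(0.85, 0.75, -0.9), n_pairs = 20L)
#' support(supportCounts(rec, screenConfig(tau = 0.8)))
#' @export
supportCounts <- function(rec, cfg = screenConfig(), nDatasetsTotal = NULL,
                          anchors = NULL) {
  validObject(cfg)
  if (is.null(nDatasetsTotal))
    nDatasetsTotal <- length(unique(rec$dataset_id))
  if (is.null(anchors))
    anchors <- sort(unique(rec$anchor), method = "radix")
  rec <- rec[rec$n_pairs >= cfg@minSamples, , drop = FALSE]
  if (!is.na(cfg@pCut)) {
    tstat <- rec$r * sqrt(rec$n_pairs - 2L) / sqrt(pmax(1 - rec$r^2, 1e-300))
    p <- 2 * stats::pt(abs(tstat), df = rec$n_pairs - 2L, lower.tail = FALSE)
    pass <- p <= cfg@pCut & (cfg@mode == "absolute" | rec$r >= 0)
  } else {
    pass <- if (cfg@mode == "absolute") abs(rec$r) >= cfg@tau
            else rec$r >= cfg@tau
  }
  genes <- sort(unique(rec$gene), method = "radix")
  hits <- rec[pass, c("gene", "anchor", "dataset_id", "r"), drop = FALSE]
  hits <- hits[!duplicated(hits[c("gene", "anchor", "dataset_id")]), ,
               drop = FALSE]
  hits <- hits[radixOrder(hits$gene, hits$anchor, hits$dataset_id), ,
               drop = FALSE]
  rownames(hits) <- NULL
  sup <- matrix(0L, length(genes), length(anchors),
                dimnames = list(genes, anchors))
  if (nrow(hits)) {
    tab <- table(factor(hits$gene, genes), factor(hits$anchor, anchors))
    sup[] <- as.integer(tab)
  }
  gd <- rec[!duplicated(rec[c("gene", "dataset_id")]), "gene"]
  geneDatasets <- stats::setNames(
    as.integer(table(factor(gd, genes))), genes)
  new("SupportMatrix", support = sup,
      nDatasets = as.integer(nDatasetsTotal), geneDatasets = geneDatasets,
      passes = hits, config = cfg)
}
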