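#' @import methods
#' @import SummarizedExperiment
NULL

#' Expression dataset container
#'
#' One study's expression matrix (rows = probes or gene symbols, columns =
#' samples, values = log-scale intensities, `NA` allowed) together with its
#' accession-like identifier and the identifier level of its rows. Extends
#' [SummarizedExperiment::SummarizedExperiment] with a single `"exprs"` assay.
#'
#' @slot datasetId single accession-like string, e.g. `"GSE20292"`.
#' @slot idLevel `"probe"` or `"symbol"`. Row names must be unique at symbol
#'   level; probe-level files occasionally carry duplicated probe ids, which
#'   are tolerated until collapsing.
#'
#' @export
setClass("ExpressionDataset",
  contains = "SummarizedExperiment",
  slots = c(datasetId = "character", idLevel = "character")
)

setValidity("ExpressionDataset", function(object) {
  msg <- character()
  if (length(object@datasetId) != 1L || is.na(object@datasetId) ||
      !nzchar(object@datasetId))
    msg <- c(msg, "datasetId must be a single non-empty string")
  if (length(object@idLevel) != 1L ||
      !object@idLevel %in% c("probe", "symbol"))
    msg <- c(msg, "idLevel must be 'probe' or 'symbol'")
  if (!"exprs" %in% assayNames(object))
    msg <- c(msg, "an assay named 'exprs' is required")
  if (ncol(object) < 4L)
    msg <- c(msg, sprintf("at least 4 samples required (got %d)", ncol(object)))
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids must be present and unique")
  if (is.null(rownames(object)))
    msg <- c(msg, "row ids must be present")
  if (identical(object@idLevel, "symbol") && anyDuplicated(rownames(object)))
    msg <- c(msg, "row ids must be unique at symbol level")
  if (length(msg)) msg else TRUE
})

#' Construct an ExpressionDataset
#'
#' @param values numeric matrix (rows identifiers, columns samples) with
#'   dimnames set; `NA` marks missing measurements.
#' @param datasetId accession-like string identifying the study.
#' @param idLevel whether rows are array probes or gene symbols.
#'
#' @return An [ExpressionDataset-class] object.
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(c("G1", "G2", "G3"), paste0("S", 1:4)))
#' ExpressionDataset(m, "TOY1", "symbol")
#' @export
ExpressionDataset <- function(values, datasetId,
                              idLevel = c("symbol", "probe")) {
  idLevel <- match.arg(idLevel)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  se <- SummarizedExperiment(assays = list(exprs = values))
  new("ExpressionDataset", se, datasetId = as.character(datasetId),
      idLevel = idLevel)
}

#' Anchor gene set
#'
#' The ordered reference genes against which all other genes are screened,
#' with accepted alternate symbols. See [defaultAnchors()] for the shipped
#' Parkinson's disease set.
#'
#' @slot symbols unique ordered gene symbols.
#' @slot aliases named list: canonical symbol -> character vector of accepted
#'   alternates (possibly empty).
#' @export
setClass("AnchorSet",
  slots = c(symbols = "character", aliases = "list")
)

setValidity("AnchorSet", function(object) {
  msg <- character()
  if (length(object@symbols) < 1L || anyDuplicated(object@symbols))
    msg <- c(msg, "anchor symbols must be non-empty and unique")
  if (length(object@aliases) &&
      !all(names(object@aliases) %in% object@symbols))
    msg <- c(msg, "alias names must be anchor symbols")
  if (length(msg)) msg else TRUE
})

#' Construct an AnchorSet
#'
#' @param symbols ordered unique gene symbols.
#' @param aliases named list mapping a symbol to accepted alternate symbols.
#' @return An [AnchorSet-class].
#' @examples
#' anchorSet(c("SNCA", "LRRK2"), aliases = list(SNCA = "SCNA"))
#' @export
anchorSet <- function(symbols, aliases = list()) {
  new("AnchorSet", symbols = as.character(symbols), aliases = aliases)
}

#' Screen configuration
#'
#' All tunable parameters of the frequent co-expression rule. The correlation
#' threshold `tau` and its `mode` are deliberately mandatory, echoed into
#' every output so each run is self-describing.
#'
#' @slot tau correlation threshold in (0, 1].
#' @slot mode `"absolute"` (pass when `|r| >= tau`) or `"positive"`
#'   (pass when `r >= tau`).
#' @slot minAnchors minimum number of supported anchors A for candidacy.
#' @slot minDatasets minimum number of supporting datasets D.
#' @slot minSamples minimum complete sample pairs for a correlation to count.
#' @slot semantics `"pair_support"` (per-pair dataset support, N = number of
#'   anchors with support >= D) or `"per_dataset_joint"` (candidate iff >= A
#'   anchors pass simultaneously within each of >= D datasets).
#' @slot pCut optional two-sided p-value cut replacing the raw `tau` rule
#'   (`NA` = off); `r` is converted to `t = r * sqrt(n - 2) / sqrt(1 - r^2)`.
#' @export
setClass("ScreenConfig",
  slots = c(tau = "numeric", mode = "character", minAnchors = "integer",
            minDatasets = "integer", minSamples = "integer",
            semantics = "character", pCut = "numeric")
)

setValidity("ScreenConfig", function(object) {
  msg <- character()
  if (length(object@tau) != 1L || is.na(object@tau) ||
      object@tau <= 0 || object@tau > 1)
    msg <- c(msg, "tau must be a single value in (0, 1]")
  if (!object@mode %in% c("absolute", "positive"))
    msg <- c(msg, "mode must be 'absolute' or 'positive'")
  if (!object@semantics %in% c("pair_support", "per_dataset_joint"))
    msg <- c(msg, "semantics must be 'pair_support' or 'per_dataset_joint'")
  if (object@minAnchors < 1L)
    msg <- c(msg, "minAnchors must be >= 1")
  if (object@minDatasets < 1L)
    msg <- c(msg, "minDatasets must be >= 1")
  if (object@minSamples < 3L)
    msg <- c(msg, "minSamples must be >= 3 (correlation undefined below)")
  if (length(object@pCut) != 1L ||
      (!is.na(object@pCut) && (object@pCut <= 0 || object@pCut >= 1)))
    msg <- c(msg, "pCut must be NA or in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' Construct a ScreenConfig
#'
#' Defaults: `tau = 0.8` in absolute mode (a conventional "high correlation"
#' cut), candidacy at `A = 3` anchors supported in `D = 5` datasets,
#' correlations based on at least 6 complete sample pairs, pair-support rule
#' semantics.
#'
#' @param tau correlation threshold in (0, 1].
#' @param mode `"absolute"` or `"positive"`.
#' @param minAnchors,minDatasets candidacy thresholds A and D.
#' @param minSamples minimum complete pairs per correlation.
#' @param semantics `"pair_support"` or `"per_dataset_joint"`.
#' @param pCut optional two-sided p cut (`NA` disables significance mode).
#' @return A [ScreenConfig-class].
#' @examples
#' screenConfig()
#' screenConfig(tau = 0.9, mode = "positive")
#' @export
screenConfig <- function(tau = 0.8, mode = c("absolute", "positive"),
                         minAnchors = 3L, minDatasets = 5L, minSamples = 6L,
                         semantics = c("pair_support", "per_dataset_joint"),
                         pCut = NA_real_) {
  mode <- match.arg(mode)
  semantics <- match.arg(semantics)
  new("ScreenConfig", tau = as.numeric(tau), mode = mode,
      minAnchors = as.integer(minAnchors),
      minDatasets = as.integer(minDatasets),
      minSamples = as.integer(minSamples),
      semantics = semantics, pCut = as.numeric(pCut))
}

#' Simulation configuration
#'
#' Parameters of the synthetic multi-dataset generator. Defaults mirror the
#' regime the screen targets: 11 heterogeneous datasets, 7 anchors, 2,000
#' background genes, per-dataset sample sizes in 10..50.
#'
#' @slot nDatasets number of datasets in the collection.
#' @slot samplesPerDataset integer vector of per-dataset sample counts
#'   (length `nDatasets`, each >= 4).
#' @slot nBackgroundGenes number of uncorrelated background genes.
#' @slot anchorNames anchor gene symbols (present in every dataset).
#' @slot planted data.frame with columns `gene` (symbol), `anchors` (list
#'   column of target anchor subsets) and `rho` (target per-anchor
#'   correlation in `[0, 1)`).
#' @slot dropoutProb probability a non-anchor gene is absent from a given
#'   dataset (platform coverage differences); anchors are exempt.
#' @slot noiseSd standard deviation of non-anchor profiles (log2 units).
#' @slot baselineMean location of all profiles (log2 units).
#' @slot anchorCor pairwise correlation among anchor profiles (shared latent
#'   module factor); see the package vignette for why anchors are mutually
#'   co-expressed by construction.
#' @slot seed master seed; per-dataset streams are derived from it by index,
#'   so extending the collection leaves earlier datasets untouched.
#' @export
setClass("SimConfig",
  slots = c(nDatasets = "integer", samplesPerDataset = "integer",
            nBackgroundGenes = "integer", anchorNames = "character",
            planted = "data.frame", dropoutProb = "numeric",
            noiseSd = "numeric", baselineMean = "numeric",
            anchorCor = "numeric", seed = "integer")
)

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@nDatasets < 1L)
    msg <- c(msg, "nDatasets must be >= 1")
  if (length(object@samplesPerDataset) != object@nDatasets)
    msg <- c(msg, sprintf(
      "samplesPerDataset has length %d but nDatasets is %d",
      length(object@samplesPerDataset), object@nDatasets))
  if (any(object@samplesPerDataset < 4L))
    msg <- c(msg, "every samplesPerDataset entry must be >= 4")
  if (length(object@anchorNames) < 1L || anyDuplicated(object@anchorNames))
    msg <- c(msg, "anchorNames must be non-empty and unique")
  pl <- object@planted
  if (!all(c("gene", "anchors", "rho") %in% names(pl))) {
    msg <- c(msg, "planted needs columns gene, anchors, rho")
  } else if (nrow(pl)) {
    if (anyDuplicated(pl$gene))
      msg <- c(msg, "planted gene symbols must be unique")
    if (any(pl$rho < 0 | pl$rho >= 1))
      msg <- c(msg, "planted rho must lie in [0, 1)")
    bad <- !vapply(pl$anchors, function(a)
      length(a) >= 1L && all(a %in% object@anchorNames), logical(1))
    if (any(bad))
      msg <- c(msg, sprintf(
        "planted target anchors must be a non-empty subset of anchorNames (offending gene(s): %s)",
        paste(pl$gene[bad], collapse = ", ")))
    if (any(pl$gene %in% object@anchorNames))
      msg <- c(msg, "planted symbols must be disjoint from anchorNames")
    # attainability: corr with each of m target anchors is capped by the
    # anchor-anchor correlation structure
    if (!length(msg)) {
      m <- lengths(pl$anchors)
      cap <- sqrt(object@anchorCor + (1 - object@anchorCor) / m)
      over <- pl$rho > cap + 1e-12
      if (any(over))
        msg <- c(msg, sprintf(
          "rho exceeds the attainable per-anchor correlation sqrt(anchorCor + (1 - anchorCor)/m) for gene(s): %s",
          paste(pl$gene[over], collapse = ", ")))
    }
  }
  if (object@dropoutProb < 0 || object@dropoutProb >= 1)
    msg <- c(msg, "dropoutProb must lie in [0, 1)")
  if (object@noiseSd <= 0)
    msg <- c(msg, "noiseSd must be positive")
  if (object@anchorCor < 0 || object@anchorCor >= 1)
    msg <- c(msg, "anchorCor must lie in [0, 1)")
  if (is.na(object@seed))
    msg <- c(msg, "seed must be a finite integer")
  if (length(msg)) msg else TRUE
})

#' Construct a SimConfig
#'
#' @param nDatasets number of datasets (default 11).
#' @param samplesPerDataset per-dataset sample counts; if `NULL`, drawn
#'   reproducibly from 10..50 using `seed`.
#' @param nBackgroundGenes background (null) gene count (default 2000, a
#'   desk-scale stand-in for a genome-wide array).
#' @param anchorNames anchor symbols (default: the shipped 7-gene set).
#' @param planted data.frame of planted genes (`gene`, `anchors` list column,
#'   `rho`); see [plantedModule()]. Default: none.
#' @param dropoutProb per-(gene, dataset) absence probability (default 0.1).
#' @param noiseSd profile standard deviation in log2 units (default 1).
#' @param baselineMean profile location in log2 units (default 8).
#' @param anchorCor pairwise anchor-anchor correlation (default 0.9, which
#'   keeps per-anchor planted correlations up to 0.95 attainable for target
#'   sets as large as the full anchor panel).
#' @param seed master integer seed.
#' @return A [SimConfig-class].
#' @examples
#' cfg <- simConfig(nDatasets = 2, nBackgroundGenes = 10, seed = 1)
#' @export
simConfig <- function(nDatasets = 11L, samplesPerDataset = NULL,
                      nBackgroundGenes = 2000L,
                      anchorNames = defaultAnchors()@symbols,
                      planted = plantedModule(character(0), list(), numeric(0)),
                      dropoutProb = 0.1, noiseSd = 1, baselineMean = 8,
                      anchorCor = 0.9, seed = 1L) {
  nDatasets <- as.integer(nDatasets)
  seed <- as.integer(seed)
  if (is.null(samplesPerDataset)) {
    samplesPerDataset <- withSeed(seed, function()
      sample(10:50, nDatasets, replace = TRUE))
  }
  new("SimConfig", nDatasets = nDatasets,
      samplesPerDataset = as.integer(samplesPerDataset),
      nBackgroundGenes = as.integer(nBackgroundGenes),
      anchorNames = as.character(anchorNames), planted = planted,
      dropoutProb = as.numeric(dropoutProb), noiseSd = as.numeric(noiseSd),
      baselineMean = as.numeric(baselineMean),
      anchorCor = as.numeric(anchorCor), seed = seed)
}

#' Simulated collection with ground truth
#'
#' @slot datasets list of [ExpressionDataset-class] objects.
#' @slot planted the planted-gene manifest (`gene`, `anchors`, `rho`).
#' @slot config the [SimConfig-class] that produced the collection.
#' @export
setClass("SimTruth",
  slots = c(datasets = "list", planted = "data.frame", config = "SimConfig")
)

setValidity("SimTruth", function(object) {
  msg <- character()
  if (!all(vapply(object@datasets, is, logical(1), "ExpressionDataset")))
    msg <- c(msg, "datasets must all be ExpressionDataset objects")
  else {
    rows <- lapply(object@datasets, rownames)
    anchors <- object@config@anchorNames
    if (!all(vapply(rows, function(r) all(anchors %in% r), logical(1))))
      msg <- c(msg, "every anchor must appear in every dataset")
    if (nrow(object@planted)) {
      seen <- unique(unlist(rows))
      missing <- setdiff(object@planted$gene, seen)
      if (length(missing))
        msg <- c(msg, sprintf("planted gene(s) absent from all datasets: %s",
                              paste(missing, collapse = ", ")))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Cross-dataset support tally
#'
#' For every screened (gene, anchor) pair, the number of datasets in which
#' the pair's correlation passed the configured threshold, together with the
#' underlying pass table (needed for the per-dataset joint rule semantics)
#' and the number of datasets in which each gene was measurable at all.
#'
#' @slot support integer gene x anchor matrix of dataset counts.
#' @slot nDatasets total datasets screened.
#' @slot geneDatasets named integer: datasets in which each gene had at least
#'   one usable correlation record.
#' @slot passes data.frame (`gene`, `anchor`, `dataset_id`, `r`) of passing
#'   records, at most one row per (gene, anchor, dataset).
#' @slot config the [ScreenConfig-class] under which the tally was built.
#' @export
setClass("SupportMatrix",
  slots = c(support = "matrix", nDatasets = "integer",
            geneDatasets = "integer", passes = "data.frame",
            config = "ScreenConfig")
)

setValidity("SupportMatrix", function(object) {
  msg <- character()
  s <- object@support
  if (!is.integer(s) || is.null(rownames(s)) || is.null(colnames(s)))
    msg <- c(msg, "support must be an integer matrix with dimnames")
  else {
    if (any(s < 0L) || any(s > object@nDatasets))
      msg <- c(msg, "support counts must lie in [0, nDatasets]")
    if (anyDuplicated(rownames(s)) || anyDuplicated(colnames(s)))
      msg <- c(msg, "support dimnames must be unique")
  }
  if (length(msg)) msg else TRUE
})

#' Ranked candidate table
#'
#' Output of the frequent co-expression rule: one row per screened gene with
#' its anchor count N, candidacy flag, a testability flag (genes measured in
#' fewer than D datasets can never qualify, and that is platform coverage,
#' not biology), and its supporting anchors formatted
#' `"anchor:datasets_passed"` (semicolon-joined). Rows are sorted by N
#' descending then gene symbol ascending (C-locale), so reports are
#' byte-reproducible.
#'
#' @slot records data.frame with columns `gene`, `N`, `candidate`,
#'   `testable`, `anchors`.
#' @slot config the [ScreenConfig-class] applied.
#' @slot provenance list (dataset ids, config echo/hash, package version).
#' @export
setClass("CandidateTable",
  slots = c(records = "data.frame", config = "ScreenConfig",
            provenance = "list")
)

setValidity("CandidateTable", function(object) {
  msg <- character()
  rec <- object@records
  need <- c("gene", "N", "candidate", "testable", "anchors")
  if (!all(need %in% names(rec)))
    msg <- c(msg, paste("records needs columns:", paste(need, collapse = ", ")))
  else if (nrow(rec)) {
    if (anyDuplicated(rec$gene))
      msg <- c(msg, "genes must be unique")
    ord <- order(-rec$N, rec$gene, method = "radix")
    if (!identical(ord, seq_len(nrow(rec))))
      msg <- c(msg, "records must be sorted by (N desc, gene asc)")
    if (any(rec$N < 0L))
      msg <- c(msg, "N must be non-negative")
  }
  if (length(msg)) msg else TRUE
})

#' Recovery / calibration report
#'
#' @slot sensitivity fraction of planted genes called candidate (`NA` when
#'   the truth contains no planted genes, e.g. null calibration).
#' @slot falseCalls number of candidate calls outside the planted set
#'   (summed over replicates for calibration runs).
#' @slot perGene data.frame (`gene`, `called`, `N`, `rho`) for every planted
#'   gene.
#' @slot replicates number of simulated collections contributing.
#' @slot seed master seed of the underlying simulation(s).
#' @slot candidateCounts per-replicate candidate counts (calibration runs;
#'   length 0 otherwise).
#' @export
setClass("RecoveryReport",
  slots = c(sensitivity = "numeric", falseCalls = "numeric",
            perGene = "data.frame", replicates = "integer", seed = "integer",
            candidateCounts = "integer")
)

setValidity("RecoveryReport", function(object) {
  msg <- character()
  s <- object@sensitivity
  if (length(s) != 1L || (!is.na(s) && (s < 0 || s > 1)))
    msg <- c(msg, "sensitivity must be a single value in [0, 1] or NA")
  if (object@falseCalls < 0)
    msg <- c(msg, "falseCalls must be non-negative")
  if (object@replicates < 0L)
    msg <- c(msg, "replicates must be non-negative")
  if (length(msg)) msg else TRUE
})
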