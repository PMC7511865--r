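# Readable one-line echo of a ScreenConfig; its md5 doubles as config hash
# in provenance headers.
configEcho <- function(cfg) {
  sprintf("tau=%g mode=%s min_anchors=%d min_datasets=%d min_samples=%d semantics=%s p_cut=%s",
          cfg@tau, cfg@mode, cfg@minAnchors, cfg@minDatasets,
          cfg@minSamples, cfg@semantics,
          if (is.na(cfg@pCut)) "off" else format(cfg@pCut))
}

formatAnchorSupport <- function(anchors, counts) {
  if (!length(anchors)) return("")
  ord <- radixOrder(-counts, anchors)
  paste(sprintf("%s:%d", anchors[ord], counts[ord]), collapse = ";")
}

#' Apply the frequent co-expression rule
#'
#' Under the default `pair_support` semantics, a gene's anchor count is
#' `N(g) = #\{anchors k : support(g, k) >= D\}` and `g` is a candidate iff
#' `N(g) >= A`. Under the alternate `per_dataset_joint` semantics, `g` is a
#' candidate iff in at least `D` datasets it passes the correlation threshold
#' with at least `A` anchors simultaneously, and `N(g)` is the maximum
#' per-dataset anchor tally over those supporting datasets. Anchor genes
#' themselves are excluded. Every screened gene is reported (with a
#' `candidate` flag), along with a `testable` flag marking genes measured in
#' at least `D` datasets: an untestable gene can never qualify, and that is
#' platform coverage, not biology.
#'
#' @param sup a [SupportMatrix-class] built under the same rule parameters.
#' @param cfg the [ScreenConfig-class] to apply; defaults to the config the
#'   support tally was built with.
#' @param provenance optional list recorded in the table (e.g. dataset ids).
#' @return A [CandidateTable-class], rows sorted by (N desc, gene asc).
#' @examples
#' rec <- expand.grid(gene = "G1", anchor = c("A1", "A2", "A3", "A4"),
#'                    dataset_id = paste0("d", 1:6),
#'                    stringsAsFactors = FALSE)
#' rec$r <- ifelse(rec$anchor == "A4" & rec$dataset_id > "d2", 0, 0.9)
#' rec$n_pairs <- 20L
#' tbl <- candidateCall(supportCounts(rec, screenConfig()))
#' records(tbl)   # A1:6, A2:6, A3:6 pass D=5; A4 only 2 -> N = 3
#' @export
candidateCall <- function(sup, cfg = screenParams(sup),
                          provenance = list()) {
  validObject(cfg)
  if (!identical(cfg@tau, sup@config@tau) ||
      !identical(cfg@mode, sup@config@mode) ||
      !identical(cfg@minSamples, sup@config@minSamples) ||
      !identical(cfg@pCut, sup@config@pCut))
    stop("support tally was built under different pass-rule parameters ",
         "(tau/mode/minSamples/pCut); rebuild supportCounts() with `cfg`")
  s <- support(sup)
  anchorsCols <- colnames(s)
  keep <- !(rownames(s) %in% anchorsCols)
  s <- s[keep, , drop = FALSE]
  genes <- rownames(s)
  D <- cfg@minDatasets
  A <- cfg@minAnchors
  if (cfg@semantics == "pair_support") {
    N <- as.integer(rowSums(s >= D))
    cand <- N >= A
  } else {
    p <- passes(sup)
    p <- p[p$gene %in% genes, , drop = FALSE]
    key <- paste(p$gene, p$dataset_id, sep = "\r")
    tally <- vapply(split(p$anchor, key), function(a)
      length(unique(a)), integer(1))
    gOf <- sub("\r.*$", "", names(tally))
    N <- integer(length(genes))
    cand <- logical(length(genes))
    for (i in seq_along(genes)) {
      tg <- tally[gOf == genes[i]]
      qual <- tg[tg >= A]
      cand[i] <- length(qual) >= D
      N[i] <- if (cand[i]) max(qual) else if (length(tg)) max(tg) else 0L
    }
    N <- as.integer(N)
  }
  anchorsTxt <- vapply(seq_along(genes), function(i) {
    nz <- which(s[i, ] > 0L)
    formatAnchorSupport(anchorsCols[nz], s[i, nz])
  }, character(1))
  recs <- data.frame(gene = genes, N = N, candidate = cand,
                     testable = unname(geneDatasets(sup)[genes] >= D),
                     anchors = anchorsTxt)
  recs <- recs[radixOrder(-recs$N, recs$gene), , drop = FALSE]
  rownames(recs) <- NULL
  prov <- c(provenance,
            list(config = configEcho(cfg),
                 config_md5 = md5string(configEcho(cfg)),
                 n_datasets = nDatasets(sup),
                 package_version = as.character(
                   utils::packageVersion("anchorCoex"))))
  new("CandidateTable", records = recs, config = cfg, provenance = prov)
}

#' Write a candidate table as TSV
#'
#' Provenance lines (config echo and hash, dataset count, package version)
#' are written as `#`-prefixed header comments; candidate rows follow with
#' columns `gene`, `N`, `anchors` (`anchor:datasets_passed`,
#' semicolon-joined); a tier summary block closes the file, one
#' `#`-prefixed line per N value with its gene count. Output is
#' byte-deterministic for a fixed table (no timestamps).
#'
#' @param tbl a [CandidateTable-class].
#' @param path output path.
#' @param what `"candidates"` (default, mirroring the published table shape)
#'   or `"all"` screened genes.
#' @return `path`, invisibly.
#' @export
writeCandidateTable <- function(tbl, path, what = c("candidates", "all")) {
  what <- match.arg(what)
  rows <- if (what == "candidates") candidates(tbl) else records(tbl)
  con <- file(path, open = "wt")
  on.exit(close(con))
  prov <- tbl@provenance
  for (nm in names(prov))
    writeLines(sprintf("# %s: %s", nm,
                       paste(format(prov[[nm]]), collapse = ",")), con)
  writeLines("gene\tN\tanchors", con)
  if (nrow(rows))
    writeLines(sprintf("%s\t%d\t%s", rows$gene, rows$N, rows$anchors), con)
  ts <- tierSummary(tbl)
  writeLines("# tier summary", con)
  if (nrow(ts))
    writeLines(sprintf("# N=%d\t%d", ts$N, ts$genes), con)
  invisible(path)
}

#' Read back a written candidate table
#'
#' Inverse of [writeCandidateTable()] for the candidate rows (provenance
#' comments are kept as attributes of the provenance list; the tier summary
#' is recomputed, not parsed).
#'
#' @param path TSV written by [writeCandidateTable()].
#' @param cfg the [ScreenConfig-class] to attach (defaults to
#'   [screenConfig()]).
#' @return A [CandidateTable-class] whose records are the file's rows.
#' @export
readCandidateTable <- function(path, cfg = screenConfig()) {
  lines <- readLines(path, warn = FALSE)
  comments <- grepl("^#", lines)
  body <- lines[!comments]
  header <- strsplit(body[[1L]], "\t", fixed = TRUE)[[1L]]
  if (!identical(header, c("gene", "N", "anchors")))
    stop("unrecognised candidate table header in ", path)
  rows <- body[-1L]
  if (length(rows)) {
    cells <- strsplit(rows, "\t", fixed = TRUE)
    recs <- data.frame(
      gene = vapply(cells, `[`, character(1), 1L),
      N = as.integer(vapply(cells, `[`, character(1), 2L)),
      candidate = TRUE,
      testable = TRUE,
      anchors = vapply(cells, function(x)
        if (length(x) >= 3L) x[[3L]] else "", character(1))
    )
  } else {
    recs <- data.frame(gene = character(0), N = integer(0),
                       candidate = logical(0), testable = logical(0),
                       anchors = character(0))
  }
  new("CandidateTable", records = recs, config = cfg,
      provenance = list(source = path))
}

#' Run the full screen over a dataset collection
#'
#' Convenience pipeline: [anchorCorrelations()] on every dataset,
#' [supportCounts()], then [candidateCall()], with dataset ids recorded in
#' the table's provenance.
#'
#' @param datasets list of symbol-level [ExpressionDataset-class] objects.
#' @param anchors an [AnchorSet-class] (default [defaultAnchors()]).
#' @param cfg a [ScreenConfig-class] (default [screenConfig()]).
#' @return A [CandidateTable-class].
#' @examples
#' truth <- simulateCollection(recoverySimConfig(seed = 1, nPlanted = 2))
#' \donttest{
#' tbl <- runScreen(simDatasets(truth))
#' candidates(tbl)
#' }
#' @export
runScreen <- function(datasets, anchors = defaultAnchors(),
                      cfg = screenConfig()) {
  rec <- anchorCorrelations(datasets, anchors, minSamples = cfg@minSamples)
  sup <- supportCounts(rec, cfg, nDatasetsTotal = length(datasets),
                       anchors = anchorSymbols(anchors))
  ids <- vapply(datasets, datasetId, character(1))
  candidateCall(sup, cfg, provenance = list(datasets = ids))
}
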