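#' Write a dataset in the GEO series-matrix dialect
#'
#' Tab-delimited, `!`-prefixed metadata lines, quoted identifiers, with the
#' value block between the `!series_matrix_table_begin` and
#' `!series_matrix_table_end` sentinels. Values are written at 6 decimal
#' places; missing values as empty cells.
#'
#' @param ds an [ExpressionDataset-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeSeriesMatrix <- function(ds, path) {
  vals <- exprs(ds)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    sprintf("!Series_geo_accession\t\"%s\"", datasetId(ds)),
    sprintf("!Series_id_level\t\"%s\"", idLevel(ds)),
    "!series_matrix_table_begin",
    paste(c("\"ID_REF\"", sprintf("\"%s\"", colnames(vals))),
          collapse = "\t")
  ), con)
  body <- formatC(vals, format = "f", digits = 6)
  body[is.na(vals)] <- ""
  writeLines(paste(sprintf("\"%s\"", rownames(vals)),
                   apply(body, 1L, paste, collapse = "\t"), sep = "\t"), con)
  writeLines("!series_matrix_table_end", con)
  invisible(path)
}

stripQuotes <- function(x) gsub("^\"|\"$", "", x)

#' Read an expression dataset
#'
#' Reads either the GEO series-matrix dialect (metadata lines are parsed only
#' for the accession; the probe x sample block must sit between the
#' `!series_matrix_table_begin` / `!series_matrix_table_end` sentinels) or a
#' plain TSV whose header row holds sample ids and whose first column holds
#' row identifiers. Empty cells and the literals `NA`, `null` and `NULL`
#' become missing values. Values are used as stored (assumed log-scale); a
#' dataset maximum above 50 triggers a warning suggesting a log2 transform,
#' but no transform is ever applied silently.
#'
#' @param path input file.
#' @param format `"auto"` (series-matrix if any `!` line is present, plain
#'   TSV otherwise), `"series_matrix"` or `"tsv"`.
#' @param level identifier level to record: `"auto"` (default) honours a
#'   `!Series_id_level` metadata line when present and otherwise assumes
#'   `"probe"`, the GEO convention; or force `"probe"`/`"symbol"`.
#' @param datasetId accession override; defaults to the
#'   `!Series_geo_accession` metadata value, else the file name stem.
#' @return An [ExpressionDataset-class].
#' @examples
#' truth <- simulateCollection(simConfig(nDatasets = 1, nBackgroundGenes = 3,
#'                                       samplesPerDataset = 6, seed = 2))
#' f <- tempfile(fileext = ".txt")
#' writeSeriesMatrix(simDatasets(truth)[[1]], f)
#' readSeriesMatrix(f)
#' @export
readSeriesMatrix <- function(path, format = c("auto", "series_matrix", "tsv"),
                             level = c("auto", "probe", "symbol"),
                             datasetId = NULL) {
  format <- match.arg(format)
  level <- match.arg(level)
  if (!file.exists(path))
    stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  meta <- grepl("^!", lines)
  if (format == "auto")
    format <- if (any(meta)) "series_matrix" else "tsv"
  if (level == "auto") {
    lv <- grep("^!Series_id_level\t", lines, value = TRUE)
    level <- if (length(lv))
      stripQuotes(strsplit(lv[[1L]], "\t", fixed = TRUE)[[1L]][2L])
    else "probe"
    if (!level %in% c("probe", "symbol"))
      stop("unrecognised !Series_id_level value in ", path)
  }
  if (format == "series_matrix") {
    beg <- which(lines == "!series_matrix_table_begin")
    end <- which(lines == "!series_matrix_table_end")
    if (length(beg) != 1L || length(end) != 1L || end <= beg + 1L)
      stop("malformed series matrix: missing or empty ",
           "!series_matrix_table_begin/!series_matrix_table_end block in ",
           path)
    if (is.null(datasetId)) {
      acc <- grep("^!Series_geo_accession\t", lines, value = TRUE)
      datasetId <- if (length(acc))
        stripQuotes(strsplit(acc[[1L]], "\t", fixed = TRUE)[[1L]][2L])
      else sub("\\.[^.]*$", "", basename(path))
    }
    block <- lines[(beg + 1L):(end - 1L)]
  } else {
    if (any(meta))
      stop("plain TSV mode but '!' metadata lines present in ", path)
    if (is.null(datasetId))
      datasetId <- sub("\\.[^.]*$", "", basename(path))
    block <- lines
  }
  cells <- strsplit(block, "\t", fixed = TRUE)
  header <- stripQuotes(cells[[1L]])
  sampleIds <- header[-1L]
  if (anyDuplicated(sampleIds))
    stop("duplicate sample columns in ", path)
  if (length(sampleIds) < 4L)
    stop(sprintf("fewer than 4 samples (%d) in %s", length(sampleIds), path))
  body <- cells[-1L]
  nc <- length(header)
  rowIds <- vapply(body, function(x) stripQuotes(x[[1L]]), character(1))
  vals <- matrix(NA_real_, length(body), length(sampleIds),
                 dimnames = list(rowIds, sampleIds))
  for (i in seq_along(body)) {
    x <- body[[i]]
    length(x) <- nc                       # trailing empty cells
    v <- x[-1L]
    v[is.na(v) | v %in% c("", "NA", "null", "NULL")] <- NA
    vals[i, ] <- as.numeric(stripQuotes(v))
  }
  mx <- suppressWarnings(max(vals, na.rm = TRUE))
  if (is.finite(mx) && mx > 50)
    warning(sprintf(
      "%s: maximum value %.3g suggests unlogged intensities; consider log2 transforming before screening",
      datasetId, mx))
  ExpressionDataset(vals, datasetId, level)
}

#' Read a probe-to-symbol map
#'
#' Two-column TSV `probe<TAB>symbol` (header optional, detected when the
#' first line is `probe<TAB>symbol`). An empty symbol marks an unmapped
#' probe.
#'
#' @param path input TSV.
#' @return named character vector: probe id -> gene symbol.
#' @export
readProbeMap <- function(path) {
  df <- utils::read.delim(path, header = FALSE, colClasses = "character",
                          col.names = c("probe", "symbol"),
                          na.strings = character(0), quote = "")
  if (nrow(df) && identical(tolower(unlist(df[1L, ])),
                            c(probe = "probe", symbol = "symbol")))
    df <- df[-1L, , drop = FALSE]
  if (anyDuplicated(df$probe))
    stop("duplicate probe ids in probe map ", path)
  stats::setNames(df$symbol, df$probe)
}

#' Collapse probe-level rows to gene symbols
#'
#' Unmapped probes (absent from the map, or mapped to the empty string) are
#' dropped. When several probes map to one symbol, `"max_mean"` keeps the
#' probe with the highest mean intensity (ties broken by the
#' lexicographically smallest probe id) and `"mean"` averages the probe rows
#' cell-wise, ignoring missing values. Collapsing a symbol-level dataset is
#' the identity.
#'
#' @param ds an [ExpressionDataset-class] at probe level.
#' @param map named character vector probe -> symbol (see [readProbeMap()]).
#' @param method `"max_mean"` (default, common microarray practice and
#'   deterministic) or `"mean"`.
#' @return A symbol-level [ExpressionDataset-class].
#' @examples
#' m <- matrix(c(1, 3, 3, 5), 2, 2, byrow = TRUE,
#'             dimnames = list(c("p1", "p2"), paste0("S", 1:2)))
#' m <- cbind(m, m)  # >= 4 samples
#' colnames(m) <- paste0("S", 1:4)
#' ds <- ExpressionDataset(m, "TOY", "probe")
#' exprs(collapseProbes(ds, c(p1 = "G", p2 = "G"), "mean"))
#' @export
collapseProbes <- function(ds, map, method = c("max_mean", "mean")) {
  method <- match.arg(method)
  if (idLevel(ds) == "symbol")
    return(ds)
  vals <- exprs(ds)
  sym <- unname(map[rownames(vals)])
  mapped <- !is.na(sym) & nzchar(sym)
  if (!any(mapped))
    stop("no probes of ", datasetId(ds), " are mapped to a gene symbol")
  vals <- vals[mapped, , drop = FALSE]
  sym <- sym[mapped]
  if (method == "max_mean") {
    mn <- rowMeans(vals, na.rm = TRUE)
    ord <- radixOrder(sym, -mn, rownames(vals))
    pick <- ord[!duplicated(sym[ord])]
    pick <- pick[radixOrder(sym[pick])]
    out <- vals[pick, , drop = FALSE]
    rownames(out) <- sym[pick]
  } else {
    grp <- factor(sym, levels = sort(unique(sym), method = "radix"))
    cnt <- rowsum((!is.na(vals)) * 1, grp)
    sm <- rowsum(ifelse(is.na(vals), 0, vals), grp)
    out <- sm / cnt
    out[cnt == 0] <- NA_real_
  }
  ExpressionDataset(out, datasetId(ds), "symbol")
}

#' Load a collection of expression datasets
#'
#' Reads every dataset listed in a JSON manifest (as written by
#' [writeCollection()]) or every `*.txt`/`*.tsv` file of a directory,
#' collapsing probe-level datasets through `map` when supplied. No file is
#' skipped silently: per-file failures are re-raised with the dataset id
#' attached, and per-dataset gene and sample counts are reported via
#' [message()].
#'
#' @param path manifest JSON file or directory.
#' @param map optional probe map (named character vector); applied only to
#'   probe-level files.
#' @param method collapse method, see [collapseProbes()].
#' @param level identifier level of the files, passed to
#'   [readSeriesMatrix()]; the default `"auto"` lets mixed probe- and
#'   symbol-level files coexist, with `map` applied only where needed.
#' @return list of symbol-level [ExpressionDataset-class] objects.
#' @export
loadCollection <- function(path, map = NULL,
                           method = c("max_mean", "mean"),
                           level = c("auto", "probe", "symbol")) {
  method <- match.arg(method)
  level <- match.arg(level)
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(txt|tsv)$", full.names = TRUE)
    files <- setdiff(files, file.path(path, "truth.tsv"))
    files <- files[radixOrder(basename(files))]
  } else if (grepl("\\.json$", path)) {
    manifest <- jsonlite::read_json(path, simplifyVector = TRUE)
    files <- file.path(dirname(path), manifest$datasets$file)
  } else {
    stop("`path` must be a manifest JSON or a directory")
  }
  if (!length(files))
    stop("no dataset files found under ", path)
  lapply(files, function(f) {
    ds <- tryCatch({
      d <- readSeriesMatrix(f, level = level)
      if (idLevel(d) == "probe") {
        if (is.null(map))
          stop("probe-level file but no probe map supplied")
        d <- collapseProbes(d, map, method)
      }
      d
    }, error = function(e)
      stop(sprintf("[%s] %s", basename(f), conditionMessage(e)),
           call. = FALSE))
    message(sprintf("loaded %s: %d genes x %d samples", datasetId(ds),
                    nrow(ds), ncol(ds)))
    ds
  })
}
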