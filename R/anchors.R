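#' Default Parkinson's disease anchor set
#'
#' The seven commonly known PD genes used as anchors, stored exactly as the
#' source study printed them, with an alias table resolving them to current
#' HGNC usage: SCNA (alpha-synuclein, usually written SNCA), LRRK2, PARKIN
#' (PRKN/PARK2), DJ1 (PARK7), PINK1, ATP13A2 and HTR2A. Note HTR2A is the
#' serotonin receptor 2A symbol; the recessive PD gene is HTRA2, and the
#' alias table carries both readings rather than silently resolving the
#' discrepancy.
#'
#' @return An [AnchorSet-class] of 7 symbols with aliases attached.
#' @examples
#' defaultAnchors()
#' @export
defaultAnchors <- function() {
  anchorSet(
    c("SCNA", "LRRK2", "PARKIN", "DJ1", "PINK1", "ATP13A2", "HTR2A"),
    aliases = list(
      SCNA   = "SNCA",
      PARKIN = c("PRKN", "PARK2"),
      DJ1    = "PARK7",
      HTR2A  = "HTRA2"
    )
  )
}

#' GEO accessions of the reference dataset collection
#'
#' The eleven NCBI GEO DataSets / Series of human brain (substantia nigra)
#' expression profiles that define the screen's intended input regime. These
#' are a manifest only: the package does not download from GEO.
#'
#' @return character vector of 11 accessions.
#' @examples
#' pdDatasetManifest()
#' @export
pdDatasetManifest <- function() {
  c("GDS2519", "GDS2821", "GDS3128", "GDS3129", "GSE19587", "GSE20141",
    "GSE20146", "GSE20153", "GSE20292", "GSE20295", "GSE20333")
}

#' Resolve anchor rows present in a dataset
#'
#' Matches each anchor (canonical symbol first, then its aliases) against the
#' row ids of a symbol-level dataset.
#'
#' @param ds an [ExpressionDataset-class] at symbol level.
#' @param anchors an [AnchorSet-class].
#' @return named character vector mapping canonical anchor symbol to the
#'   matched row id, for anchors present; anchors absent are omitted.
#' @keywords internal
matchAnchorRows <- function(ds, anchors) {
  rows <- rownames(ds)
  hits <- vapply(anchorSymbols(anchors), function(sym) {
    cand <- c(sym, anchorAliases(anchors)[[sym]])
    hit <- cand[cand %in% rows]
    if (length(hit)) hit[[1L]] else NA_character_
  }, character(1))
  hits[!is.na(hits)]
}
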