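#' Accession of an expression dataset
#' @param x an [ExpressionDataset-class].
#' @return single character accession.
#' @name datasetId
#' @export
setMethod("datasetId", "ExpressionDataset", function(x) x@datasetId)

#' Identifier level of an expression dataset
#' @param x an [ExpressionDataset-class].
#' @return `"probe"` or `"symbol"`.
#' @name idLevel
#' @export
setMethod("idLevel", "ExpressionDataset", function(x) x@idLevel)

#' Expression matrix of a dataset
#' @param x an [ExpressionDataset-class].
#' @return numeric matrix of log-intensities (rows identifiers, columns
#'   samples), `NA` marking missing values.
#' @name exprs
#' @export
setMethod("exprs", "ExpressionDataset", function(x) assay(x, "exprs"))

#' Anchor symbols
#' @param x an [AnchorSet-class].
#' @return ordered character vector of anchor symbols.
#' @name anchorSymbols
#' @export
setMethod("anchorSymbols", "AnchorSet", function(x) x@symbols)

#' Anchor aliases
#' @param x an [AnchorSet-class].
#' @return named list of accepted alternate symbols.
#' @name anchorAliases
#' @export
setMethod("anchorAliases", "AnchorSet", function(x) x@aliases)

#' Support counts
#' @param x a [SupportMatrix-class].
#' @return integer gene x anchor matrix of dataset counts.
#' @name support
#' @export
setMethod("support", "SupportMatrix", function(x) x@support)

#' Total number of datasets
#' @param x a [SupportMatrix-class] or [SimTruth-class].
#' @return integer count.
#' @name nDatasets
#' @export
setMethod("nDatasets", "SupportMatrix", function(x) x@nDatasets)

#' @name nDatasets
#' @export
setMethod("nDatasets", "SimTruth", function(x) length(x@datasets))

#' Passing (gene, anchor, dataset) records
#' @param x a [SupportMatrix-class].
#' @return data.frame with columns `gene`, `anchor`, `dataset_id`, `r`.
#' @name passes
#' @export
setMethod("passes", "SupportMatrix", function(x) x@passes)

#' Datasets in which each gene was measurable
#' @param x a [SupportMatrix-class].
#' @return named integer vector.
#' @name geneDatasets
#' @export
setMethod("geneDatasets", "SupportMatrix", function(x) x@geneDatasets)

#' All screened records of a candidate table
#' @param x a [CandidateTable-class].
#' @return data.frame (`gene`, `N`, `candidate`, `testable`, `anchors`).
#' @name records
#' @export
setMethod("records", "CandidateTable", function(x) x@records)

#' Candidate rows of a table
#' @param x a [CandidateTable-class].
#' @return the subset of [records()] with `candidate == TRUE`.
#' @name candidates
#' @export
setMethod("candidates", "CandidateTable", function(x)
  x@records[x@records$candidate, , drop = FALSE])

#' Tier summary of a candidate table
#'
#' One row per anchor count N among candidates, with the number of genes in
#' that tier, N descending.
#'
#' @param x a [CandidateTable-class].
#' @return data.frame with columns `N` and `genes`.
#' @name tierSummary
#' @export
setMethod("tierSummary", "CandidateTable", function(x) {
  cand <- candidates(x)
  if (!nrow(cand))
    return(data.frame(N = integer(0), genes = integer(0)))
  tab <- table(cand$N)
  out <- data.frame(N = as.integer(names(tab)), genes = as.integer(tab))
  out[order(-out$N, method = "radix"), , drop = FALSE]
})

#' Screen configuration attached to an object
#' @param x a [SupportMatrix-class] or [CandidateTable-class].
#' @return the [ScreenConfig-class] under which the object was built.
#' @name screenParams
#' @export
setMethod("screenParams", "SupportMatrix", function(x) x@config)

#' @name screenParams
#' @export
setMethod("screenParams", "CandidateTable", function(x) x@config)

#' Simulated datasets
#' @param x a [SimTruth-class].
#' @return list of [ExpressionDataset-class] objects.
#' @name simDatasets
#' @export
setMethod("simDatasets", "SimTruth", function(x) x@datasets)

#' Planted-gene manifest
#' @param x a [SimTruth-class] or [SimConfig-class].
#' @return data.frame (`gene`, `anchors` list column, `rho`).
#' @name plantedGenes
#' @export
setMethod("plantedGenes", "SimTruth", function(x) x@planted)

#' @name plantedGenes
#' @export
setMethod("plantedGenes", "SimConfig", function(x) x@planted)

#' Simulation configuration attached to a collection
#' @param x a [SimTruth-class].
#' @return the [SimConfig-class] echo.
#' @name simParams
#' @export
setMethod("simParams", "SimTruth", function(x) x@config)

#' Sensitivity of a recovery report
#' @param x a [RecoveryReport-class].
#' @return fraction of planted genes called (NA for planted-free runs).
#' @name sensitivity
#' @export
setMethod("sensitivity", "RecoveryReport", function(x) x@sensitivity)

#' False candidate calls
#' @param x a [RecoveryReport-class].
#' @return count of candidates outside the planted set.
#' @name falseCalls
#' @export
setMethod("falseCalls", "RecoveryReport", function(x) x@falseCalls)

#' Per-planted-gene outcomes
#' @param x a [RecoveryReport-class].
#' @return data.frame (`gene`, `called`, `N`, `rho`).
#' @name perGene
#' @export
setMethod("perGene", "RecoveryReport", function(x) x@perGene)

#' Per-replicate candidate counts (null calibration)
#' @param x a [RecoveryReport-class].
#' @return integer vector, one entry per replicate.
#' @name candidateCounts
#' @export
setMethod("candidateCounts", "RecoveryReport", function(x) x@candidateCounts)
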