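#' @rdname datasetId
#' @export
setGeneric("datasetId", function(x) standardGeneric("datasetId"))

#' @rdname idLevel
#' @export
setGeneric("idLevel", function(x) standardGeneric("idLevel"))

#' @rdname exprs
#' @export
setGeneric("exprs", function(x) standardGeneric("exprs"))

#' @rdname anchorSymbols
#' @export
setGeneric("anchorSymbols", function(x) standardGeneric("anchorSymbols"))

#' @rdname anchorAliases
#' @export
setGeneric("anchorAliases", function(x) standardGeneric("anchorAliases"))

#' @rdname support
#' @export
setGeneric("support", function(x) standardGeneric("support"))

#' @rdname nDatasets
#' @export
setGeneric("nDatasets", function(x) standardGeneric("nDatasets"))

#' @rdname passes
#' @export
setGeneric("passes", function(x) standardGeneric("passes"))

#' @rdname geneDatasets
#' @export
setGeneric("geneDatasets", function(x) standardGeneric("geneDatasets"))

#' @rdname records
#' @export
setGeneric("records", function(x) standardGeneric("records"))

#' @rdname candidates
#' @export
setGeneric("candidates", function(x) standardGeneric("candidates"))

#' @rdname tierSummary
#' @export
setGeneric("tierSummary", function(x) standardGeneric("tierSummary"))

#' @rdname screenParams
#' @export
setGeneric("screenParams", function(x) standardGeneric("screenParams"))

#' @rdname simDatasets
#' @export
setGeneric("simDatasets", function(x) standardGeneric("simDatasets"))

#' @rdname plantedGenes
#' @export
setGeneric("plantedGenes", function(x) standardGeneric("plantedGenes"))

#' @rdname simParams
#' @export
setGeneric("simParams", function(x) standardGeneric("simParams"))

#' @rdname sensitivity
#' @export
setGeneric("sensitivity", function(x) standardGeneric("sensitivity"))

#' @rdname falseCalls
#' @export
setGeneric("falseCalls", function(x) standardGeneric("falseCalls"))

#' @rdname perGene
#' @export
setGeneric("perGene", function(x) standardGeneric("perGene"))

#' @rdname candidateCounts
#' @export
setGeneric("candidateCounts", function(x) standardGeneric("candidateCounts"))
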