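#' Accessor generics
#'
#' Small accessor generics for the package's S4 containers: `hours()` and
#' `cellLines()` for \linkS4class{TimeCourseExperiment},
#' `sf2Values()` for \linkS4class{RadiosensitivityTable},
#' `profileMatrix()` for \linkS4class{ProfileLibrary},
#' `assignments()` and `clusterStats()` for
#' \linkS4class{ClusterAssignment}, `layerKind()`, `layerEdges()` and
#' `nodeHeat()` for \linkS4class{NetworkLayer}, `hubGenes()` and
#' `centralityTable()` for \linkS4class{HubReport}, and
#' `candidateGenes()`, `funnel()` and `enrichment()` for
#' \linkS4class{CandidateReport}.
#'
#' @param x an object of the class the accessor belongs to.
#' @return the slot contents, see the class documentation.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("hours", function(x) standardGeneric("hours"))

#' @rdname accessors
#' @export
setGeneric("cellLines", function(x) standardGeneric("cellLines"))

#' @rdname accessors
#' @export
setGeneric("baselineMatrix", function(x) standardGeneric("baselineMatrix"))

#' @rdname accessors
#' @export
setGeneric("sf2Values", function(x) standardGeneric("sf2Values"))

#' @rdname accessors
#' @export
setGeneric("profileMatrix", function(x) standardGeneric("profileMatrix"))

#' @rdname accessors
#' @export
setGeneric("assignments", function(x) standardGeneric("assignments"))

#' @rdname accessors
#' @export
setGeneric("clusterStats", function(x) standardGeneric("clusterStats"))

#' @rdname accessors
#' @export
setGeneric("layerKind", function(x) standardGeneric("layerKind"))

#' @rdname accessors
#' @export
setGeneric("layerEdges", function(x) standardGeneric("layerEdges"))

#' @rdname accessors
#' @export
setGeneric("nodeHeat", function(x) standardGeneric("nodeHeat"))

#' @rdname accessors
#' @export
setGeneric("hubGenes", function(x) standardGeneric("hubGenes"))

#' @rdname accessors
#' @export
setGeneric("centralityTable", function(x) standardGeneric("centralityTable"))

#' @rdname accessors
#' @export
setGeneric("candidateGenes", function(x) standardGeneric("candidateGenes"))

#' @rdname accessors
#' @export
setGeneric("funnel", function(x) standardGeneric("funnel"))

#' @rdname accessors
#' @export
setGeneric("enrichment", function(x) standardGeneric("enrichment"))

#' @rdname accessors
#' @export
setGeneric("signatureGenes", function(x) standardGeneric("signatureGenes"))
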