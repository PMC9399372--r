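#' Construct a TimeCourseExperiment
#'
#' @param values numeric matrix, genes x samples; column order must match
#'   `cellLine`/`hour`.
#' @param cellLine character vector, one cell line per column.
#' @param hour numeric vector, one timepoint (hours post-IR) per column.
#' @return a \linkS4class{TimeCourseExperiment}.
#' @examples
#' m <- matrix(rnorm(12), 2, 6,
#'             dimnames = list(c("g1", "g2"), NULL))
#' tce <- TimeCourseExperiment(m, rep(c("A", "B"), each = 3),
#'                             rep(c(0, 2, 4), 2))
#' hours(tce)
#' @export
TimeCourseExperiment <- function(values, cellLine, hour) {
  stopifnot(is.matrix(values), ncol(values) == length(cellLine),
            length(cellLine) == length(hour))
  colnames(values) <- paste0(cellLine, "__t", hour)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = values),
    colData = S4Vectors::DataFrame(cell_line = cellLine, hour = hour))
  new("TimeCourseExperiment", se)
}

#' @rdname accessors
#' @export
setMethod("hours", "TimeCourseExperiment", function(x)
  sort(unique(SummarizedExperiment::colData(x)$hour)))

#' @rdname accessors
#' @export
setMethod("cellLines", "TimeCourseExperiment", function(x)
  unique(SummarizedExperiment::colData(x)$cell_line))

#' @describeIn accessors expression submatrix (genes x cell lines) at the
#'   earliest timepoint, the "untreated" baseline used for SF2 screens.
#' @export
setMethod("baselineMatrix", "TimeCourseExperiment", function(x) {
  cd <- SummarizedExperiment::colData(x)
  h0 <- min(cd$hour)
  keep <- cd$hour == h0
  m <- SummarizedExperiment::assay(x, "exprs")[, keep, drop = FALSE]
  colnames(m) <- cd$cell_line[keep]
  m
})

setMethod("show", "TimeCourseExperiment", function(object) {
  cd <- SummarizedExperiment::colData(object)
  cat("TimeCourseExperiment:", nrow(object), "genes,",
      length(unique(cd$cell_line)), "cell lines,",
      length(unique(cd$hour)), "timepoints (",
      paste(sort(unique(cd$hour)), collapse = ","), "h )\n")
})

#' Construct a RadiosensitivityTable
#'
#' @param cellLine unique cell-line identifiers.
#' @param sf2 survival fractions at 2 Gy, each in (0, 1].
#' @return a \linkS4class{RadiosensitivityTable}.
#' @examples
#' radiosensitivityTable(c("A549", "H1299"), c(0.61, 0.80))
#' @export
radiosensitivityTable <- function(cellLine, sf2) {
  new("RadiosensitivityTable", cellLine = as.character(cellLine),
      sf2 = as.numeric(sf2))
}

#' @describeIn accessors named numeric vector of SF2 values.
#' @export
setMethod("sf2Values", "RadiosensitivityTable", function(x)
  setNames(x@sf2, x@cellLine))

setMethod("show", "RadiosensitivityTable", function(object) {
  cat("RadiosensitivityTable:", length(object@cellLine),
      "cell lines, SF2 range [",
      sprintf("%.3f", min(object@sf2)), ",",
      sprintf("%.3f", max(object@sf2)), "]\n")
})

#' @rdname accessors
#' @export
setMethod("profileMatrix", "ProfileLibrary", function(x) x@profiles)

setMethod("show", "ProfileLibrary", function(object) {
  cat("ProfileLibrary:", nrow(object@profiles), "representatives of",
      object@nCandidates, "candidates (c =", object@maxUnitChange,
      ", T =", ncol(object@profiles), ")\n")
})

#' @rdname accessors
#' @export
setMethod("assignments", "ClusterAssignment", function(x) x@assignments)

#' @rdname accessors
#' @export
setMethod("clusterStats", "ClusterAssignment", function(x) x@stats)

setMethod("show", "ClusterAssignment", function(object) {
  cat("ClusterAssignment:", length(object@assignments), "genes over",
      length(unique(object@assignments)), "profiles;",
      length(object@unassigned), "unassigned\n")
  if (nrow(object@stats) && "qvalue" %in% colnames(object@stats))
    cat("  significant profiles:", sum(object@stats$significant), "\n")
})

#' Construct a NetworkLayer
#'
#' @param kind layer kind: "mutation", "cna", "coexpression" or "protein".
#' @param edges data.frame with columns from, to and optionally weight.
#' @param heat named non-negative node heat (mutation/cna layers).
#' @param nodes node universe; defaults to the union of edge endpoints and
#'   heat names.
#' @return a \linkS4class{NetworkLayer}.
#' @export
networkLayer <- function(kind, edges, heat = numeric(0), nodes = NULL) {
  edges <- as.data.frame(edges)
  if (nrow(edges) && !"weight" %in% colnames(edges)) edges$weight <- 1
  if (is.null(nodes))
    nodes <- unique(c(as.character(edges$from), as.character(edges$to),
                      names(heat)))
  new("NetworkLayer", kind = kind, edges = edges, heat = heat,
      nodes = as.character(nodes))
}

#' @rdname accessors
#' @export
setMethod("layerKind", "NetworkLayer", function(x) x@kind)

#' @rdname accessors
#' @export
setMethod("layerEdges", "NetworkLayer", function(x) x@edges)

#' @rdname accessors
#' @export
setMethod("nodeHeat", "NetworkLayer", function(x) x@heat)

setMethod("show", "NetworkLayer", function(object) {
  cat("NetworkLayer <", object@kind, ">:", length(object@nodes), "nodes,",
      nrow(object@edges), "edges",
      if (length(object@heat)) "(with heat)" else "", "\n")
})

setMethod("show", "DiffusionResult", function(object) {
  cat("DiffusionResult: restart beta =", object@restartBeta,
      ", delta =", signif(object@delta, 4), ";",
      nrow(object@hotEdges), "hot edges,",
      length(object@subnetworks), "hot subnetworks\n")
})

setMethod("show", "CoexpressionModules", function(object) {
  sz <- table(object@labels[object@labels > 0])
  cat("CoexpressionModules: power", object@power, ",",
      length(sz), "modules (sizes:",
      paste(as.integer(sz), collapse = ","), "),",
      sum(object@labels == 0), "unassigned genes\n")
})

#' @describeIn accessors genes flagged as hubs.
#' @export
setMethod("hubGenes", "HubReport", function(x)
  x@table$node[x@table$hub])

#' @rdname accessors
#' @export
setMethod("centralityTable", "HubReport", function(x) x@table)

setMethod("show", "HubReport", function(object) {
  cat("HubReport (", object@closenessType, "closeness ):",
      nrow(object@table), "nodes,", sum(object@table$hub), "hubs;",
      "medians d/b/c =",
      paste(signif(object@medians, 3), collapse = "/"), "\n")
})

#' @describeIn accessors ordered final candidate genes.
#' @export
setMethod("candidateGenes", "CandidateReport", function(x)
  x@candidates$gene)

#' @rdname accessors
#' @export
setMethod("funnel", "CandidateReport", function(x) x@funnel)

#' @describeIn accessors per-profile cluster statistics of a run.
#' @export
setMethod("clusterStats", "CandidateReport", function(x) x@clusters)

#' @rdname accessors
#' @export
setMethod("enrichment", "CandidateReport", function(x) x@enrichment)

setMethod("show", "CandidateReport", function(object) {
  cat("CandidateReport [", object@status, "]:",
      nrow(object@candidates), "final candidates\n")
  if (nrow(object@funnel)) {
    cat("  funnel:\n")
    print(object@funnel, row.names = FALSE)
  }
  if (length(object@truthMetrics))
    cat("  truth: precision =",
        sprintf("%.3f", object@truthMetrics[["precision"]]),
        ", recall =", sprintf("%.3f", object@truthMetrics[["recall"]]), "\n")
})

#' @describeIn accessors planted signature gene identifiers.
#' @export
setMethod("signatureGenes", "GroundTruth", function(x) x@signatureGenes)

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth:", length(object@signatureGenes), "signature genes,",
      length(object@responsiveGenes), "responsive decoys,",
      length(object@blocks), "co-expression blocks\n")
})

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", object@nGenes, "genes (",
      object@nSignature, "signature,", object@nResponsive, "decoys ),",
      length(object@cellLines), "cell lines,",
      length(object@timepointsH), "timepoints; seed", object@seed, "\n")
})

setMethod("show", "SGLQFit", function(object) {
  cat("SGLQFit", object@gene, ": alpha =", signif(object@alpha, 4),
      ", beta =", signif(object@beta, 4),
      ", R2(log) =", signif(object@r2Log, 3),
      ", F p =", signif(object@fPValue, 3),
      if (isTRUE(object@pass)) "[pass]" else "[fail]", "\n")
})

setMethod("show", "ClusterEigenvalue", function(object) {
  cat("ClusterEigenvalue", object@clusterId, ":",
      length(object@loadings), "genes,",
      sprintf("%.1f%%", 100 * object@varExplained),
      "variance on PC1\n")
})
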