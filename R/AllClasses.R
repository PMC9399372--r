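#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom stats cor cor.test lm median p.adjust pf phyper prcomp
#'   quantile rbinom rnorm runif sd setNames var hclust cutree as.dist
#'   resid coef fitted
#' @importFrom utils read.delim write.table head combn
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))
setClassUnion("characterOrNULL", c("character", "NULL"))

#' Simulation configuration for the synthetic study generator
#'
#' Holds every knob of the synthetic radiosensitivity study: the gene
#' universe, the planted signature, the irradiation time grid, the SGLQ
#' coefficients used generatively, the noise model, the co-expression block
#' structure, and the interaction-network family. Construct with
#' [simulationConfig()], which supplies the default study conditions.
#'
#' @slot nGenes total number of genes in the universe.
#' @slot nSignature number of planted signature genes (drive SF2).
#' @slot nResponsive number of time-responsive decoy genes that follow a
#'   planted temporal archetype but are marginally independent of SF2.
#' @slot cellLines cell-line identifiers.
#' @slot timepointsH strictly increasing hours post-irradiation.
#' @slot nProfiles number of planted temporal archetypes.
#' @slot maxUnitChange,libSize profile-library parameters (`c` and `m`)
#'   used to draw the planted archetypes.
#' @slot profileAmplitude expression change (z-units) per profile unit.
#' @slot sglqAlpha,sglqBeta SGLQ coefficients (per expression unit) used to
#'   generate SF2 from signature-gene expression.
#' @slot signatureLoading loading of signature baseline expression on the
#'   latent per-line radioresponse factor, in [0,1].
#' @slot noiseSd expression noise standard deviation (z-units).
#' @slot sf2NoiseSd log-scale noise added to generated SF2.
#' @slot nBlocks,blockSize,blockLoading background co-expression blocks.
#' @slot meanDegree mean degree of the Erdos-Renyi background interaction
#'   graph.
#' @slot signatureDensity edge density of the planted signature subgraph.
#' @slot heatFactor multiplicative elevation of mutation/CNA heat on
#'   signature genes (1 = no elevation).
#' @slot proteinWeightRange range of the uniform confidence weights on
#'   interaction edges.
#' @slot seed integer RNG seed.
#' @export
setClass("SimulationConfig",
  representation(
    nGenes = "integer", nSignature = "integer", nResponsive = "integer",
    cellLines = "character", timepointsH = "numeric", nProfiles = "integer",
    maxUnitChange = "integer", libSize = "integer",
    profileAmplitude = "numeric", sglqAlpha = "numeric", sglqBeta = "numeric",
    signatureLoading = "numeric", noiseSd = "numeric", sf2NoiseSd = "numeric",
    nBlocks = "integer", blockSize = "integer", blockLoading = "numeric",
    meanDegree = "numeric", signatureDensity = "numeric",
    heatFactor = "numeric", proteinWeightRange = "numeric", seed = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@nSignature >= object@nGenes)
    msg <- c(msg, "nSignature must be smaller than nGenes")
  if (object@nSignature + object@nResponsive > object@nGenes)
    msg <- c(msg, "signature + responsive genes exceed nGenes")
  if (any(diff(object@timepointsH) <= 0))
    msg <- c(msg, "timepointsH must be strictly increasing")
  if (length(object@timepointsH) < 2)
    msg <- c(msg, "need at least two timepoints")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be non-negative")
  if (object@sf2NoiseSd < 0) msg <- c(msg, "sf2NoiseSd must be non-negative")
  if (anyDuplicated(object@cellLines))
    msg <- c(msg, "cell lines must be unique")
  if (object@signatureDensity < 0 || object@signatureDensity > 1)
    msg <- c(msg, "signatureDensity must be in [0,1]")
  if (object@heatFactor <= 0) msg <- c(msg, "heatFactor must be positive")
  if (object@nProfiles > object@libSize)
    msg <- c(msg, "nProfiles cannot exceed libSize")
  if (length(msg)) msg else TRUE
})

#' Record of the planted ground truth of a synthetic bundle
#'
#' @slot signatureGenes identifiers of the planted signature genes.
#' @slot responsiveGenes time-responsive decoy genes (no SF2 link).
#' @slot alpha,beta named per-gene SGLQ coefficients used generatively.
#' @slot profileId named planted archetype id (library profile index) per
#'   responsive gene (signature genes included).
#' @slot mutationHeat,cnaHeat named planted heats.
#' @slot blocks list of background co-expression block memberships.
#' @export
setClass("GroundTruth",
  representation(
    signatureGenes = "character", responsiveGenes = "character",
    alpha = "numeric", beta = "numeric", profileId = "integer",
    mutationHeat = "numeric", cnaHeat = "numeric", blocks = "list"
  )
)

#' Time-course expression experiment
#'
#' A \linkS4class{SummarizedExperiment} whose columns are (cell line, hour)
#' pairs after irradiation; `colData` carries `cell_line` and `hour`. The
#' single assay `exprs` holds normalized (z-scored per gene) expression.
#'
#' @export
setClass("TimeCourseExperiment",
  contains = "SummarizedExperiment")

setValidity("TimeCourseExperiment", function(object) {
  cd <- SummarizedExperiment::colData(object)
  msg <- character()
  if (!all(c("cell_line", "hour") %in% colnames(cd)))
    return("colData must contain 'cell_line' and 'hour'")
  if (anyDuplicated(paste(cd$cell_line, cd$hour)))
    msg <- c(msg, "every (cell_line, hour) combination must be unique")
  if (length(msg)) msg else TRUE
})

#' Per-cell-line radiosensitivity (SF2) table
#'
#' Survival fraction at 2 Gy per cell line; values constrained to (0, 1].
#'
#' @slot cellLine unique cell-line identifiers.
#' @slot sf2 survival fractions in (0, 1].
#' @export
setClass("RadiosensitivityTable",
  representation(cellLine = "character", sf2 = "numeric"))

setValidity("RadiosensitivityTable", function(object) {
  msg <- character()
  if (length(object@cellLine) != length(object@sf2))
    msg <- c(msg, "cellLine and sf2 lengths differ")
  if (anyDuplicated(object@cellLine))
    msg <- c(msg, "cell lines must be unique")
  if (any(!is.finite(object@sf2)) || any(object@sf2 <= 0 | object@sf2 > 1))
    msg <- c(msg, "SF2 values must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' Library of short time-series model profiles
#'
#' Candidate profiles are sequences of integer unit changes per
#' inter-timepoint interval, bounded by `maxUnitChange`; the library stores
#' them as cumulative value curves (leading 0). The flat profile is always
#' excluded.
#'
#' @slot profiles m x T matrix of cumulative profile values (first column 0).
#' @slot changes m x (T-1) matrix of the underlying unit changes.
#' @slot maxUnitChange bound `c` on |change| per interval.
#' @slot nCandidates size of the full enumeration (2c+1)^(T-1).
#' @export
setClass("ProfileLibrary",
  representation(profiles = "matrix", changes = "matrix",
                 maxUnitChange = "integer", nCandidates = "integer"))

setValidity("ProfileLibrary", function(object) {
  msg <- character()
  if (any(rowSums(abs(object@changes)) == 0))
    msg <- c(msg, "the flat (all-zero) profile must not be in the library")
  if (any(abs(object@changes) > object@maxUnitChange))
    msg <- c(msg, "profile changes exceed maxUnitChange")
  if (anyDuplicated(object@changes))
    msg <- c(msg, "representatives must be pairwise distinct")
  if (length(msg)) msg else TRUE
})

#' Assignment of genes to temporal profiles
#'
#' @slot assignments named integer vector, gene -> profile row index.
#' @slot correlation named numeric, correlation to the assigned profile.
#' @slot unassigned genes with zero variance after the 0 h transform.
#' @slot stats per-profile data.frame: size, expected size, p-value, BH
#'   q-value and significance flag (filled by [profileSignificance()]).
#' @export
setClass("ClusterAssignment",
  representation(assignments = "integer", correlation = "numeric",
                 unassigned = "character", stats = "data.frame"))

setValidity("ClusterAssignment", function(object) {
  msg <- character()
  if (length(object@assignments) != length(object@correlation))
    msg <- c(msg, "assignments and correlation lengths differ")
  if (nrow(object@stats) &&
      sum(object@stats$size) != length(object@assignments))
    msg <- c(msg, "profile sizes must sum to the number of assigned genes")
  if (length(msg)) msg else TRUE
})

#' First principal component summary of a gene cluster
#'
#' PC1 of the standardized member x cell-line submatrix, oriented so the
#' score series correlates non-negatively with the members' mean profile.
#'
#' @slot clusterId identifier of the summarized cluster.
#' @slot loadings named gene loadings on PC1.
#' @slot scores named per-cell-line PC1 scores (zero mean).
#' @slot varExplained fraction of variance carried by PC1.
#' @export
setClass("ClusterEigenvalue",
  representation(clusterId = "character", loadings = "numeric",
                 scores = "numeric", varExplained = "numeric"))

setValidity("ClusterEigenvalue", function(object) {
  if (abs(mean(object@scores)) > 1e-8)
    "PC1 scores must have zero mean" else TRUE
})

#' Single-gene linear-quadratic (SGLQ) fit
#'
#' No-intercept least squares of ln(SF2) on (E, E^2); the model is
#' SF = e^(alpha*E - beta*E^2), so survival is exactly 1 at E = 0.
#'
#' @slot gene gene identifier.
#' @slot alpha linear coefficient per expression unit.
#' @slot beta quadratic coefficient (note the sign convention above).
#' @slot r2Log coefficient of determination on the log-SF scale
#'   (no-intercept convention).
#' @slot fPValue overall regression F-test p-value.
#' @slot pass logical pass flag at the configured level.
#' @export
setClass("SGLQFit",
  representation(gene = "character", alpha = "numeric", beta = "numeric",
                 r2Log = "numeric", fPValue = "numeric", pass = "logical"))

#' One omics layer of the multi-layer network
#'
#' @slot kind one of "mutation", "cna", "coexpression", "protein".
#' @slot edges data.frame with columns from, to, weight (undirected).
#' @slot heat named non-negative node heat (mutation/cna layers).
#' @slot nodes node identifiers covered by the layer.
#' @export
setClass("NetworkLayer",
  representation(kind = "character", edges = "data.frame",
                 heat = "numeric", nodes = "character"))

setValidity("NetworkLayer", function(object) {
  msg <- character()
  if (!object@kind %in% c("mutation", "cna", "coexpression", "protein"))
    msg <- c(msg, "unknown layer kind")
  if (nrow(object@edges)) {
    if (!all(c("from", "to") %in% colnames(object@edges)))
      msg <- c(msg, "edges need 'from' and 'to' columns")
    else if (any(object@edges$from == object@edges$to))
      msg <- c(msg, "self-loops are not allowed")
  }
  if (length(object@heat) && any(object@heat < 0))
    msg <- c(msg, "heats must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Result of insulated heat diffusion on one network layer
#'
#' @slot exchangedHeat dense matrix E with E[i,j] = F[i,j] * h[j].
#' @slot hotEdges data.frame of layer edges whose bidirectional exchanged
#'   heat min(Eij, Eji) is positive and >= delta.
#' @slot subnetworks list of hot connected components (size >= kMin).
#' @slot delta threshold actually used.
#' @slot restartBeta restart probability of the walk.
#' @export
setClass("DiffusionResult",
  representation(exchangedHeat = "matrix", hotEdges = "data.frame",
                 subnetworks = "list", delta = "numeric",
                 restartBeta = "numeric"))

#' Co-expression modules from topological overlap clustering
#'
#' @slot power soft-thresholding power applied to |cor|.
#' @slot tom topological overlap matrix (values in [0,1], unit diagonal).
#' @slot labels named integer module label per gene (0 = unassigned).
#' @slot eigengenes module eigengene score matrix (samples x modules).
#' @slot moduleTrait named Pearson correlation of each eigengene with the
#'   supplied trait (empty if no trait given).
#' @export
setClass("CoexpressionModules",
  representation(power = "numeric", tom = "matrix", labels = "integer",
                 eigengenes = "matrix", moduleTrait = "numeric"))

#' Node centralities and median-threshold hub calls
#'
#' A node is a hub iff its degree, betweenness and closeness are all
#' strictly greater than the respective medians over all nodes.
#'
#' @slot table data.frame: node, degree, betweenness, closeness, hub.
#' @slot medians named medians of the three centralities.
#' @slot closenessType "harmonic" or "classic".
#' @export
setClass("HubReport",
  representation(table = "data.frame", medians = "numeric",
                 closenessType = "character"))

setValidity("HubReport", function(object) {
  need <- c("node", "degree", "betweenness", "closeness", "hub")
  if (!all(need %in% colnames(object@table)))
    "table must have node/degree/betweenness/closeness/hub columns" else TRUE
})

#' Full report of one discovery run
#'
#' @slot candidates data.frame of final candidate genes with per-stage
#'   evidence (cluster id and correlation, RF importance, SGLQ fit,
#'   centralities, hub flag).
#' @slot clusters data.frame of per-profile cluster statistics (size,
#'   permutation p/q, significance, SF2 correlation and screen outcome).
#' @slot funnel data.frame of stage-by-stage gene counts and percentages.
#' @slot enrichment over-representation results on the final gene set.
#' @slot hubReport the \linkS4class{HubReport} of the union graph.
#' @slot status "ok" or "no_significant_clusters".
#' @slot truthMetrics named numeric (precision, recall) when ground truth
#'   was available; empty otherwise.
#' @slot config the pipeline configuration used.
#' @export
setClass("CandidateReport",
  representation(candidates = "data.frame", clusters = "data.frame",
                 funnel = "data.frame",
                 enrichment = "data.frame", hubReport = "ANY",
                 status = "character", truthMetrics = "numeric",
                 config = "list"))
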