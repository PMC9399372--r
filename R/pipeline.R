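#' Pipeline configuration
#'
#' Nested list of stage parameters mirroring the module defaults: ANOVA
#' level, profile-library and permutation settings, the cluster/SF2
#' correlation screen (absolute |cor| by default, signed optionally), the
#' single-gene RF/SGLQ screens, the network stage (restart probability,
#' hot-edge rule, co-expression settings, protein confidence filter,
#' harmonic vs classic closeness, hub scope candidates vs full graph) and
#' the enrichment threshold. Round-trips through YAML unchanged.
#'
#' @param seed integer master seed for all stochastic stages.
#' @param ... replacement values for any top-level or nested entry, e.g.
#'   `screen = list(threshold = 0.2)` (partial lists are merged).
#' @return a list of class `radiosigConfig`.
#' @examples
#' cfg <- pipelineConfig(seed = 1, screen = list(use = "signed"))
#' cfg$screen$use
#' @export
pipelineConfig <- function(seed = 20220810, ...) {
  base <- list(
    seed = as.integer(seed),
    anova = list(alpha = 0.05),
    stem = list(maxUnitChange = 2, m = 50, nPerm = 1000, qThreshold = 0.01),
    screen = list(threshold = 0.1, use = "absolute"),
    singleGene = list(nTrees = 500, sglqAlpha = 0.05),
    network = list(restartBeta = 0.4, delta = NULL, hotQuantile = 0.95,
                   kMin = 3, power = 6, minModuleSize = 30,
                   cutHeight = 0.99, mergeCor = 0.75, edgeQuantile = 0.9,
                   proteinMinWeight = 0.7, closeness = "harmonic",
                   hubScope = "candidates"),
    ora = list(qThreshold = 0.05))
  mods <- list(...)
  for (nm in names(mods)) {
    if (is.list(mods[[nm]]) && is.list(base[[nm]]))
      base[[nm]][names(mods[[nm]])] <- mods[[nm]]
    else base[[nm]] <- mods[[nm]]
  }
  structure(base, class = c("radiosigConfig", "list"))
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config a `radiosigConfig` list.
#' @param path file path.
#' @return `readPipelineConfig` returns the configuration with class and
#'   types restored, so `readPipelineConfig(writePipelineConfig(cfg, f))`
#'   equals `cfg`.
#' @export
writePipelineConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname writePipelineConfig
#' @export
readPipelineConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipelineConfig, c(list(seed = raw$seed),
                            raw[setdiff(names(raw), "seed")]))
}

#' Hypergeometric over-representation analysis
#'
#' One-sided upper-tail hypergeometric test of a hit set against each
#' gene set (sets are intersected with the universe first), with
#' Benjamini-Hochberg correction across sets. An overlap of zero has
#' upper-tail probability P(X >= 0) = 1.
#'
#' @param hits non-empty character vector, a subset of `universe`.
#' @param universe non-empty background gene universe.
#' @param geneSets named list of character vectors (e.g. from
#'   [readGMT()]).
#' @return data.frame: set, setSize, overlap, p, q.
#' @examples
#' oraEnrichment(paste0("g", 1:5), paste0("g", 1:10),
#'               list(S = paste0("g", c(1:4, 10))))
#' @export
oraEnrichment <- function(hits, universe, geneSets) {
  if (!length(universe)) stop("empty universe")
  if (!length(hits)) stop("empty hit set")
  if (!all(hits %in% universe)) stop("hits must be a subset of the universe")
  N <- length(unique(universe))
  n <- length(unique(hits))
  rows <- lapply(names(geneSets), function(nm) {
    set <- intersect(geneSets[[nm]], universe)
    K <- length(set)
    k <- length(intersect(hits, set))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, setSize = K, overlap = k, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Run the full signature-discovery pipeline
#'
#' Executes the discovery funnel on a bundle of inputs: (1) one-way ANOVA
#' filter on the time course; (2) short time-series profile assignment
#' with permutation significance; (3) cluster eigengene vs SF2 screen on
#' the untreated baseline; (4) single-gene RF importance + SGLQ fits with
#' the fail-both exclusion; (5) four-layer network construction
#' (mutation-heat diffusion, CNA-heat diffusion, co-expression modules,
#' confidence-filtered protein edges), union graph on the surviving
#' candidates, and the median-centrality hub rule. Final candidates are
#' the hub genes; over-representation of the final set is tested against
#' the bundle's gene sets, and when ground truth is available precision
#' and recall against the planted signature are attached.
#'
#' If no profile cluster reaches significance the run returns cleanly
#' with status `"no_significant_clusters"` and an empty candidate list;
#' any later stage emptying the gene set aborts with a stage-named error.
#' Fixed seed and inputs give identical reports.
#'
#' @param bundle list with tce, sf2, layers, geneSets and optionally
#'   truth, as from [simulateBundle()] or [readFixtureBundle()].
#' @param config a [pipelineConfig()].
#' @return a \linkS4class{CandidateReport}.
#' @export
runPipeline <- function(bundle, config = pipelineConfig()) {
  stopifnot(is(bundle$tce, "TimeCourseExperiment"),
            is(bundle$sf2, "RadiosensitivityTable"))
  tce <- bundle$tce
  seeds <- deriveSeeds(config$seed, 6)
  allGenes <- rownames(tce)

  ## stage 1: ANOVA time-response filter
  an <- anovaFilter(tce, alpha = config$anova$alpha)
  genes1 <- an$gene[an$keep]
  if (!length(genes1)) stop("stage anova: no time-responsive genes")

  ## stage 2: profile assignment + permutation significance
  lib <- buildProfileLibrary(length(hours(tce)), config$stem$maxUnitChange,
                             config$stem$m)
  tceF <- methods::as(tce[genes1, ], "TimeCourseExperiment")
  asn <- assignGenes(tceF, lib)
  asn <- profileSignificance(tceF, lib, asn, nPerm = config$stem$nPerm,
                             qThreshold = config$stem$qThreshold,
                             seed = seeds[1])
  st <- clusterStats(asn)
  sigProfiles <- which(st$significant)
  funnelRows <- list(data.frame(stage = "anova", n_in = length(allGenes),
                                n_out = length(genes1)))
  if (!length(sigProfiles)) {
    funnelRows[[2]] <- data.frame(stage = "profile_clusters",
                                  n_in = length(genes1), n_out = 0L)
    return(new("CandidateReport",
               candidates = data.frame(gene = character(0)),
               clusters = st,
               funnel = finishFunnel(funnelRows),
               enrichment = data.frame(), hubReport = NULL,
               status = "no_significant_clusters",
               truthMetrics = numeric(0), config = unclass(config)))
  }
  clusterOf <- assignments(asn)
  genes2a <- names(clusterOf)[clusterOf %in% sigProfiles]
  funnelRows[[2]] <- data.frame(stage = "profile_clusters",
                                n_in = length(genes1),
                                n_out = length(genes2a))

  ## stage 3: cluster eigengene vs SF2 screen on untreated baseline
  baseline <- baselineMatrix(tce)
  eigs <- lapply(sigProfiles, function(pid)
    clusterEigenvalue(baseline, names(clusterOf)[clusterOf == pid],
                      clusterId = st$profile[pid]))
  scr <- screenClusters(eigs, bundle$sf2,
                        threshold = config$screen$threshold,
                        use = config$screen$use)
  clusterTable <- st
  clusterTable$sf2Cor <- NA_real_
  clusterTable$sf2Pass <- NA
  clusterTable$sf2Cor[sigProfiles] <- scr$cor
  clusterTable$sf2Pass[sigProfiles] <- scr$pass
  passProfiles <- sigProfiles[scr$pass]
  genes2 <- names(clusterOf)[clusterOf %in% passProfiles]
  funnelRows[[3]] <- data.frame(stage = "sf2_cluster_screen",
                                n_in = length(genes2a),
                                n_out = length(genes2))
  if (!length(genes2)) stop("stage sf2_cluster_screen: no genes retained")

  ## stage 4: single-gene RF + SGLQ, fail-both exclusion
  imp <- rfImportance(baseline[genes2, , drop = FALSE], bundle$sf2,
                      nTrees = config$singleGene$nTrees, seed = seeds[2])
  sg <- sglqScreen(baseline[genes2, , drop = FALSE], bundle$sf2,
                   alphaLevel = config$singleGene$sglqAlpha)
  fb <- failBothFilter(imp, sg)
  genes3 <- fb$retained
  funnelRows[[4]] <- data.frame(stage = "fail_both_filter",
                                n_in = length(genes2),
                                n_out = length(genes3))
  if (!length(genes3)) stop("stage fail_both_filter: no genes retained")

  ## stage 5: four-layer network, union graph, hub screen
  net <- config$network
  mutDiff <- diffuseHeat(bundle$layers$mutation,
                         restartBeta = net$restartBeta, delta = net$delta,
                         kMin = net$kMin, hotQuantile = net$hotQuantile)
  cnaDiff <- diffuseHeat(bundle$layers$cna,
                         restartBeta = net$restartBeta, delta = net$delta,
                         kMin = net$kMin, hotQuantile = net$hotQuantile)
  coex <- suppressWarnings(
    coexpressionLayer(baseline, power = net$power,
                      minModuleSize = net$minModuleSize,
                      trait = sf2Values(bundle$sf2),
                      cutHeight = net$cutHeight, mergeCor = net$mergeCor,
                      edgeQuantile = net$edgeQuantile))
  prot <- layerEdges(bundle$layers$protein)
  prot <- prot[prot$weight >= net$proteinMinWeight, , drop = FALSE]
  unionLayers <- list(mutDiff@hotEdges, cnaDiff@hotEdges,
                      coex$layer, prot)
  scopeGenes <- if (identical(net$hubScope, "full")) allGenes else genes3
  ug <- unionGraph(unionLayers, scopeGenes)
  hubs <- hubScreen(ug, closenessType = net$closeness)
  finalGenes <- intersect(genes3, hubGenes(hubs))
  funnelRows[[5]] <- data.frame(stage = "hub_screen",
                                n_in = length(genes3),
                                n_out = length(finalGenes))

  ## evidence table for the final candidates
  ct <- centralityTable(hubs)
  rownames(ct) <- ct$node
  rownames(fb$table) <- fb$table$gene
  candidates <- data.frame(gene = finalGenes, stringsAsFactors = FALSE)
  if (length(finalGenes)) {
    candidates$cluster <- st$profile[clusterOf[finalGenes]]
    candidates$clusterCor <-
      scr$cor[match(candidates$cluster, scr$cluster)]
    candidates <- cbind(candidates,
                        fb$table[finalGenes, c("rfImportance", "rfPass",
                                               "alpha", "beta", "fPValue",
                                               "sglqPass")],
                        ct[finalGenes, c("degree", "betweenness",
                                         "closeness")])
    candidates <- candidates[order(-candidates$rfImportance), ]
    rownames(candidates) <- NULL
  }

  enr <- if (length(finalGenes) && length(bundle$geneSets))
    oraEnrichment(finalGenes, genes3, bundle$geneSets)
  else data.frame()

  tm <- numeric(0)
  report <- new("CandidateReport", candidates = candidates,
                clusters = clusterTable,
                funnel = finishFunnel(funnelRows), enrichment = enr,
                hubReport = hubs, status = "ok", truthMetrics = tm,
                config = unclass(config))
  if (!is.null(bundle$truth))
    report@truthMetrics <- unlist(evaluateAgainstTruth(report, bundle$truth))
  report
}

finishFunnel <- function(rows) {
  f <- do.call(rbind, rows)
  f$pct_retained <- pct1(f$n_out / f$n_in)
  f
}

#' Stage-by-stage funnel counts and percentages
#'
#' @param report a \linkS4class{CandidateReport}.
#' @return data.frame: stage, n_in, n_out, pct_retained, pct_excluded
#'   (one-decimal percentages of each stage's entry set).
#' @export
funnelSummary <- function(report) {
  stopifnot(is(report, "CandidateReport"))
  f <- funnel(report)
  f$pct_excluded <- pct1((f$n_in - f$n_out) / f$n_in)
  f
}

#' Precision and recall against the planted signature
#'
#' @param report a \linkS4class{CandidateReport}.
#' @param truth a \linkS4class{GroundTruth}.
#' @return list with precision, recall, nCandidates, nPlanted. Precision
#'   is defined as 0 when the candidate list is empty.
#' @export
evaluateAgainstTruth <- function(report, truth) {
  stopifnot(is(report, "CandidateReport"), is(truth, "GroundTruth"))
  cand <- candidateGenes(report)
  planted <- signatureGenes(truth)
  tp <- length(intersect(cand, planted))
  list(precision = if (length(cand)) tp / length(cand) else 0,
       recall = if (length(planted)) tp / length(planted) else NA_real_,
       nCandidates = length(cand), nPlanted = length(planted))
}
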