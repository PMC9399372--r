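#' Configure the synthetic radiosensitivity study
#'
#' Returns a \linkS4class{SimulationConfig} whose defaults define the
#' package's reference study conditions: 2,000 genes of which 20 are
#' planted signature genes and 300 are time-responsive decoys, a panel of
#' 24 cell lines profiled at 0, 2, 4, 8, 12 and 24 h after 2 Gy
#' irradiation, SF2 generated from the signature genes through the SGLQ
#' law SF = e^(alpha*E - beta*E^2) with log-scale noise, background
#' co-expression blocks, and an Erdos-Renyi interaction network with a
#' dense planted signature subgraph and elevated mutation/CNA heats on
#' signature genes. See the class documentation for every field.
#'
#' @param nGenes,nSignature,nResponsive gene-universe composition.
#' @param cellLines cell-line identifiers.
#' @param timepointsH strictly increasing hours post-irradiation.
#' @param nProfiles number of planted temporal archetypes.
#' @param maxUnitChange,libSize profile-library parameters.
#' @param profileAmplitude expression units per profile unit change.
#' @param sglqAlpha,sglqBeta generative SGLQ coefficients.
#' @param signatureLoading loading of signature baselines on the latent
#'   per-line radioresponse factor.
#' @param noiseSd,sf2NoiseSd expression / log-SF2 noise SDs.
#' @param nBlocks,blockSize,blockLoading background co-expression blocks.
#' @param meanDegree,signatureDensity interaction-network family.
#' @param heatFactor heat elevation on signature genes (1 = none).
#' @param proteinWeightRange uniform range for edge confidence weights.
#' @param seed integer RNG seed (every generator op derives child seeds
#'   from it, so a fixed seed gives a bit-identical bundle).
#' @return a validated \linkS4class{SimulationConfig}.
#' @export
simulationConfig <- function(nGenes = 2000, nSignature = 20,
                             nResponsive = 300,
                             cellLines = sprintf("CL%02d", 1:24),
                             timepointsH = c(0, 2, 4, 8, 12, 24),
                             nProfiles = 10, maxUnitChange = 2, libSize = 50,
                             profileAmplitude = 1, sglqAlpha = 0.05,
                             sglqBeta = 0.2, signatureLoading = 0.8,
                             noiseSd = 0.5, sf2NoiseSd = 0.1,
                             nBlocks = 4, blockSize = 60, blockLoading = 0.8,
                             meanDegree = 4, signatureDensity = 0.6,
                             heatFactor = 10, proteinWeightRange = c(0.4, 1),
                             seed = 20220810) {
  new("SimulationConfig",
      nGenes = as.integer(nGenes), nSignature = as.integer(nSignature),
      nResponsive = as.integer(nResponsive),
      cellLines = as.character(cellLines),
      timepointsH = as.numeric(timepointsH),
      nProfiles = as.integer(nProfiles),
      maxUnitChange = as.integer(maxUnitChange),
      libSize = as.integer(libSize),
      profileAmplitude = profileAmplitude, sglqAlpha = sglqAlpha,
      sglqBeta = sglqBeta, signatureLoading = signatureLoading,
      noiseSd = noiseSd, sf2NoiseSd = sf2NoiseSd,
      nBlocks = as.integer(nBlocks), blockSize = as.integer(blockSize),
      blockLoading = blockLoading, meanDegree = meanDegree,
      signatureDensity = signatureDensity, heatFactor = heatFactor,
      proteinWeightRange = proteinWeightRange, seed = as.integer(seed))
}

# Deterministic planted truth shared by every generator op: gene classes,
# archetype ids, SGLQ coefficients and heats all derive from cfg@seed, so
# simulateTimeCourse / simulateSF2 / simulateNetworkLayers agree without
# shared state.
planTruth <- function(cfg) {
  set.seed(childSeed(cfg@seed, 1))
  genes <- sprintf("G%04d", seq_len(cfg@nGenes))
  sig <- sort(sample(genes, cfg@nSignature))
  rest <- setdiff(genes, sig)
  decoys <- sort(sample(rest, cfg@nResponsive))
  blocks <- list()
  if (cfg@nBlocks > 0 && cfg@blockSize > 0)
    blocks <- lapply(seq_len(cfg@nBlocks), function(b)
      sort(sample(rest, min(cfg@blockSize, length(rest)))))
  profileId <- integer(0)
  if (length(c(sig, decoys))) {
    # signature genes share archetype 1; decoys cycle over the others so
    # the signature cluster's eigengene stays driven by the latent factor
    decoyIds <- if (cfg@nProfiles > 1)
      rep(2:cfg@nProfiles, length.out = length(decoys))
    else rep(1L, length(decoys))
    profileId <- setNames(c(rep(1L, length(sig)), as.integer(decoyIds)),
                          c(sig, decoys))
  }
  mut <- setNames(runif(cfg@nGenes, 0.01, 0.1), genes)
  cna <- setNames(abs(rnorm(cfg@nGenes, 0, 0.05)), genes)
  mut[sig] <- mut[sig] * cfg@heatFactor
  cna[sig] <- cna[sig] * cfg@heatFactor
  new("GroundTruth", signatureGenes = sig, responsiveGenes = decoys,
      alpha = setNames(rep(cfg@sglqAlpha, length(sig)), sig),
      beta = setNames(rep(cfg@sglqBeta, length(sig)), sig),
      profileId = profileId, mutationHeat = mut, cnaHeat = cna,
      blocks = blocks)
}

plantedLibrary <- function(cfg) {
  buildProfileLibrary(length(cfg@timepointsH), cfg@maxUnitChange,
                      cfg@libSize)
}

#' Simulate the post-irradiation time-course expression matrix
#'
#' Signature and decoy genes follow their planted temporal archetype
#' (a short time-series profile curve scaled by `profileAmplitude`) on top
#' of a per-line baseline; all other genes are time-independent noise.
#' Signature baselines load on a latent per-line radioresponse factor
#' (which later drives SF2) and block genes load on their block factor.
#' The matrix is emitted z-scored per gene across all samples, mirroring
#' Z-score integration of expression panels.
#'
#' @param cfg a \linkS4class{SimulationConfig}.
#' @return a \linkS4class{TimeCourseExperiment} of dimension
#'   nGenes x (cell lines x timepoints).
#' @export
simulateTimeCourse <- function(cfg) {
  stopifnot(is(cfg, "SimulationConfig"))
  validObject(cfg)
  truth <- planTruth(cfg)
  lib <- plantedLibrary(cfg)
  set.seed(childSeed(cfg@seed, 2))
  genes <- sprintf("G%04d", seq_len(cfg@nGenes))
  nL <- length(cfg@cellLines)
  nT <- length(cfg@timepointsH)
  u <- rnorm(nL)                               # latent radioresponse factor
  # Only signature and block genes carry a per-line baseline; all other
  # genes are time-independent iid noise, so the across-timepoint ANOVA
  # stays calibrated at its nominal level on null genes.
  base <- matrix(0, cfg@nGenes, nL,
                 dimnames = list(genes, cfg@cellLines))
  lam <- cfg@signatureLoading
  if (length(truth@signatureGenes))
    base[truth@signatureGenes, ] <-
      lam * rep(u, each = length(truth@signatureGenes)) +
      sqrt(1 - lam^2) *
        matrix(rnorm(length(truth@signatureGenes) * nL),
               length(truth@signatureGenes), nL)
  for (blk in truth@blocks) {
    v <- rnorm(nL)
    bl <- cfg@blockLoading
    base[blk, ] <- bl * rep(v, each = length(blk)) +
      sqrt(1 - bl^2) * matrix(rnorm(length(blk) * nL), length(blk), nL)
  }
  cellLine <- rep(cfg@cellLines, each = nT)
  hour <- rep(cfg@timepointsH, times = nL)
  m <- base[, rep(seq_len(nL), each = nT)]
  responsive <- names(truth@profileId)
  if (length(responsive)) {
    curves <- profileMatrix(lib)[truth@profileId, , drop = FALSE]
    m[responsive, ] <- m[responsive, ] +
      cfg@profileAmplitude * curves[, rep(seq_len(nT), times = nL)]
  }
  if (cfg@noiseSd > 0)
    m <- m + matrix(rnorm(length(m), 0, cfg@noiseSd), nrow(m), ncol(m))
  z <- t(scale(t(m)))
  z[!is.finite(z)] <- 0
  dimnames(z) <- list(genes, NULL)
  TimeCourseExperiment(z, cellLine, hour)
}

#' Generate SF2 from signature-gene expression through the SGLQ law
#'
#' Each line's log survival fraction is the mean SGLQ prediction
#' alpha*E - beta*E^2 over the planted signature genes, perturbed by
#' Gaussian noise on the log scale, exponentiated and clipped to (0, 1].
#'
#' @param cfg a \linkS4class{SimulationConfig} with nSignature > 0.
#' @param baseline numeric matrix, genes x cell lines (e.g.
#'   [baselineMatrix()] of the simulated experiment).
#' @return a \linkS4class{RadiosensitivityTable}.
#' @export
simulateSF2 <- function(cfg, baseline) {
  stopifnot(is(cfg, "SimulationConfig"), is.matrix(baseline))
  truth <- planTruth(cfg)
  if (!length(truth@signatureGenes))
    stop("cannot generate SF2 from an empty signature set")
  if (!all(truth@signatureGenes %in% rownames(baseline)))
    stop("baseline expression must cover all signature genes")
  if (!all(cfg@cellLines %in% colnames(baseline)))
    stop("baseline expression must cover all cell lines")
  set.seed(childSeed(cfg@seed, 3))
  E <- baseline[truth@signatureGenes, cfg@cellLines, drop = FALSE]
  lnSF <- colMeans(truth@alpha * E - truth@beta * E^2)
  if (cfg@sf2NoiseSd > 0)
    lnSF <- lnSF + rnorm(length(lnSF), 0, cfg@sf2NoiseSd)
  radiosensitivityTable(cfg@cellLines, pmin(exp(lnSF), 1))
}

#' Simulate the interaction network and the mutation/CNA heat layers
#'
#' The interaction graph is an Erdos-Renyi background with mean degree
#' `meanDegree`, on top of which the signature genes are rewired into a
#' dense subgraph (all pairs with probability `signatureDensity`); a
#' disconnected planted subgraph is a generation error. Edges carry
#' uniform confidence weights. Mutation heat is a background mutation
#' frequency and CNA heat the absolute deviation from neutral copy
#' number, both multiplied by `heatFactor` on signature genes.
#'
#' @param cfg a \linkS4class{SimulationConfig}.
#' @return named list of \linkS4class{NetworkLayer}s: mutation, cna,
#'   protein (the protein layer carries the confidence weights).
#' @export
simulateNetworkLayers <- function(cfg) {
  stopifnot(is(cfg, "SimulationConfig"))
  truth <- planTruth(cfg)
  set.seed(childSeed(cfg@seed, 4))
  genes <- sprintf("G%04d", seq_len(cfg@nGenes))
  p <- min(1, cfg@meanDegree / (cfg@nGenes - 1))
  g <- igraph::sample_gnp(cfg@nGenes, p)
  igraph::V(g)$name <- genes
  ed <- igraph::as_data_frame(g, what = "edges")
  sig <- truth@signatureGenes
  if (length(sig) >= 2) {
    pairs <- t(combn(sig, 2))
    keep <- runif(nrow(pairs)) < cfg@signatureDensity
    sigEdges <- data.frame(from = pairs[keep, 1], to = pairs[keep, 2],
                           stringsAsFactors = FALSE)
    ed <- rbind(ed[, c("from", "to")], sigEdges)
    key <- ifelse(ed$from < ed$to, paste(ed$from, ed$to),
                  paste(ed$to, ed$from))
    ed <- ed[!duplicated(key), , drop = FALSE]
    sigSub <- igraph::induced_subgraph(
      igraph::graph_from_data_frame(ed, directed = FALSE,
                                    vertices = data.frame(name = genes)),
      sig)
    if (!igraph::is_connected(sigSub))
      stop("planted signature subgraph is disconnected; ",
           "increase signatureDensity or meanDegree")
  }
  ed$weight <- runif(nrow(ed), cfg@proteinWeightRange[1],
                     cfg@proteinWeightRange[2])
  list(
    mutation = networkLayer("mutation",
                            data.frame(from = ed$from, to = ed$to, weight = 1),
                            heat = truth@mutationHeat, nodes = genes),
    cna = networkLayer("cna",
                       data.frame(from = ed$from, to = ed$to, weight = 1),
                       heat = truth@cnaHeat, nodes = genes),
    protein = networkLayer("protein", ed, nodes = genes))
}

#' Simulate a complete input bundle
#'
#' Composes the generator ops into the full set of pipeline inputs:
#' time-course expression, SF2 (drawn uniformly in (0.2, 0.95) when no
#' signature genes are planted, since the SGLQ generator then has nothing
#' to work from), network layers, GMT gene sets (the planted signature
#' plus random decoy sets) and the ground-truth record.
#'
#' @param cfg a \linkS4class{SimulationConfig}.
#' @return list with elements tce, sf2, layers, geneSets, truth, config.
#' @examples
#' cfg <- simulationConfig(nGenes = 120, nSignature = 8, nResponsive = 20,
#'                         cellLines = paste0("L", 1:8), nBlocks = 1,
#'                         blockSize = 15)
#' bundle <- simulateBundle(cfg)
#' bundle$tce
#' @export
simulateBundle <- function(cfg) {
  tce <- simulateTimeCourse(cfg)
  truth <- planTruth(cfg)
  sf2 <- if (cfg@nSignature > 0) {
    simulateSF2(cfg, baselineMatrix(tce))
  } else {
    set.seed(childSeed(cfg@seed, 3))
    radiosensitivityTable(cfg@cellLines,
                          runif(length(cfg@cellLines), 0.2, 0.95))
  }
  layers <- simulateNetworkLayers(cfg)
  set.seed(childSeed(cfg@seed, 5))
  genes <- sprintf("G%04d", seq_len(cfg@nGenes))
  geneSets <- list()
  if (cfg@nSignature > 0)
    geneSets$PLANTED_SIGNATURE <- truth@signatureGenes
  for (i in 1:3)
    geneSets[[paste0("RANDOM_SET_", i)]] <-
      sort(sample(genes, min(50, cfg@nGenes)))
  list(tce = tce, sf2 = sf2, layers = layers, geneSets = geneSets,
       truth = truth, config = cfg)
}

truthToList <- function(truth) {
  list(signature_genes = truth@signatureGenes,
       responsive_genes = truth@responsiveGenes,
       alpha = as.list(truth@alpha), beta = as.list(truth@beta),
       profile_id = as.list(truth@profileId),
       mutation_heat = as.list(truth@mutationHeat),
       cna_heat = as.list(truth@cnaHeat),
       blocks = truth@blocks)
}

listToTruth <- function(x) {
  new("GroundTruth",
      signatureGenes = as.character(unlist(x$signature_genes)),
      responsiveGenes = as.character(unlist(x$responsive_genes)),
      alpha = unlist(x$alpha), beta = unlist(x$beta),
      profileId = vapply(x$profile_id, as.integer, 1L),
      mutationHeat = unlist(x$mutation_heat),
      cnaHeat = unlist(x$cna_heat),
      blocks = lapply(x$blocks, function(b) as.character(unlist(b))))
}

#' Write / read a fixture bundle to a directory of plain-text files
#'
#' Emits expression, SF2, mutation/CNA heat and protein edge TSVs, the
#' gene sets as GMT, the planted truth as JSON, and a manifest JSON
#' listing every file with its MD5 checksum. A fixed generator seed gives
#' a bit-identical bundle (the manifest carries no timestamps).
#'
#' @param bundle list as returned by [simulateBundle()].
#' @param dir writable target directory (created if needed).
#' @return `writeFixtureBundle` returns the manifest (invisibly readable
#'   from `manifest.json`); `readFixtureBundle` returns the bundle list.
#' @export
writeFixtureBundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- c(expression = "expression.tsv", sf2 = "sf2.tsv",
             mutation_heat = "mutation_heat.tsv", cna_heat = "cna_heat.tsv",
             protein_edges = "protein_edges.tsv", gene_sets = "genesets.gmt",
             truth = "truth.json")
  paths <- file.path(dir, files)
  names(paths) <- names(files)
  tryCatch({
    writeExpressionTSV(bundle$tce, paths["expression"])
    writeSF2TSV(bundle$sf2, paths["sf2"])
    writeHeatTSV(nodeHeat(bundle$layers$mutation), paths["mutation_heat"])
    writeHeatTSV(nodeHeat(bundle$layers$cna), paths["cna_heat"])
    writeEdgeTSV(layerEdges(bundle$layers$protein), paths["protein_edges"])
    writeGMT(bundle$geneSets, paths["gene_sets"])
    jsonlite::write_json(truthToList(bundle$truth), paths["truth"],
                         auto_unbox = TRUE, digits = NA)
  }, error = function(e)
    stop("failed writing bundle under ", dir, ": ", conditionMessage(e)))
  manifest <- list(files = lapply(seq_along(paths), function(i)
    list(name = unname(files[i]),
         md5 = unname(tools::md5sum(paths[i])))))
  names(manifest$files) <- names(files)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' @rdname writeFixtureBundle
#' @export
readFixtureBundle <- function(dir) {
  need <- file.path(dir, c("expression.tsv", "sf2.tsv", "mutation_heat.tsv",
                           "cna_heat.tsv", "protein_edges.tsv",
                           "genesets.gmt"))
  missing <- need[!file.exists(need)]
  if (length(missing))
    stop("bundle files missing: ", paste(missing, collapse = ", "))
  tce <- readExpressionTSV(file.path(dir, "expression.tsv"))
  genes <- rownames(tce)
  edges <- readEdgeTSV(file.path(dir, "protein_edges.tsv"))
  layers <- list(
    mutation = networkLayer("mutation",
                            data.frame(from = edges$from, to = edges$to,
                                       weight = 1),
                            heat = readHeatTSV(file.path(dir,
                                                         "mutation_heat.tsv")),
                            nodes = genes),
    cna = networkLayer("cna",
                       data.frame(from = edges$from, to = edges$to,
                                  weight = 1),
                       heat = readHeatTSV(file.path(dir, "cna_heat.tsv")),
                       nodes = genes),
    protein = networkLayer("protein", edges, nodes = genes))
  truthPath <- file.path(dir, "truth.json")
  truth <- if (file.exists(truthPath))
    listToTruth(jsonlite::read_json(truthPath)) else NULL
  list(tce = tce, sf2 = readSF2TSV(file.path(dir, "sf2.tsv")),
       layers = layers, geneSets = readGMT(file.path(dir, "genesets.gmt")),
       truth = truth, config = NULL)
}
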