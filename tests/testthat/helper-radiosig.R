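# Shared fixtures and independent oracles for the test suite.

# Reduced-scale study conditions used across tests (small enough to keep the
# suite fast, large enough that planted clusters clear the permutation
# floor: cluster sizes are several times the permuted mean).
smallConfig <- function(seed = 7, ...) {
  args <- list(nGenes = 500, nSignature = 12, nResponsive = 105,
               nProfiles = 8, cellLines = sprintf("L%02d", 1:16),
               nBlocks = 2, blockSize = 30, seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(simulationConfig, args)
}

.cache <- new.env(parent = emptyenv())

# One small bundle + pipeline report, computed once per test run.
smallBundle <- function() {
  if (is.null(.cache$bundle)) .cache$bundle <- simulateBundle(smallConfig())
  .cache$bundle
}

smallReport <- function() {
  if (is.null(.cache$report))
    .cache$report <- runPipeline(smallBundle(),
                                 pipelineConfig(seed = 7,
                                                network = list(minModuleSize = 15)))
  .cache$report
}

# Random connected-ish undirected graph as a NetworkLayer with positive heats.
randomHeatLayer <- function(n, pEdge = 0.4, seed = 1) {
  set.seed(seed)
  a <- matrix(0, n, n)
  a[upper.tri(a)] <- runif(n * (n - 1) / 2) < pEdge
  a <- a + t(a)
  nodes <- paste0("n", seq_len(n))
  idx <- which(upper.tri(a) & a > 0, arr.ind = TRUE)
  edges <- if (nrow(idx)) {
    data.frame(from = nodes[idx[, 1]], to = nodes[idx[, 2]], weight = 1)
  } else {
    data.frame(from = character(0), to = character(0), weight = numeric(0))
  }
  networkLayer("mutation", edges,
               heat = setNames(runif(n, 0.1, 1), nodes), nodes = nodes)
}

# Dense-inversion diffusion oracle: one global walk matrix, no
# per-component decomposition (blocks are identical since W is
# block-diagonal across components).
diffusionOracle <- function(layer, beta) {
  nodes <- layer@nodes
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  ed <- layerEdges(layer)
  A[cbind(ed$from, ed$to)] <- 1
  A[cbind(ed$to, ed$from)] <- 1
  W <- sweep(A, 2, pmax(colSums(A), 1), "/")
  Fm <- beta * solve(diag(n) - (1 - beta) * W)
  Fm %*% diag(layer@heat[nodes], n)
}

# Brute-force shortest-path machinery via walk counting: A^k counts walks,
# and the shortest-path count equals the walk count at the distance.
bruteShortestPaths <- function(A) {
  n <- nrow(A)
  dist <- matrix(Inf, n, n)
  sigma <- matrix(0, n, n)
  diag(dist) <- 0
  diag(sigma) <- 1
  Ak <- diag(n)
  for (k in seq_len(n)) {
    Ak <- Ak %*% A
    newly <- is.infinite(dist) & Ak > 0
    dist[newly] <- k
    sigma[newly] <- Ak[newly]
  }
  list(dist = dist, sigma = sigma)
}

bruteBetweenness <- function(A) {
  sp <- bruteShortestPaths(A)
  n <- nrow(A)
  btw <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n - 1)) for (t in seq((s + 1), n)) {
      if (s == v || t == v || is.infinite(sp$dist[s, t])) next
      if (sp$dist[s, v] + sp$dist[v, t] == sp$dist[s, t])
        btw[v] <- btw[v] +
          sp$sigma[s, v] * sp$sigma[v, t] / sp$sigma[s, t]
    }
  }
  btw
}

bruteHarmonic <- function(A) {
  sp <- bruteShortestPaths(A)
  d <- sp$dist
  diag(d) <- Inf
  rowSums(1 / d)
}

layerToAdjacency <- function(layer) {
  nodes <- layer@nodes
  A <- matrix(0, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  ed <- layerEdges(layer)
  if (nrow(ed)) {
    A[cbind(ed$from, ed$to)] <- 1
    A[cbind(ed$to, ed$from)] <- 1
  }
  A
}

# Exhaustive hypergeometric upper tail by enumerating every possible draw.
enumHyperP <- function(N, K, n, k) {
  draws <- combn(N, n)
  inSet <- seq_len(K)
  overlaps <- apply(draws, 2, function(d) sum(d %in% inSet))
  mean(overlaps >= k)
}
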