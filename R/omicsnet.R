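layerGraph <- function(layer) {
  igraph::graph_from_data_frame(
    layer@edges[, c("from", "to"), drop = FALSE],
    directed = FALSE,
    vertices = data.frame(name = layer@nodes))
}

#' Insulated heat diffusion on a network layer
#'
#' Random-walk-with-restart heat diffusion in the HotNet2 style: with walk
#' matrix W (adjacency column-normalized by degree) and restart
#' probability beta, the diffusion operator is
#' F = beta * (I - (1-beta) W)^-1, computed per connected component, and
#' the exchanged heat is E[i,j] = F[i,j] * h[j] for node heats h. Layer
#' edges whose bidirectional exchange min(Eij, Eji) is strictly positive
#' and at least `delta` are "hot"; connected components of the hot-edge
#' graph with at least `kMin` nodes are returned as hot subnetworks. With
#' beta = 1 the walk always restarts, F = I, and no multi-node subnetwork
#' can form.
#'
#' HotNet2 selects delta by a permutation statistic; here `delta = NULL`
#' defaults to the `hotQuantile` quantile of the positive edge
#' min-exchange values (keep the hottest interactions), and any fixed
#' delta can be supplied instead.
#'
#' @param layer a \linkS4class{NetworkLayer} with heats for all nodes.
#' @param restartBeta restart probability in (0, 1] (default 0.4).
#' @param delta hot-edge threshold, or NULL for the quantile default.
#' @param kMin minimum subnetwork size (default 3).
#' @param hotQuantile quantile used when delta is NULL (default 0.95).
#' @return a \linkS4class{DiffusionResult}.
#' @export
diffuseHeat <- function(layer, restartBeta = 0.4, delta = NULL, kMin = 3,
                        hotQuantile = 0.95) {
  stopifnot(is(layer, "NetworkLayer"))
  if (restartBeta <= 0 || restartBeta > 1)
    stop("restartBeta must be in (0, 1]")
  h <- layer@heat[layer@nodes]
  if (any(is.na(h)))
    stop("heat missing for nodes: ",
         paste(head(layer@nodes[is.na(h)], 5), collapse = ", "))
  if (any(h < 0)) stop("heats must be non-negative")
  g <- layerGraph(layer)
  n <- length(layer@nodes)
  E <- matrix(0, n, n, dimnames = list(layer@nodes, layer@nodes))
  comp <- igraph::components(g)
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  for (ci in seq_len(comp$no)) {
    idx <- which(comp$membership == ci)
    Ac <- A[idx, idx, drop = FALSE]
    deg <- colSums(Ac)
    W <- sweep(Ac, 2, pmax(deg, 1), "/")
    Fc <- restartBeta * solve(diag(length(idx)) - (1 - restartBeta) * W)
    E[idx, idx] <- Fc %*% diag(h[idx], nrow = length(idx))
  }
  ed <- layer@edges
  hot <- data.frame(from = character(0), to = character(0),
                    exchange = numeric(0))
  if (nrow(ed)) {
    me <- pmin(E[cbind(ed$from, ed$to)], E[cbind(ed$to, ed$from)])
    if (is.null(delta)) {
      pos <- me[me > 0]
      delta <- if (length(pos)) unname(stats::quantile(pos, hotQuantile))
               else Inf
    }
    keep <- me > 0 & me >= delta
    hot <- data.frame(from = ed$from[keep], to = ed$to[keep],
                      exchange = me[keep], stringsAsFactors = FALSE)
  } else if (is.null(delta)) delta <- Inf
  hg <- igraph::graph_from_data_frame(hot[, c("from", "to")],
                                      directed = FALSE,
                                      vertices = data.frame(name = layer@nodes))
  hc <- igraph::components(hg)
  subs <- split(layer@nodes, hc$membership)
  subs <- unname(subs[vapply(subs, length, 1L) >= kMin])
  new("DiffusionResult", exchangedHeat = E, hotEdges = hot,
      subnetworks = subs, delta = delta, restartBeta = restartBeta)
}

#' Topological overlap from a soft adjacency matrix
#'
#' TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij) with
#' k_i the connectivity sum_u a_iu and unit diagonal by convention.
#'
#' @param a symmetric adjacency matrix with values in [0,1]; the diagonal
#'   is ignored.
#' @return the TOM matrix (symmetric, unit diagonal).
#' @examples
#' a <- matrix(0.5, 3, 3); diag(a) <- 0
#' tomSimilarity(a)    # all off-diagonal entries 0.5
#' @export
tomSimilarity <- function(a) {
  stopifnot(is.matrix(a), nrow(a) == ncol(a))
  diag(a) <- 0
  k <- rowSums(a)
  L <- a %*% a
  denom <- outer(k, k, pmin) + 1 - a
  tom <- (L + a) / denom
  diag(tom) <- 1
  tom
}

#' Build the co-expression layer by topological overlap clustering
#'
#' Weighted co-expression in the WGCNA tradition: soft adjacency
#' a = |pearson cor|^power, topological overlap (see [tomSimilarity()]),
#' average-linkage clustering of 1 - TOM cut at a fixed height, modules
#' below `minModuleSize` dropped to the unassigned label 0, and modules
#' whose eigengenes correlate above `mergeCor` merged. Each module is
#' summarized by its eigengene (PC1 via [clusterEigenvalue()]) and, when a
#' trait is supplied, by the Pearson eigengene-trait correlation. The
#' emitted network layer connects within-module gene pairs whose TOM
#' reaches the `edgeQuantile` quantile of within-module TOM values.
#'
#' @param expr numeric matrix, genes x samples; constant genes are dropped
#'   with a warning, and fewer than 20 samples triggers a warning.
#' @param power soft-thresholding power (default 6).
#' @param minModuleSize minimum module size (default 30).
#' @param trait optional named per-sample value (e.g. SF2) to correlate
#'   with module eigengenes.
#' @param cutHeight fixed tree-cut height on 1 - TOM (default 0.99).
#' @param mergeCor eigengene correlation above which modules merge
#'   (default 0.75).
#' @param edgeQuantile within-module TOM quantile defining layer edges
#'   (default 0.9).
#' @return list with elements `modules` (a
#'   \linkS4class{CoexpressionModules}) and `layer` (a
#'   \linkS4class{NetworkLayer} of kind "coexpression").
#' @export
coexpressionLayer <- function(expr, power = 6, minModuleSize = 30,
                              trait = NULL, cutHeight = 0.99,
                              mergeCor = 0.75, edgeQuantile = 0.9) {
  stopifnot(is.matrix(expr))
  if (ncol(expr) < 20)
    warning("fewer than 20 samples; co-expression estimates are noisy")
  sds <- apply(expr, 1, stats::sd)
  if (any(sds == 0)) {
    warning("dropping ", sum(sds == 0), " constant genes")
    expr <- expr[sds > 0, , drop = FALSE]
  }
  a <- abs(stats::cor(t(expr)))^power
  tom <- tomSimilarity(a)
  hc <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  labels <- stats::cutree(hc, h = cutHeight)
  sz <- table(labels)
  labels[labels %in% as.integer(names(sz[sz < minModuleSize]))] <- 0L
  labels <- relabelBySize(labels)
  labels <- mergeModules(expr, labels, mergeCor)
  mods <- sort(unique(labels[labels > 0]))
  eg <- if (length(mods)) {
    vapply(mods, function(m)
      clusterEigenvalue(expr, rownames(expr)[labels == m],
                        clusterId = paste0("M", m))@scores,
      numeric(ncol(expr)))
  } else matrix(numeric(0), ncol(expr), 0)
  if (length(mods)) {
    rownames(eg) <- colnames(expr)
    colnames(eg) <- paste0("M", mods)
  }
  mt <- numeric(0)
  if (!is.null(trait) && length(mods)) {
    tv <- trait[rownames(eg)]
    mt <- setNames(as.numeric(stats::cor(eg, tv)), colnames(eg))
  }
  edges <- moduleEdges(tom, labels, edgeQuantile)
  modulesObj <- new("CoexpressionModules", power = power, tom = tom,
                    labels = setNames(as.integer(labels), rownames(expr)),
                    eigengenes = eg, moduleTrait = mt)
  layer <- networkLayer("coexpression", edges, nodes = rownames(expr))
  list(modules = modulesObj, layer = layer)
}

relabelBySize <- function(labels) {
  pos <- labels[labels > 0]
  if (!length(pos)) return(labels)
  ord <- names(sort(table(pos), decreasing = TRUE))
  map <- setNames(seq_along(ord), ord)
  out <- labels
  out[labels > 0] <- map[as.character(pos)]
  as.integer(out)
}

mergeModules <- function(expr, labels, mergeCor) {
  repeat {
    mods <- sort(unique(labels[labels > 0]))
    if (length(mods) < 2) return(labels)
    eg <- vapply(mods, function(m)
      clusterEigenvalue(expr, rownames(expr)[labels == m])@scores,
      numeric(ncol(expr)))
    cc <- stats::cor(eg)
    diag(cc) <- -Inf
    if (max(cc) <= mergeCor) return(labels)
    ij <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    labels[labels == mods[max(ij)]] <- mods[min(ij)]
    labels <- relabelBySize(labels)
  }
}

moduleEdges <- function(tom, labels, edgeQuantile) {
  genes <- rownames(tom)
  rows <- list()
  within <- c()
  for (m in sort(unique(labels[labels > 0]))) {
    gs <- genes[labels == m]
    sub <- tom[gs, gs, drop = FALSE]
    within <- c(within, sub[upper.tri(sub)])
  }
  if (!length(within))
    return(data.frame(from = character(0), to = character(0),
                      weight = numeric(0)))
  thr <- stats::quantile(within, edgeQuantile)
  for (m in sort(unique(labels[labels > 0]))) {
    gs <- genes[labels == m]
    sub <- tom[gs, gs, drop = FALSE]
    idx <- which(upper.tri(sub) & sub >= thr, arr.ind = TRUE)
    if (nrow(idx))
      rows[[length(rows) + 1]] <- data.frame(
        from = gs[idx[, 1]], to = gs[idx[, 2]],
        weight = sub[idx], stringsAsFactors = FALSE)
  }
  if (length(rows)) do.call(rbind, rows)
  else data.frame(from = character(0), to = character(0),
                  weight = numeric(0))
}

#' Union of network layers induced on a candidate gene set
#'
#' Unweighted union of all layer edge sets restricted to candidate genes;
#' candidates without any edge are retained as isolated nodes so the
#' median-centrality rule sees the full candidate set.
#'
#' @param layers list of \linkS4class{NetworkLayer} objects (or objects
#'   with `from`/`to` edge data.frames).
#' @param candidates non-empty character vector of genes.
#' @return an [igraph::graph] on the candidate genes.
#' @export
unionGraph <- function(layers, candidates) {
  if (!length(candidates)) stop("candidate gene set is empty")
  eds <- lapply(layers, function(l) {
    e <- if (is(l, "NetworkLayer")) l@edges else as.data.frame(l)
    e[, c("from", "to"), drop = FALSE]
  })
  ed <- do.call(rbind, eds)
  ed <- ed[ed$from %in% candidates & ed$to %in% candidates, , drop = FALSE]
  if (nrow(ed)) {
    key <- ifelse(ed$from < ed$to, paste(ed$from, ed$to),
                  paste(ed$to, ed$from))
    ed <- ed[!duplicated(key), , drop = FALSE]
    ed <- ed[ed$from != ed$to, , drop = FALSE]
  }
  igraph::graph_from_data_frame(ed, directed = FALSE,
                                vertices = data.frame(name = candidates))
}

#' Call hub genes by the median-centrality rule
#'
#' Computes degree, shortest-path betweenness, and closeness (harmonic by
#' default, so disconnected graphs are handled without arbitrary
#' conventions; classic closeness via `closenessType = "classic"`). A node
#' is a hub iff all three centralities are strictly greater than their
#' medians over the nodes; ties at the median are not hubs, and a graph
#' with identical centralities everywhere has no hubs.
#'
#' @param graph an [igraph::graph]; edge weights are ignored.
#' @param closenessType "harmonic" (default) or "classic".
#' @return a \linkS4class{HubReport}.
#' @export
hubScreen <- function(graph, closenessType = c("harmonic", "classic")) {
  closenessType <- match.arg(closenessType)
  stopifnot(igraph::vcount(graph) >= 1)
  deg <- igraph::degree(graph)
  btw <- igraph::betweenness(graph, weights = NA)
  clo <- if (closenessType == "harmonic")
    igraph::harmonic_centrality(graph, weights = NA, normalized = FALSE)
  else suppressWarnings(igraph::closeness(graph, weights = NA))
  clo[is.na(clo)] <- 0
  med <- c(degree = stats::median(deg), betweenness = stats::median(btw),
           closeness = stats::median(clo))
  tab <- data.frame(node = igraph::V(graph)$name, degree = unname(deg),
                    betweenness = unname(btw), closeness = unname(clo),
                    stringsAsFactors = FALSE)
  tab$hub <- tab$degree > med["degree"] &
    tab$betweenness > med["betweenness"] &
    tab$closeness > med["closeness"]
  new("HubReport", table = tab, medians = med,
      closenessType = closenessType)
}
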