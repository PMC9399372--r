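test_that("pure restart produces diagonal exchange and no subnetworks", {
  l <- randomHeatLayer(6, seed = 3)
  d <- diffuseHeat(l, restartBeta = 1, delta = 0, kMin = 2)
  E <- d@exchangedHeat
  expect_equal(E[upper.tri(E) | lower.tri(E)],
               rep(0, length(E[upper.tri(E) | lower.tri(E)])))
  expect_equal(diag(E), nodeHeat(l)[l@nodes], ignore_attr = TRUE)
  expect_length(d@subnetworks, 0)
})

test_that("three-node path matches the dense-inversion oracle", {
  edges <- data.frame(from = c("A", "B"), to = c("B", "C"), weight = 1)
  l <- networkLayer("mutation", edges,
                    heat = c(A = 1, B = 0.5, C = 0.2),
                    nodes = c("A", "B", "C"))
  d <- diffuseHeat(l, restartBeta = 0.5, delta = 0, kMin = 1)
  W <- matrix(c(0, 1, 0,
                0.5, 0, 0.5,
                0, 1, 0), 3, 3)   # columns normalized by degree
  # W[i,j] = A[i,j]/deg(j): build explicitly
  A <- matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3, 3)
  W <- sweep(A, 2, colSums(A), "/")
  oracle <- 0.5 * solve(diag(3) - 0.5 * W) %*% diag(c(1, 0.5, 0.2))
  expect_equal(unname(d@exchangedHeat), oracle, tolerance = 1e-12)
})

test_that("diffusion equals dense inversion on random small graphs", {
  for (s in 1:20) {
    n <- sample(3:10, 1)
    l <- randomHeatLayer(n, pEdge = 0.45, seed = 1000 + s)
    beta <- runif(1, 0.2, 0.9)
    d <- diffuseHeat(l, restartBeta = beta, delta = 0, kMin = 1)
    expect_equal(unname(d@exchangedHeat),
                 unname(diffusionOracle(l, beta)), tolerance = 1e-10)
  }
})

test_that("zero threshold recovers the layer's connected components", {
  edges <- data.frame(from = c("A", "B", "D"), to = c("B", "C", "E"),
                      weight = 1)
  l <- networkLayer("mutation", edges,
                    heat = setNames(rep(1, 6), c(LETTERS[1:5], "Z")),
                    nodes = c(LETTERS[1:5], "Z"))
  d <- diffuseHeat(l, restartBeta = 0.4, delta = 0, kMin = 1)
  comps <- lapply(d@subnetworks, sort)
  expect_setequal(comps, list(c("A", "B", "C"), c("D", "E"), "Z"))
})

test_that("diffusion conserves injected heat per source column", {
  # ring plus chords: every column of the walk matrix sums to one, so the
  # closed-form column sum of the diffusion operator is exactly one and
  # each source's heat is fully redistributed
  nodes <- paste0("n", 1:8)
  edges <- data.frame(from = nodes[c(1:8, 1, 3)],
                      to = nodes[c(2:8, 1, 5, 7)], weight = 1)
  set.seed(77)
  l <- networkLayer("mutation", edges,
                    heat = setNames(runif(8, 0.1, 1), nodes), nodes = nodes)
  d <- diffuseHeat(l, restartBeta = 0.3, delta = 0, kMin = 1)
  expect_equal(colSums(d@exchangedHeat), nodeHeat(l)[l@nodes],
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("diffusion rejects invalid parameters", {
  l <- randomHeatLayer(5, seed = 2)
  expect_error(diffuseHeat(l, restartBeta = 0), "restartBeta")
  expect_error(diffuseHeat(l, restartBeta = 1.2), "restartBeta")
  bad <- l
  bad@heat[1] <- -1
  expect_error(diffuseHeat(bad, 0.5), "non-negative")
})

test_that("TOM matches the hand-computed triangle and its conventions", {
  a <- matrix(0.5, 3, 3)
  diag(a) <- 0
  tom <- tomSimilarity(a)
  # (0.25 + 0.5) / (min(1,1) + 1 - 0.5) = 0.5
  expect_equal(tom[upper.tri(tom)], rep(0.5, 3), tolerance = 1e-12)
  expect_equal(diag(tom), rep(1, 3))
  # symmetry and unit diagonal on a random soft adjacency
  set.seed(8)
  r <- matrix(runif(49), 7, 7)
  r <- (r + t(r)) / 2
  tr <- tomSimilarity(r)
  expect_equal(tr, t(tr), tolerance = 1e-12)
  expect_true(all(tr >= 0 & tr <= 1 + 1e-12))
})

test_that("block-structured expression yields intact co-expression modules", {
  set.seed(14)
  nS <- 30
  f1 <- rnorm(nS); f2 <- rnorm(nS)
  b1 <- t(vapply(1:12, function(i) 2 * f1 + rnorm(nS, 0, 1e-4),
                 numeric(nS)))
  b2 <- t(vapply(1:12, function(i) -f2 + rnorm(nS, 0, 1e-4),
                 numeric(nS)))
  expr <- rbind(b1, b2)
  rownames(expr) <- c(paste0("a", 1:12), paste0("b", 1:12))
  colnames(expr) <- paste0("S", 1:nS)
  cx <- coexpressionLayer(expr, power = 6, minModuleSize = 5)
  labels <- cx$modules@labels
  expect_equal(length(unique(labels[labels > 0])), 2)
  expect_equal(length(unique(labels[paste0("a", 1:12)])), 1)
  expect_equal(length(unique(labels[paste0("b", 1:12)])), 1)
  expect_true(labels[["a1"]] != labels[["b1"]])

  # a trait equal to a module eigengene correlates perfectly with it
  trait <- setNames(cx$modules@eigengenes[, 1],
                    rownames(cx$modules@eigengenes))
  cx2 <- coexpressionLayer(expr, power = 6, minModuleSize = 5, trait = trait)
  expect_equal(max(abs(cx2$modules@moduleTrait)), 1, tolerance = 1e-8)
})

test_that("constant genes are dropped from co-expression with a warning", {
  set.seed(15)
  expr <- rbind(matrix(rnorm(4 * 25), 4, 25), flat = rep(1, 25))
  rownames(expr)[1:4] <- paste0("g", 1:4)
  colnames(expr) <- paste0("S", 1:25)
  expect_warning(cx <- coexpressionLayer(expr, minModuleSize = 2),
                 "constant")
  expect_false("flat" %in% names(cx$modules@labels))
})

test_that("union graph is idempotent, additive and keeps isolated nodes", {
  l1 <- data.frame(from = c("a", "b"), to = c("b", "c"))
  l2 <- data.frame(from = "d", to = "e")
  cand <- letters[1:6]
  g1 <- unionGraph(list(l1, l1), cand)
  expect_equal(igraph::ecount(g1), 2)              # idempotence
  g2 <- unionGraph(list(l1, l2), cand)
  expect_equal(igraph::ecount(g2), 3)              # disjoint additivity
  expect_equal(igraph::vcount(g2), 6)              # f kept though isolated
  g3 <- unionGraph(list(l1), "z")
  expect_equal(igraph::vcount(g3), 1)
  expect_equal(igraph::ecount(g3), 0)
  expect_error(unionGraph(list(l1), character(0)), "empty")
})

test_that("hub screen resolves the star and the complete graph", {
  star <- igraph::make_star(4, mode = "undirected", center = 1)
  igraph::V(star)$name <- c("hub", "a", "b", "c")
  hr <- hubScreen(star)
  tab <- centralityTable(hr)
  expect_equal(tab$degree, c(3, 1, 1, 1))
  expect_equal(tab$betweenness, c(3, 0, 0, 0))
  expect_equal(tab$closeness, c(3, 2, 2, 2))       # harmonic
  expect_identical(hubGenes(hr), "hub")

  full <- igraph::make_full_graph(5)
  igraph::V(full)$name <- paste0("n", 1:5)
  expect_length(hubGenes(hubScreen(full)), 0)      # strict > median
})

test_that("hub screen is invariant under node relabeling", {
  set.seed(33)
  l <- randomHeatLayer(7, pEdge = 0.5, seed = 33)
  g <- radiosig:::layerGraph(l)
  hr1 <- hubScreen(g)
  perm <- sample(7)
  g2 <- igraph::permute(g, perm)
  hr2 <- hubScreen(g2)
  t1 <- centralityTable(hr1); t2 <- centralityTable(hr2)
  expect_setequal(t1$node[t1$hub], t2$node[t2$hub])
  expect_equal(sort(t1$betweenness), sort(t2$betweenness))
})

test_that("centralities match brute-force path enumeration on small graphs", {
  for (s in 1:20) {
    n <- sample(4:8, 1)
    l <- randomHeatLayer(n, pEdge = 0.5, seed = 2000 + s)
    A <- layerToAdjacency(l)
    hr <- hubScreen(radiosig:::layerGraph(l))
    tab <- centralityTable(hr)
    expect_equal(tab$betweenness, bruteBetweenness(A), tolerance = 1e-10)
    expect_equal(tab$closeness, unname(bruteHarmonic(A)), tolerance = 1e-10)
  }
})

test_that("classic closeness is available behind the flag", {
  g <- igraph::make_ring(4)
  igraph::V(g)$name <- paste0("n", 1:4)
  hr <- hubScreen(g, closenessType = "classic")
  expect_equal(centralityTable(hr)$closeness, rep(1 / 4, 4))
})
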