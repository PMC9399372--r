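# internal numerical helpers

# Row-wise one-way ANOVA F statistics and p-values.
# x: genes x samples matrix; group: factor of length ncol(x).
# Degenerate rows (total sum of squares ~ 0) get F = 0, p = 1; rows with
# zero within-group variance but distinct means get F = Inf, p = 0.
rowAnova <- function(x, group) {
  group <- as.factor(group)
  k <- nlevels(group)
  n <- ncol(x)
  if (k < 2) stop("need at least two groups")
  counts <- as.vector(table(group))
  if (any(counts < 2)) stop("need at least two replicates per group")
  ind <- stats::model.matrix(~ 0 + group)         # n x k indicator
  gm <- (x %*% ind) %*% diag(1 / counts, k)        # group means
  rm_ <- rowMeans(x)
  ssb <- as.vector((gm - rm_)^2 %*% counts)
  sst <- rowSums((x - rm_)^2)
  ssw <- pmax(sst - ssb, 0)
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  p <- stats::pf(f, k - 1, n - k, lower.tail = FALSE)
  tol <- 1e-12 * pmax(sst, 1)
  degenerate <- sst < 1e-12
  f[degenerate] <- 0
  p[degenerate] <- 1
  exact <- !degenerate & ssw < tol & ssb > tol
  f[exact] <- Inf
  p[exact] <- 0
  genes <- rownames(x)
  if (is.null(genes)) genes <- paste0("gene", seq_len(nrow(x)))
  data.frame(gene = genes, F = f, p = p,
             row.names = NULL, stringsAsFactors = FALSE)
}

# All permutations of 1:n as an (n!) x n matrix, in lexicographic-ish order.
allPermutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- allPermutations(n - 1)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (i in seq_len(n)) {
    rows <- r + seq_len(nrow(sub))
    out[rows, 1] <- i
    rest <- seq_len(n)[-i]
    out[rows, -1] <- matrix(rest[sub], nrow(sub), n - 1)
    r <- r + nrow(sub)
  }
  out
}

# Deterministic child seeds below 2^31, derived from one parent seed.
deriveSeeds <- function(seed, n) {
  (as.numeric(seed) * 48271 + 7919 * seq_len(n)) %% 2147483647
}

# The k-th child seed, as an integer ready for set.seed().
childSeed <- function(seed, k) {
  as.integer(deriveSeeds(seed, k)[k])
}

# Per-gene per-timepoint mean matrix (genes x timepoints, ordered by hour).
timepointMeans <- function(tce) {
  cd <- SummarizedExperiment::colData(tce)
  hs <- sort(unique(cd$hour))
  x <- SummarizedExperiment::assay(tce, "exprs")
  out <- vapply(hs, function(h)
    rowMeans(x[, cd$hour == h, drop = FALSE]), numeric(nrow(x)))
  out <- matrix(out, nrow = nrow(x),
                dimnames = list(rownames(x), paste0("t", hs)))
  out
}

# Pearson correlation between rows of a and rows of b (both p columns),
# returning nrow(a) x nrow(b); rows with zero variance give NA.
rowCorRows <- function(a, b) {
  suppressWarnings(stats::cor(t(a), t(b)))
}

pct1 <- function(x) round(100 * x, 1)
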