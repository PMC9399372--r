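#' Summarize a gene cluster by its first principal component
#'
#' The cluster eigengene: PC1 of the member x cell-line submatrix with
#' genes standardized first. Since the sign of a principal component is
#' arbitrary, the score series is oriented so that it correlates
#' non-negatively with the members' mean standardized profile; this makes
#' downstream correlations reproducible across linear-algebra backends.
#'
#' @param expr numeric matrix, genes x cell lines (untreated/baseline
#'   expression).
#' @param members character vector of member genes; all must be rows of
#'   `expr`.
#' @param clusterId label carried through to the result.
#' @return a \linkS4class{ClusterEigenvalue}.
#' @examples
#' m <- matrix(rnorm(40), 5, 8,
#'             dimnames = list(paste0("g", 1:5), paste0("L", 1:8)))
#' clusterEigenvalue(m, c("g1", "g3", "g5"))
#' @export
clusterEigenvalue <- function(expr, members, clusterId = "cluster") {
  missing <- setdiff(members, rownames(expr))
  if (length(missing))
    stop("cluster members absent from expression matrix: ",
         paste(missing, collapse = ", "))
  x <- expr[members, , drop = FALSE]
  z <- t(scale(t(x)))
  z[!is.finite(z)] <- 0        # constant members carry no information
  pc <- stats::prcomp(t(z), center = TRUE, scale. = FALSE)
  scores <- pc$x[, 1]
  loadings <- pc$rotation[, 1]
  vexp <- pc$sdev[1]^2 / max(sum(pc$sdev^2), .Machine$double.eps)
  meanProfile <- colMeans(z)
  orient <- suppressWarnings(stats::cor(scores, meanProfile))
  if (is.na(orient)) orient <- sign(loadings[which(loadings != 0)[1]])
  if (!is.na(orient) && orient < 0) {
    scores <- -scores
    loadings <- -loadings
  }
  new("ClusterEigenvalue", clusterId = as.character(clusterId),
      loadings = setNames(as.numeric(loadings), members),
      scores = setNames(as.numeric(scores), colnames(expr)),
      varExplained = vexp)
}

# Spearman correlation with the degenerate-series convention rho = 0
spearmanOrZero <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  suppressWarnings(stats::cor(x, y, method = "spearman"))
}

#' Screen cluster eigengenes by correlation with SF2
#'
#' Spearman correlation between each cluster's PC1 score series and SF2
#' over the shared cell lines. By default a cluster is retained when the
#' absolute correlation exceeds `threshold`, so protective (negative)
#' clusters are kept; set `use = "signed"` to require cor > threshold.
#' A constant score series has no defined rank correlation and is reported
#' as 0, so batch screening never aborts.
#'
#' @param eigs list of \linkS4class{ClusterEigenvalue} objects.
#' @param sf2 a \linkS4class{RadiosensitivityTable}.
#' @param threshold correlation cutoff (default 0.1).
#' @param use "absolute" (default) or "signed".
#' @return data.frame with cluster, cor, pass.
#' @export
screenClusters <- function(eigs, sf2, threshold = 0.1,
                           use = c("absolute", "signed")) {
  use <- match.arg(use)
  stopifnot(is(sf2, "RadiosensitivityTable"))
  sv <- sf2Values(sf2)
  rows <- lapply(eigs, function(e) {
    shared <- intersect(names(e@scores), names(sv))
    if (length(shared) < 3)
      stop("fewer than 3 shared cell lines for cluster ", e@clusterId)
    rho <- spearmanOrZero(e@scores[shared], sv[shared])
    data.frame(cluster = e@clusterId, cor = rho, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$pass <- if (use == "absolute") abs(out$cor) > threshold
              else out$cor > threshold
  out
}

#' Spearman correlation of a single gene with SF2
#'
#' Validation-panel statistic: Spearman rho and two-sided p-value between
#' one gene's expression and SF2 over the shared cell lines (exact p when
#' sample size and ties permit, via [stats::cor.test()]).
#'
#' @param expr numeric matrix, genes x cell lines.
#' @param gene gene identifier (must be a row of `expr`).
#' @param sf2 a \linkS4class{RadiosensitivityTable}.
#' @return list with elements rho and p.
#' @export
correlateGeneSF2 <- function(expr, gene, sf2) {
  if (!gene %in% rownames(expr))
    stop("gene not in expression matrix: ", gene)
  sv <- sf2Values(sf2)
  shared <- intersect(colnames(expr), names(sv))
  if (length(shared) < 3) stop("fewer than 3 shared cell lines")
  x <- expr[gene, shared]
  y <- sv[shared]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = 0, p = 1))
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value)
}
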