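#' Fit the single-gene linear-quadratic (SGLQ) model
#'
#' The SGLQ model transfers the classical radiobiology dose-survival law
#' to gene expression: SF = e^(alpha*E - beta*E^2), where E is the
#' expression of one gene across cell lines. On the log scale this is
#' linear in (alpha, beta) with no intercept, so the fit is ordinary least
#' squares of ln(SF2) on (E, E^2) through the origin; the prediction at
#' E = 0 is therefore exactly SF = 1. Because E is typically z-scored and
#' can be negative, alpha and beta are not sign-constrained.
#'
#' The reported pass flag uses the overall no-intercept regression F-test
#' at level `alphaLevel`. A rank-deficient design (for example constant
#' expression) cannot be fit and yields pass = FALSE with NA coefficients.
#'
#' @param e named numeric vector of one gene's expression per cell line.
#' @param sf2 a \linkS4class{RadiosensitivityTable}; all SF2 in (0, 1].
#' @param gene identifier carried into the result.
#' @param alphaLevel F-test significance level for the pass flag.
#' @return an \linkS4class{SGLQFit}.
#' @examples
#' e <- c(A = -1, B = 0, C = 1, D = 2)
#' sf2 <- radiosensitivityTable(names(e), exp(0.2 * e - 0.2 * e^2))
#' fitSGLQ(e, sf2)
#' @export
fitSGLQ <- function(e, sf2, gene = "gene", alphaLevel = 0.05) {
  stopifnot(is(sf2, "RadiosensitivityTable"))
  sv <- sf2Values(sf2)
  shared <- intersect(names(e), names(sv))
  if (length(shared) < 3) stop("fewer than 3 shared cell lines")
  x <- as.numeric(e[shared])
  y <- log(sv[shared])
  X <- cbind(E = x, E2 = x^2)
  if (qr(X)$rank < 2)
    return(new("SGLQFit", gene = gene, alpha = NA_real_, beta = NA_real_,
               r2Log = NA_real_, fPValue = NA_real_, pass = FALSE))
  fit <- stats::lm.fit(X, y)
  cf <- fit$coefficients
  rss <- sum(fit$residuals^2)
  tss <- sum(y^2)                       # no-intercept convention
  n <- length(y)
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  mss <- sum((y - fit$residuals)^2)
  fstat <- (mss / 2) / (rss / (n - 2))
  p <- if (!is.finite(fstat) || mss == 0) 1
       else stats::pf(fstat, 2, n - 2, lower.tail = FALSE)
  new("SGLQFit", gene = gene,
      alpha = unname(cf["E"]), beta = -unname(cf["E2"]),
      r2Log = unname(r2), fPValue = unname(p),
      pass = isTRUE(p < alphaLevel))
}

#' Predicted survival fraction under an SGLQ fit
#'
#' @param fit an \linkS4class{SGLQFit}.
#' @param e expression values at which to predict.
#' @return predicted SF = e^(alpha*e - beta*e^2).
#' @export
predictSF <- function(fit, e) {
  stopifnot(is(fit, "SGLQFit"))
  exp(fit@alpha * e - fit@beta * e^2)
}

#' Batch SGLQ screen over a gene panel
#'
#' @param expr numeric matrix, genes x cell lines.
#' @param sf2 a \linkS4class{RadiosensitivityTable}.
#' @param alphaLevel F-test level for the per-gene pass flag.
#' @return data.frame: gene, alpha, beta, r2Log, fPValue, sglqPass.
#' @export
sglqScreen <- function(expr, sf2, alphaLevel = 0.05) {
  rows <- lapply(rownames(expr), function(g) {
    f <- fitSGLQ(setNames(expr[g, ], colnames(expr)), sf2, gene = g,
                 alphaLevel = alphaLevel)
    data.frame(gene = g, alpha = f@alpha, beta = f@beta, r2Log = f@r2Log,
               fPValue = f@fPValue, sglqPass = f@pass,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Random-forest permutation importance of genes for SF2
#'
#' Trains one regression forest predicting SF2 from all candidate genes
#' jointly and reports each gene's permutation importance, the increase in
#' out-of-bag mean-squared error when the gene is permuted (unscaled). A
#' gene passes when its importance is strictly positive. Deterministic
#' under a fixed seed.
#'
#' @param expr numeric matrix, genes x cell lines (>= 5 cell lines).
#' @param sf2 a \linkS4class{RadiosensitivityTable}.
#' @param nTrees number of trees (default 500).
#' @param seed mandatory integer seed.
#' @param mtry predictors tried per split; default max(1, p/3) as usual
#'   for regression forests.
#' @return data.frame: gene, rfImportance, rfPass.
#' @export
rfImportance <- function(expr, sf2, nTrees = 500, seed,
                         mtry = max(1, floor(nrow(expr) / 3))) {
  if (missing(seed)) stop("rfImportance requires an explicit seed")
  if (nTrees < 1) stop("nTrees must be at least 1")
  sv <- sf2Values(sf2)
  shared <- intersect(colnames(expr), names(sv))
  if (length(shared) < 5) stop("need at least 5 shared cell lines")
  x <- t(expr[, shared, drop = FALSE])
  set.seed(as.integer(seed %% 2147483647))
  fit <- randomForest::randomForest(x = x, y = sv[shared], ntree = nTrees,
                                    mtry = min(mtry, nrow(expr)),
                                    importance = TRUE)
  imp <- randomForest::importance(fit, type = 1, scale = FALSE)[, 1]
  data.frame(gene = rownames(expr), rfImportance = unname(imp[rownames(expr)]),
             rfPass = unname(imp[rownames(expr)] > 0),
             stringsAsFactors = FALSE)
}

#' Exclude genes that fail both the RF and the SGLQ screen
#'
#' A gene is excluded iff it fails both single-gene models; passing either
#' one keeps it, so the filter is monotone in the pass flags. The report
#' carries counts and one-decimal percentages of the excluded and retained
#' fractions.
#'
#' @param importances data.frame from [rfImportance()].
#' @param sglqFits data.frame from [sglqScreen()].
#' @return list: retained (character), excluded (character), report
#'   (data.frame with n and pct rows), table (merged per-gene flags).
#' @export
failBothFilter <- function(importances, sglqFits) {
  if (!setequal(importances$gene, sglqFits$gene))
    stop("RF and SGLQ analyses cover different gene sets")
  tab <- merge(importances, sglqFits, by = "gene", sort = TRUE)
  tab$failsBoth <- !tab$rfPass & !tab$sglqPass
  total <- nrow(tab)
  nExcl <- sum(tab$failsBoth)
  report <- data.frame(
    class = c("excluded", "retained"),
    n = c(nExcl, total - nExcl),
    pct = c(pct1(nExcl / total), pct1((total - nExcl) / total)))
  list(retained = tab$gene[!tab$failsBoth],
       excluded = tab$gene[tab$failsBoth],
       report = report, table = tab)
}

#' Dose-linearity check by polynomial AIC
#'
#' For expression measured over a ladder of radiation doses, fits
#' polynomials of the requested degrees per gene and selects the degree
#' minimizing AIC = n*ln(RSS/n) + 2k with k the number of regression
#' parameters including the intercept. Degrees with more parameters than
#' distinct dose levels are skipped. A residual sum of squares below
#' `rssFloor` is clamped (with a warning) so the log stays finite; nested
#' larger models are then still penalized by their extra 2 per parameter.
#'
#' @param expr numeric matrix, genes x samples.
#' @param dose numeric dose (Gy) per sample; >= 4 distinct levels.
#' @param degrees polynomial degrees to compare (default 1:3).
#' @param rssFloor clamp for near-zero RSS (default 1e-12).
#' @return data.frame with one AIC column per degree and bestDegree.
#' @export
doseLinearityAIC <- function(expr, dose, degrees = 1:3, rssFloor = 1e-12) {
  stopifnot(is.matrix(expr), ncol(expr) == length(dose))
  nLevels <- length(unique(dose))
  if (nLevels < 4) stop("need at least 4 dose levels")
  n <- length(dose)
  clamped <- FALSE
  basis <- lapply(degrees, function(d)
    if (nLevels >= d + 1) cbind(1, stats::poly(dose, d, raw = TRUE)) else NULL)
  rows <- lapply(rownames(expr), function(g) {
    y <- expr[g, ]
    aics <- vapply(seq_along(degrees), function(i) {
      X <- basis[[i]]
      if (is.null(X)) return(NA_real_)
      rss <- sum(stats::lm.fit(X, y)$residuals^2)
      if (rss < rssFloor) {
        clamped <<- TRUE
        rss <- rssFloor
      }
      n * log(rss / n) + 2 * (degrees[i] + 1)
    }, numeric(1))
    best <- degrees[which.min(aics)]
    out <- as.data.frame(as.list(setNames(aics, paste0("aic", degrees))))
    out$gene <- g
    out$bestDegree <- best
    out
  })
  if (clamped)
    warning("residual sum of squares below floor clamped to ", rssFloor)
  out <- do.call(rbind, rows)
  out[, c("gene", paste0("aic", degrees), "bestDegree")]
}
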