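#' Filter time-responsive genes by one-way ANOVA
#'
#' One-way ANOVA of expression across post-irradiation timepoints, with
#' cell lines acting as replicates within each timepoint. Per the usual
#' practice for this screen, p-values are left unadjusted and genes with
#' p below `alpha` are retained; multiplicity is handled later, at the
#' profile-significance step.
#'
#' Constant genes (zero total variance) are a degenerate case: the F
#' statistic is undefined and the gene is reported with p = 1, hence
#' filtered out.
#'
#' @param tce a \linkS4class{TimeCourseExperiment} with >= 2 timepoints and
#'   >= 2 cell lines per timepoint.
#' @param alpha unadjusted significance level (default 0.05).
#' @return data.frame with columns gene, F, p, keep.
#' @examples
#' cfg <- simulationConfig(nGenes = 50, nSignature = 5, nResponsive = 0,
#'                         cellLines = paste0("L", 1:6))
#' tce <- simulateTimeCourse(cfg)
#' head(anovaFilter(tce))
#' @export
anovaFilter <- function(tce, alpha = 0.05) {
  stopifnot(is(tce, "TimeCourseExperiment"))
  cd <- SummarizedExperiment::colData(tce)
  if (length(unique(cd$hour)) < 2)
    stop("anovaFilter needs at least two timepoints")
  res <- rowAnova(SummarizedExperiment::assay(tce, "exprs"), cd$hour)
  res$keep <- res$p < alpha
  res
}

#' Build a library of short time-series model profiles
#'
#' Enumerates all (2c+1)^(T-1) candidate profiles of integer unit changes
#' bounded by `c` per inter-timepoint interval, drops the flat profile, and
#' greedily selects `m` representatives that maximize the minimum pairwise
#' distance 1 - Pearson correlation between cumulative profile curves.
#' Selection starts from the first candidate in enumeration order and
#' breaks ties by lowest candidate index, so the library is fully
#' deterministic; `seed` is accepted for interface stability but the
#' procedure draws no random numbers.
#'
#' @param nTimepoints number of timepoints T (>= 2).
#' @param maxUnitChange bound c on the per-interval change (>= 1).
#' @param m number of representative profiles to retain.
#' @param seed unused; kept so callers can thread a seed uniformly.
#' @return a \linkS4class{ProfileLibrary}.
#' @examples
#' lib <- buildProfileLibrary(nTimepoints = 3, maxUnitChange = 1, m = 8)
#' profileMatrix(lib)
#' @export
buildProfileLibrary <- function(nTimepoints, maxUnitChange = 2, m = 50,
                                seed = NULL) {
  stopifnot(nTimepoints >= 2, maxUnitChange >= 1)
  steps <- nTimepoints - 1
  grid <- as.matrix(expand.grid(rep(list(seq(-maxUnitChange, maxUnitChange)),
                                    steps)))
  colnames(grid) <- NULL
  flat <- rowSums(abs(grid)) == 0
  changes <- grid[!flat, , drop = FALSE]
  nCand <- nrow(grid)
  if (m > nrow(changes))
    stop("m exceeds the number of distinct non-flat profiles (",
         nrow(changes), ")")
  curves <- cbind(0, t(apply(changes, 1, cumsum)))
  if (m < nrow(changes)) {
    cc <- rowCorRows(curves, curves)
    d <- 1 - cc
    chosen <- 1L
    while (length(chosen) < m) {
      dmin <- apply(d[, chosen, drop = FALSE], 1, min)
      dmin[chosen] <- -Inf
      chosen <- c(chosen, which.max(dmin))  # which.max: lowest index on ties
    }
    # keep selection order: the first k representatives are identical for
    # every library size m >= k, so planted archetypes are m-invariant
    changes <- changes[chosen, , drop = FALSE]
    curves <- curves[chosen, , drop = FALSE]
  }
  rownames(curves) <- rownames(changes) <- paste0("P", seq_len(nrow(curves)))
  new("ProfileLibrary", profiles = curves, changes = changes,
      maxUnitChange = as.integer(maxUnitChange),
      nCandidates = as.integer(nCand))
}

# genes x T matrix of per-timepoint means expressed as change from 0 h
transformSeries <- function(tce) {
  tm <- timepointMeans(tce)
  sweep(tm, 1, tm[, 1])
}

#' Assign genes to their best-matching temporal profile
#'
#' Each gene's series is the per-timepoint mean across cell lines,
#' transformed to change relative to the earliest timepoint (profiles are
#' time-shapes, so level is removed). The gene is assigned to the library
#' profile with the highest Pearson correlation to the transformed series;
#' ties break to the lowest profile index. Genes whose transformed series
#' has zero variance cannot be correlated and are reported unassigned.
#'
#' @param tce a \linkS4class{TimeCourseExperiment}, typically already
#'   restricted to ANOVA-passing genes.
#' @param lib a \linkS4class{ProfileLibrary} with matching timepoint count.
#' @return a \linkS4class{ClusterAssignment} (sizes only; significance is
#'   added by [profileSignificance()]).
#' @export
assignGenes <- function(tce, lib) {
  stopifnot(is(tce, "TimeCourseExperiment"), is(lib, "ProfileLibrary"))
  s <- transformSeries(tce)
  if (ncol(s) != ncol(lib@profiles))
    stop("library was built for ", ncol(lib@profiles), " timepoints, data has ",
         ncol(s))
  cc <- rowCorRows(s, lib@profiles)
  ok <- !apply(is.na(cc), 1, all)
  asn <- rep(NA_integer_, nrow(s))
  best <- rep(NA_real_, nrow(s))
  if (any(ok)) {
    asn[ok] <- max.col(cc[ok, , drop = FALSE], ties.method = "first")
    best[ok] <- cc[cbind(seq_len(nrow(s)), asn)][ok]
  }
  sizes <- tabulate(asn[ok], nbins = nrow(lib@profiles))
  stats <- data.frame(profile = rownames(lib@profiles), size = sizes,
                      stringsAsFactors = FALSE)
  new("ClusterAssignment",
      assignments = setNames(asn[ok], rownames(s)[ok]),
      correlation = setNames(best[ok], rownames(s)[ok]),
      unassigned = rownames(s)[!ok],
      stats = stats)
}

#' Permutation significance of temporal profile clusters
#'
#' For each library profile, the expected cluster size is estimated by
#' permuting every gene's timepoint labels independently `nPerm` times and
#' re-running the assignment. The p-value is the fraction of permutations
#' whose cluster size reaches the observed size, with the usual +1
#' smoothing, so p lies in [1/(nPerm+1), 1]. Benjamini-Hochberg correction
#' is applied across profiles and clusters with q below `qThreshold` are
#' flagged significant.
#'
#' @param tce the same \linkS4class{TimeCourseExperiment} used for the
#'   assignment.
#' @param lib the \linkS4class{ProfileLibrary}.
#' @param assignment the observed \linkS4class{ClusterAssignment}.
#' @param nPerm number of label permutations (warning below 100).
#' @param qThreshold BH q-value threshold for significance (default 0.01).
#' @param seed integer seed for the permutation RNG.
#' @return the \linkS4class{ClusterAssignment} with `stats` extended by
#'   expected, pvalue, qvalue, significant.
#' @export
profileSignificance <- function(tce, lib, assignment, nPerm = 1000,
                                qThreshold = 0.01, seed = 1L) {
  stopifnot(is(assignment, "ClusterAssignment"))
  if (nPerm < 100)
    warning("nPerm < 100 gives unstable permutation p-values")
  s <- transformSeries(tce)
  s <- s[names(assignment@assignments), , drop = FALSE]
  tm <- timepointMeans(tce)[names(assignment@assignments), , drop = FALSE]
  nT <- ncol(s)
  nG <- nrow(s)
  m <- nrow(lib@profiles)
  obs <- assignment@stats$size
  count <- integer(m)
  expSum <- numeric(m)
  set.seed(as.integer(seed %% 2147483647))
  if (nT <= 8) {
    perms <- allPermutations(nT)
    pick <- function() perms[sample.int(nrow(perms), nG, replace = TRUE), ,
                             drop = FALSE]
  } else {
    pick <- function() t(vapply(seq_len(nG), function(i) sample.int(nT),
                                integer(nT)))
  }
  rowIdx <- rep(seq_len(nG), times = nT)
  for (b in seq_len(nPerm)) {
    colIdx <- pick()
    sp <- matrix(tm[cbind(rowIdx, as.vector(colIdx))], nG, nT)
    sp <- sweep(sp, 1, sp[, 1])
    cc <- rowCorRows(sp, lib@profiles)
    ok <- !apply(is.na(cc), 1, all)
    asn <- max.col(cc[ok, , drop = FALSE], ties.method = "first")
    sizes <- tabulate(asn, nbins = m)
    count <- count + (sizes >= obs)
    expSum <- expSum + sizes
  }
  st <- assignment@stats
  st$expected <- expSum / nPerm
  st$pvalue <- (count + 1) / (nPerm + 1)
  st$qvalue <- stats::p.adjust(st$pvalue, method = "BH")
  st$significant <- st$qvalue < qThreshold
  new("ClusterAssignment", assignments = assignment@assignments,
      correlation = assignment@correlation,
      unassigned = assignment@unassigned, stats = st)
}
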