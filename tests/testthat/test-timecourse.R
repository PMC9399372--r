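test_that("row-wise ANOVA matches hand computation and the stats oracle", {
  # two timepoints, values {1,2} and {3,4}: SSB = 4, SSW = 1, F = 8 on (1,2)
  m <- matrix(c(1, 3, 2, 4), nrow = 1)
  tce <- TimeCourseExperiment(m, rep(c("A", "B"), each = 2), c(0, 2, 0, 2))
  res <- anovaFilter(tce)
  expect_equal(res$F, 8)
  expect_equal(res$p, pf(8, 1, 2, lower.tail = FALSE))

  # cross-check against stats::oneway.test on random genes
  set.seed(42)
  m <- matrix(rnorm(5 * 12), 5, 12, dimnames = list(paste0("g", 1:5), NULL))
  hrs <- rep(c(0, 2, 4), 4)
  tce <- TimeCourseExperiment(m, rep(paste0("L", 1:4), each = 3),
                              hrs)
  res <- anovaFilter(tce)
  for (i in 1:5) {
    ref <- stats::oneway.test(m[i, ] ~ factor(hrs), var.equal = TRUE)
    expect_equal(res$p[i], ref$p.value, tolerance = 1e-12)
  }
})

test_that("constant genes are degenerate and filtered with p = 1", {
  m <- rbind(g1 = rep(2.5, 8), g2 = rnorm(8))
  tce <- TimeCourseExperiment(m, rep(c("A", "B"), each = 4),
                              rep(c(0, 2, 4, 8), 2))
  res <- anovaFilter(tce)
  expect_equal(res$p[res$gene == "g1"], 1)
  expect_false(res$keep[res$gene == "g1"])
})

test_that("profile library enumerates (2c+1)^(T-1) candidates without flat", {
  lib <- buildProfileLibrary(nTimepoints = 3, maxUnitChange = 1, m = 8)
  expect_equal(lib@nCandidates, 9L)
  expect_equal(nrow(profileMatrix(lib)), 8L)      # full non-flat enumeration
  expect_true(all(rowSums(abs(lib@changes)) > 0))
  expect_true(all(abs(lib@changes) <= 1))
  expect_equal(profileMatrix(lib)[, 1], setNames(rep(0, 8),
                                                 rownames(profileMatrix(lib))))

  # determinism and representative subselection
  lib50a <- buildProfileLibrary(6, 2, 50)
  lib50b <- buildProfileLibrary(6, 2, 50)
  expect_identical(profileMatrix(lib50a), profileMatrix(lib50b))
  expect_equal(lib50a@nCandidates, 5^5)
  # the first k representatives do not depend on the library size
  lib20 <- buildProfileLibrary(6, 2, 20)
  expect_equal(unname(lib20@changes),
               unname(lib50a@changes[1:20, ]))
  expect_error(buildProfileLibrary(3, 1, 9), "non-flat")
})

test_that("genes are assigned to their generating profile", {
  lib <- buildProfileLibrary(4, 1, 26)
  curves <- profileMatrix(lib)
  # three genes exactly on profiles 2, 5, 9, one negated profile
  pick <- c(2, 5, 9)
  m <- curves[pick, rep(1:4, times = 3)]
  rownames(m) <- paste0("g", 1:3)
  tce <- TimeCourseExperiment(m, rep(paste0("L", 1:3), each = 4),
                              rep(c(0, 2, 4, 8), 3))
  asn <- assignGenes(tce, lib)
  expect_equal(unname(assignments(asn)), pick)
  expect_equal(unname(asn@correlation), rep(1, 3), tolerance = 1e-12)

  # negation maps to the negated profile when it is in the library
  neg <- -curves[2, , drop = FALSE]
  negId <- which(apply(curves, 1, function(p) all(p == neg[1, ])))
  expect_length(negId, 1)
  m2 <- neg[1, rep(1:4, times = 3), drop = FALSE]
  rownames(m2) <- "gneg"
  tce2 <- TimeCourseExperiment(m2, rep(paste0("L", 1:3), each = 4),
                               rep(c(0, 2, 4, 8), 3))
  expect_equal(unname(assignments(assignGenes(tce2, lib))),
               unname(negId))
})

test_that("assignment equals the brute-force correlation argmax", {
  lib <- buildProfileLibrary(4, 1, 10)
  set.seed(11)
  m <- matrix(rnorm(5 * 12), 5, 12, dimnames = list(paste0("g", 1:5), NULL))
  tce <- TimeCourseExperiment(m, rep(paste0("L", 1:3), each = 4),
                              rep(c(0, 2, 4, 8), 3))
  asn <- assignGenes(tce, lib)
  # oracle: mean per timepoint, change from 0 h, full correlation matrix
  hrs <- rep(c(0, 2, 4, 8), 3)
  for (g in rownames(m)) {
    s <- tapply(m[g, ], hrs, mean)[c("0", "2", "4", "8")]
    s <- s - s[1]
    cors <- apply(profileMatrix(lib), 1, function(p) cor(s, p))
    expect_equal(unname(assignments(asn)[g]), unname(which.max(cors)))
  }
})

test_that("assignment is invariant to adding a constant to a gene series", {
  lib <- buildProfileLibrary(4, 1, 10)
  set.seed(12)
  m <- matrix(rnorm(4 * 12), 4, 12, dimnames = list(paste0("g", 1:4), NULL))
  tce1 <- TimeCourseExperiment(m, rep(paste0("L", 1:3), each = 4),
                               rep(c(0, 2, 4, 8), 3))
  tce2 <- TimeCourseExperiment(m + 100, rep(paste0("L", 1:3), each = 4),
                               rep(c(0, 2, 4, 8), 3))
  expect_identical(assignments(assignGenes(tce1, lib)),
                   assignments(assignGenes(tce2, lib)))
})

test_that("zero-variance series are reported unassigned", {
  lib <- buildProfileLibrary(4, 1, 10)
  m <- rbind(gflat = rep(1, 12),
             gok = profileMatrix(lib)[3, rep(1:4, 3)])
  tce <- TimeCourseExperiment(m, rep(paste0("L", 1:3), each = 4),
                              rep(c(0, 2, 4, 8), 3))
  asn <- assignGenes(tce, lib)
  expect_identical(asn@unassigned, "gflat")
  expect_identical(names(assignments(asn)), "gok")
})

test_that("permutation significance flags an extreme planted cluster", {
  lib <- buildProfileLibrary(4, 1, 8)
  curve <- profileMatrix(lib)[3, ]
  m <- matrix(rep(curve, each = 30), 30, 4)[, rep(1:4, times = 3)]
  # 30 genes exactly on profile 3, zero noise, 3 cell lines
  m <- matrix(rep(curve[rep(1:4, 3)], each = 30), 30, 12,
              dimnames = list(paste0("g", 1:30), NULL))
  tce <- TimeCourseExperiment(m, rep(paste0("L", 1:3), each = 4),
                              rep(c(0, 2, 4, 8), 3))
  asn <- assignGenes(tce, lib)
  asn <- profileSignificance(tce, lib, asn, nPerm = 1000, seed = 5)
  st <- clusterStats(asn)
  expect_equal(st$pvalue[3], 1 / 1001)             # permutation floor
  expect_true(st$significant[3])
  expect_true(all(st$pvalue >= 1 / 1001 & st$pvalue <= 1))
  # BH q-values are monotone in p
  ord <- order(st$pvalue)
  expect_true(all(diff(st$qvalue[ord]) >= -1e-12))
  expect_warning(profileSignificance(tce, lib, asn, nPerm = 50, seed = 1),
                 "unstable")
})

test_that("planted profiles are recovered on synthetic data", {
  b <- smallBundle()
  truth <- b$truth
  lib <- buildProfileLibrary(6, 2, 50)
  an <- anovaFilter(b$tce)
  tceF <- b$tce[an$gene[an$keep], ]
  asn <- assignGenes(tceF, lib)
  planted <- truth@profileId
  found <- assignments(asn)[names(planted)]
  recovered <- mean(found == planted, na.rm = TRUE)
  expect_gte(recovered, 0.9)
})
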