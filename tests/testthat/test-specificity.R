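test_that("partial correlation reduces to Pearson without real covariates", {
  set.seed(2)
  x <- rnorm(100); y <- 0.5 * x + rnorm(100)
  pc <- partialCorrelation(x, y, matrix(1, 100, 1))  # constant covariate
  expect_equal(pc$r, cor(x, y), tolerance = 1e-12)
  ## y fully explained by x plus covariates: residual correlation is 1
  covs <- matrix(rnorm(200), 100, 2)
  y2 <- x + drop(covs %*% c(2, -1))
  pc2 <- partialCorrelation(x, y2, covs)
  expect_equal(pc2$r, 1, tolerance = 1e-10)
  expect_error(partialCorrelation(x, drop(covs %*% c(1, 1)), covs),
               "zero residual")
})

test_that("partial correlation matches the precision-matrix oracle", {
  set.seed(6)
  S <- matrix(c(1, 0.5, 0.3,
                0.5, 1, 0.4,
                0.3, 0.4, 1), 3, 3)
  L <- t(chol(S))
  M <- t(L %*% matrix(rnorm(3 * 2000), 3))
  pc <- partialCorrelation(M[, 1], M[, 2], M[, 3, drop = FALSE])
  expect_equal(pc$r, precisionPartialCor(M), tolerance = 0.02)
  ## and converges to plain Pearson when the covariate is irrelevant
  z <- rnorm(5000); x <- rnorm(5000); y <- 0.4 * x + rnorm(5000)
  pcBig <- partialCorrelation(x, y, matrix(z))
  expect_lt(abs(pcBig$r - cor(x, y)), 0.01)
})

test_that("Fisher z is the odd atanh map with clipping at |r| = 1", {
  expect_identical(fisherZ(0), 0)
  expect_equal(fisherZ(0.5), 0.5493061, tolerance = 1e-6)
  expect_equal(fisherZ(-0.7), -fisherZ(0.7), tolerance = 1e-12)
  rr <- seq(-0.99, 0.99, length.out = 21)
  expect_equal(tanh(fisherZ(rr)), rr, tolerance = 1e-12)
  zz <- seq(-4.9, 4.9, length.out = 11)
  expect_equal(fisherZ(tanh(zz)), zz, tolerance = 1e-9)
  expect_message(zc <- fisherZ(1), "clipped")
  expect_true(is.finite(zc))
  expect_error(fisherZ(1.2), "exceed")
})

test_that("the specificity Z-test uses SE = 1/sqrt(N - k - 3)", {
  flat <- specificityZTest(0.4, c(0.4, 0.4), N = 616)
  expect_equal(unname(flat["Z"]), 0)
  expect_equal(unname(flat["p"]), 0.5)
  unit <- specificityZTest(0.5 + 1 / sqrt(610), rep(0.5, 5), N = 616, k = 3)
  expect_equal(unname(unit["Z"]), 1, tolerance = 1e-12)
  crit <- specificityZTest(0.5 + 1.6448536 / sqrt(610), rep(0.5, 5), N = 616)
  expect_equal(unname(crit["p"]), 0.05, tolerance = 1e-6)
  expect_error(specificityZTest(1, numeric(0), N = 616), "empty")
  expect_error(specificityZTest(1, 0, N = 6, k = 3), "N > k")
  ## strictly increasing in the associated z
  zs <- vapply(seq(0, 1, 0.1), function(z)
    unname(specificityZTest(z, c(0.1, 0.2), N = 100)["Z"]), numeric(1))
  expect_true(all(diff(zs) > 0))
})

test_that("inter-feature matrices have the contracted structure", {
  d <- SimDesign(nParticipants = 120, pathways = paste0("P", 1:3), seed = 8)
  se <- simulateCohort(d)
  mats <- interFeatureMatrices(se, "P1")
  expect_true(all(diag(mats$SAF.SAF$r) == 1))
  expect_true(all(diag(mats$LR.LR$r) == 1))
  expect_equal(mats$SAF.SAF$r, t(mats$SAF.SAF$r))
  expect_false(isSymmetric(unname(mats$SAF.LR$r)))
  expect_error(interFeatureMatrices(se, "nope"))
})

test_that("estimated inter-feature correlations track the design matrix", {
  fc <- 0.4^abs(outer(1:7, 1:7, "-"))
  d <- SimDesign(nParticipants = 2000, pathways = paste0("P", 1:3),
                 featureCorrelation = fc, seed = 77)
  se <- simulateCohort(d)
  mats <- interFeatureMatrices(se, "P2")
  off <- upper.tri(fc)
  mad1 <- mean(abs(mats$SAF.SAF$r[off] - fc[off]))
  expect_lte(mad1, 0.05)
})

test_that("a duplicated noise-free feature gives a unit cross-tier diagonal", {
  d <- SimDesign(nParticipants = 100, pathways = paste0("P", 1:3),
                 noiseSd = 0, couplingAssoc = 0.5, couplingNonassoc = 0.1,
                 seed = 3)
  se <- simulateCohort(d)
  ## same latent + same linear predictor in both tiers: identical values
  expect_equal(
    partialCorrelation(bundleValues(se, "P1", "SAF", "FA"),
                       bundleValues(se, "P1", "LR", "FA"),
                       cbind(cohortTable(se)$Age))$r,
    1, tolerance = 1e-10)
})

test_that("specificity Z values match a hand-computed toy table", {
  ## fixed 10-row cohort, 3 pathways, deterministic feature values
  n <- 10
  cohort <- data.frame(Age = seq(6, 20, length.out = n),
                       Sex = rep(c(0, 1), 5),
                       TICV = c(0.3, -0.5, 1.2, 0.8, -1.1,
                                0.05, 0.9, -0.4, 1.6, -0.2))
  set.seed(101)
  vals <- matrix(rnorm(n * 3 * 2 * 7), nrow = 3 * 2 * 7)
  rd <- expand.grid(feature = SAFTractometry:::FEATURES,
                    tier = c("SAF", "LR"), pathway = paste0("P", 1:3),
                    stringsAsFactors = FALSE)[, 3:1]
  rownames(vals) <- paste(rd$pathway, rd$tier, rd$feature, sep = ".")
  colnames(vals) <- sprintf("s%02d", 1:n)
  se <- SAFExperiment(vals, rd, data.frame(cohort,
    row.names = colnames(vals)))
  res <- runSpecificity(se)

  ## spreadsheet-style oracle for one cell: LR P1, feature FA, H1
  covs <- cbind(cohort$Age, cohort$Sex, zTransform(cohort$TICV))
  Q <- cbind(1, covs)
  resid <- function(v) v - Q %*% solve(t(Q) %*% Q, t(Q) %*% v)
  pcor <- function(a, b) cor(resid(a), resid(b))[1, 1]
  lr1 <- vals["P1.LR.FA", ]
  zAssoc <- atanh(pcor(lr1, vals["P1.SAF.FA", ]))
  zOthers <- atanh(c(pcor(lr1, vals["P2.SAF.FA", ]),
                     pcor(lr1, vals["P3.SAF.FA", ])))
  Zoracle <- (zAssoc - mean(zOthers)) * sqrt(n - 3 - 3)
  got <- res[res$pathway == "P1" & res$feature == "FA" &
             res$hypothesis == "H1", ]
  expect_equal(got$Z, Zoracle, tolerance = 1e-10)
  expect_equal(got$p, 1 - pnorm(Zoracle), tolerance = 1e-10)

  ## H2 oracle for the same pathway/feature
  zOthersLL <- atanh(c(pcor(lr1, vals["P2.LR.FA", ]),
                       pcor(lr1, vals["P3.LR.FA", ])))
  ZoracleH2 <- (zAssoc - mean(zOthersLL)) * sqrt(n - 3 - 3)
  gotH2 <- res[res$pathway == "P1" & res$feature == "FA" &
               res$hypothesis == "H2", ]
  expect_equal(gotH2$Z, ZoracleH2, tolerance = 1e-10)
})

test_that("FDR families are feature-by-hypothesis and match a recomputation", {
  d <- SimDesign(nParticipants = 200, pathways = paste0("P", 1:5),
                 couplingAssoc = 0.6, couplingNonassoc = 0.2, seed = 19)
  se <- simulateCohort(d)
  res <- runSpecificity(se)
  for (f in c("FA", "ODI")) for (h in c("H1", "H2")) {
    fam <- res[res$feature == f & res$hypothesis == h, ]
    want <- bruteForceBH(fam$p)
    expect_equal(fam$q, want$q, tolerance = 1e-12)
    expect_identical(fam$significant, want$reject)
  }
  expect_error(runSpecificity(se[, 1:3][rowData(se)$pathway %in% "P1", ]))
})

test_that("a missing associated partner yields NA cells, not an abort", {
  d <- SimDesign(nParticipants = 100, pathways = paste0("P", 1:4), seed = 4)
  se <- simulateCohort(d)
  pairing <- c(P1 = "P1", P2 = "P2", P3 = "P3", P4 = "absent")
  res <- runSpecificity(se, pairing = pairing)
  p4 <- res[res$pathway == "P4", ]
  expect_true(all(is.na(p4$Z)))
  expect_true(all(!is.na(res$Z[res$pathway == "P1"])))
})
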