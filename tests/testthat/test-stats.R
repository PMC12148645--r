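test_that("z-transform uses the sample-SD convention and is idempotent", {
  expect_equal(zTransform(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(4)
  x <- rnorm(50, 10, 3)
  z <- zTransform(x)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_equal(zTransform(z), z, tolerance = 1e-12)
  expect_error(zTransform(rep(2, 5), "FA.P1"), "FA.P1")
  expect_error(zTransform(1), "at least 2")
})

test_that("the design matrix encodes age, sex, interaction and zTICV", {
  cohort <- data.frame(Age = c(10, 12), Sex = c(1, 0), TICV = c(1.2, 0.8))
  X <- buildDesign(cohort)
  expect_identical(colnames(X), c("Intercept", "Age", "Sex", "Age:Sex", "zTICV"))
  expect_equal(unname(X[1, "Age:Sex"]), 10)    # male, age 10
  expect_equal(unname(X[2, "Age:Sex"]), 0)
  expect_equal(unname(X[, "zTICV"]), zTransform(c(1.2, 0.8)))

  allF <- data.frame(Age = runif(20, 6, 20), Sex = 0, TICV = rnorm(20))
  Xf <- buildDesign(allF)
  expect_true(all(Xf[, "Sex"] == 0) && all(Xf[, "Age:Sex"] == 0))
  ## single-sex cohorts are rank-deficient for the sex terms
  expect_lt(qr(Xf)$rank, ncol(Xf))
  bad <- data.frame(participant_id = c("a", "b"), Age = c(10, NA),
                    Sex = c(0, 1), TICV = c(1, 2))
  expect_error(buildDesign(bad), "b")
})

test_that("exact linear data return the OLS solution with zero scale", {
  set.seed(7)
  X <- cbind(1, rnorm(30), rnorm(30))
  y <- drop(X %*% c(2, -1, 0.5))
  fit <- fitRobustLM(X, y)
  expect_equal(unname(coef(fit)), c(2, -1, 0.5), tolerance = 1e-10)
  expect_identical(fit@scale, 0)
  expect_true(fit@converged)
})

test_that("IRLS with an enormous tuning constant reproduces OLS", {
  set.seed(20)
  for (rep in 1:100) {
    n <- sample(20:60, 1)
    p <- sample(2:4, 1)
    X <- cbind(1, matrix(rnorm(n * (p - 1)), n))
    y <- rnorm(n, drop(X %*% runif(p, -2, 2)))
    fit <- fitRobustLM(X, y, tuningC = 1e6)
    expect_lt(max(abs(coef(fit) - olsOracle(X, y))), 1e-8)
  }
})

test_that("the bisquare fit agrees with an independent implementation", {
  set.seed(33)
  n <- 200
  X <- cbind(1, runif(n, 5, 22), rbinom(n, 1, 0.5))
  y <- drop(X %*% c(1, 0.05, 0.2)) + rnorm(n) * ifelse(runif(n) < 0.1, 8, 1)
  fit <- fitRobustLM(X, y)
  ref <- MASS::rlm(X, y, psi = MASS::psi.bisquare, scale.est = "MAD",
                   maxit = 100)
  expect_equal(unname(coef(fit)), unname(coef(ref)), tolerance = 5e-3)
})

test_that("bisquare resists gross contamination better than OLS", {
  set.seed(55)
  n <- 616
  diffs <- replicate(30, {
    X <- cbind(1, runif(n, 5.6, 21.9))
    noise <- rnorm(n) * ifelse(runif(n) < 0.2, 10, 1)
    y <- drop(X %*% c(0, 0.05)) + noise
    c(abs(coef(fitRobustLM(X, y))[2] - 0.05),
      abs(olsOracle(X, y)[2] - 0.05))
  })
  expect_lt(median(diffs[1, ]), median(diffs[2, ]))
})

test_that("robust confidence intervals cover at their nominal rate", {
  set.seed(77)
  n <- 616
  hits <- replicate(200, {
    age <- runif(n, 5.6, 21.9); sex <- rbinom(n, 1, 279 / 616)
    X <- cbind(1, age, sex, age * sex, rnorm(n))
    y <- drop(X %*% c(0, 0.05, 0.1, 0.02, 0.05)) + rnorm(n)
    fit <- fitRobustLM(X, y)
    ci <- coef(fit)[2] + c(-1, 1) * qt(0.975, fit@df) * fit@se[2]
    ci[1] <= 0.05 && 0.05 <= ci[2]
  })
  expect_gte(mean(hits), 0.91)
  expect_lte(mean(hits), 0.99)
})

test_that("relative percent change is the normalized raw slope", {
  expect_equal(relativePercentChange(-0.002, 0.4), -0.5)
  expect_identical(relativePercentChange(0, 2), 0)
  expect_error(relativePercentChange(1, 0), "zero")
})

test_that("effect-size comparison behaves like a two-tailed normal test", {
  eq <- compareEffectSizes(0.3, 0.1, 0.3, 0.2)
  expect_equal(unname(eq["t"]), 0)
  expect_equal(unname(eq["p"]), 1)
  ab <- compareEffectSizes(0.5, 0.1, 0.2, 0.15)
  ba <- compareEffectSizes(0.2, 0.15, 0.5, 0.1)
  expect_equal(unname(ab["t"]), -unname(ba["t"]))
  expect_equal(unname(ab["p"]), unname(ba["p"]))
  d <- 1.959964 * sqrt(0.1^2 + 0.15^2)
  expect_equal(unname(compareEffectSizes(0.2 + d, 0.1, 0.2, 0.15)["p"]), 0.05,
               tolerance = 1e-6)
  expect_error(compareEffectSizes(1, 0, 1, 1), "positive")
})

test_that("BH adjustment matches brute-force step-up enumeration", {
  r <- bhFdr(c(0.01, 0.02, 0.03, 0.04))
  expect_true(all(r$reject))                  # largest i with p_(i) <= i*0.0125
  expect_false(any(bhFdr(rep(1, 6))$reject))
  expect_true(bhFdr(0.04)$reject)
  expect_error(bhFdr(c(0.5, 1.2)), "0, 1")
  set.seed(123)
  for (rep in 1:300) {
    m <- sample(1:12, 1)
    p <- round(runif(m), 3)
    got <- bhFdr(p)
    want <- bruteForceBH(p)
    expect_equal(got$q, want$q, tolerance = 1e-12)
    expect_identical(got$reject, want$reject)
  }
})

test_that("batch fitting recovers a zero-noise design grid exactly", {
  d <- SimDesign(nParticipants = 80, pathways = paste0("P", 1:3),
                 noiseSd = 0, seed = 17)
  se <- simulateCohort(d)
  res <- fitAllBundles(se, standardize = FALSE)
  expect_false(any(res$failed))
  expect_equal(res$estimate[res$term == "age"],
               rep(0.05, sum(res$term == "age")), tolerance = 1e-10)
  expect_equal(res$estimate[res$term == "sex"],
               rep(0.1, sum(res$term == "sex")), tolerance = 1e-8)
  em <- effectMatrix(res, "age", "SAF")
  expect_identical(dim(em), c(3L, 7L))
  expect_equal(unname(em["P2", "MD"]), 0.05, tolerance = 1e-10)
})

test_that("null designs stay near the nominal FDR and strong effects are found", {
  fr <- vapply(1:5, function(s) {
    d <- SimDesign(nParticipants = 200, pathways = paste0("P", 1:8),
                   beta = c(0, 0, 0, 0, 0), seed = 600 + s)
    mean(fitAllBundles(simulateCohort(d))$significant)
  }, numeric(1))
  expect_lte(mean(fr), 0.05)

  ## sex shares variance with the age-by-sex column, so a strong design
  ## needs a large sex effect to overcome the collinearity
  d <- SimDesign(nParticipants = 616, pathways = paste0("P", 1:4),
                 beta = c(0, 0.08, 1.2, 0, 0.3), seed = 9)
  res <- fitAllBundles(simulateCohort(d))
  expect_gte(mean(res$significant[res$term == "age"]), 0.95)
  expect_gte(mean(res$significant[res$term == "sex"]), 0.95)
})

test_that("tier comparison and percent change run end to end", {
  d <- SimDesign(nParticipants = 150, pathways = paste0("P", 1:3), seed = 12)
  se <- simulateCohort(d)
  res <- fitAllBundles(se)
  cmp <- compareTiers(res, "age")
  expect_identical(nrow(cmp), 21L)
  expect_true(all(is.finite(cmp$t)))
  rpc <- relPercentChangeTable(se)
  expect_equal(rpc$percentPerYear,
               100 * rpc$beta1Raw / rpc$meanFeature, tolerance = 1e-12)
})

test_that("the TICV sub-model male slope is the sum of age and interaction", {
  d <- SimDesign(nParticipants = 300, ticvNoiseSd = 0, seed = 41)
  se <- simulateCohort(d)
  m <- fitTICVModel(cohortTable(se), standardize = FALSE)
  expect_equal(m$femaleSlope, -0.04, tolerance = 1e-10)
  expect_equal(m$maleSlope, 0.03, tolerance = 1e-10)
})
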