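#' Simulate a developmental cohort with known bundle-feature structure
#'
#' Draws ages uniformly over the design's age range and sex as Bernoulli
#' with the design's male fraction, simulates total intracranial volume
#' (TICV) from its own small age/sex/age-by-sex model, and generates every
#' (pathway, tier, feature) bundle value from the linear model
#' `beta0 + beta1*Age + beta2*Sex + beta3*Age*Sex + beta4*zTICV`
#' plus latent SAF-LR coupling and correlated residual noise.
#'
#' The latent structure uses one standard-normal factor per participant per
#' pathway, loaded onto both tiers of that pathway with
#' `sqrt(couplingAssoc^2 - couplingNonassoc^2)`, plus one global factor per
#' participant loaded with `couplingNonassoc` onto every bundle, so the
#' covariance added between an associated SAF-LR pair is `couplingAssoc^2`
#' and between any non-associated pair `couplingNonassoc^2`; equal loadings
#' give an exchangeable null. Residuals are multivariate normal across the
#' seven features with the design's correlation, scaled by `noiseSd`, and
#' inflated tenfold for the contaminated participants.
#'
#' The generator is bit-reproducible: the same design (including its seed)
#' always yields an identical object.
#'
#' @param design a [SimDesign-class].
#' @return An [SAFExperiment-class]; the generating design is echoed in
#'   `metadata(se)$design` and the contaminated participants in
#'   `metadata(se)$contaminated`.
#' @examples
#' se <- simulateCohort(SimDesign(nParticipants = 50, seed = 7))
#' se
#' @export
simulateCohort <- function(design) {
  stopifnot(is(design, "SimDesign"))
  validObject(design)
  set.seed(design@seed)
  n <- design@nParticipants
  P <- length(design@pathways)

  age <- runif(n, design@ageRange[1], design@ageRange[2])
  sex <- rbinom(n, 1L, design@sexProportion)
  tb <- design@ticvBeta
  ticv <- tb[1] * age + tb[2] * sex + tb[3] * age * sex +
    design@ticvNoiseSd * rnorm(n)
  zticv <- if (sd(ticv) > 0) (ticv - mean(ticv)) / sd(ticv) else ticv * 0

  X <- cbind(1, age, sex, age * sex, zticv)

  a <- design@couplingAssoc
  c0 <- design@couplingNonassoc
  aEff <- sqrt(max(a^2 - c0^2, 0))
  Fpath <- matrix(rnorm(n * P), n, P)   # per-participant pathway factors
  G <- rnorm(n)                         # global factor

  nContam <- floor(design@contaminationRate * n)
  contam <- rep(FALSE, n)
  if (nContam > 0) contam[sample.int(n, nContam)] <- TRUE
  noiseScale <- ifelse(contam, 10 * design@noiseSd, design@noiseSd)

  L <- chol2L(design@featureCorrelation)

  nRows <- P * 2L * 7L
  vals <- matrix(0, nRows, n)
  rd <- data.frame(
    pathway = rep(design@pathways, each = 2L * 7L),
    tier = rep(rep(TIERS, each = 7L), P),
    feature = rep(FEATURES, 2L * P))
  row <- 0L
  for (p in seq_len(P)) {
    latentP <- aEff * Fpath[, p] + c0 * G
    ## one correlated residual draw per tier x feature, scaled per subject
    for (tier in 1:2) {
      eps <- matrix(rnorm(n * 7L), n, 7L) %*% t(L)
      for (f in 1:7) {
        row <- row + 1L
        mu <- X %*% design@betas[p, tier, f, ]
        vals[row, ] <- mu + latentP + noiseScale * eps[, f]
      }
    }
  }
  ids <- sprintf("sub-%04d", seq_len(n))
  rownames(vals) <- paste(rd$pathway, rd$tier, rd$feature, sep = ".")
  colnames(vals) <- ids
  SAFExperiment(vals, rowData = rd,
    colData = data.frame(Age = age, Sex = sex, TICV = ticv,
                         row.names = ids),
    metadata = list(design = design, contaminated = contam))
}

## Lower-triangular factor of a PSD correlation matrix; falls back to an
## eigendecomposition square root when Cholesky fails on a semi-definite
## boundary case.
chol2L <- function(S) {
  ev <- eigen(S, symmetric = TRUE)
  if (min(ev$values) < -1e-10)
    stop("featureCorrelation must be positive semi-definite")
  L <- try(t(chol(S)), silent = TRUE)
  if (inherits(L, "try-error"))
    L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)))
  L
}
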