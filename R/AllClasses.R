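#' @import methods
#' @importFrom stats median mad sd cor pnorm pt qt rnorm runif rbinom p.adjust
#'   lm.fit lm.wfit approx quantile var setNames
#' @importFrom utils read.delim write.table packageVersion
NULL

## Canonical microstructural feature set: four DTI scalars and three
## NODDI-style features consumed at feature level.
FEATURES <- c("FA", "MD", "AD", "RD", "ICVF", "ISOVF", "ODI")
TIERS <- c("SAF", "LR")

#' VolumeGrid: voxel lattice with a voxel-to-world affine
#'
#' A minimal image geometry: integer dimensions and a 4x4 NIfTI-style
#' affine mapping 0-based voxel indices (voxel centers at integers) to
#' world coordinates in mm.
#'
#' @slot dims integer(3), voxel counts along each axis.
#' @slot affine 4x4 numeric matrix, voxel (0-based) to world mm.
#' @export
setClass("VolumeGrid",
  representation(dims = "integer", affine = "matrix"),
  validity = function(object) {
    msg <- NULL
    if (length(object@dims) != 3L || any(object@dims < 1L))
      msg <- c(msg, "dims must be three positive integers")
    if (!all(dim(object@affine) == c(4L, 4L)))
      msg <- c(msg, "affine must be 4x4")
    else if (abs(det(object@affine)) < .Machine$double.eps * 100)
      msg <- c(msg, "affine must be invertible")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a VolumeGrid
#'
#' @param dims integer(3) voxel dimensions.
#' @param affine 4x4 voxel-to-world affine; default isotropic spacing
#'   with the volume centered on the world origin.
#' @param voxelSize voxel edge length in mm used when `affine` is NULL.
#' @return A [VolumeGrid-class] object.
#' @export
VolumeGrid <- function(dims, affine = NULL, voxelSize = 1) {
  dims <- as.integer(dims)
  if (is.null(affine)) {
    affine <- diag(c(rep(voxelSize, 3), 1))
    affine[1:3, 4] <- -voxelSize * (dims - 1) / 2
  }
  new("VolumeGrid", dims = dims, affine = affine)
}

#' Tractogram: streamlines in world mm plus a reference grid
#'
#' @slot streamlines list of numeric matrices (n_i x 3), ordered points in
#'   world coordinates (mm).
#' @slot grid the reference [VolumeGrid-class].
#' @export
setClass("Tractogram",
  representation(streamlines = "list", grid = "VolumeGrid"),
  validity = function(object) {
    ok <- vapply(object@streamlines, function(s)
      is.matrix(s) && ncol(s) == 3L && nrow(s) >= 2L && all(is.finite(s)),
      logical(1))
    if (!all(ok))
      return("every streamline must be a finite n x 3 matrix with n >= 2")
    TRUE
  })

#' Construct a Tractogram
#' @param streamlines list of n x 3 matrices (world mm).
#' @param grid a [VolumeGrid-class].
#' @return A [Tractogram-class].
#' @export
Tractogram <- function(streamlines, grid) {
  streamlines <- lapply(streamlines, function(s) {
    s <- as.matrix(s)
    dimnames(s) <- NULL
    storage.mode(s) <- "double"
    s
  })
  new("Tractogram", streamlines = streamlines, grid = grid)
}

#' @describeIn Tractogram number of streamlines
#' @param x a Tractogram
#' @export
setMethod("length", "Tractogram", function(x) length(x@streamlines))

#' Streamlines accessor
#' @param x a Tractogram
#' @return list of n x 3 point matrices.
#' @export
streamlines <- function(x) x@streamlines

#' AcquisitionScheme: diffusion gradient table
#'
#' b-values (s/mm^2) with unit gradient directions, FSL bval/bvec style.
#'
#' @slot bvals numeric vector of b-values.
#' @slot bvecs n x 3 matrix of directions; unit norm where b > 0.
#' @export
setClass("AcquisitionScheme",
  representation(bvals = "numeric", bvecs = "matrix"),
  validity = function(object) {
    if (nrow(object@bvecs) != length(object@bvals) || ncol(object@bvecs) != 3L)
      return("bvecs must be n x 3 matching bvals")
    nz <- object@bvals > 0
    if (any(nz)) {
      nrm <- sqrt(rowSums(object@bvecs[nz, , drop = FALSE]^2))
      if (any(abs(nrm - 1) > 1e-6))
        return("bvecs must be unit vectors where b > 0")
    }
    TRUE
  })

#' Construct an AcquisitionScheme
#' @param bvals numeric b-values (s/mm^2).
#' @param bvecs n x 3 direction matrix (normalized where b > 0).
#' @return An [AcquisitionScheme-class].
#' @export
AcquisitionScheme <- function(bvals, bvecs) {
  bvecs <- unname(as.matrix(bvecs))
  nz <- bvals > 0
  if (any(nz)) {
    nrm <- sqrt(rowSums(bvecs[nz, , drop = FALSE]^2))
    nrm[abs(nrm - 1) < 1e-12] <- 1   # already unit: keep bits untouched
    bvecs[nz, ] <- bvecs[nz, , drop = FALSE] / nrm
  }
  new("AcquisitionScheme", bvals = as.numeric(bvals), bvecs = bvecs)
}

#' SimDesign: ground-truth generative design for synthetic cohorts
#'
#' Holds every parameter of the cohort generator: sample size, age range,
#' sex balance, per-bundle-per-feature regression coefficients on the
#' standardized feature scale, the 7x7 inter-feature noise correlation,
#' latent SAF-LR coupling loadings, and the gross-contamination rate.
#'
#' The linear model for each bundle feature is
#' `beta0 + beta1*Age + beta2*Sex + beta3*Age*Sex + beta4*zTICV` with Age in
#' years, Sex coded 0 = female / 1 = male, and TICV z-scored; betas are in
#' feature standard deviations (beta1 in SD/year).
#'
#' @slot nParticipants integer cohort size.
#' @slot ageRange numeric(2), years.
#' @slot sexProportion fraction male.
#' @slot pathways character pathway labels.
#' @slot betas 4-d array `[pathway, tier, feature, coefficient]` with
#'   coefficients beta0..beta4 on the standardized scale.
#' @slot noiseSd residual SD (standardized units).
#' @slot featureCorrelation 7x7 PSD correlation of residuals across features.
#' @slot couplingAssoc,couplingNonassoc latent loadings in [0,1); an
#'   associated SAF-LR pair correlates at about couplingAssoc^2, any
#'   non-associated pair at about couplingNonassoc^2 (before noise scaling).
#' @slot contaminationRate fraction of participants whose residual noise is
#'   inflated tenfold (gross outliers).
#' @slot ticvBeta numeric(3): TICV-model coefficients (age, sex, age x sex)
#'   in TICV SD units.
#' @slot ticvNoiseSd residual SD of simulated TICV.
#' @slot seed integer RNG seed.
#' @export
setClass("SimDesign",
  representation(nParticipants = "integer", ageRange = "numeric",
    sexProportion = "numeric", pathways = "character", betas = "array",
    noiseSd = "numeric", featureCorrelation = "matrix",
    couplingAssoc = "numeric", couplingNonassoc = "numeric",
    contaminationRate = "numeric", ticvBeta = "numeric",
    ticvNoiseSd = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- NULL
    if (object@nParticipants < 2L)
      msg <- c(msg, "need at least 2 participants")
    if (length(object@ageRange) != 2L || diff(object@ageRange) <= 0)
      msg <- c(msg, "ageRange must be (low, high) with low < high")
    if (object@sexProportion < 0 || object@sexProportion > 1)
      msg <- c(msg, "sexProportion must be in [0,1]")
    d <- dim(object@betas)
    if (length(d) != 4L || d[1] != length(object@pathways) || d[2] != 2L ||
        d[3] != length(FEATURES) || d[4] != 5L)
      msg <- c(msg, "betas must be [pathway, tier, feature, 5] array")
    fc <- object@featureCorrelation
    if (!all(dim(fc) == c(7L, 7L)) || any(abs(diag(fc) - 1) > 1e-12) ||
        any(abs(fc - t(fc)) > 1e-12))
      msg <- c(msg, "featureCorrelation must be symmetric 7x7 with unit diagonal")
    else if (min(eigen(fc, symmetric = TRUE, only.values = TRUE)$values) < -1e-10)
      msg <- c(msg, "featureCorrelation must be positive semi-definite")
    if (object@couplingNonassoc < 0 || object@couplingAssoc >= 1 ||
        object@couplingAssoc < object@couplingNonassoc)
      msg <- c(msg, "need couplingAssoc >= couplingNonassoc >= 0 and couplingAssoc < 1")
    if (object@contaminationRate < 0 || object@contaminationRate >= 0.5)
      msg <- c(msg, "contaminationRate must be in [0, 0.5)")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a SimDesign
#'
#' Defaults mirror the study conditions the generator emulates: 616
#' participants aged uniformly on 5.6-21.9 years, 279/616 male, and a TICV
#' sub-model with a small negative age slope (-0.04 SD/yr) and positive
#' age-by-sex interaction (+0.07 SD/yr).
#'
#' @param nParticipants cohort size.
#' @param pathways character vector of pathway labels.
#' @param beta either a numeric(5) recycled to every (pathway, tier,
#'   feature) cell, or a full `[pathway, tier, feature, 5]` array.
#' @param ageRange,sexProportion cohort demographics.
#' @param noiseSd residual SD in feature-SD units.
#' @param featureCorrelation 7x7 residual correlation across features.
#' @param couplingAssoc,couplingNonassoc latent coupling loadings.
#' @param contaminationRate fraction of gross-outlier participants.
#' @param ticvBeta numeric(3) TICV model (age, sex, age x sex) coefficients.
#' @param ticvNoiseSd residual SD of TICV.
#' @param seed integer RNG seed.
#' @return A validated [SimDesign-class].
#' @export
SimDesign <- function(nParticipants = 616L,
                      pathways = paste0("P", 1:8),
                      beta = c(0, 0.05, 0.1, 0.02, 0.05),
                      ageRange = c(5.6, 21.9),
                      sexProportion = 279 / 616,
                      noiseSd = 1,
                      featureCorrelation = diag(7),
                      couplingAssoc = 0,
                      couplingNonassoc = 0,
                      contaminationRate = 0,
                      ticvBeta = c(age = -0.04, sex = 0.09, agesex = 0.07),
                      ticvNoiseSd = 1,
                      seed = 1L) {
  P <- length(pathways)
  if (is.array(beta) && length(dim(beta)) == 4L) {
    betas <- beta
  } else {
    stopifnot(length(beta) == 5L)
    betas <- array(rep(beta, each = P * 2L * 7L), dim = c(P, 2L, 7L, 5L))
  }
  dimnames(betas) <- list(pathways, TIERS, FEATURES, paste0("beta", 0:4))
  fc <- as.matrix(featureCorrelation)
  dimnames(fc) <- list(FEATURES, FEATURES)
  new("SimDesign", nParticipants = as.integer(nParticipants),
    ageRange = as.numeric(ageRange), sexProportion = sexProportion,
    pathways = pathways, betas = betas, noiseSd = noiseSd,
    featureCorrelation = fc, couplingAssoc = couplingAssoc,
    couplingNonassoc = couplingNonassoc,
    contaminationRate = contaminationRate,
    ticvBeta = as.numeric(ticvBeta), ticvNoiseSd = ticvNoiseSd,
    seed = as.integer(seed))
}

#' PhantomSet: geometric phantom with ground truth
#'
#' Tube-shaped long-range bundle masks, U-shaped SAF streamlines that dip
#' through them, unassigned distractors, and flagged gross-outlier
#' streamlines, all with generator-recorded truth.
#'
#' @slot grid the shared [VolumeGrid-class].
#' @slot lrMasks named list of logical arrays, one per pathway.
#' @slot tractogram the [Tractogram-class] of all streamlines.
#' @slot truthLabels list of character vectors: the pathways each
#'   streamline truly belongs to (empty for distractors and outliers).
#' @slot outlierFlags logical per streamline.
#' @slot outlierOf character per streamline: the bundle an outlier was
#'   injected next to (NA otherwise).
#' @slot lengths numeric per-streamline polyline length (mm).
#' @export
setClass("PhantomSet",
  representation(grid = "VolumeGrid", lrMasks = "list",
    tractogram = "Tractogram", truthLabels = "list",
    outlierFlags = "logical", outlierOf = "character", lengths = "numeric"),
  validity = function(object) {
    n <- length(object@tractogram)
    if (length(object@truthLabels) != n || length(object@outlierFlags) != n ||
        length(object@outlierOf) != n || length(object@lengths) != n)
      return("per-streamline slots must match the tractogram length")
    TRUE
  })

#' RobustFit: result of an IRLS bisquare robust regression
#'
#' @slot beta,se,tStat,pValue named numeric per coefficient.
#' @slot n observations; @slot df residual degrees of freedom.
#' @slot iterations IRLS iterations used.
#' @slot converged logical.
#' @slot scale robust residual scale (MAD/0.6745).
#' @slot weights final bisquare weights.
#' @export
setClass("RobustFit",
  representation(beta = "numeric", se = "numeric", tStat = "numeric",
    pValue = "numeric", n = "integer", df = "integer",
    iterations = "integer", converged = "logical", scale = "numeric",
    weights = "numeric"))

setMethod("show", "VolumeGrid", function(object) {
  cat("VolumeGrid:", paste(object@dims, collapse = " x "),
      "voxels, voxel->world affine det", signif(det(object@affine), 4), "\n")
})

setMethod("show", "Tractogram", function(object) {
  npts <- vapply(object@streamlines, nrow, integer(1))
  cat("Tractogram with", length(object), "streamlines",
      sprintf("(%d-%d points)\n", min(npts), max(npts)))
})

setMethod("show", "SimDesign", function(object) {
  cat("SimDesign:", object@nParticipants, "participants,",
      length(object@pathways), "pathways x 2 tiers x 7 features\n")
  cat("  age", object@ageRange[1], "-", object@ageRange[2], "y;",
      sprintf("%.1f%% male;", 100 * object@sexProportion),
      "noise SD", object@noiseSd, "\n")
  cat("  coupling assoc/nonassoc:", object@couplingAssoc, "/",
      object@couplingNonassoc, "; contamination",
      object@contaminationRate, "\n")
})

setMethod("show", "PhantomSet", function(object) {
  cat("PhantomSet:", length(object@lrMasks), "LR masks,",
      length(object@tractogram), "streamlines (",
      sum(object@outlierFlags), "flagged outliers )\n")
})

setMethod("show", "RobustFit", function(object) {
  cat("Robust linear fit (bisquare IRLS), n =", object@n,
      ", iterations =", object@iterations,
      if (object@converged) "(converged)\n" else "(NOT converged)\n")
  print(data.frame(beta = object@beta, se = object@se,
                   t = object@tStat, p = object@pValue))
})

#' Coefficients of a RobustFit
#' @param object a [RobustFit-class]
#' @param ... ignored
#' @export
setMethod("coef", "RobustFit", function(object, ...) object@beta)
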