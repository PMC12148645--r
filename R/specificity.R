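## Partial inter-feature correlations and the Fisher-z specificity test of
## associated SAF-LR coupling.

#' Partial correlation controlling for covariates
#'
#' Residualizes `x` and `y` on `[1, covariates]` by least squares and takes
#' the Pearson correlation of the residuals; the p-value comes from
#' `t = r * sqrt((n - 2 - k) / (1 - r^2))` on `n - 2 - k` degrees of
#' freedom (two-tailed), with k the number of covariates.
#'
#' @param x,y numeric vectors.
#' @param covariates numeric matrix (n x k), or NULL for a plain Pearson
#'   correlation.
#' @return list: r, p, n, k.
#' @export
partialCorrelation <- function(x, y, covariates = NULL) {
  n <- length(x)
  if (is.null(covariates)) covariates <- matrix(numeric(0), n, 0)
  covariates <- as.matrix(covariates)
  k <- ncol(covariates)
  if (n <= k + 2) stop("need n > k + 2 observations")
  Q <- cbind(1, covariates)
  qrQ <- qr(Q)
  rx <- qr.resid(qrQ, x)
  ry <- qr.resid(qrQ, y)
  ## residuals numerically in the covariate span count as zero variance
  if (sd(rx) <= 1e-10 * max(sd(x), 1e-30) ||
      sd(ry) <= 1e-10 * max(sd(y), 1e-30))
    stop("zero residual variance: partial correlation undefined")
  r <- cor(rx, ry)
  r <- max(min(r, 1), -1)
  df <- n - 2 - k
  tt <- if (abs(r) >= 1) Inf else r * sqrt(df / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(tt), df = df), n = n, k = k)
}

#' Fisher's z-transformation
#'
#' `z = atanh(r)`, the variance-stabilizing map for correlation
#' coefficients; |r| is clipped to 1 - 1e-15 (with a message) so perfect
#' correlations map to a large finite z.
#'
#' @param r correlation in [-1, 1].
#' @return z value.
#' @export
fisherZ <- function(r) {
  if (any(abs(r) > 1)) stop("|r| must not exceed 1")
  clip <- abs(r) > 1 - 1e-15
  if (any(clip)) {
    message(sum(clip), " correlation(s) clipped before Fisher z")
    r[clip] <- sign(r[clip]) * (1 - 1e-15)
  }
  atanh(r)
}

#' One-tailed Z-test of correlation specificity
#'
#' Tests whether a Fisher-z-transformed associated correlation exceeds the
#' mean of a comparison set of z-transformed correlations:
#' `Z = (zAssoc - mean(zOthers)) * sqrt(N - k - 3)`, using the standard
#' error of a single z-transformed partial correlation
#' `SE = 1 / sqrt(N - k - 3)` (N subjects, k covariates). The one-tailed
#' p-value is `1 - Phi(Z)` for the "greater" direction.
#'
#' @param zAssoc Fisher z of the associated correlation.
#' @param zOthers Fisher z values of the comparison correlations.
#' @param N number of subjects; requires `N > k + 3`.
#' @param k number of covariates (default 3: age, sex, zTICV).
#' @param tail `"greater"` (default) or `"less"`.
#' @return named numeric: Z, p.
#' @export
specificityZTest <- function(zAssoc, zOthers, N, k = 3, tail = "greater") {
  if (N <= k + 3) stop("need N > k + 3 subjects")
  if (length(zOthers) == 0L) stop("empty comparison set")
  Z <- (zAssoc - mean(zOthers)) * sqrt(N - k - 3)
  p <- if (tail == "greater") pnorm(Z, lower.tail = FALSE) else pnorm(Z)
  c(Z = Z, p = p)
}

## Covariate matrix [Age, Sex, zTICV] for the partial correlations.
covariateMatrix <- function(se) {
  cd <- cohortTable(se)
  cbind(Age = cd$Age, Sex = cd$Sex, zTICV = zTransform(cd$TICV, "TICV"))
}

#' Inter-feature partial correlation matrices for one pathway
#'
#' The three 7x7 matrices of partial correlations (controlling for age,
#' sex, z-normalized TICV) between feature pairs: within the SAF bundle,
#' within the LR bundle, and across tiers (SAF feature x LR feature, a
#' full asymmetric matrix). BH FDR is applied within each matrix (unique
#' off-diagonal pairs for the symmetric matrices, all 49 cells for the
#' cross matrix).
#'
#' @param se an [SAFExperiment-class].
#' @param pathway pathway label.
#' @param alpha FDR level.
#' @return list of three elements (`SAF.SAF`, `LR.LR`, `SAF.LR`), each a
#'   list of 7x7 matrices r, p, q, significant.
#' @export
interFeatureMatrices <- function(se, pathway, alpha = 0.05) {
  covs <- covariateMatrix(se)
  vals <- function(tier) {
    sapply(FEATURES, function(f) bundleValues(se, pathway, tier, f))
  }
  vSAF <- vals("SAF"); vLR <- vals("LR")
  build <- function(A, B, symmetric) {
    r <- p <- matrix(NA_real_, 7, 7, dimnames = list(FEATURES, FEATURES))
    for (i in 1:7) for (j in 1:7) {
      if (symmetric && j < i) next
      if (symmetric && i == j) { r[i, j] <- 1; p[i, j] <- 0; next }
      pc <- partialCorrelation(A[, i], B[, j], covs)
      r[i, j] <- pc$r; p[i, j] <- pc$p
      if (symmetric) { r[j, i] <- pc$r; p[j, i] <- pc$p }
    }
    fam <- if (symmetric) which(upper.tri(p)) else seq_along(p)
    q <- sig <- matrix(NA_real_, 7, 7, dimnames = dimnames(r))
    adj <- bhFdr(p[fam], alpha)
    q[fam] <- adj$q; sig[fam] <- adj$reject
    if (symmetric) { q[lower.tri(q)] <- t(q)[lower.tri(q)]
                     sig[lower.tri(sig)] <- t(sig)[lower.tri(sig)] }
    list(r = r, p = p, q = q, significant = sig == 1)
  }
  list(SAF.SAF = build(vSAF, vSAF, TRUE),
       LR.LR = build(vLR, vLR, TRUE),
       SAF.LR = build(vSAF, vLR, FALSE))
}

#' Specificity of associated SAF-LR coupling
#'
#' For every long-range pathway LRi and feature, compares the Fisher-z
#' partial correlation between LRi and its associated SAF bundle with
#' (H1) the mean z-correlation between LRi and the other, non-associated
#' SAF bundles and (H2) the mean z-correlation between LRi and the other
#' LR bundles, using the one-tailed Z approximation of
#' [specificityZTest()]. All correlations are partial (age, sex, zTICV).
#' BH FDR is applied across pathways within each feature-by-hypothesis
#' family.
#'
#' @param se an [SAFExperiment-class] with at least 3 pathways.
#' @param pairing named character vector `lr_pathway -> saf_pathway`;
#'   default pairs each pathway with itself. A pathway whose partner is
#'   missing yields NA rows.
#' @param alpha FDR level.
#' @param k number of covariates in the partial correlations (3).
#' @return data.frame: pathway, feature, hypothesis (H1/H2), rAssoc,
#'   zAssoc, meanZOther, Z, p, q, significant.
#' @export
runSpecificity <- function(se, pairing = NULL, alpha = 0.05, k = 3) {
  pw <- pathwayLabels(se)
  if (length(pw) < 3L) stop("need at least 3 pathways")
  if (is.null(pairing)) pairing <- setNames(pw, pw)
  covs <- covariateMatrix(se)
  N <- ncol(se)

  rows <- list()
  for (f in FEATURES) {
    lrv <- sapply(pw, function(p) bundleValues(se, p, "LR", f))
    safv <- sapply(pw, function(p) bundleValues(se, p, "SAF", f))
    pcor <- function(a, b) partialCorrelation(a, b, covs)$r
    ## all LR x SAF and LR x LR partial correlations for this feature
    rLS <- outer(seq_along(pw), seq_along(pw),
                 Vectorize(function(i, j) pcor(lrv[, i], safv[, j])))
    rLL <- outer(seq_along(pw), seq_along(pw),
                 Vectorize(function(i, j)
                   if (i == j) NA_real_ else pcor(lrv[, i], lrv[, j])))
    zLS <- suppressMessages(fisherZ(rLS))
    zLL <- matrix(NA_real_, length(pw), length(pw))
    zLL[!is.na(rLL)] <- suppressMessages(fisherZ(rLL[!is.na(rLL)]))
    for (i in seq_along(pw)) {
      partner <- pairing[[pw[i]]]
      pj <- match(partner, pw)
      for (hyp in c("H1", "H2")) {
        if (is.na(pj)) {
          rows[[length(rows) + 1L]] <- data.frame(
            pathway = pw[i], feature = f, hypothesis = hyp,
            rAssoc = NA_real_, zAssoc = NA_real_, meanZOther = NA_real_,
            Z = NA_real_, p = NA_real_)
          next
        }
        zAssoc <- zLS[i, pj]
        zOthers <- if (hyp == "H1") zLS[i, -pj] else zLL[i, -i]
        zt <- specificityZTest(zAssoc, zOthers, N, k = k)
        rows[[length(rows) + 1L]] <- data.frame(
          pathway = pw[i], feature = f, hypothesis = hyp,
          rAssoc = rLS[i, pj], zAssoc = zAssoc,
          meanZOther = mean(zOthers), Z = unname(zt["Z"]),
          p = unname(zt["p"]))
      }
    }
  }
  res <- do.call(rbind, rows)
  res$q <- NA_real_
  res$significant <- NA
  for (f in FEATURES) for (hyp in c("H1", "H2")) {
    fam <- which(res$feature == f & res$hypothesis == hyp & !is.na(res$p))
    if (length(fam)) {
      adj <- bhFdr(res$p[fam], alpha)
      res$q[fam] <- adj$q
      res$significant[fam] <- adj$reject
    }
  }
  res
}
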