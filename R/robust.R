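#' z-transform a vector (sample SD convention)
#'
#' Centers and scales by the sample standard deviation (n - 1 denominator),
#' the normalization applied to every bundle-feature column and to TICV
#' before model fitting.
#'
#' @param values numeric vector, length >= 2.
#' @param name optional column label used in the zero-variance error.
#' @return z-scores with mean 0 and sample SD 1.
#' @export
zTransform <- function(values, name = NULL) {
  if (length(values) < 2L) stop("need at least 2 values")
  s <- sd(values)
  if (!is.finite(s) || s == 0)
    stop("zero variance in ", if (is.null(name)) "input" else name,
         ": cannot z-transform")
  (values - mean(values)) / s
}

#' Build the developmental design matrix
#'
#' Columns `[Intercept, Age, Sex, Age:Sex, zTICV]`: Age in raw years, Sex
#' coded 0 = female / 1 = male, their elementwise product, and TICV
#' z-transformed across participants. With this coding the Age coefficient
#' is the female slope and the male slope is Age + Age:Sex.
#'
#' @param cohort data.frame with Age, Sex, TICV (and optionally
#'   participant_id used in error messages).
#' @param includeTICV set FALSE for the TICV sub-model design
#'   `[Intercept, Age, Sex, Age:Sex]`.
#' @return numeric design matrix.
#' @export
buildDesign <- function(cohort, includeTICV = TRUE) {
  need <- c("Age", "Sex", if (includeTICV) "TICV")
  for (v in need) {
    if (!v %in% names(cohort)) stop("cohort lacks column ", v)
    bad <- !is.finite(cohort[[v]])
    if (any(bad)) {
      ids <- if ("participant_id" %in% names(cohort))
        cohort$participant_id[bad] else which(bad)
      stop("missing ", v, " for participant(s): ",
           paste(utils::head(ids, 5), collapse = ", "))
    }
  }
  if (!all(cohort$Sex %in% c(0, 1)))
    stop("Sex must be coded 0 (female) / 1 (male)")
  X <- cbind(Intercept = 1, Age = cohort$Age, Sex = cohort$Sex,
             `Age:Sex` = cohort$Age * cohort$Sex)
  if (includeTICV)
    X <- cbind(X, zTICV = zTransform(cohort$TICV, "TICV"))
  X
}

## Tukey bisquare psi and its derivative on standardized residuals u = r/s.
bisquarePsi <- function(u, c) ifelse(abs(u) < c, u * (1 - (u / c)^2)^2, 0)
bisquarePsiPrime <- function(u, c)
  ifelse(abs(u) < c, (1 - (u / c)^2) * (1 - 5 * (u / c)^2), 0)

#' Robust linear regression by IRLS with the bisquare weight
#'
#' Iteratively reweighted least squares: the fit starts at OLS; at each
#' iteration the robust residual scale is re-estimated as
#' `median(|r|) / 0.6745` (the MAD-based scale), Tukey bisquare weights
#' `w = (1 - (r / (c s))^2)^2` for `|r| < c s` (0 beyond) are formed, and a
#' weighted least-squares step is taken, until the largest coefficient
#' change falls below `tol`. The default tuning constant c = 4.685 gives
#' 95% efficiency under Gaussian errors.
#'
#' Standard errors use the Huber-corrected robust covariance
#' `s^2 * [sum psi(u)^2 / (n - p)] / [mean psi'(u)]^2 * kappa^2 * (X'X)^-1`
#' with Huber's small-sample kappa; p-values are two-tailed from a
#' t-distribution on n - p degrees of freedom. When the data are exactly
#' linear (robust scale 0) the OLS solution is returned unchanged.
#'
#' @param X full-column-rank design matrix (n rows > p columns).
#' @param y response vector.
#' @param tuningC bisquare tuning constant.
#' @param maxIter,tol IRLS iteration cap and coefficient tolerance.
#' @return A [RobustFit-class].
#' @export
fitRobustLM <- function(X, y, tuningC = 4.685, maxIter = 50L, tol = 1e-8) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stop("need more observations than coefficients")
  qrX <- qr(X)
  if (qrX$rank < p) stop("design matrix is rank-deficient")
  cn <- colnames(X)
  if (is.null(cn)) cn <- paste0("beta", seq_len(p) - 1L)

  beta <- qr.coef(qrX, y)
  r <- y - drop(X %*% beta)
  olsSigma2 <- sum(r^2) / (n - p)
  XtXinv <- chol2inv(qr.R(qrX))

  finish <- function(beta, se, iterations, converged, scale, w) {
    tstat <- beta / se
    pval <- 2 * pt(-abs(tstat), df = n - p)
    new("RobustFit", beta = setNames(as.numeric(beta), cn),
        se = setNames(as.numeric(se), cn),
        tStat = setNames(as.numeric(tstat), cn),
        pValue = setNames(as.numeric(pval), cn),
        n = as.integer(n), df = as.integer(n - p),
        iterations = as.integer(iterations), converged = converged,
        scale = scale, weights = as.numeric(w))
  }

  scaleOf <- function(r) median(abs(r)) / 0.6745
  scaleTol <- 1e-10 * max(abs(y), 1)
  s <- scaleOf(r)
  if (s <= scaleTol) {
    ## exactly (or degenerately) linear data: the OLS fit is final
    se <- sqrt(olsSigma2 * diag(XtXinv))
    return(finish(beta, se, 0L, TRUE, 0, rep(1, n)))
  }

  converged <- FALSE
  iter <- 0L
  while (iter < maxIter) {
    iter <- iter + 1L
    u <- r / s
    w <- ifelse(abs(u) < tuningC, (1 - (u / tuningC)^2)^2, 0)
    if (all(w == 0)) stop("all bisquare weights are zero")
    fit <- lm.wfit(X, y, w)
    betaNew <- fit$coefficients
    delta <- max(abs(betaNew - beta))
    beta <- betaNew
    r <- y - drop(X %*% beta)
    sNew <- scaleOf(r)
    if (sNew <= scaleTol) { s <- 0; break }
    s <- sNew
    if (delta < tol) { converged <- TRUE; break }
  }
  if (s == 0) {
    se <- sqrt(olsSigma2 * diag(XtXinv))
    return(finish(beta, se, iter, TRUE, 0, rep(1, n)))
  }
  u <- r / s
  psi <- bisquarePsi(u, tuningC)
  psip <- bisquarePsiPrime(u, tuningC)
  m1 <- sum(psi^2) / (n - p)
  m2 <- mean(psip)
  if (abs(m2) < .Machine$double.eps) stop("degenerate robust fit: mean psi' is zero")
  kappa <- 1 + p * var(psip) / (n * m2^2)   # Huber's correction
  stddev2 <- kappa^2 * s^2 * m1 / m2^2
  se <- sqrt(stddev2 * diag(XtXinv))
  w <- ifelse(abs(u) < tuningC, (1 - (u / tuningC)^2)^2, 0)
  finish(beta, se, iter, converged, s, w)
}

#' Relative percent change per year
#'
#' A raw-scale age slope normalized by the cohort-average feature value and
#' multiplied by 100; with sex coded 0 = female the slope is the female
#' model's change per year.
#'
#' @param beta1Raw per-year slope from the raw-data fit.
#' @param meanFeature average feature value across participants (nonzero).
#' @return percent change per year.
#' @export
relativePercentChange <- function(beta1Raw, meanFeature) {
  if (meanFeature == 0) stop("mean feature value is zero")
  100 * beta1Raw / meanFeature
}

#' Compare two effect sizes by their standard errors
#'
#' Two-tailed test of `betaA - betaB` using
#' `t = (betaA - betaB) / sqrt(seA^2 + seB^2)` with a standard-normal
#' reference (large-sample approximation).
#'
#' @param betaA,seA,betaB,seB coefficients and their standard errors.
#' @return named numeric: t, p.
#' @export
compareEffectSizes <- function(betaA, seA, betaB, seB) {
  if (seA <= 0 || seB <= 0) stop("standard errors must be positive")
  t <- (betaA - betaB) / sqrt(seA^2 + seB^2)
  c(t = t, p = 2 * pnorm(-abs(t)))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up FDR control: adjusted values are the monotone-enforced
#' `min over j >= i of m * p(j) / j`; a test is rejected when its adjusted
#' value is at most `alpha`.
#'
#' @param pvalues numeric vector in [0, 1].
#' @param alpha FDR level (default 0.05).
#' @return list with `q` (adjusted values) and `reject` (logical).
#' @export
bhFdr <- function(pvalues, alpha = 0.05) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  q <- p.adjust(pvalues, method = "BH")
  list(q = q, reject = q <= alpha)
}

#' Fit the TICV sub-model
#'
#' Robust fit of (z-transformed, unless `standardize = FALSE`) TICV on
#' `[Intercept, Age, Sex, Age:Sex]`. The female age slope is the Age
#' coefficient; the male age slope is Age + Age:Sex.
#'
#' @param cohort data.frame with Age, Sex, TICV.
#' @param standardize z-transform TICV first (default TRUE).
#' @param ... passed to [fitRobustLM()].
#' @return list with `fit` (a [RobustFit-class]), `femaleSlope`,
#'   `maleSlope` (SD/year).
#' @export
fitTICVModel <- function(cohort, standardize = TRUE, ...) {
  X <- buildDesign(cohort, includeTICV = FALSE)
  y <- if (standardize) zTransform(cohort$TICV, "TICV") else cohort$TICV
  fit <- fitRobustLM(X, y, ...)
  b <- coef(fit)
  list(fit = fit, femaleSlope = unname(b["Age"]),
       maleSlope = unname(b["Age"] + b["Age:Sex"]))
}
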