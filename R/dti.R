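## Diffusion-tensor estimation (log-linear, restricted to b <= 1500 s/mm^2)
## and the FA/MD/AD/RD scalar derivations.

#' Simulate a diffusion-weighted signal from a tensor
#'
#' Standard single-tensor forward model `S(b, g) = S0 * exp(-b g' D g)`
#' with optional noise on the magnitude (Gaussian by default, Rician on
#' request).
#'
#' @param tensor symmetric positive semi-definite 3x3 matrix (mm^2/s).
#' @param S0 non-diffusion-weighted signal.
#' @param scheme an [AcquisitionScheme-class].
#' @param noiseSd noise standard deviation (same units as S0).
#' @param seed optional integer seed for the noise draw.
#' @param noiseModel `"gaussian"` or `"rician"`.
#' @return numeric signal vector, one value per scheme row.
#' @examples
#' sch <- AcquisitionScheme(c(0, 1500), rbind(c(0, 0, 0), c(1, 0, 0)))
#' simulateDwiSignal(diag(1e-3, 3), 100, sch)  # c(100, 100 * exp(-1.5))
#' @export
simulateDwiSignal <- function(tensor, S0, scheme, noiseSd = 0, seed = NULL,
                              noiseModel = c("gaussian", "rician")) {
  noiseModel <- match.arg(noiseModel)
  tensor <- as.matrix(tensor)
  if (any(abs(tensor - t(tensor)) > 1e-12 * max(abs(tensor), 1e-30)))
    stop("tensor must be symmetric")
  ev <- eigen(tensor, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-12 * max(abs(ev), .Machine$double.eps))
    stop("tensor has a negative eigenvalue")
  g <- scheme@bvecs
  bgDg <- scheme@bvals * rowSums((g %*% tensor) * g)
  S <- S0 * exp(-bgDg)
  if (noiseSd > 0) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    if (noiseModel == "gaussian") {
      S <- S + rnorm(length(S), sd = noiseSd)
    } else {
      S <- sqrt((S + rnorm(length(S), sd = noiseSd))^2 +
                rnorm(length(S), sd = noiseSd)^2)
    }
  }
  S
}

#' DTI scalar measures from sorted eigenvalues
#'
#' MD = mean eigenvalue, AD = largest, RD = mean of the two smaller, and
#' FA = sqrt(3/2) * ||lambda - MD|| / ||lambda|| (0 when all eigenvalues
#' vanish).
#'
#' @param lambda numeric(3), eigenvalues sorted descending, all >= 0.
#' @return named numeric: FA, MD, AD, RD.
#' @export
tensorScalars <- function(lambda) {
  if (length(lambda) != 3L) stop("need three eigenvalues")
  if (is.unsorted(rev(lambda))) stop("eigenvalues must be sorted descending")
  if (any(lambda < 0)) stop("eigenvalues must be non-negative")
  md <- mean(lambda)
  nrm <- sqrt(sum(lambda^2))
  fa <- if (nrm == 0) 0 else sqrt(1.5) * sqrt(sum((lambda - md)^2)) / nrm
  c(FA = min(fa, 1), MD = md, AD = lambda[1], RD = (lambda[2] + lambda[3]) / 2)
}

#' Fit a diffusion tensor to one voxel's signals
#'
#' Log-linear least squares on `ln S = ln S0 - b g' D g`, restricted to
#' measurements with `b <= bMax` (1500 s/mm^2 by default — higher shells
#' are ignored entirely), followed by one reweighting pass with weights
#' equal to the squared predicted signals. Nonpositive signals are excluded
#' with a message; at least 7 usable rows including a b = 0 measurement are
#' required. Negative eigenvalues are clamped to zero before the scalar
#' derivation so FA stays in [0, 1].
#'
#' @param signals numeric vector, one per scheme row.
#' @param scheme an [AcquisitionScheme-class].
#' @param bMax b-value cutoff (s/mm^2).
#' @return list with `D` (3x3), `lnS0`, `eigenvalues` (descending,
#'   unclamped), `FA`, `MD`, `AD`, `RD`, `nUsed`, `nExcluded`.
#' @export
fitTensor <- function(signals, scheme, bMax = 1500) {
  sel <- scheme@bvals <= bMax
  b <- scheme@bvals[sel]
  g <- scheme@bvecs[sel, , drop = FALSE]
  s <- signals[sel]
  pos <- is.finite(s) & s > 0
  nExcluded <- sum(!pos)
  if (nExcluded > 0)
    message(nExcluded, " nonpositive signal(s) excluded from tensor fit")
  b <- b[pos]; g <- g[pos, , drop = FALSE]; s <- s[pos]
  if (length(s) < 7L) stop("fewer than 7 usable measurements with b <= ", bMax)
  if (!any(b == 0)) stop("no b = 0 measurement available")
  X <- cbind(1, -b * g[, 1]^2, -b * g[, 2]^2, -b * g[, 3]^2,
             -2 * b * g[, 1] * g[, 2], -2 * b * g[, 1] * g[, 3],
             -2 * b * g[, 2] * g[, 3])
  if (qr(X)$rank < 7L)
    stop("rank-deficient design: gradient directions insufficient for a tensor fit")
  y <- log(s)
  beta <- qr.coef(qr(X), y)
  ## one reweighting pass: Var(ln S) ~ 1/S^2, so weight by predicted S^2
  w <- exp(X %*% beta)^2
  beta <- lm.wfit(X, y, as.vector(w))$coefficients
  D <- matrix(c(beta[2], beta[5], beta[6],
                beta[5], beta[3], beta[7],
                beta[6], beta[7], beta[4]), 3, 3)
  ev <- eigen(D, symmetric = TRUE, only.values = TRUE)$values
  ev <- sort(ev, decreasing = TRUE)
  sc <- tensorScalars(pmax(ev, 0))
  list(D = D, lnS0 = unname(beta[1]), eigenvalues = ev,
       FA = unname(sc["FA"]), MD = unname(sc["MD"]), AD = unname(sc["AD"]),
       RD = unname(sc["RD"]), nUsed = length(s), nExcluded = nExcluded)
}

#' Voxelwise DTI scalar maps
#'
#' Applies [fitTensor()] at every voxel of a 4-D signal array where the
#' mask is nonzero, producing FA/MD/AD/RD maps.
#'
#' @param signals4d array x, y, z, measurement.
#' @param scheme an [AcquisitionScheme-class].
#' @param mask optional 3-D array; default: voxels with positive mean b0.
#' @param bMax b-value cutoff.
#' @return list of 3-D arrays FA, MD, AD, RD (NA outside the mask).
#' @export
fitTensorMap <- function(signals4d, scheme, mask = NULL, bMax = 1500) {
  d <- dim(signals4d)
  stopifnot(length(d) == 4L, d[4] == length(scheme@bvals))
  if (is.null(mask)) {
    b0 <- scheme@bvals == 0
    mask <- apply(signals4d[, , , b0, drop = FALSE], 1:3, mean) > 0
  }
  maps <- lapply(c(FA = 1, MD = 2, AD = 3, RD = 4),
                 function(i) array(NA_real_, d[1:3]))
  idx <- which(mask > 0, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    v <- idx[r, ]
    fit <- try(suppressMessages(
      fitTensor(signals4d[v[1], v[2], v[3], ], scheme, bMax = bMax)),
      silent = TRUE)
    if (inherits(fit, "try-error")) next
    maps$FA[v[1], v[2], v[3]] <- fit$FA
    maps$MD[v[1], v[2], v[3]] <- fit$MD
    maps$AD[v[1], v[2], v[3]] <- fit$AD
    maps$RD[v[1], v[2], v[3]] <- fit$RD
  }
  maps
}
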