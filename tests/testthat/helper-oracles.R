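## Independent oracles used across the suite. These deliberately avoid the
## package's own code paths (brute-force enumeration, closed forms,
## exact ray marching) so each check is a genuine dual route.

## Exact voxel traversal of one segment (Amanatides-Woo ray march) in
## continuous voxel coordinates, where voxel i spans [i - 0.5, i + 0.5).
ddaSegmentVoxels <- function(p, q) {
  d <- q - p
  v <- round(p)
  vEnd <- round(q)
  out <- list(v)
  step <- sign(d)
  tMax <- rep(Inf, 3)
  tDelta <- rep(Inf, 3)
  for (k in 1:3) {
    if (d[k] != 0) {
      boundary <- v[k] + 0.5 * step[k]
      tMax[k] <- (boundary - p[k]) / d[k]
      tDelta[k] <- abs(1 / d[k])
    }
  }
  guard <- 0L
  while (any(v != vEnd) && guard < 10000L) {
    guard <- guard + 1L
    k <- which.min(tMax)
    if (tMax[k] > 1) break
    v[k] <- v[k] + step[k]
    tMax[k] <- tMax[k] + tDelta[k]
    out[[length(out) + 1L]] <- v
  }
  do.call(rbind, out)
}

## All voxels (0-based, in-bounds) exactly traversed by a streamline.
ddaStreamlineVoxels <- function(s, grid) {
  inv <- solve(grid@affine)
  vc <- t(inv[1:3, 1:3] %*% t(s) + inv[1:3, 4])
  vox <- list()
  for (i in seq_len(nrow(vc) - 1L))
    vox[[i]] <- ddaSegmentVoxels(vc[i, ], vc[i + 1L, ])
  m <- unique(do.call(rbind, vox))
  dims <- grid@dims
  inb <- m[, 1] >= 0 & m[, 1] < dims[1] & m[, 2] >= 0 & m[, 2] < dims[2] &
    m[, 3] >= 0 & m[, 3] < dims[3]
  m[inb, , drop = FALSE]
}

## Oracle assignment decision: does the exact traversal hit a mask voxel?
ddaHitsMask <- function(s, grid, mask) {
  v <- ddaStreamlineVoxels(s, grid)
  if (nrow(v) == 0L) return(FALSE)
  any(mask[v + 1L])
}

## Brute-force Benjamini-Hochberg by direct enumeration of the step-up
## definition: q_(i) = min over j >= i of m * p_(j) / j (capped at 1);
## reject the i smallest p-values where i is the largest index with
## p_(i) <= i * alpha / m.
bruteForceBH <- function(p, alpha = 0.05) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    vals <- sapply(i:m, function(j) m * ps[j] / j)
    q[i] <- min(1, min(vals))
  }
  kmax <- 0L
  for (i in seq_len(m)) if (ps[i] <= i * alpha / m) kmax <- i
  rej <- rep(FALSE, m)
  if (kmax > 0L) rej[seq_len(kmax)] <- TRUE
  qOut <- numeric(m); rOut <- logical(m)
  qOut[o] <- q; rOut[o] <- rej
  list(q = qOut, reject = rOut)
}

## Closed-form OLS through the normal equations (no qr/lm machinery).
olsOracle <- function(X, y) {
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}

## Partial correlation of variables 1 and 2 given the rest, from the
## precision matrix of the joint sample covariance.
precisionPartialCor <- function(M) {
  Om <- solve(cov(M))
  -Om[1, 2] / sqrt(Om[1, 1] * Om[2, 2])
}

## Brute-force MDF: resample by hand with explicit arc-length walking,
## then direct/flipped mean distances.
bruteMdf <- function(a, b, nPoints = 12L) {
  res <- function(s) {
    seg <- sqrt(rowSums(diff(s)^2))
    cum <- c(0, cumsum(seg))
    tt <- seq(0, cum[length(cum)], length.out = nPoints)
    out <- matrix(0, nPoints, 3)
    for (i in seq_len(nPoints)) {
      t0 <- tt[i]
      j <- max(which(cum <= t0 + 1e-12))
      if (j >= nrow(s)) { out[i, ] <- s[nrow(s), ]; next }
      f <- (t0 - cum[j]) / (cum[j + 1] - cum[j])
      out[i, ] <- s[j, ] + f * (s[j + 1, ] - s[j, ])
    }
    out
  }
  ra <- res(a); rb <- res(b)
  direct <- mean(sqrt(rowSums((ra - rb)^2)))
  flip <- mean(sqrt(rowSums((ra - rb[nPoints:1, ])^2)))
  min(direct, flip)
}

## A wiggly random streamline for property tests.
randomStreamline <- function(nPts = 20, scale = 10) {
  start <- runif(3, -scale, scale)
  steps <- matrix(rnorm(3 * (nPts - 1), sd = scale / nPts), ncol = 3)
  apply(rbind(start, steps), 2, cumsum)
}

## Tiny standard phantom used by several suites.
smallPhantom <- function(seed, ...) {
  args <- list(gridDims = c(24L, 24L, 24L), nPathways = 2, fibersPerBundle = 8,
               nDistractors = 3, nOutliers = 2, lengthRange = c(8, 25),
               seed = seed)
  args[names(list(...))] <- list(...)
  do.call(simulatePhantom, args)
}
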