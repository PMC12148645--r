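## Streamline geometry, SAF-to-LR assignment, MDF/QuickBundles clustering,
## ladder-score outlier rejection, and bundle voxel occupancy.

polylineLength <- function(pts) {
  d <- diff(pts)
  sum(sqrt(rowSums(d^2)))
}

#' Arc length of a streamline
#'
#' Sum of consecutive Euclidean segment lengths, in mm.
#'
#' @param s an n x 3 point matrix (world mm), n >= 2.
#' @return length in mm.
#' @examples
#' streamlineLength(rbind(c(0, 0, 0), c(3, 4, 0)))  # 5
#' @export
streamlineLength <- function(s) {
  s <- rbind3(s)
  if (nrow(s) < 2L) stop("a streamline needs at least 2 points")
  polylineLength(s)
}

#' Filter streamlines by length
#'
#' Keeps streamlines whose arc length lies in `[minMm, maxMm]`, both ends
#' inclusive — the 5-40 mm band that defines short association fibers.
#'
#' @param tractogram a [Tractogram-class] (or list of point matrices).
#' @param minMm,maxMm inclusive bounds in mm.
#' @return integer indices of retained streamlines.
#' @export
filterByLength <- function(tractogram, minMm = 5, maxMm = 40) {
  if (minMm > maxMm) stop("minMm must not exceed maxMm")
  sl <- if (is(tractogram, "Tractogram")) streamlines(tractogram) else tractogram
  if (length(sl) == 0L) return(integer(0))
  len <- vapply(sl, polylineLength, numeric(1))
  which(len >= minMm & len <= maxMm)
}

#' Resample a streamline
#'
#' Arc-length parameterization with linear interpolation, either to a fixed
#' number of equidistant points or to a fixed inter-point spacing.
#'
#' @param s n x 3 point matrix.
#' @param nPoints number of output points (exclusive with `spacing`).
#' @param spacing target step in mm; the step actually used is the largest
#'   value <= `spacing` that divides the arc length evenly.
#' @return resampled point matrix.
#' @export
resampleStreamline <- function(s, nPoints = NULL, spacing = NULL) {
  s <- rbind3(s)
  seg <- sqrt(rowSums(diff(s)^2))
  cum <- c(0, cumsum(seg))
  L <- cum[length(cum)]
  if (is.null(nPoints)) {
    if (is.null(spacing)) stop("give nPoints or spacing")
    nPoints <- max(2L, as.integer(ceiling(L / spacing)) + 1L)
  }
  if (L == 0) return(matrix(s[1, ], nPoints, 3, byrow = TRUE))
  tt <- seq(0, L, length.out = nPoints)
  ## de-duplicate zero-length segments for approx()
  keep <- c(TRUE, seg > 0)
  cbind(approx(cum[keep], s[keep, 1], tt)$y,
        approx(cum[keep], s[keep, 2], tt)$y,
        approx(cum[keep], s[keep, 3], tt)$y)
}

#' Assign streamlines to long-range bundle masks
#'
#' Implements proximity-based SAF classification: a streamline is assigned
#' to every pathway whose binary mask it passes through. Before the voxel
#' test each streamline is resampled to a spacing of half the smallest
#' voxel edge (so no traversed voxel is skipped), points are mapped
#' world -> voxel with the grid affine and the nearest-voxel convention,
#' and a streamline joins a bundle iff any point lands in a nonzero voxel.
#' A streamline may join several bundles.
#'
#' @param tractogram a [Tractogram-class].
#' @param lrMasks named list of logical/0-1 arrays on the tractogram grid.
#' @param spacingFactor resampling step as a fraction of the smallest
#'   voxel edge (default 0.5).
#' @return named list: pathway -> integer streamline indices.
#' @export
assignStreamlines <- function(tractogram, lrMasks, spacingFactor = 0.5) {
  grid <- tractogram@grid
  dims <- grid@dims
  for (m in lrMasks)
    if (!all(dim(m) == dims)) stop("mask dimensions do not match the grid")
  step <- spacingFactor * min(voxelEdges(grid))
  out <- lapply(lrMasks, function(m) integer(0))
  for (i in seq_along(tractogram@streamlines)) {
    v <- worldToVoxel(
      resampleStreamline(tractogram@streamlines[[i]], spacing = step),
      grid, round = TRUE)
    inb <- v[, 1] >= 0 & v[, 1] < dims[1] &
           v[, 2] >= 0 & v[, 2] < dims[2] &
           v[, 3] >= 0 & v[, 3] < dims[3]
    if (!any(inb)) next
    idx <- v[inb, , drop = FALSE] + 1L
    lin <- unique(idx[, 1] + dims[1] * (idx[, 2] - 1L) +
                  dims[1] * dims[2] * (idx[, 3] - 1L))
    for (p in names(lrMasks)) {
      if (any(lrMasks[[p]][lin])) out[[p]] <- c(out[[p]], i)
    }
  }
  out
}

#' Minimum average direct-flip (MDF) distance
#'
#' The QuickBundles metric: both streamlines are resampled to `nPoints`
#' equidistant points and the mean pointwise Euclidean distance is taken in
#' the direct and the flipped orientation; the smaller is returned.
#'
#' @param a,b streamlines (n x 3 matrices).
#' @param nPoints resampling resolution (default 12).
#' @return distance in mm.
#' @export
mdfDistance <- function(a, b, nPoints = 12L) {
  ra <- resampleStreamline(a, nPoints = nPoints)
  rb <- resampleStreamline(b, nPoints = nPoints)
  mdfResampled(ra, rb)
}

mdfResampled <- function(ra, rb) {
  direct <- mean(sqrt(rowSums((ra - rb)^2)))
  flipped <- mean(sqrt(rowSums((ra - rb[nrow(rb):1, , drop = FALSE])^2)))
  min(direct, flipped)
}

#' QuickBundles clustering
#'
#' Deterministic single-pass clustering in input order: each streamline
#' (resampled to `nPoints`) is compared with the running centroids of the
#' existing clusters in creation order and joins the first one within
#' `thresholdMm` (MDF); otherwise it founds a new cluster. Centroids are
#' running means of the resampled points, with the new member flipped first
#' when its flipped orientation is closer to the centroid.
#'
#' @param streamlines list of n x 3 matrices (or a [Tractogram-class]).
#' @param thresholdMm MDF threshold (> 0).
#' @param nPoints resampling resolution.
#' @return list of clusters, each `list(members, centroid)`.
#' @export
quickBundles <- function(streamlines, thresholdMm, nPoints = 12L) {
  if (thresholdMm <= 0) stop("thresholdMm must be positive")
  if (is(streamlines, "Tractogram")) streamlines <- streamlines(streamlines)
  rs <- lapply(streamlines, resampleStreamline, nPoints = nPoints)
  clusters <- list()
  for (i in seq_along(rs)) {
    s <- rs[[i]]
    placed <- FALSE
    for (ci in seq_along(clusters)) {
      cl <- clusters[[ci]]
      cent <- cl$sum / cl$n
      sFlip <- s[nrow(s):1, , drop = FALSE]
      dDir <- mean(sqrt(rowSums((s - cent)^2)))
      dFlip <- mean(sqrt(rowSums((sFlip - cent)^2)))
      if (min(dDir, dFlip) <= thresholdMm) {
        aligned <- if (dFlip < dDir) sFlip else s
        cl$sum <- cl$sum + aligned
        cl$n <- cl$n + 1L
        cl$members <- c(cl$members, i)
        clusters[[ci]] <- cl
        placed <- TRUE
        break
      }
    }
    if (!placed)
      clusters[[length(clusters) + 1L]] <- list(sum = s, n = 1L, members = i)
  }
  lapply(clusters, function(cl)
    list(members = cl$members, centroid = cl$sum / cl$n))
}

#' Ladder-score outlier rejection for a bundle
#'
#' Re-specification of toolkit-style hierarchical QuickBundles outlier
#' pruning as an explicit rule: QuickBundles is run at each threshold of a
#' geometric ladder (default 8 levels spanning 2-16 mm); a streamline's
#' score is the fraction of levels at which its cluster holds at least
#' `minClusterFrac` of the bundle's streamlines, and streamlines with
#' score >= `outlierAlpha` are kept.
#'
#' @param streamlines list of n x 3 matrices (>= 2 streamlines).
#' @param outlierAlpha keep threshold on the ladder score (default 0.6).
#' @param thresholdLadder numeric vector of QuickBundles thresholds (mm).
#' @param minClusterFrac minimum cluster occupancy fraction (default 0.05).
#' @param nPoints MDF resampling resolution.
#' @return integer indices of kept streamlines.
#' @export
removeOutliers <- function(streamlines, outlierAlpha = 0.6,
                           thresholdLadder = 2 * 8^(seq(0, 1, length.out = 8)),
                           minClusterFrac = 0.05, nPoints = 12L) {
  if (is(streamlines, "Tractogram")) streamlines <- streamlines(streamlines)
  if (length(streamlines) < 2L) stop("need at least 2 streamlines")
  if (length(thresholdLadder) == 0L) stop("threshold ladder is empty")
  n <- length(streamlines)
  score <- numeric(n)
  for (th in thresholdLadder) {
    cl <- quickBundles(streamlines, th, nPoints = nPoints)
    ok <- logical(n)
    for (c in cl)
      if (length(c$members) >= minClusterFrac * n) ok[c$members] <- TRUE
    score <- score + ok
  }
  score <- score / length(thresholdLadder)
  which(score >= outlierAlpha)
}

## Exact voxel traversal of one polyline (Amanatides-Woo ray march) in the
## grid's voxel space, where voxel i spans [i - 0.5, i + 0.5). Returns
## 0-based voxel indices, possibly out of bounds.
traverseVoxels <- function(s, grid) {
  inv <- solve(grid@affine)
  vc <- t(inv[1:3, 1:3] %*% t(s) + inv[1:3, 4])
  out <- list()
  for (i in seq_len(nrow(vc) - 1L)) {
    p <- vc[i, ]; q <- vc[i + 1L, ]
    d <- q - p
    v <- round(p); vEnd <- round(q)
    seg <- list(v)
    step <- sign(d)
    tMax <- tDelta <- rep(Inf, 3)
    nz <- d != 0
    tMax[nz] <- (v[nz] + 0.5 * step[nz] - p[nz]) / d[nz]
    tDelta[nz] <- abs(1 / d[nz])
    while (any(v != vEnd)) {
      k <- which.min(tMax)
      if (tMax[k] > 1) break
      v[k] <- v[k] + step[k]
      tMax[k] <- tMax[k] + tDelta[k]
      seg[[length(seg) + 1L]] <- v
    }
    out[[i]] <- do.call(rbind, seg)
  }
  unique(do.call(rbind, out))
}

#' Voxel occupancy of a bundle
#'
#' The set of voxels visited by at least one member streamline. The
#' default `"exact"` method marches each polyline segment through the
#' voxel lattice (voxel i spanning the half-open cube centered on it) so
#' the voxel set does not depend on a sampling density; `"points"`
#' reproduces the resampling + nearest-voxel rule of
#' [assignStreamlines()].
#'
#' @param streamlines list of n x 3 matrices (world mm).
#' @param grid a [VolumeGrid-class].
#' @param method `"exact"` (default) or `"points"`.
#' @param spacingFactor resampling step for `method = "points"`.
#' @return logical array of `grid@dims`.
#' @export
bundleOccupancy <- function(streamlines, grid,
                            method = c("exact", "points"),
                            spacingFactor = 0.5) {
  method <- match.arg(method)
  dims <- grid@dims
  mask <- array(FALSE, dim = dims)
  if (length(streamlines) == 0L) return(mask)
  step <- spacingFactor * min(voxelEdges(grid))
  for (s in streamlines) {
    v <- if (method == "exact") traverseVoxels(s, grid)
         else worldToVoxel(resampleStreamline(s, spacing = step), grid)
    inb <- v[, 1] >= 0 & v[, 1] < dims[1] &
           v[, 2] >= 0 & v[, 2] < dims[2] &
           v[, 3] >= 0 & v[, 3] < dims[3]
    if (any(inb)) mask[v[inb, , drop = FALSE] + 1L] <- TRUE
  }
  mask
}

#' Mean of a scalar map over a mask
#'
#' Arithmetic mean of the map over the nonzero mask voxels; NaN/NA voxels
#' are excluded and their count is attached as attribute `nExcluded` (and
#' reported via `message()` when any are dropped).
#'
#' @param mask logical/0-1 array.
#' @param map numeric array of identical dimensions.
#' @return scalar mean with attribute `nExcluded`.
#' @export
bundleMeanFeature <- function(mask, map) {
  if (!all(dim(mask) == dim(map))) stop("mask and map dimensions differ")
  v <- map[mask > 0]
  if (length(v) == 0L) stop("empty mask")
  bad <- !is.finite(v)
  if (all(bad)) stop("all mask voxels are NaN")
  if (any(bad)) message(sum(bad), " NaN voxel(s) excluded from bundle mean")
  structure(mean(v[!bad]), nExcluded = sum(bad))
}

#' Extract bundle-mean features from masks and scalar maps
#'
#' Averages each scalar map over each bundle mask (the per-participant
#' feature-extraction step).
#'
#' @param masks named list of binary arrays (one per bundle).
#' @param maps named list of numeric arrays (one per feature), same grid.
#' @return data.frame: bundle, feature, value, nExcluded.
#' @export
extractFeatures <- function(masks, maps) {
  out <- expand.grid(bundle = names(masks), feature = names(maps),
                     stringsAsFactors = FALSE)
  out$value <- NA_real_
  out$nExcluded <- NA_integer_
  for (i in seq_len(nrow(out))) {
    v <- suppressMessages(
      bundleMeanFeature(masks[[out$bundle[i]]], maps[[out$feature[i]]]))
    out$value[i] <- as.numeric(v)
    out$nExcluded[i] <- attr(v, "nExcluded")
  }
  out
}

#' Classify short association fibers against long-range bundles
#'
#' The full classification computation: streamlines are filtered to the
#' SAF length band, assigned by mask passage to every long-range bundle,
#' and each bundle is pruned with the ladder-score outlier rule.
#'
#' @param tractogram a [Tractogram-class].
#' @param lrMasks named list of binary arrays on the tractogram grid.
#' @param minMm,maxMm inclusive SAF length band (mm).
#' @param outlierAlpha ladder-score keep threshold.
#' @param ... passed to [removeOutliers()].
#' @return named list per pathway:
#'   `list(pathway, streamlineIndices, postFilterIndices)` — assigned
#'   indices before and after outlier removal (indices into the input
#'   tractogram).
#' @export
classifySAF <- function(tractogram, lrMasks, minMm = 5, maxMm = 40,
                        outlierAlpha = 0.6, ...) {
  keep <- filterByLength(tractogram, minMm, maxMm)
  sub <- Tractogram(streamlines(tractogram)[keep], tractogram@grid)
  assigned <- assignStreamlines(sub, lrMasks)
  out <- list()
  for (p in names(assigned)) {
    idx <- keep[assigned[[p]]]
    post <- idx
    if (length(idx) >= 2L) {
      ki <- removeOutliers(streamlines(tractogram)[idx],
                           outlierAlpha = outlierAlpha, ...)
      post <- idx[ki]
    }
    out[[p]] <- list(pathway = p, streamlineIndices = idx,
                     postFilterIndices = post)
  }
  out
}
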