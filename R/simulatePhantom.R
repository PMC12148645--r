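#' Simulate a geometric phantom with known SAF/LR ground truth
#'
#' Builds tube-shaped long-range (LR) bundle masks along gently curved
#' centerlines, U-shaped short-association-fiber (SAF) streamlines whose
#' endpoints straddle each tube and whose lowest point passes through it,
#' distractor streamlines that intersect no mask, and optional gross
#' outlier streamlines (bundle copies displaced far beyond any clustering
#' threshold) with recorded flags. Streamline lengths are drawn inside
#' `lengthRange` so the 5-40 mm length filter can be exercised on either
#' side by widening the band.
#'
#' @param gridDims integer(3) voxel dimensions (>= 20 each).
#' @param nPathways number of LR tubes / SAF bundles.
#' @param fibersPerBundle SAF streamlines per bundle.
#' @param nDistractors streamlines intersecting no mask.
#' @param nOutliers displaced outlier streamlines per bundle.
#' @param lengthRange numeric(2), target streamline arc-length band (mm).
#' @param maskRadius tube radius in voxels.
#' @param voxelSize isotropic voxel edge (mm).
#' @param nonOverlap error if tubes would overlap (default TRUE).
#' @param pointsPerStreamline polyline resolution.
#' @param seed integer RNG seed; fixed seed gives identical output.
#' @return A [PhantomSet-class].
#' @examples
#' ph <- simulatePhantom(seed = 3)
#' ph
#' @export
simulatePhantom <- function(gridDims = c(40L, 40L, 40L), nPathways = 3,
                            fibersPerBundle = 40, nDistractors = 10,
                            nOutliers = 5, lengthRange = c(10, 35),
                            maskRadius = 2, voxelSize = 1,
                            nonOverlap = TRUE,
                            pointsPerStreamline = 30L, seed = 1L) {
  if (any(gridDims < 20L)) stop("grid must be at least 20 voxels per axis")
  if (lengthRange[1] >= lengthRange[2]) stop("lengthRange must be (low, high)")
  set.seed(as.integer(seed))
  dims <- as.integer(gridDims)
  grid <- VolumeGrid(dims, voxelSize = voxelSize)
  pathways <- paste0("LR", seq_len(nPathways))

  ## Tube centerlines: gentle sinusoids along y, spread across x, at the
  ## lower third of z so SAF arcs have headroom above.
  spacing <- (dims[1] - 4) * voxelSize / max(nPathways, 1)
  if (nonOverlap && spacing <= 2 * (maskRadius + 1) * voxelSize)
    stop("LR masks would overlap: reduce nPathways, maskRadius, or enlarge grid")
  x0 <- function(w) grid@affine[1:3, 1:3] %*% w + grid@affine[1:3, 4]
  worldMin <- as.vector(x0(c(0, 0, 0)))
  worldMax <- as.vector(x0(dims - 1))
  zTube <- worldMin[3] + 0.3 * (worldMax[3] - worldMin[3])
  yy <- seq(worldMin[2] + 2 * voxelSize, worldMax[2] - 2 * voxelSize,
            by = voxelSize / 2)

  lrMasks <- list()
  centerlines <- list()
  for (p in seq_len(nPathways)) {
    xc <- worldMin[1] + 2 * voxelSize + (p - 0.5) * spacing
    amp <- 0.5 * voxelSize
    curve <- cbind(xc + amp * sin(2 * pi * (yy - yy[1]) /
                                  (max(yy) - min(yy))), yy, zTube)
    centerlines[[p]] <- curve
    lrMasks[[pathways[p]]] <- tubeMask(curve, grid, maskRadius * voxelSize)
  }
  if (nonOverlap && nPathways > 1) {
    tot <- Reduce(`+`, lapply(lrMasks, function(m) m * 1L))
    if (any(tot > 1L)) stop("LR masks overlap despite nonOverlap = TRUE")
  }

  sl <- list(); labels <- list(); outFlag <- logical(0); outOf <- character(0)

  ## U-shaped SAF arcs: semicircle of radius r in the x-z plane, bottom at
  ## a point on the tube centerline, endpoints at height r above it.
  ## A rigid per-streamline offset (not pointwise noise) provides bundle
  ## spread without inflating arc length; tiny pointwise jitter roughens
  ## the polyline.
  drawLen <- function(k) runif(k, lengthRange[1] * 1.03, lengthRange[2] * 0.97)
  makeArc <- function(center, r, rigidSd = 0.25 * voxelSize,
                      jitterSd = 0.03 * voxelSize) {
    th <- seq(-pi / 2, pi / 2, length.out = pointsPerStreamline)
    pts <- cbind(center[1] + r * sin(th), center[2],
                 center[3] + r - r * cos(th))
    pts <- pts + matrix(rnorm(3, sd = rigidSd), nrow(pts), 3, byrow = TRUE)
    pts + matrix(rnorm(length(pts), sd = jitterSd), ncol = 3)
  }
  ## Anchors for one bundle sit in a narrow window along its centerline so
  ## the bundle is compact relative to the clustering threshold ladder.
  pickAnchors <- function(curve, k) {
    mid <- sample.int(nrow(curve), 1L)
    win <- which(abs(curve[, 2] - curve[mid, 2]) <= 5 * voxelSize)
    curve[sample(win, k, replace = TRUE), , drop = FALSE]
  }
  for (p in seq_len(nPathways)) {
    curve <- centerlines[[p]]
    rs <- drawLen(fibersPerBundle) / pi
    anchors <- pickAnchors(curve, fibersPerBundle)
    for (i in seq_len(fibersPerBundle)) {
      sl[[length(sl) + 1L]] <- makeArc(anchors[i, ], rs[i])
      labels[[length(labels) + 1L]] <- pathways[p]
      outFlag <- c(outFlag, FALSE); outOf <- c(outOf, NA_character_)
    }
  }

  ## Distractors: same arcs, floated near the top of the volume where no
  ## tube (and no SAF arc apex) reaches.
  if (nDistractors > 0) {
    zTop <- worldMax[3] + 10 * voxelSize
    rs <- drawLen(nDistractors) / pi
    for (i in seq_len(nDistractors)) {
      ctr <- c(runif(1, worldMin[1], worldMax[1]),
               runif(1, worldMin[2] + 2, worldMax[2] - 2), zTop)
      sl[[length(sl) + 1L]] <- makeArc(ctr, rs[i])
      labels[[length(labels) + 1L]] <- character(0)
      outFlag <- c(outFlag, FALSE); outOf <- c(outOf, NA_character_)
    }
  }

  ## Gross outliers: arcs anchored on a bundle but displaced by ~40 mm,
  ## far beyond the outlier-rejection threshold ladder (and off all masks).
  if (nOutliers > 0) {
    for (p in seq_len(nPathways)) {
      curve <- centerlines[[p]]
      rs <- drawLen(nOutliers) / pi
      for (i in seq_len(nOutliers)) {
        ctr <- curve[sample.int(nrow(curve), 1L), ] +
          c(0, 0, 40 * voxelSize + runif(1, 0, 10 * voxelSize))
        sl[[length(sl) + 1L]] <- makeArc(ctr, rs[i])
        labels[[length(labels) + 1L]] <- character(0)
        outFlag <- c(outFlag, TRUE); outOf <- c(outOf, pathways[p])
      }
    }
  }

  tg <- Tractogram(sl, grid)
  lens <- vapply(sl, polylineLength, numeric(1))
  new("PhantomSet", grid = grid, lrMasks = lrMasks, tractogram = tg,
      truthLabels = labels, outlierFlags = outFlag, outlierOf = outOf,
      lengths = lens)
}

## Voxels within `radius` (world mm) of a densely sampled curve.
tubeMask <- function(curve, grid, radius) {
  dims <- grid@dims
  inv <- solve(grid@affine)
  mask <- array(FALSE, dim = dims)
  rvox <- ceiling(radius / min(voxelEdges(grid)))
  vox <- worldToVoxel(curve, grid, round = FALSE)
  for (i in seq_len(nrow(vox))) {
    c0 <- vox[i, ]
    lo <- pmax(floor(c0 - rvox), 0)
    hi <- pmin(ceiling(c0 + rvox), dims - 1)
    if (any(lo > hi)) next
    ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
    gridpts <- as.matrix(expand.grid(i = ix, j = iy, k = iz))
    w <- voxelToWorld(gridpts, grid)
    d2 <- rowSums((w - matrix(curve[i, ], nrow(w), 3, byrow = TRUE))^2)
    sel <- gridpts[d2 <= radius^2, , drop = FALSE] + 1L
    if (nrow(sel)) mask[sel] <- TRUE
  }
  mask
}

#' Voxel edge lengths of a grid (mm)
#' @param grid a [VolumeGrid-class]
#' @export
voxelEdges <- function(grid) sqrt(colSums(grid@affine[1:3, 1:3]^2))

#' Map world-mm points to (0-based) voxel indices
#'
#' Uses the grid's NIfTI affine; with `round = TRUE` points are assigned to
#' the nearest voxel (voxel centers sit at integer indices).
#'
#' @param pts n x 3 world coordinates.
#' @param grid a [VolumeGrid-class].
#' @param round round to nearest voxel index.
#' @return n x 3 matrix of voxel coordinates (0-based).
#' @export
worldToVoxel <- function(pts, grid, round = TRUE) {
  pts <- rbind3(pts)
  inv <- solve(grid@affine)
  v <- t(inv[1:3, 1:3] %*% t(pts) + inv[1:3, 4])
  if (round) round(v) else v
}

#' Map (0-based) voxel indices to world mm
#' @param ijk n x 3 voxel indices (0-based).
#' @param grid a [VolumeGrid-class].
#' @export
voxelToWorld <- function(ijk, grid) {
  ijk <- rbind3(ijk)
  t(grid@affine[1:3, 1:3] %*% t(ijk) + grid@affine[1:3, 4])
}

rbind3 <- function(x) {
  if (is.null(dim(x))) matrix(x, ncol = 3) else as.matrix(x)
}
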