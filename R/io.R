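## File formats: MRtrix TCK and TrackVis TRK tractograms, NIfTI-1 masks
## and scalar maps (via RNifti), FSL bval/bvec schemes, and TSV tables.

#' Write a tractogram as MRtrix TCK
#'
#' Text header plus little-endian Float32 triplets; streamlines are
#' separated by NaN triplets and the file ends with an Inf triplet.
#' Coordinates are world mm.
#'
#' @param tractogram a [Tractogram-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeTck <- function(tractogram, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  sl <- streamlines(tractogram)
  hdr <- c("mrtrix tracks", "datatype: Float32LE",
           paste0("count: ", length(sl)))
  ## the offset names the byte where data begin, i.e. total header length
  ## including the offset digits themselves; iterate until stable
  offset <- 0L
  repeat {
    lines <- c(hdr, paste0("file: . ", offset), "END")
    total <- sum(nchar(lines)) + length(lines)  # newline per line
    if (total == offset) break
    offset <- total
  }
  writeLines(lines, con, sep = "\n")
  for (s in sl) {
    writeBin(as.numeric(t(s)), con, size = 4, endian = "little")
    writeBin(as.numeric(c(NaN, NaN, NaN)), con, size = 4, endian = "little")
  }
  writeBin(as.numeric(c(Inf, Inf, Inf)), con, size = 4, endian = "little")
  invisible(path)
}

#' Read an MRtrix TCK tractogram
#'
#' @param path TCK file.
#' @param grid optional [VolumeGrid-class] to attach (TCK carries no
#'   geometry); default: unit grid.
#' @return a [Tractogram-class].
#' @export
readTck <- function(path, grid = NULL) {
  if (!file.exists(path)) stop("cannot open TCK file: ", path)
  raw <- readBin(path, "raw", file.size(path))
  nl <- which(raw == as.raw(10))
  lines <- character(0)
  start <- 1L
  offset <- NA_integer_
  for (i in nl) {
    ln <- rawToChar(raw[start:(i - 1L)])
    lines <- c(lines, ln)
    if (grepl("^file:", ln))
      offset <- as.integer(trimws(sub("^file: *\\.", "", ln)))
    start <- i + 1L
    if (ln == "END") break
  }
  if (!identical(lines[1], "mrtrix tracks"))
    stop("not a TCK file (bad magic at byte 0): ", path)
  if (is.na(offset)) stop("TCK header lacks a file offset line: ", path)
  vals <- readBin(raw[(offset + 1L):length(raw)], "numeric",
                  n = (length(raw) - offset) / 4, size = 4,
                  endian = "little")
  m <- matrix(vals, ncol = 3, byrow = TRUE)
  isNan <- rowSums(is.na(m)) > 0
  isInf <- rowSums(is.infinite(m)) > 0
  breaks <- which(isNan | isInf)
  sl <- list()
  s0 <- 1L
  for (b in breaks) {
    if (b > s0) sl[[length(sl) + 1L]] <- m[s0:(b - 1L), , drop = FALSE]
    s0 <- b + 1L
    if (isInf[b]) break
  }
  if (is.null(grid))
    grid <- VolumeGrid(c(1L, 1L, 1L), affine = diag(4))
  Tractogram(sl, grid)
}

#' Write a tractogram as TrackVis TRK
#'
#' TRK version 2 with a 1000-byte header. Point coordinates are stored in
#' the TrackVis "voxmm" convention (voxel indices scaled by voxel size,
#' corner-origin: voxmm = (voxel + 0.5) * voxel_size) and the header
#' carries the grid's voxel-to-world affine, so world coordinates survive a
#' round trip for any invertible affine.
#'
#' @param tractogram a [Tractogram-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeTrk <- function(tractogram, path) {
  grid <- tractogram@grid
  zooms <- voxelEdges(grid)
  inv <- solve(grid@affine)
  con <- file(path, "wb")
  on.exit(close(con))
  wchar <- function(s, n) {
    b <- charToRaw(s)
    writeBin(c(b[seq_len(min(length(b), n))],
               raw(max(0, n - length(b)))), con)
  }
  wchar("TRACK", 6)
  writeBin(as.integer(grid@dims), con, size = 2, endian = "little")
  writeBin(as.numeric(zooms), con, size = 4, endian = "little")
  writeBin(as.numeric(c(0, 0, 0)), con, size = 4, endian = "little")  # origin
  writeBin(0L, con, size = 2, endian = "little")   # n_scalars
  writeBin(raw(200), con)                          # scalar names
  writeBin(0L, con, size = 2, endian = "little")   # n_properties
  writeBin(raw(200), con)                          # property names
  writeBin(as.numeric(t(grid@affine)), con, size = 4, endian = "little")
  writeBin(raw(444), con)                          # reserved
  wchar("RAS", 4)                                  # voxel_order
  wchar("", 4)                                     # pad2
  writeBin(as.numeric(c(1, 0, 0, 0, 1, 0)), con, size = 4, endian = "little")
  writeBin(raw(2), con)                            # pad1
  writeBin(raw(6), con)                            # invert/swap flags
  writeBin(length(tractogram), con, size = 4, endian = "little")
  writeBin(2L, con, size = 4, endian = "little")   # version
  writeBin(1000L, con, size = 4, endian = "little")
  for (s in streamlines(tractogram)) {
    vox <- t(inv[1:3, 1:3] %*% t(s) + inv[1:3, 4])        # voxel indices
    voxmm <- sweep(vox + 0.5, 2, zooms, `*`)
    writeBin(nrow(s), con, size = 4, endian = "little")
    writeBin(as.numeric(t(voxmm)), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a TrackVis TRK tractogram
#'
#' Parses the version-2 header, converts voxmm-stored points back to world
#' mm with the header affine, and returns a [Tractogram-class] whose grid
#' carries the header's dimensions and affine.
#'
#' @param path TRK file.
#' @return a [Tractogram-class].
#' @export
readTrk <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 6)[1:5])
  if (magic != "TRACK")
    stop("not a TRK file (bad magic at byte 0): ", path)
  dims <- readBin(con, "integer", 3, size = 2, endian = "little")
  zooms <- readBin(con, "numeric", 3, size = 4, endian = "little")
  invisible(readBin(con, "numeric", 3, size = 4, endian = "little"))
  nScalars <- readBin(con, "integer", 1, size = 2, endian = "little")
  invisible(readBin(con, "raw", 200))
  nProps <- readBin(con, "integer", 1, size = 2, endian = "little")
  invisible(readBin(con, "raw", 200))
  aff <- matrix(readBin(con, "numeric", 16, size = 4, endian = "little"),
                4, 4, byrow = TRUE)
  invisible(readBin(con, "raw", 444 + 4 + 4 + 24 + 2 + 6))
  nCount <- readBin(con, "integer", 1, size = 4, endian = "little")
  version <- readBin(con, "integer", 1, size = 4, endian = "little")
  hdrSize <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (hdrSize != 1000L)
    stop("malformed TRK header (hdr_size != 1000 at byte 996): ", path)
  if (all(aff == 0)) aff <- diag(4)
  grid <- VolumeGrid(pmax(dims, 1L), affine = aff)
  sl <- list()
  repeat {
    npts <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (length(npts) == 0L) break
    vals <- readBin(con, "numeric", npts * (3 + nScalars), size = 4,
                    endian = "little")
    if (nProps > 0)
      invisible(readBin(con, "numeric", nProps, size = 4, endian = "little"))
    m <- matrix(vals, ncol = 3 + nScalars, byrow = TRUE)[, 1:3, drop = FALSE]
    vox <- sweep(m, 2, zooms, `/`) - 0.5
    sl[[length(sl) + 1L]] <- t(aff[1:3, 1:3] %*% t(vox) + aff[1:3, 4])
  }
  if (nCount > 0 && length(sl) != nCount)
    warning("TRK declared ", nCount, " tracks but contained ", length(sl))
  Tractogram(sl, grid)
}

#' Write a binary mask (or scalar map) as NIfTI-1
#'
#' @param vol 3-D array (logical masks are written as uint8).
#' @param grid a [VolumeGrid-class] supplying the affine.
#' @param path output `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
writeMaskNifti <- function(vol, grid, path) {
  dat <- if (is.logical(vol)) array(as.integer(vol), dim(vol)) else vol
  img <- RNifti::asNifti(dat)
  img <- RNifti::`sform<-`(img, structure(grid@affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume and its grid
#'
#' @param path NIfTI file.
#' @return list: `data` (array) and `grid` (a [VolumeGrid-class] from the
#'   xform affine).
#' @export
readMaskNifti <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- matrix(RNifti::xform(img), 4, 4)
  list(data = array(as.vector(img), dim(img)),
       grid = VolumeGrid(dim(img)[1:3], affine = aff))
}

#' Read / write FSL-style bval and bvec files
#'
#' bvals are one whitespace-separated row; bvecs are three rows (x, y, z).
#'
#' @param bvalPath,bvecPath file paths.
#' @return an [AcquisitionScheme-class].
#' @export
readScheme <- function(bvalPath, bvecPath) {
  bvals <- scan(bvalPath, quiet = TRUE)
  bv <- as.matrix(read.table(bvecPath))
  if (nrow(bv) == 3L) bv <- t(bv)
  AcquisitionScheme(bvals, bv)
}

#' @rdname readScheme
#' @param scheme an [AcquisitionScheme-class] to write.
#' @export
writeScheme <- function(scheme, bvalPath, bvecPath) {
  writeLines(paste(scheme@bvals, collapse = " "), bvalPath)
  write.table(t(scheme@bvecs), bvecPath, row.names = FALSE,
              col.names = FALSE)
  invisible(NULL)
}

#' Write / read cohort and feature tables as TSV
#'
#' Plain tab-separated values with a header row; numeric values survive a
#' round trip exactly (full precision).
#'
#' @param df data.frame to write.
#' @param path TSV file.
#' @export
writeTsv <- function(df, path) {
  write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTsv
#' @export
readTsv <- function(path) {
  read.delim(path, sep = "\t", check.names = FALSE)
}

#' Write an SAFExperiment to cohort + feature TSV files
#'
#' @param se an [SAFExperiment-class].
#' @param cohortPath,featuresPath output TSVs (long feature format).
#' @export
writeExperimentTsv <- function(se, cohortPath, featuresPath) {
  writeTsv(cohortTable(se), cohortPath)
  writeTsv(featureTable(se), featuresPath)
  invisible(NULL)
}

#' Read an SAFExperiment back from cohort + feature TSV files
#'
#' @param cohortPath,featuresPath TSVs written by [writeExperimentTsv()].
#' @return an [SAFExperiment-class].
#' @export
readExperimentTsv <- function(cohortPath, featuresPath) {
  cohort <- readTsv(cohortPath)
  feat <- readTsv(featuresPath)
  ids <- cohort$participant_id
  combos <- unique(feat[, c("pathway", "tier", "feature")])
  m <- matrix(NA_real_, nrow(combos), length(ids))
  key <- paste(feat$pathway, feat$tier, feat$feature, sep = ".")
  ckey <- paste(combos$pathway, combos$tier, combos$feature, sep = ".")
  m[cbind(match(key, ckey), match(feat$participant_id, ids))] <- feat$value
  rownames(m) <- ckey
  colnames(m) <- ids
  SAFExperiment(m, rowData = combos,
    colData = data.frame(Age = cohort$Age, Sex = cohort$Sex,
                         TICV = cohort$TICV, row.names = ids))
}
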