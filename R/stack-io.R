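#' Write a FretStack as a 16-bit multi-page TIFF
#'
#' Pages are ordered z-major, channel-minor (DxDm, DxAm, AxAm per slice).
#' Intensities are clipped to \[0, 65535\] and rounded. Because baseline
#' TIFF tags cannot carry voxel size and channel order portably, a YAML
#' sidecar (`<path>.yaml`) records voxel size (um), channel order and
#' stack shape; [readStack()] requires it (or an explicit voxel size).
#'
#' @param stack a [FretStack-class].
#' @param path output TIFF path.
#' @return Invisibly, the sidecar path.
#' @export
writeStack <- function(stack, path) {
  stopifnot(is(stack, "FretStack"))
  stk <- quantizeStack(stack)
  d <- dim(stk)
  pages <- vector("list", d[3] * 3L)
  p <- 0L
  for (z in seq_len(d[3])) {
    for (nm in fretChannels()) {
      p <- p + 1L
      pages[[p]] <- t(stk@channels[[nm]][, , z]) / 65535
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L,
                  compression = "deflate", reduce = FALSE)
  side <- paste0(path, ".yaml")
  yaml::write_yaml(list(voxel_size_um = as.numeric(voxelSize(stack)),
                        channel_order = fretChannels(),
                        shape_xyz = as.integer(d)), side)
  invisible(side)
}

#' Read a FretStack written by [writeStack()]
#'
#' @param path TIFF path (sidecar `<path>.yaml` expected alongside).
#' @param voxelSize numeric(3) um; overrides/replaces the sidecar.
#' @return A [FretStack-class] with intensities in counts.
#' @export
readStack <- function(path, voxelSize = NULL) {
  side <- paste0(path, ".yaml")
  meta <- if (file.exists(side)) yaml::read_yaml(side) else NULL
  if (is.null(voxelSize)) {
    if (is.null(meta))
      stop("no sidecar metadata found; supply voxelSize")
    voxelSize <- as.numeric(meta$voxel_size_um)
  }
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  nPages <- length(pages)
  if (nPages %% 3L != 0L) stop("page count is not a multiple of 3")
  nz <- nPages %/% 3L
  d1 <- dim(pages[[1]])
  arr <- function(chIdx) {
    a <- array(0, c(d1[2], d1[1], nz))
    for (z in seq_len(nz))
      a[, , z] <- t(pages[[(z - 1L) * 3L + chIdx]]) * 65535
    round(a)
  }
  FretStack(arr(1L), arr(2L), arr(3L), voxelSize = voxelSize)
}

#' Write a LabelMap as a 16-bit multi-page TIFF
#'
#' One page per z-slice; label ids are stored as 16-bit grey values.
#'
#' @param labels a [LabelMap-class] with at most 65535 labels.
#' @param path output TIFF path.
#' @return Invisibly, the sidecar path.
#' @export
writeLabelMap <- function(labels, path) {
  stopifnot(is(labels, "LabelMap"))
  if (nLabels(labels) > 65535L) stop("too many labels for 16-bit storage")
  d <- dim(labelData(labels))
  pages <- lapply(seq_len(d[3]), function(z)
    t(labelData(labels)[, , z]) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L,
                  compression = "deflate", reduce = FALSE)
  side <- paste0(path, ".yaml")
  yaml::write_yaml(list(voxel_size_um = as.numeric(voxelSize(labels)),
                        shape_xyz = as.integer(d)), side)
  invisible(side)
}

#' Read a LabelMap written by [writeLabelMap()]
#' @param path TIFF path.
#' @param voxelSize numeric(3) um; overrides the sidecar.
#' @return A [LabelMap-class].
#' @export
readLabelMap <- function(path, voxelSize = NULL) {
  side <- paste0(path, ".yaml")
  meta <- if (file.exists(side)) yaml::read_yaml(side) else NULL
  if (is.null(voxelSize)) {
    if (is.null(meta)) stop("no sidecar metadata found; supply voxelSize")
    voxelSize <- as.numeric(meta$voxel_size_um)
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  d1 <- dim(pages[[1]])
  a <- array(0L, c(d1[2], d1[1], length(pages)))
  for (z in seq_along(pages))
    a[, , z] <- as.integer(round(t(pages[[z]]) * 65535))
  LabelMap(a, voxelSize)
}

#' Write a 2D image as PNG
#'
#' Grayscale matrices and RGB arrays (\[x, y\] or \[x, y, 3\], values in
#' \[0,1\]) are transposed to PNG row-major convention on write.
#'
#' @param image matrix or 3-channel array.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeImagePNG <- function(image, path) {
  img <- if (length(dim(image)) == 2L) t(image) else aperm(image, c(2, 1, 3))
  png::writePNG(pmin(pmax(img, 0), 1), path)
  invisible(path)
}

#' Read a 2D image written by [writeImagePNG()]
#' @param path PNG path.
#' @return matrix (grayscale) or \[x, y, 3\] array, values in \[0,1\].
#' @export
readImagePNG <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) return(t(img))
  if (dim(img)[3] == 4L) img <- img[, , 1:3]   # drop alpha
  aperm(img, c(2, 1, 3))
}
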