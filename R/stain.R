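# fit a circular disk mask to the non-white region of an RGB image
.autoCircle <- function(image) {
  nonwhite <- pmin(image[, , 1], image[, , 2], image[, , 3]) < 0.95
  if (sum(nonwhite) < 50)
    stop("could not resolve a disk by auto_circle; supply a mask ",
         "(diskMode = 'provided_mask')")
  idx <- which(nonwhite)
  i <- ((idx - 1L) %% nrow(nonwhite)) + 1L
  j <- ((idx - 1L) %/% nrow(nonwhite)) + 1L
  cx <- mean(i); cy <- mean(j)
  r <- sqrt(length(idx) / pi)
  xg <- matrix(seq_len(nrow(nonwhite)), nrow(nonwhite), ncol(nonwhite))
  yg <- matrix(seq_len(ncol(nonwhite)), nrow(nonwhite), ncol(nonwhite),
               byrow = TRUE)
  (xg - cx)^2 + (yg - cy)^2 <= r^2
}

#' Segment stained pixels in an RGB leaf-disk image
#'
#' Classifies each pixel by the stain's colour rule and intersects the
#' result with the disk mask, so stain-coloured splash outside the disk is
#' ignored. Rules (all tunable via [stainParams()]):
#' \itemize{
#'   \item trypan blue: blue channel exceeds red by `blueMargin`;
#'   \item DAB: HSV hue inside a brown window with a saturation floor;
#'   \item chlorosis: HSV hue inside a yellow window with a saturation
#'     floor.
#' }
#' Hue windows are robust to overall illumination scaling, which manual
#' threshold picking is not. The disk mask is either fitted automatically
#' as a circle over the non-white region (`auto_circle`) or supplied by the
#' caller (`provided_mask`) — e.g. a rosette mask for whole-plant chlorotic
#' damage, which uses the identical computation.
#'
#' @param image numeric array \[x, y, 3\] in \[0,1\].
#' @param params a [StainParams-class].
#' @param mask logical matrix, required when
#'   `diskMode = "provided_mask"`.
#' @return logical matrix of stained pixels inside the disk.
#' @examples
#' d <- generateStainedDisk(diskRadiusPx = 50, stainedFraction = 0.1,
#'                          seed = 3)
#' mean(stainedMask(d$image, stainParams("trypan_blue"))[d$diskMask])
#' @export
stainedMask <- function(image, params, mask = NULL) {
  validObject(params)
  stopifnot(length(dim(image)) == 3L, dim(image)[3] == 3L)
  disk <- switch(params@diskMode,
                 auto_circle = .autoCircle(image),
                 provided_mask = {
                   if (is.null(mask)) stop("provided_mask requires `mask`")
                   mask
                 })
  r <- image[, , 1]; g <- image[, , 2]; b <- image[, , 3]
  stained <- if (params@stain == "trypan_blue") {
    b - r >= params@blueMargin
  } else {
    hsv <- rgb2hsv(as.vector(r), as.vector(g), as.vector(b),
                   maxColorValue = 1)
    hit <- hsv[1, ] >= params@hueWindow[1] &
           hsv[1, ] <= params@hueWindow[2] &
           hsv[2, ] >= params@saturationFloor
    matrix(hit, nrow(r), ncol(r))
  }
  stained & disk
}

#' Stained area in square millimetres
#'
#' `count(stained pixels) * pixelSize^2 / 1e6` — the square-millimetre
#' readout used for trypan-blue cell death and chlorotic damage.
#'
#' @param mask logical matrix from [stainedMask()].
#' @param pixelSize um per pixel.
#' @return Area in mm^2.
#' @examples
#' stainedArea(matrix(rep(c(TRUE, FALSE), 5000), 100), pixelSize = 10)
#' @export
stainedArea <- function(mask, pixelSize) {
  stopifnot(is.logical(mask), pixelSize > 0)
  sum(mask) * pixelSize^2 / 1e6
}

#' Relative staining units
#'
#' Normalises sample areas by the control-group mean, so the control mean
#' maps to 1.0 — the relative-DAB-staining-unit readout for H2O2
#' accumulation.
#'
#' @param sampleAreas numeric vector.
#' @param controlAreas numeric vector with positive mean.
#' @return Numeric vector of relative units, same length as `sampleAreas`.
#' @examples
#' relativeStaining(2.0, c(0.5, 1.5))
#' @export
relativeStaining <- function(sampleAreas, controlAreas) {
  m <- mean(controlAreas)
  if (!is.finite(m) || m <= 0) stop("control mean must be > 0")
  sampleAreas / m
}
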