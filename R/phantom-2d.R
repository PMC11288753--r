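#' Generate a synthetic stomatal impression image
#'
#' Emulates a nail-varnish leaf impression: dark filled elliptical pores on
#' a bright background. Pore major-axis length and aperture (width/length)
#' ratio are drawn uniformly from the given ranges; orientations are
#' uniform. Pores are placed by rejection sampling so that bounding circles
#' do not overlap. Deterministic given `seed`.
#'
#' @param nPores number of pores.
#' @param lengthRange numeric(2), pore major-axis length range, um.
#' @param apertureRatioRange numeric(2), width/length range in (0, 1\].
#' @param pixelSize um per pixel.
#' @param imageShape integer(2), pixels (width, height). The default
#'   1000 x 500 at 1 um/px is a 0.5 mm^2 field.
#' @param background,foreground grayscale levels in \[0,1\].
#' @param seed integer seed.
#' @param maxAttempts placement attempts per pore.
#' @return list with `image` (numeric matrix, \[0,1\], indexed \[x, y\]),
#'   `truth` (data.frame: id, cx, cy (um), length, width (um),
#'   aperture_ratio, theta) and `fieldAreaMm2`.
#' @examples
#' imp <- generateImpression(nPores = 10, seed = 4)
#' imp$fieldAreaMm2
#' @export
generateImpression <- function(nPores = 30, lengthRange = c(18, 30),
                               apertureRatioRange = c(0.2, 0.5),
                               pixelSize = 1,
                               imageShape = c(1000L, 500L),
                               background = 0.85, foreground = 0.15,
                               seed = 1L, maxAttempts = 5000L) {
  stopifnot(nPores >= 0, lengthRange[1] > 0,
            lengthRange[1] <= lengthRange[2],
            apertureRatioRange[1] > 0, apertureRatioRange[2] <= 1,
            pixelSize > 0)
  set.seed(seed)
  nx <- as.integer(imageShape[1]); ny <- as.integer(imageShape[2])
  field <- c(nx, ny) * pixelSize
  img <- matrix(background, nx, ny)
  placed <- matrix(numeric(0), ncol = 3)   # cx, cy, bounding radius (um)
  rows <- list()
  for (i in seq_len(nPores)) {
    ok <- FALSE
    for (att in seq_len(maxAttempts)) {
      len <- runif(1, lengthRange[1], lengthRange[2])
      ar <- runif(1, apertureRatioRange[1], apertureRatioRange[2])
      a <- len / 2; b <- a * ar
      p <- c(runif(1, a + pixelSize, field[1] - a - pixelSize),
             runif(1, a + pixelSize, field[2] - a - pixelSize))
      if (nrow(placed)) {
        d <- sqrt((placed[, 1] - p[1])^2 + (placed[, 2] - p[2])^2)
        if (any(d < placed[, 3] + a + 2 * pixelSize)) next
      }
      theta <- runif(1, 0, pi)
      placed <- rbind(placed, c(p, a))
      rows[[i]] <- data.frame(id = i, cx = p[1], cy = p[2], length = len,
                              width = 2 * b, aperture_ratio = ar,
                              theta = theta)
      # rasterise with subpixel coverage shading (8x8 supersampling), as
      # optics blur real pore edges over a pixel
      i0 <- max(1L, floor((p[1] - a) / pixelSize) - 1L)
      i1 <- min(nx, ceiling((p[1] + a) / pixelSize) + 2L)
      j0 <- max(1L, floor((p[2] - a) / pixelSize) - 1L)
      j1 <- min(ny, ceiling((p[2] + a) / pixelSize) + 2L)
      cov <- matrix(0, length(i0:i1), length(j0:j1))
      off <- ((seq_len(8L) - 0.5) / 8 - 0.5) * pixelSize
      for (ox in off) for (oy in off) {
        xs <- (i0:i1 - 0.5) * pixelSize + ox - p[1]
        ys <- (j0:j1 - 0.5) * pixelSize + oy - p[2]
        U <- outer(xs * cos(theta), ys * sin(theta), "+")
        V <- outer(-xs * sin(theta), ys * cos(theta), "+")
        cov <- cov + ((U / a)^2 + (V / b)^2 <= 1)
      }
      cov <- cov / 64
      img[i0:i1, j0:j1] <- img[i0:i1, j0:j1] -
        cov * (background - foreground)
      ok <- TRUE
      break
    }
    if (!ok)
      stop(sprintf("could not place pore %d of %d without overlap", i,
                   nPores))
  }
  truth <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = integer(), cx = numeric(), cy = numeric(),
               length = numeric(), width = numeric(),
               aperture_ratio = numeric(), theta = numeric())
  list(image = img, truth = truth,
       fieldAreaMm2 = prod(field) / 1e6)
}

# default stain colours (RGB in [0,1])
.stainColor <- function(stain) {
  switch(stain,
         trypan_blue = c(0.25, 0.30, 0.75),
         dab = c(0.45, 0.30, 0.12),
         chlorosis = c(0.85, 0.80, 0.25),
         stop("unknown stain '", stain, "'"))
}

#' Generate a synthetic stained leaf disk
#'
#' Renders a circular leaf disk (pale green) on a white background, with
#' randomly placed stained blobs of the requested stain colour covering
#' `stainedFraction` of the disk area to within 1%. Blob geometry depends
#' only on the seed and the geometric parameters, so the same seed with a
#' different stain yields an identical mask in a different colour. A truth
#' mask and the exact stained pixel count are returned. Optional
#' `outsideSplash` blobs of stain colour are placed outside the disk to
#' exercise disk masking.
#'
#' @param diskRadiusPx disk radius in pixels.
#' @param stainedFraction target stained fraction of the disk, in \[0, 0.8\]
#'   (higher packing is refused).
#' @param stain "trypan_blue", "dab" or "chlorosis".
#' @param seed integer seed.
#' @param blobRadiusRange integer(2), blob radius range in pixels.
#' @param outsideSplash number of stain-coloured blobs outside the disk.
#' @return list with `image` (array height-less \[x, y, 3\] in \[0,1\]),
#'   `mask` (logical matrix, truth stained pixels inside the disk),
#'   `diskMask` (logical), `stainedPx`, `diskPx`, `fraction`.
#' @examples
#' d <- generateStainedDisk(diskRadiusPx = 60, stainedFraction = 0.2,
#'                          seed = 5)
#' abs(d$fraction - 0.2) < 0.01
#' @export
generateStainedDisk <- function(diskRadiusPx = 200, stainedFraction = 0.25,
                                stain = c("trypan_blue", "dab",
                                          "chlorosis"),
                                seed = 1L, blobRadiusRange = c(4L, 12L),
                                outsideSplash = 0L) {
  stain <- match.arg(stain)
  stopifnot(stainedFraction >= 0, diskRadiusPx >= 10)
  if (stainedFraction > 0.8)
    stop("stainedFraction above 0.8 exceeds achievable blob packing")
  set.seed(seed)
  margin <- max(8L, as.integer(0.15 * diskRadiusPx))
  n <- as.integer(2L * diskRadiusPx + 2L * margin)
  cx <- (n + 1) / 2; cy <- (n + 1) / 2
  xg <- matrix(seq_len(n), n, n)
  yg <- matrix(seq_len(n), n, n, byrow = TRUE)
  diskMask <- (xg - cx)^2 + (yg - cy)^2 <= diskRadiusPx^2
  diskPx <- sum(diskMask)
  target <- round(stainedFraction * diskPx)

  mask <- matrix(FALSE, n, n)
  it <- 0L
  while (sum(mask) < target && it < 20000L) {
    it <- it + 1L
    remaining <- target - sum(mask)
    rmax <- min(blobRadiusRange[2], max(1, floor(sqrt(remaining / pi))))
    rchoices <- seq(min(blobRadiusRange[1], rmax), rmax)
    r <- if (length(rchoices) == 1L) rchoices else sample(rchoices, 1L)
    ang <- runif(1, 0, 2 * pi)
    rad <- sqrt(runif(1)) * (diskRadiusPx - 1)
    bx <- cx + rad * cos(ang); by <- cy + rad * sin(ang)
    blob <- (xg - bx)^2 + (yg - by)^2 <= r^2
    mask <- mask | (blob & diskMask)
  }
  if (target > 0 && abs(sum(mask) - target) / diskPx > 0.01)
    stop("could not reach the requested stained fraction within 1%")

  splash <- matrix(FALSE, n, n)
  if (outsideSplash > 0) {
    for (s in seq_len(outsideSplash)) {
      for (att in 1:200) {
        bx <- runif(1, 3, n - 3); by <- runif(1, 3, n - 3)
        if ((bx - cx)^2 + (by - cy)^2 >
              (diskRadiusPx + blobRadiusRange[2] + 2)^2) break
      }
      blob <- (xg - bx)^2 + (yg - by)^2 <= blobRadiusRange[1]^2
      splash <- splash | (blob & !diskMask)
    }
  }

  col <- .stainColor(stain)
  leaf <- c(0.55, 0.75, 0.45)
  img <- array(1, c(n, n, 3))
  for (k in 1:3) {
    plane <- img[, , k]
    plane[diskMask] <- leaf[k]
    plane[mask] <- col[k]
    plane[splash] <- col[k]
    img[, , k] <- plane
  }
  list(image = img, mask = mask, diskMask = diskMask,
       stainedPx = sum(mask), diskPx = diskPx,
       fraction = sum(mask) / diskPx)
}
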