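#' Detect stomatal pores in an impression image
#'
#' Dark-object segmentation of a 2D grayscale impression: the image is
#' inverted-thresholded (Otsu by default), connected components are
#' labelled (8-connectivity) and components outside the pixel-area bounds
#' are discarded. Each surviving pore is then fitted subpixel-accurately
#' using the partial-coverage shading of its edges: per-pixel darkness is
#' converted to a coverage weight `(bg - I) / (bg - fg)`, the orientation
#' and major semi-axis come from the coverage-weighted second moments
#' (`semi-axis = 2 sqrt(lambda)` for a uniform ellipse), and the minor
#' semi-axis closes the system through the exact weighted area,
#' `b = area / (pi a)` — the area is the most robust quantity on images
#' with blurred edges, which makes the width/length aperture ratio
#' accurate down to pores a few pixels wide. The fit residual reports the
#' relative disagreement between this area-based minor axis and the
#' moment-based one.
#'
#' @param image numeric matrix in \[0,1\], indexed \[x, y\].
#' @param pixelSize um per pixel.
#' @param threshold "otsu" or a numeric grayscale threshold; pixels below
#'   it are object.
#' @param minAreaPx,maxAreaPx accepted component area, pixels.
#' @return data.frame (possibly empty): id, cx, cy (um), length, width
#'   (um), aperture_ratio, theta, area_px, fit_residual.
#' @examples
#' imp <- generateImpression(nPores = 5, seed = 2)
#' nrow(detectStomata(imp$image, pixelSize = 1))
#' @export
detectStomata <- function(image, pixelSize, threshold = "otsu",
                          minAreaPx = 20, maxAreaPx = 2000) {
  stopifnot(is.matrix(image), pixelSize > 0)
  thr <- if (identical(threshold, "otsu"))
    EBImage::otsu(image, range = c(0, 1), levels = 256L)
  else as.numeric(threshold)
  mask <- image < thr
  empty <- data.frame(id = integer(), cx = numeric(), cy = numeric(),
                      length = numeric(), width = numeric(),
                      aperture_ratio = numeric(), theta = numeric(),
                      area_px = integer(), fit_residual = numeric())
  if (!any(mask)) return(empty)
  m3 <- array(mask, c(dim(mask), 1L))
  lab <- cpp_label3d(m3, 26L)[, , 1]
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= minAreaPx & sizes <= maxAreaPx)
  if (!length(keep)) return(empty)
  bg <- median(image)    # background dominates an impression field

  rows <- lapply(seq_along(keep), function(q) {
    lbl <- keep[q]
    sel <- which(lab == lbl)
    i <- ((sel - 1L) %% nrow(lab)) + 1L
    j <- ((sel - 1L) %/% nrow(lab)) + 1L
    # bounding box with margin to capture the partial-coverage fringe
    i0 <- max(1L, min(i) - 3L); i1 <- min(nrow(image), max(i) + 3L)
    j0 <- max(1L, min(j) - 3L); j1 <- min(ncol(image), max(j) + 3L)
    sub <- image[i0:i1, j0:j1, drop = FALSE]
    labSub <- lab[i0:i1, j0:j1, drop = FALSE]
    fg <- min(sub)
    w <- pmin(pmax((bg - sub) / max(bg - fg, 1e-6), 0), 1)
    w[labSub != 0L & labSub != lbl] <- 0   # exclude neighbouring pores
    w[w < 0.02] <- 0
    idx <- which(w > 0, arr.ind = TRUE)
    P <- cbind((i0 + idx[, 1] - 1L - 0.5) * pixelSize,
               (j0 + idx[, 2] - 1L - 0.5) * pixelSize)
    wt <- w[idx]
    area <- sum(wt) * pixelSize^2
    cen <- colSums(P * wt) / sum(wt)
    Pc <- sweep(P, 2, cen)
    S <- crossprod(Pc * sqrt(wt)) / sum(wt)
    e <- eigen(S, symmetric = TRUE)
    ev <- pmax(e$values, 1e-12)
    a <- 2 * sqrt(ev[1])
    bMom <- 2 * sqrt(ev[2])
    b <- min(area / (pi * a), a)
    data.frame(id = q, cx = cen[1], cy = cen[2],
               length = 2 * a, width = 2 * b,
               aperture_ratio = b / a,
               theta = atan2(e$vectors[2, 1], e$vectors[1, 1]) %% pi,
               area_px = length(sel),
               fit_residual = abs(bMom - b) / b)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Stomatal density
#'
#' @param records pore records from [detectStomata()].
#' @param fieldAreaMm2 imaged field area, mm^2 (> 0).
#' @return data.frame: count, field_area_mm2, density_per_mm2.
#' @examples
#' stomatalDensity(data.frame(id = 1:30), fieldAreaMm2 = 0.5)
#' @export
stomatalDensity <- function(records, fieldAreaMm2) {
  if (fieldAreaMm2 <= 0) stop("field area must be > 0")
  data.frame(count = nrow(records), field_area_mm2 = fieldAreaMm2,
             density_per_mm2 = nrow(records) / fieldAreaMm2)
}

#' Summarise aperture ratios by group
#'
#' Group means with s.d. and s.e.m. of the width/length aperture ratio,
#' in the same form as [summarizeRatios()].
#'
#' @param records pore records with an `aperture_ratio` column.
#' @param group vector of group labels, one per record (default: one
#'   group).
#' @return data.frame: group, n, mean, sd, sem, qc.
#' @export
apertureSummary <- function(records, group = rep("all", nrow(records))) {
  if (nrow(records) == 0L) stop("no pore records to summarise")
  df <- records
  df$group <- factor(group)
  .summarizeBy(df, "aperture_ratio", "group")
}
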