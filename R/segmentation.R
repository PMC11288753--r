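# Global Otsu threshold over a whole volume, on a 256-bin histogram of
# [0, max]. Same between-class-variance maximisation as EBImage::otsu
# (which is the cross-check oracle in the tests) but computed over the
# full 3D volume in one pass — EBImage thresholds per 2D frame and its
# histogram pass is costly on multi-megavoxel stacks.
.otsuGlobal <- function(v) {
  hi <- max(v)
  if (hi <= 0) return(Inf)
  counts <- cpp_hist256(as.numeric(v), hi)
  mids <- (seq_len(256) - 0.5) * hi / 256
  w1 <- cumsum(counts)
  w2 <- w1[256] + counts - w1
  cm <- counts * mids
  m1 <- cumsum(cm)
  m2 <- m1[256] + cm - m1
  bcv <- w1 * w2 * (m2 / w2 - m1 / w1)^2
  maxi <- which(bcv == max(bcv, na.rm = TRUE))
  (mids[maxi[1]] + mids[maxi[length(maxi)]]) / 2
}

#' Segment nuclei from the AxAm channel
#'
#' FRETENATOR-style thresholding segmentation: the AxAm (sensor-abundance)
#' channel is Gaussian-smoothed (sigma in um, converted to voxels per axis
#' for anisotropic grids), globally thresholded (Otsu on 256 levels, or a
#' fixed intensity), connected components are labelled under the configured
#' connectivity, components outside the volume bounds are removed, and the
#' survivors are relabelled 1..N. Touching nuclei are not split by
#' watershed: the phantom generator guarantees separation, and genuine
#' merges are removed by the upper volume bound.
#'
#' An empty (all-zero) channel yields a label map with zero labels; a fixed
#' threshold above the maximum intensity yields zero labels with a warning.
#'
#' @param stack a [FretStack-class].
#' @param params a [SegmentationParams-class].
#' @return A [LabelMap-class].
#' @examples
#' cfg <- sceneConfig(imageShape = c(96L, 96L, 40L), voxelSize = c(1, 1, 2),
#'                    counts = c(stomata = 2, pavement = 0,
#'                               spongy_mesophyll = 1, bundle_sheath = 0,
#'                               vascular_bundle = 0),
#'                    noiseModel = "none", backgroundLevel = c(0, 0, 0),
#'                    seed = 2)
#' stk <- renderStack(generateLeafScene(cfg), cfg)
#' nLabels(segmentNuclei(stk))
#' @export
setMethod("segmentNuclei", "FretStack", function(stack, params) {
  validObject(params)
  v <- channel(stack, "AxAm")
  vs <- voxelSize(stack)
  if (params@gaussianSigma > 0) {
    sigmaVox <- params@gaussianSigma / vs
    v <- cpp_gauss_blur3d(v, sigmaVox)
  }
  thr <- switch(params@thresholdMethod,
                otsu = .otsuGlobal(v),
                fixed = params@fixedThreshold)
  if (params@thresholdMethod == "fixed" && thr > max(v))
    warning("fixed threshold above maximum intensity: no labels")
  mask <- v > thr
  if (!any(mask))
    return(LabelMap(array(0L, dim(v)), vs))
  labels <- cpp_label3d(mask, params@connectivity)
  voxVol <- prod(vs)
  sizes <- tabulate(labels[labels > 0L])
  keep <- which(sizes * voxVol >= params@minVolume &
                sizes * voxVol <= params@maxVolume)
  lut <- integer(length(sizes) + 1L)       # index 1 = background 0
  lut[keep + 1L] <- seq_along(keep)
  relab <- array(lut[labels + 1L], dim(labels))
  LabelMap(relab, vs)
})

#' Extract per-nucleus geometric and intensity features
#'
#' Computes the per-nucleus "Result Table" analog: voxel count and volume,
#' centroid and depth below stack top (um, using the anisotropic voxel
#' size), equivalent spherical diameter, principal semi-axes a >= b >= c
#' from the second-moment ellipsoid (eigenvalues lambda of the voxel-centre
#' covariance, with the voxel self-variance added, scaled as
#' `semi-axis = sqrt(5 lambda)` for a uniform ellipsoid), elongation a/b,
#' flatness b/c, neighbour density (count of other nucleus centroids within
#' `rNb` um), and mean raw intensity of each channel over the nucleus
#' voxels. Intensity means use the unsmoothed stack — anisotropy is handled
#' by physical-unit conversion, not resampling, to avoid interpolation
#' artefacts.
#'
#' Single-voxel (degenerate) objects get semi-axes equal to the voxel
#' dimensions and qc flag `"degenerate_shape"`.
#'
#' @param labels a [LabelMap-class].
#' @param stack the matching [FretStack-class].
#' @param rNb neighbourhood radius, um.
#' @return data.frame with one row per label: id, voxel_count, volume_um3,
#'   cx, cy, cz, depth_z, equiv_diam, axis_a, axis_b, axis_c, elongation,
#'   flatness, neighbor_density, mean_DxDm, mean_DxAm, mean_AxAm, qc_flags,
#'   plus placeholder columns emission_ratio, excluded, cell_type.
#' @export
extractFeatures <- function(labels, stack, rNb = 20) {
  stopifnot(is(labels, "LabelMap"), is(stack, "FretStack"))
  if (!identical(dim(labelData(labels)), dim(stack)))
    stop("label map and stack dimensions differ")
  lab <- labelData(labels)
  vs <- voxelSize(labels)
  n <- nLabels(labels)
  empty <- data.frame(id = integer(), voxel_count = integer(),
                      volume_um3 = numeric(), cx = numeric(),
                      cy = numeric(), cz = numeric(), depth_z = numeric(),
                      equiv_diam = numeric(), axis_a = numeric(),
                      axis_b = numeric(), axis_c = numeric(),
                      elongation = numeric(), flatness = numeric(),
                      neighbor_density = integer(), mean_DxDm = numeric(),
                      mean_DxAm = numeric(), mean_AxAm = numeric(),
                      qc_flags = character(), emission_ratio = numeric(),
                      excluded = logical(), cell_type = character())
  if (n == 0L) return(empty)

  dims <- dim(lab)
  idx <- which(lab > 0L)
  l <- lab[idx]
  ord <- order(l)
  idx <- idx[ord]; l <- l[ord]
  # voxel centre coordinates in um
  i <- ((idx - 1L) %% dims[1]) + 1L
  j <- (((idx - 1L) %/% dims[1]) %% dims[2]) + 1L
  k <- ((idx - 1L) %/% (dims[1] * dims[2])) + 1L
  xs <- (i - 0.5) * vs[1]; ys <- (j - 0.5) * vs[2]; zs <- (k - 0.5) * vs[3]

  ch <- lapply(fretChannels(), function(nm) channel(stack, nm)[idx])
  names(ch) <- fretChannels()

  split_idx <- split(seq_along(l), l)
  voxVar <- vs^2 / 12    # second moment of a voxel about its centre

  rows <- lapply(seq_len(n), function(lbl) {
    sel <- split_idx[[as.character(lbl)]]
    cnt <- length(sel)
    P <- cbind(xs[sel], ys[sel], zs[sel])
    cen <- colMeans(P)
    qc <- character()
    if (cnt == 1L) {
      ax <- sort(vs, decreasing = TRUE)
      qc <- c(qc, "degenerate_shape")
    } else {
      S <- crossprod(sweep(P, 2, cen)) / cnt
      diag(S) <- diag(S) + voxVar
      ev <- sort(eigen(S, symmetric = TRUE, only.values = TRUE)$values,
                 decreasing = TRUE)
      ax <- sqrt(5 * pmax(ev, 1e-9))
    }
    vol <- cnt * prod(vs)
    data.frame(id = lbl, voxel_count = cnt, volume_um3 = vol,
               cx = cen[1], cy = cen[2], cz = cen[3], depth_z = cen[3],
               equiv_diam = 2 * (3 * vol / (4 * pi))^(1 / 3),
               axis_a = ax[1], axis_b = ax[2], axis_c = ax[3],
               elongation = ax[1] / ax[2], flatness = ax[2] / ax[3],
               neighbor_density = 0L,
               mean_DxDm = mean(ch$DxDm[sel]),
               mean_DxAm = mean(ch$DxAm[sel]),
               mean_AxAm = mean(ch$AxAm[sel]),
               qc_flags = paste(qc, collapse = ";"),
               emission_ratio = NA_real_, excluded = FALSE,
               cell_type = NA_character_, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  # neighbour density on centroid distances
  D <- as.matrix(dist(out[, c("cx", "cy", "cz")]))
  out$neighbor_density <- as.integer(rowSums(D <= rNb) - 1L)
  rownames(out) <- NULL
  out
}

#' Estimate per-channel background from unlabelled voxels
#'
#' Median intensity of each channel over voxels not assigned to any
#' nucleus. Requires at least 1% of voxels to be unlabelled.
#'
#' @param stack a [FretStack-class].
#' @param labels the matching [LabelMap-class].
#' @return Named numeric(3), one median per channel.
#' @export
estimateBackground <- function(stack, labels) {
  stopifnot(is(stack, "FretStack"), is(labels, "LabelMap"))
  bgIdx <- labelData(labels) == 0L
  if (mean(bgIdx) < 0.01)
    stop("fewer than 1% of voxels are unlabelled; cannot estimate background")
  vapply(fretChannels(),
         function(nm) median(channel(stack, nm)[bgIdx]), numeric(1))
}
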