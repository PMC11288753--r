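#' Default shape priors of the layered leaf phantom
#'
#' One row per cell type: mean ellipsoid semi-axes `sa >= sb` (in-plane) and
#' `sc` (axial) in um, a per-axis Gaussian s.d., and the depth range of the
#' nuclear centres below the stack top. The layering follows the abaxial
#' confocal imaging order: epidermal classes (stomata, pavement) shallowest,
#' then spongy mesophyll, bundle sheath, and the vascular bundle deepest.
#' Stomata nuclei are small and near-spherical; pavement nuclei large and
#' flattened; mesophyll intermediate; bundle-sheath nuclei elongated with a
#' horizontal major axis; vascular nuclei small and clustered along a vein
#' axis (see [generateLeafScene()]).
#'
#' @return A data.frame with columns class, sa, sb, sc, sdAxes, depthMin,
#'   depthMax.
#' @examples
#' defaultShapePriors()
#' @export
defaultShapePriors <- function() {
  data.frame(
    class = cellTypes(),
    sa = c(2.5, 10.0, 4.5, 9.0, 2.8),
    sb = c(2.2, 7.0, 3.5, 3.0, 2.4),
    sc = c(2.0, 2.8, 3.0, 2.8, 2.2),
    sdAxes = c(0.25, 0.6, 0.35, 0.4, 0.25),
    depthMin = c(2, 3, 20, 35, 58),
    depthMax = c(12, 12, 52, 62, 76),
    stringsAsFactors = FALSE)
}

#' Configure a synthetic leaf scene
#'
#' Builds a [SceneConfig-class] describing one phantom acquisition. The
#' defaults describe the reference phantom used throughout the package's
#' validation: a 512 x 512 x 40 voxel stack at 0.5 x 0.5 x 2 um (256 x 256 x
#' 80 um field), 40 nuclei (10 stomata, 10 pavement, 10 spongy mesophyll,
#' 5 bundle sheath, 5 vascular), equal baseline ratio 1.0 in all classes,
#' donor-excited total emission T = 300 counts, AxAm level 400 counts,
#' background 5 counts per channel, and Poisson noise plus 2-count Gaussian
#' read noise (photon-counting detector model).
#'
#' The infestation scenario adds a per-class delta to the true ratio, largest
#' for the stomatal and vascular classes, and removes spongy-mesophyll nuclei
#' with probability `mesophyllDropout` (feeding-induced cell death); both are
#' recoverable ground truth, not hard-coded results.
#'
#' @param imageShape integer(3), voxels along x, y, z.
#' @param voxelSize numeric(3), um per voxel.
#' @param counts named integer(5), nuclei per class.
#' @param shapePriors data.frame as [defaultShapePriors()].
#' @param baselineRatio named numeric(5) or scalar, control true ratio.
#' @param infestedDelta named numeric(5) or scalar, ratio increase under
#'   infestation.
#' @param ratioJitterSD per-nucleus s.d. of the true ratio.
#' @param mesophyllDropout dropout probability in \[0,1\], applied only when
#'   `condition = "infested"`.
#' @param minCenterSeparation um; centre pairs are additionally kept at
#'   least the sum of their largest semi-axes apart so ellipsoids never
#'   overlap.
#' @param emissionTotal donor-excited total emission T, counts.
#' @param acceptorLevel AxAm signal A, counts.
#' @param brightnessJitterSD lognormal s.d. of per-nucleus T and A.
#' @param backgroundLevel numeric(3) per-channel background, counts.
#' @param noiseModel "none", "gaussian", "poisson" or "poisson_gaussian".
#' @param gaussianSD read-noise s.d., counts.
#' @param poissonScale photons per count.
#' @param condition "control" or "infested".
#' @param seed integer seed; scene generation uses `seed`, rendering noise
#'   uses `seed + 1`.
#' @return A [SceneConfig-class].
#' @examples
#' cfg <- sceneConfig(condition = "control", seed = 7)
#' cfg
#' @export
sceneConfig <- function(imageShape = c(512L, 512L, 40L),
                        voxelSize = c(0.5, 0.5, 2),
                        counts = c(stomata = 10L, pavement = 10L,
                                   spongy_mesophyll = 10L,
                                   bundle_sheath = 5L,
                                   vascular_bundle = 5L),
                        shapePriors = defaultShapePriors(),
                        baselineRatio = 1.0,
                        infestedDelta = c(stomata = 0.50, pavement = 0.15,
                                          spongy_mesophyll = 0.15,
                                          bundle_sheath = 0.20,
                                          vascular_bundle = 0.45),
                        ratioJitterSD = 0.05,
                        mesophyllDropout = 0,
                        minCenterSeparation = 8,
                        emissionTotal = 300, acceptorLevel = 400,
                        brightnessJitterSD = 0.1,
                        backgroundLevel = c(5, 5, 5),
                        noiseModel = c("poisson_gaussian", "none",
                                       "gaussian", "poisson"),
                        gaussianSD = 2, poissonScale = 1,
                        condition = c("control", "infested"),
                        seed = 1L) {
  ct <- cellTypes()
  expand5 <- function(x) {
    if (length(x) == 1L) x <- setNames(rep(x, 5L), ct)
    x[ct]
  }
  new("SceneConfig",
      imageShape = as.integer(imageShape), voxelSize = as.numeric(voxelSize),
      counts = setNames(as.integer(counts[ct]), ct),
      shapePriors = shapePriors,
      baselineRatio = expand5(baselineRatio),
      infestedDelta = expand5(infestedDelta),
      ratioJitterSD = ratioJitterSD,
      mesophyllDropout = mesophyllDropout,
      minCenterSeparation = minCenterSeparation,
      emissionTotal = emissionTotal, acceptorLevel = acceptorLevel,
      brightnessJitterSD = brightnessJitterSD,
      backgroundLevel = setNames(as.numeric(backgroundLevel),
                                 fretChannels()),
      noiseModel = match.arg(noiseModel), gaussianSD = gaussianSD,
      poissonScale = poissonScale, condition = match.arg(condition),
      seed = as.integer(seed))
}

# truncated-normal draw for semi-axes: the lower tail is clipped at two
# s.d. below the mean so every generated nucleus stays within the
# detectable size range the priors describe
.rposnorm <- function(n, mean, sd) {
  x <- rnorm(n, mean, sd)
  pmax(x, pmax(mean - 2 * sd, 0.2 * mean))
}

#' Generate the ground-truth table of a leaf scene
#'
#' Samples nucleus geometry and true biosensor state for one phantom.
#' Each nucleus gets: a cell-type class, a centre (um), ellipsoid semi-axes
#' `sa >= sb` in-plane and `sc` axial (um), an in-plane orientation theta
#' (radians), a true emission ratio `baseline + delta * [infested]` plus
#' Gaussian jitter, and per-nucleus donor-excited total emission T and
#' acceptor signal A (lognormal brightness jitter). Under
#' `condition = "infested"` each spongy-mesophyll nucleus is removed with
#' probability `mesophyllDropout`; removed nuclei appear neither in the
#' table nor in the rendered image.
#'
#' Placement is by rejection sampling under a hard-core constraint: any two
#' centres are at least `max(minCenterSeparation, sa_i + sa_j + 3)` um
#' apart (sa the largest semi-axis), which guarantees non-overlapping
#' ellipsoids with a surface gap no Gaussian smoothing bridge can close at
#' the default segmentation sigma. Vascular nuclei are
#' placed along a random vein axis (a horizontal line at vascular depth)
#' with 8--10 um spacing, giving them the high local neighbour density the
#' classifier exploits. Deterministic given `config@seed`.
#'
#' @param config a [SceneConfig-class].
#' @param maxAttempts rejection-sampling attempts per nucleus before
#'   aborting with an error naming the class.
#' @return A data.frame (one row per rendered nucleus): id, class, cx, cy,
#'   cz, sa, sb, sc, theta, true_ratio, emission_T, acceptor_A.
#' @examples
#' truth <- generateLeafScene(sceneConfig(seed = 3))
#' table(truth$class)
#' @export
generateLeafScene <- function(config, maxAttempts = 5000L) {
  stopifnot(is(config, "SceneConfig"))
  validObject(config)
  set.seed(config@seed)
  ct <- cellTypes()
  sp <- config@shapePriors
  rownames(sp) <- sp$class
  vs <- config@voxelSize
  field <- config@imageShape * vs          # um extents (x, y, z)
  infested <- config@condition == "infested"

  counts <- config@counts
  if (infested && counts["spongy_mesophyll"] > 0) {
    drop <- rbinom(counts["spongy_mesophyll"], 1L, config@mesophyllDropout)
    counts["spongy_mesophyll"] <- counts["spongy_mesophyll"] - sum(drop)
  }

  acc <- list()   # accepted nuclei, each: c(cx, cy, cz, amax)
  centers <- matrix(numeric(0), ncol = 4)

  sepOK <- function(p, amax) {
    if (nrow(centers) == 0L) return(TRUE)
    d <- sqrt((centers[, 1] - p[1])^2 + (centers[, 2] - p[2])^2 +
              (centers[, 3] - p[3])^2)
    req <- pmax(config@minCenterSeparation, centers[, 4] + amax + 3)
    all(d >= req)
  }

  rows <- list()
  placeClass <- function(cls, n) {
    pri <- sp[cls, ]
    for (i in seq_len(n)) {
      placed <- FALSE
      for (att in seq_len(maxAttempts)) {
        ax <- sort(.rposnorm(2, c(pri$sa, pri$sb), pri$sdAxes),
                   decreasing = TRUE)
        cz_ <- .rposnorm(1, pri$sc, pri$sdAxes)
        amax <- max(ax[1], cz_)
        zlo <- max(pri$depthMin, cz_ + 0.25)
        zhi <- min(pri$depthMax, field[3] - cz_ - 0.25)
        if (zlo >= zhi) next
        p <- c(runif(1, ax[1] + 0.5, field[1] - ax[1] - 0.5),
               runif(1, ax[1] + 0.5, field[2] - ax[1] - 0.5),
               runif(1, zlo, zhi))
        if (!sepOK(p, amax)) next
        centers <<- rbind(centers, c(p, amax))
        rows[[length(rows) + 1L]] <<- data.frame(
          class = cls, cx = p[1], cy = p[2], cz = p[3],
          sa = ax[1], sb = ax[2], sc = cz_, theta = runif(1, 0, pi),
          stringsAsFactors = FALSE)
        placed <- TRUE
        break
      }
      if (!placed)
        stop(sprintf(paste0("could not place a '%s' nucleus after %d ",
                            "attempts under the %g um separation ",
                            "constraint"),
                     cls, maxAttempts, config@minCenterSeparation))
    }
  }

  placeVein <- function(n) {
    pri <- sp["vascular_bundle", ]
    for (veinTry in seq_len(200L)) {
      phi <- runif(1, 0, pi)
      u <- c(cos(phi), sin(phi))
      mid <- c(runif(1, 0.3 * field[1], 0.7 * field[1]),
               runif(1, 0.3 * field[2], 0.7 * field[2]))
      z0 <- runif(1, pri$depthMin + 4, pri$depthMax - 4)
      spacing <- runif(1, 8, 10)
      ts <- (seq_len(n) - (n + 1) / 2) * spacing
      cand <- list()
      ok <- TRUE
      for (i in seq_len(n)) {
        ax <- sort(.rposnorm(2, c(pri$sa, pri$sb), pri$sdAxes),
                   decreasing = TRUE)
        cz_ <- .rposnorm(1, pri$sc, pri$sdAxes)
        amax <- max(ax[1], cz_)
        p <- c(mid + ts[i] * u + rnorm(2, 0, 1.5), z0 + rnorm(1, 0, 2))
        p[3] <- min(max(p[3], pri$depthMin + cz_),
                    min(pri$depthMax, field[3] - cz_ - 0.25))
        inb <- p[1] > ax[1] + 0.5 && p[1] < field[1] - ax[1] - 0.5 &&
               p[2] > ax[1] + 0.5 && p[2] < field[2] - ax[1] - 0.5
        if (!inb || !sepOK(p, amax)) { ok <- FALSE; break }
        # provisional within-vein separation
        if (length(cand)) {
          prev <- do.call(rbind, lapply(cand, function(r)
            c(r$cx, r$cy, r$cz, max(r$sa, r$sc))))
          d <- sqrt(colSums((t(prev[, 1:3, drop = FALSE]) - p)^2))
          if (any(d < prev[, 4] + amax + 1.5)) { ok <- FALSE; break }
        }
        cand[[i]] <- data.frame(class = "vascular_bundle", cx = p[1],
                                cy = p[2], cz = p[3], sa = ax[1],
                                sb = ax[2], sc = cz_,
                                theta = runif(1, 0, pi),
                                stringsAsFactors = FALSE)
      }
      if (ok) {
        for (r in cand) {
          centers <<- rbind(centers, c(r$cx, r$cy, r$cz, max(r$sa, r$sc)))
          rows[[length(rows) + 1L]] <<- r
        }
        return(invisible(NULL))
      }
    }
    stop(sprintf(paste0("could not place the vascular vein after 200 ",
                        "attempts under the %g um separation constraint"),
                 config@minCenterSeparation))
  }

  # large classes first for packing efficiency; vein last (deep zone)
  placeClass("pavement", counts["pavement"])
  placeClass("bundle_sheath", counts["bundle_sheath"])
  placeClass("spongy_mesophyll", counts["spongy_mesophyll"])
  placeClass("stomata", counts["stomata"])
  if (counts["vascular_bundle"] > 0) placeVein(counts["vascular_bundle"])

  if (!length(rows))
    return(data.frame(id = integer(), class = character(),
                      cx = numeric(), cy = numeric(), cz = numeric(),
                      sa = numeric(), sb = numeric(), sc = numeric(),
                      theta = numeric(), true_ratio = numeric(),
                      emission_T = numeric(), acceptor_A = numeric(),
                      stringsAsFactors = FALSE))
  truth <- do.call(rbind, rows)
  # canonical row order: by class, then placement order
  truth <- truth[order(match(truth$class, ct)), , drop = FALSE]
  n <- nrow(truth)
  truth$true_ratio <- pmax(
    config@baselineRatio[truth$class] +
      (if (infested) config@infestedDelta[truth$class] else 0) +
      rnorm(n, 0, config@ratioJitterSD), 0.05)
  truth$emission_T <- config@emissionTotal *
    exp(rnorm(n, 0, config@brightnessJitterSD))
  truth$acceptor_A <- config@acceptorLevel *
    exp(rnorm(n, 0, config@brightnessJitterSD))
  truth <- data.frame(id = seq_len(n), truth, row.names = NULL,
                      stringsAsFactors = FALSE)
  truth
}

#' Render a ground-truth scene into a three-channel stack
#'
#' Rasterises each truth ellipsoid into the voxel grid with the ratiometric
#' partition `DxDm = T / (1 + R)`, `DxAm = T * R / (1 + R)` and `AxAm = A`
#' (R the nucleus's true ratio), so that the emission ratio DxAm/DxDm
#' recovers R exactly in the noiseless limit and `DxDm + DxAm = T`
#' voxelwise. Outside nuclei each channel sits at its background level.
#' Noise is applied after signal composition according to the config's
#' noise model (Poisson shot noise and/or additive Gaussian read noise).
#' Overlapping nuclei raise an error — never silent blending. Deterministic
#' given `config@seed` (noise uses `seed + 1`).
#'
#' @param truth data.frame from [generateLeafScene()].
#' @param config the matching [SceneConfig-class].
#' @param quantize clip to \[0, 65535\] and round, emulating 16-bit
#'   acquisition (default TRUE).
#' @return A [FretStack-class].
#' @examples
#' cfg <- sceneConfig(imageShape = c(96L, 96L, 40L), voxelSize = c(1, 1, 2),
#'                    counts = c(stomata = 2, pavement = 0,
#'                               spongy_mesophyll = 1, bundle_sheath = 0,
#'                               vascular_bundle = 0),
#'                    noiseModel = "none", seed = 2)
#' stk <- renderStack(generateLeafScene(cfg), cfg)
#' @export
renderStack <- function(truth, config, quantize = TRUE) {
  stopifnot(is(config, "SceneConfig"))
  dims <- config@imageShape
  vs <- config@voxelSize
  bg <- config@backgroundLevel
  dxdm <- array(bg[["DxDm"]], dims)
  dxam <- array(bg[["DxAm"]], dims)
  axam <- array(bg[["AxAm"]], dims)
  occ <- array(FALSE, dims)

  xs <- (seq_len(dims[1]) - 0.5) * vs[1]
  ys <- (seq_len(dims[2]) - 0.5) * vs[2]
  zs <- (seq_len(dims[3]) - 0.5) * vs[3]

  for (r in seq_len(nrow(truth))) {
    nuc <- truth[r, ]
    rmax <- max(nuc$sa, nuc$sb)
    i0 <- max(1L, floor((nuc$cx - rmax) / vs[1]))
    i1 <- min(dims[1], ceiling((nuc$cx + rmax) / vs[1]) + 1L)
    j0 <- max(1L, floor((nuc$cy - rmax) / vs[2]))
    j1 <- min(dims[2], ceiling((nuc$cy + rmax) / vs[2]) + 1L)
    k0 <- max(1L, floor((nuc$cz - nuc$sc) / vs[3]))
    k1 <- min(dims[3], ceiling((nuc$cz + nuc$sc) / vs[3]) + 1L)
    if (i0 > i1 || j0 > j1 || k0 > k1) next
    ii <- i0:i1; jj <- j0:j1; kk <- k0:k1
    dx <- xs[ii] - nuc$cx
    dy <- ys[jj] - nuc$cy
    dz <- zs[kk] - nuc$cz
    ct_ <- cos(nuc$theta); st_ <- sin(nuc$theta)
    U <- outer(dx * ct_, dy * st_, "+")          # u = dx cos + dy sin
    V <- outer(-dx * st_, dy * ct_, "+")         # v = -dx sin + dy cos
    Q2 <- (U / nuc$sa)^2 + (V / nuc$sb)^2
    fret_d <- nuc$emission_T / (1 + nuc$true_ratio)
    fret_a <- nuc$emission_T * nuc$true_ratio / (1 + nuc$true_ratio)
    for (k in seq_along(kk)) {
      inside <- Q2 + (dz[k] / nuc$sc)^2 <= 1
      if (!any(inside)) next
      sel <- which(inside)
      si <- ((sel - 1L) %% length(ii)) + 1L
      sj <- ((sel - 1L) %/% length(ii)) + 1L
      idx <- ii[si] + dims[1] * (jj[sj] - 1L) +
        dims[1] * dims[2] * (kk[k] - 1L)
      if (any(occ[idx]))
        stop(sprintf("overlapping nuclei while rendering id %d", nuc$id))
      occ[idx] <- TRUE
      dxdm[idx] <- fret_d
      dxam[idx] <- fret_a
      axam[idx] <- nuc$acceptor_A
    }
  }

  if (config@noiseModel != "none") {
    set.seed(config@seed + 1L)
    applyNoise <- function(a) {
      if (config@noiseModel %in% c("poisson", "poisson_gaussian"))
        a <- array(rpois(length(a), a * config@poissonScale) /
                     config@poissonScale, dim(a))
      if (config@noiseModel %in% c("gaussian", "poisson_gaussian"))
        a <- a + rnorm(length(a), 0, config@gaussianSD)
      a
    }
    dxdm <- applyNoise(dxdm)
    dxam <- applyNoise(dxam)
    axam <- applyNoise(axam)
  }

  stk <- FretStack(dxdm, dxam, axam, voxelSize = vs)
  if (quantize) stk <- quantizeStack(stk)
  stk
}

#' Quantize a stack to 16-bit integer counts
#'
#' Clips each channel to \[0, 65535\] and rounds, as on 16-bit write.
#'
#' @param stack a [FretStack-class].
#' @return A [FretStack-class] with integer-valued intensities.
#' @export
quantizeStack <- function(stack) {
  stopifnot(is(stack, "FretStack"))
  stack@channels <- lapply(stack@channels, cpp_quantize16)
  stack
}
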