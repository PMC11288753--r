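#' @name fretleaf-accessors
#' @title Accessors for FretStack and LabelMap objects
#' @param x a [FretStack-class] or [LabelMap-class].
#' @param name channel name, one of `fretChannels()`.
#' @return `channel()` the requested 3D array; `voxelSize()` numeric(3) in
#'   um; `labelData()` the integer label array; `nLabels()` the number of
#'   nuclei.
#' @examples
#' a <- array(0, c(4, 4, 2))
#' s <- FretStack(a, a, a, voxelSize = c(1, 1, 2))
#' voxelSize(s); dim(channel(s, "AxAm"))
NULL

#' @rdname fretleaf-accessors
#' @export
setGeneric("channel", function(x, name) standardGeneric("channel"))

#' @rdname fretleaf-accessors
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' @rdname fretleaf-accessors
#' @export
setGeneric("labelData", function(x) standardGeneric("labelData"))

#' @rdname fretleaf-accessors
#' @export
setGeneric("nLabels", function(x) standardGeneric("nLabels"))

#' @rdname fretleaf-accessors
#' @export
setMethod("channel", "FretStack", function(x, name) {
  name <- match.arg(name, fretChannels())
  x@channels[[name]]
})

#' @rdname fretleaf-accessors
#' @export
setMethod("voxelSize", "FretStack", function(x) x@voxelSize)

#' @rdname fretleaf-accessors
#' @export
setMethod("voxelSize", "LabelMap", function(x) x@voxelSize)

#' @rdname fretleaf-accessors
#' @export
setMethod("labelData", "LabelMap", function(x) x@labels)

#' @rdname fretleaf-accessors
#' @export
setMethod("nLabels", "LabelMap", function(x) max(0L, max(x@labels)))

#' Dimensions of a FretStack
#' @param x a [FretStack-class].
#' @return integer(3) voxel dimensions.
#' @export
setMethod("dim", "FretStack", function(x) dim(x@channels[[1]]))

#' @describeIn FretStack-class compact display
#' @param object a [FretStack-class].
#' @export
setMethod("show", "FretStack", function(object) {
  d <- dim(object)
  vs <- object@voxelSize
  cat(sprintf("FretStack: %d x %d x %d voxels (%.3g x %.3g x %.3g um)\n",
              d[1], d[2], d[3], vs[1], vs[2], vs[3]))
  cat("  channels:", paste(names(object@channels), collapse = ", "), "\n")
  rng <- range(object@channels$AxAm)
  cat(sprintf("  AxAm range: [%.4g, %.4g]\n", rng[1], rng[2]))
})

#' @describeIn LabelMap-class compact display
#' @param object a [LabelMap-class].
#' @export
setMethod("show", "LabelMap", function(object) {
  d <- dim(object@labels)
  cat(sprintf("LabelMap: %d x %d x %d voxels, %d nuclei\n",
              d[1], d[2], d[3], nLabels(object)))
})

#' @describeIn SceneConfig-class compact display
#' @param object a [SceneConfig-class].
#' @export
setMethod("show", "SceneConfig", function(object) {
  cat(sprintf("SceneConfig (%s, seed %d): %d x %d x %d voxels\n",
              object@condition, object@seed, object@imageShape[1],
              object@imageShape[2], object@imageShape[3]))
  cat("  counts:", paste(sprintf("%s=%d", names(object@counts),
                                 object@counts), collapse = " "), "\n")
  cat(sprintf("  noise: %s; mesophyll dropout: %.2f\n",
              object@noiseModel, object@mesophyllDropout))
})

#' Segment nuclei in a stack
#'
#' @param stack a [FretStack-class] (the AxAm channel is used).
#' @param params a [SegmentationParams-class].
#' @return A [LabelMap-class].
#' @seealso [extractFeatures()]
#' @export
setGeneric("segmentNuclei",
           function(stack, params = segmentationParams())
             standardGeneric("segmentNuclei"))
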