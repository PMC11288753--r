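#' Classify nuclei into the five leaf cell types
#'
#' Deterministic rule cascade on nuclear shape and position, exhaustive and
#' exclusive (every nucleus receives exactly one label):
#' \enumerate{
#'   \item depth <= `epidermisMaxDepth`: equivalent diameter below
#'     `stomataMaxEquivDiam` gives stomata, at or above
#'     `pavementMinEquivDiam` gives pavement; sizes in between are resolved
#'     by `tieBreakOrder`;
#'   \item depth >= `vascularMinDepth` with neighbour density >=
#'     `vascularMinNeighborDensity` gives vascular bundle (vein nuclei are
#'     spatially clustered);
#'   \item elongation >= `bundleSheathMinElongation` gives bundle sheath;
#'   \item otherwise spongy mesophyll.
#' }
#' Depth is measured from the shallowest segmented nucleus (robust to
#' mounting offset) unless `depthReference = "stack_top"`. Rows flagged
#' `degenerate_shape` are still classified, with qc note
#' `"classified_with_degenerate_shape"`. A missing feature raises an error
#' naming the field.
#'
#' @param records feature data.frame from [extractFeatures()] (the
#'   `neighbor_density` column must correspond to `config@rNb`).
#' @param config a [ClassifierConfig-class].
#' @return `records` with `cell_type` filled and `depth_rel` added.
#' @seealso [cellTypeCounts()], [confusionMatrix()]
#' @export
classifyNuclei <- function(records, config = classifierConfig()) {
  validObject(config)
  if (nrow(records) == 0L) stop("cannot classify an empty record list")
  needed <- c("depth_z", "equiv_diam", "elongation", "neighbor_density")
  for (f in needed) {
    if (!f %in% names(records)) stop("missing feature column '", f, "'")
    if (anyNA(records[[f]])) stop("missing values in feature '", f, "'")
  }
  depth <- records$depth_z
  if (config@depthReference == "shallowest_nucleus")
    depth <- depth - min(depth)

  tie <- intersect(config@tieBreakOrder, c("stomata", "pavement"))[1]
  if (is.na(tie)) tie <- "stomata"

  lbl <- character(nrow(records))
  epidermal <- depth <= config@epidermisMaxDepth
  small <- records$equiv_diam < config@stomataMaxEquivDiam
  large <- records$equiv_diam >= config@pavementMinEquivDiam
  lbl[epidermal & small] <- "stomata"
  lbl[epidermal & large] <- "pavement"
  lbl[epidermal & !small & !large] <- tie
  deep <- !epidermal
  vasc <- deep & depth >= config@vascularMinDepth &
    records$neighbor_density >= config@vascularMinNeighborDensity
  lbl[vasc] <- "vascular_bundle"
  bs <- deep & !vasc & records$elongation >= config@bundleSheathMinElongation
  lbl[bs] <- "bundle_sheath"
  lbl[deep & !vasc & !bs] <- "spongy_mesophyll"

  records$cell_type <- lbl
  records$depth_rel <- depth
  degen <- grepl("degenerate_shape", records$qc_flags)
  records$qc_flags <- ifelse(degen,
    paste(records$qc_flags, "classified_with_degenerate_shape", sep = ";"),
    records$qc_flags)
  records
}

#' Per-class nucleus counts
#'
#' @param records classified records (non-excluded rows are counted).
#' @return Named integer(5) over [cellTypes()]; sums to the number of
#'   retained nuclei.
#' @export
cellTypeCounts <- function(records) {
  df <- records[!records$excluded, , drop = FALSE]
  tab <- table(factor(df$cell_type, levels = cellTypes()))
  setNames(as.integer(tab), cellTypes())
}

#' Confusion matrix against generator ground truth
#'
#' Matches predicted nuclei to truth nuclei by nearest centroid within
#' `matchRadius` (greedy nearest-first; a duplicate candidate assignment is
#' resolved greedily with a warning), then tabulates truth classes (rows)
#' against predicted classes (columns). Unmatched nuclei on either side are
#' reported separately and do not enter the matrix.
#'
#' @param records classified records with centroids cx, cy, cz (um).
#' @param truth ground-truth table from [generateLeafScene()].
#' @param matchRadius um.
#' @return list: `matrix` (5 x 5 counts), `accuracy` (trace/total),
#'   `nMatched`, `unmatchedTruth`, `unmatchedPredicted`.
#' @export
confusionMatrix <- function(records, truth, matchRadius = 5) {
  ct <- cellTypes()
  P <- as.matrix(records[, c("cx", "cy", "cz")])
  Tm <- as.matrix(truth[, c("cx", "cy", "cz")])
  m <- matrix(0L, 5, 5, dimnames = list(truth = ct, predicted = ct))
  usedT <- rep(FALSE, nrow(Tm)); usedP <- rep(FALSE, nrow(P))
  if (nrow(P) > 0 && nrow(Tm) > 0) {
    D <- sqrt(pmax(outer(rowSums(P^2), rowSums(Tm^2), "+") -
                     2 * P %*% t(Tm), 0))
    pairs <- which(D <= matchRadius, arr.ind = TRUE)
    if (nrow(pairs)) {
      ord <- order(D[pairs])
      dup <- FALSE
      for (r in ord) {
        p <- pairs[r, 1]; t <- pairs[r, 2]
        if (usedP[p] || usedT[t]) { dup <- dup || (usedP[p] != usedT[t])
          next }
        usedP[p] <- TRUE; usedT[t] <- TRUE
        m[truth$class[t], records$cell_type[p]] <-
          m[truth$class[t], records$cell_type[p]] + 1L
      }
      if (dup)
        warning("duplicate match candidates resolved greedily ",
                "(nearest first)")
    }
  }
  total <- sum(m)
  list(matrix = m,
       accuracy = if (total > 0) sum(diag(m)) / total else NA_real_,
       nMatched = total,
       unmatchedTruth = sum(!usedT),
       unmatchedPredicted = sum(!usedP))
}
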