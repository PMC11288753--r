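#' Compute per-nucleus emission ratios
#'
#' The biosensor emission ratio of a nucleus is the ratio of
#' background-corrected mean intensities
#' `(mean DxAm - bg_DxAm) / (mean DxDm - bg_DxDm)` — a ratio of per-ROI
#' means, not a mean of voxelwise ratios, which would amplify noise.
#' When `backgroundMode = "none"` the background is taken as zero. Nuclei
#' whose corrected denominator falls below `denominatorFloor` are excluded
#' with qc flag `"low_donor_signal"`; a negative corrected numerator clamps
#' the ratio at 0 with qc flag `"negative_numerator"` (ratios are never
#' negative).
#'
#' @param records feature data.frame from [extractFeatures()].
#' @param background named numeric per-channel background (e.g. from
#'   [estimateBackground()]); ignored when `backgroundMode = "none"`.
#' @param params a [RatioParams-class].
#' @return `records` with `emission_ratio`, `excluded` and `qc_flags`
#'   updated.
#' @export
computeEmissionRatios <- function(records,
                                  background = c(DxDm = 0, DxAm = 0,
                                                 AxAm = 0),
                                  params = ratioParams()) {
  validObject(params)
  if (!all(c("mean_DxAm", "mean_DxDm") %in% names(records)))
    stop("records must carry mean_DxAm and mean_DxDm")
  if (params@backgroundMode == "none")
    background <- c(DxDm = 0, DxAm = 0, AxAm = 0)
  num <- records$mean_DxAm - background[["DxAm"]]
  den <- records$mean_DxDm - background[["DxDm"]]
  if (params@invertRatio) { tmp <- num; num <- den; den <- tmp }

  addFlag <- function(flags, which, flag)
    ifelse(which, ifelse(nchar(flags) > 0,
                         paste(flags, flag, sep = ";"), flag), flags)

  lowDonor <- den < params@denominatorFloor
  negNum <- !lowDonor & num < 0
  ratio <- ifelse(lowDonor, NA_real_, pmax(num, 0) / den)
  records$emission_ratio <- ratio
  records$excluded <- records$excluded | lowDonor
  records$qc_flags <- addFlag(records$qc_flags, lowDonor,
                              "low_donor_signal")
  records$qc_flags <- addFlag(records$qc_flags, negNum,
                              "negative_numerator")
  records
}

# shared summariser: n / mean / sd / sem of `values` by grouping columns
.summarizeBy <- function(df, valueCol, groupCols) {
  for (g in groupCols)
    if (!g %in% names(df)) stop("missing grouping column '", g, "'")
  key <- interaction(df[groupCols], drop = FALSE, sep = "\r")
  lev <- levels(key)
  out <- do.call(rbind, lapply(lev, function(lv) {
    v <- df[[valueCol]][key == lv]
    v <- v[!is.na(v)]
    n <- length(v)
    parts <- strsplit(lv, "\r", fixed = TRUE)[[1]]
    row <- as.data.frame(as.list(parts), stringsAsFactors = FALSE)
    names(row) <- groupCols
    row$n <- n
    row$mean <- if (n > 0) mean(v) else NA_real_
    row$sd <- if (n > 1) sd(v) else NA_real_
    row$sem <- if (n > 1) sd(v) / sqrt(n) else NA_real_
    row$qc <- if (n == 0) "empty_group" else ""
    row
  }))
  ord <- do.call(order, out[groupCols])
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarise emission ratios by group
#'
#' The "Summary Table" analog: per group, the number of retained nuclei and
#' the mean, s.d. and s.e.m. of the emission ratio. Excluded nuclei are
#' dropped; empty groups are reported with n = 0 and flagged, not silently
#' omitted. Rows are ordered deterministically by group key.
#'
#' @param records records with `emission_ratio` filled.
#' @param groupBy "cell_type", "image", or "condition_cell_type"
#'   (condition x cell type).
#' @return data.frame with the group columns plus n, mean, sd, sem, qc.
#' @export
summarizeRatios <- function(records,
                            groupBy = c("cell_type", "image",
                                        "condition_cell_type")) {
  groupBy <- match.arg(groupBy)
  df <- records[!records$excluded & !is.na(records$emission_ratio), ,
                drop = FALSE]
  cols <- switch(groupBy,
                 cell_type = "cell_type",
                 image = "image",
                 condition_cell_type = c("condition", "cell_type"))
  # keep empty groups visible: reuse full factor levels from the input
  for (cc in cols) {
    lv <- unique(records[[cc]])
    df[[cc]] <- factor(df[[cc]], levels = lv)
  }
  .summarizeBy(df, "emission_ratio", cols)
}

#' Per-class ratio increase between conditions
#'
#' For each cell type, the difference of mean emission ratios
#' (infested minus control) with its independent-groups standard error
#' `sqrt(sem_inf^2 + sem_ctl^2)`.
#'
#' @param summaryControl,summaryInfested summaries from
#'   [summarizeRatios()] with `groupBy = "cell_type"`, covering the same
#'   class set.
#' @return data.frame: cell_type, delta, se, n_control, n_infested.
#' @export
ratioIncreaseByClass <- function(summaryControl, summaryInfested) {
  a <- summaryControl; b <- summaryInfested
  missing_b <- setdiff(a$cell_type, b$cell_type)
  missing_a <- setdiff(b$cell_type, a$cell_type)
  if (length(missing_b) || length(missing_a))
    stop("class present in only one summary: ",
         paste(c(missing_b, missing_a), collapse = ", "))
  b <- b[match(a$cell_type, b$cell_type), , drop = FALSE]
  data.frame(cell_type = as.character(a$cell_type),
             delta = b$mean - a$mean,
             se = sqrt(ifelse(is.na(a$sem), 0, a$sem)^2 +
                       ifelse(is.na(b$sem), 0, b$sem)^2),
             n_control = a$n, n_infested = b$n,
             stringsAsFactors = FALSE)
}
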