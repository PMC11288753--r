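#' Welch two-sample t test
#'
#' Unequal-variance (Welch) t test by default — a robust default where the
#' variance assumption is unstated — with a pooled-variance (Student) mode
#' by flag. Two-sided. The effect estimate is `mean(a) - mean(b)`.
#'
#' Degenerate inputs follow explicit conventions rather than failing midway
#' through a batch: if both samples have zero variance and equal means,
#' p = 1 (note `"zero_variance_equal"`); zero variance in both with
#' different means gives p = 0 (note `"zero_variance_separated"`). Samples
#' with n < 2 are an error.
#'
#' @param a,b numeric samples, each of length >= 2.
#' @param pooled use the pooled-variance Student t instead of Welch.
#' @return One-row data.frame: test, statistic, df, p, effect, n_a, n_b,
#'   note.
#' @examples
#' welchT(c(1, 2, 3), c(1, 2, 3))$p
#' @export
welchT <- function(a, b, pooled = FALSE) {
  if (length(a) < 2 || length(b) < 2)
    stop("each sample needs n >= 2")
  testName <- if (pooled) "student_t" else "welch_t"
  eff <- mean(a) - mean(b)
  if (var(a) == 0 && var(b) == 0) {
    equal <- isTRUE(all.equal(mean(a), mean(b)))
    return(data.frame(test = testName, statistic = if (equal) 0 else Inf,
                      df = NA_real_, p = if (equal) 1 else 0,
                      effect = eff, n_a = length(a), n_b = length(b),
                      note = if (equal) "zero_variance_equal"
                             else "zero_variance_separated",
                      stringsAsFactors = FALSE))
  }
  ht <- t.test(a, b, var.equal = pooled)
  data.frame(test = testName, statistic = unname(ht$statistic),
             df = unname(ht$parameter), p = ht$p.value, effect = eff,
             n_a = length(a), n_b = length(b), note = "",
             stringsAsFactors = FALSE)
}

#' Two-way factorial ANOVA with post hoc comparisons
#'
#' Type-II sums of squares (via `car::Anova`) on a two-factor crossed
#' design, reporting F and p for both main effects and the interaction.
#' Mirroring the reporting convention of factorial stomatal/ratio
#' experiments, post hoc pairwise comparisons (Tukey or Sidak adjustment,
#' via emmeans) are computed only when the relevant term is significant at
#' `alpha`: cell-by-cell pairs when the interaction is significant,
#' otherwise factor-level pairs for each significant main effect.
#'
#' Degenerate designs follow conventions: identical values everywhere give
#' p = 1 for all terms (flagged); a perfectly additive noiseless design has
#' interaction SS = 0 and is reported with interaction p = 1.
#'
#' @param values numeric response.
#' @param factorR,factorC factors (coerced), >= 2 levels each, every cell
#'   non-empty and >= 2 replicates per cell.
#' @param posthoc "tukey" or "sidak".
#' @param alpha significance level for the post hoc gate.
#' @return list: `effects` (data.frame term, sumsq, df, statistic, p,
#'   significant, note), `posthoc` (data.frame or NULL), `method`.
#' @examples
#' r <- rep(c("t1", "t2"), each = 6)
#' c_ <- rep(rep(c("ctl", "inf"), each = 3), 2)
#' y <- rnorm(12) + (c_ == "inf")
#' twoWayFactorial(y, r, c_)$effects
#' @export
twoWayFactorial <- function(values, factorR, factorC,
                            posthoc = c("tukey", "sidak"), alpha = 0.05) {
  posthoc <- match.arg(posthoc)
  R <- factor(factorR); C <- factor(factorC)
  if (nlevels(R) < 2 || nlevels(C) < 2)
    stop("each factor needs >= 2 levels")
  tab <- table(R, C)
  if (any(tab == 0)) {
    bad <- which(tab == 0, arr.ind = TRUE)[1, ]
    stop(sprintf("empty design cell: %s x %s",
                 levels(R)[bad[1]], levels(C)[bad[2]]))
  }
  if (any(tab < 2))
    stop("the interaction term needs >= 2 replicates per cell")

  terms <- c("R", "C", "R:C")
  if (var(values) == 0) {
    eff <- data.frame(term = terms, sumsq = 0, df = NA_real_,
                      statistic = 0, p = 1, significant = FALSE,
                      note = "constant_response", stringsAsFactors = FALSE)
    return(list(effects = eff, posthoc = NULL, method = posthoc))
  }

  df <- data.frame(y = values, R = R, C = C)
  fit <- lm(y ~ R * C, data = df)
  an <- tryCatch(car::Anova(fit, type = "II"), error = function(e) {
    if (!grepl("residual sum of squares is 0", conditionMessage(e)))
      stop(e)
    # perfect fit: assemble the type-II table from nested deviances so the
    # zero-residual conventions below can apply
    fitRC <- lm(y ~ R + C, data = df)
    ss <- c(deviance(lm(y ~ C, data = df)) - deviance(fitRC),
            deviance(lm(y ~ R, data = df)) - deviance(fitRC),
            deviance(fitRC) - deviance(fit))
    data.frame(`Sum Sq` = c(ss, 0),
               Df = c(nlevels(R) - 1L, nlevels(C) - 1L,
                      (nlevels(R) - 1L) * (nlevels(C) - 1L),
                      fit$df.residual),
               `F value` = NaN, `Pr(>F)` = NaN, check.names = FALSE)
  })
  ssTot <- sum(an[["Sum Sq"]])
  rows <- lapply(seq_along(terms), function(i) {
    ss <- an[["Sum Sq"]][i]
    Fv <- an[["F value"]][i]
    p <- an[["Pr(>F)"]][i]
    note <- ""
    if (!is.finite(p)) {
      # zero residual variance: effect SS decides
      if (ss <= 1e-10 * ssTot) { p <- 1; Fv <- 0
        note <- "zero_effect_convention" }
      else { p <- 0; Fv <- Inf; note <- "zero_residual_convention" }
    }
    data.frame(term = terms[i], sumsq = ss, df = an[["Df"]][i],
               statistic = Fv, p = p, significant = p < alpha,
               note = note, stringsAsFactors = FALSE)
  })
  eff <- do.call(rbind, rows)

  ph <- NULL
  perfectFit <- deviance(fit) <= 1e-10 * ssTot
  if (!perfectFit && eff$significant[eff$term == "R:C"]) {
    emm <- suppressMessages(emmeans::emmeans(fit, ~ R * C))
    ph <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                          adjust = posthoc))
  } else if (!perfectFit) {
    sig <- eff$term[eff$significant & eff$term %in% c("R", "C")]
    if (length(sig)) {
      phl <- lapply(sig, function(tm) {
        emm <- suppressMessages(
          emmeans::emmeans(fit, stats::as.formula(paste("~", tm))))
        out <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                               adjust = posthoc))
        out$factor <- tm
        out
      })
      ph <- do.call(rbind, phl)
    }
  }
  list(effects = eff, posthoc = ph, method = posthoc)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment (`p.adjust(method = "BH")`).
#' q-values satisfy q >= p elementwise and are invariant to input order.
#'
#' @param pvalues numeric vector of p-values in \[0,1\].
#' @return Numeric vector of q-values.
#' @examples
#' bhFdr(c(0.01, 0.02, 0.03))
#' @export
bhFdr <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(pvalues, method = "BH")
}

#' Per-image nucleus count table
#'
#' @param records classified records with `image` and `condition` columns.
#' @return data.frame: image, condition, one count column per cell type.
#' @export
nucleusCountTable <- function(records) {
  df <- records[!records$excluded, , drop = FALSE]
  imgs <- unique(df[, c("image", "condition")])
  counts <- t(vapply(seq_len(nrow(imgs)), function(i) {
    sub <- df[df$image == imgs$image[i], , drop = FALSE]
    cellTypeCounts(sub)
  }, setNames(numeric(5), cellTypes())))
  out <- cbind(imgs, as.data.frame(counts))
  rownames(out) <- NULL
  out
}

#' Per-class nucleus-count comparison between conditions
#'
#' The cell-viability readout: for each cell type (and the total), a Welch
#' t test of per-image nucleus counts between the two conditions, with
#' Benjamini-Hochberg correction across the six tests. A reduction in a
#' class's counts under infestation indicates feeding-induced death of
#' that cell type.
#'
#' @param countTable data.frame from [nucleusCountTable()] (columns image,
#'   condition, and one per cell type). Each condition needs >= 2 images.
#' @param conditions character(2): reference (control) and treatment
#'   (infested) condition labels.
#' @return data.frame: cell_type (five classes plus "total"), per-condition
#'   means, effect (treatment minus reference), statistic, p, q, note.
#' @export
countComparison <- function(countTable,
                            conditions = c("control", "infested")) {
  for (cc in conditions)
    if (sum(countTable$condition == cc) < 2)
      stop("need >= 2 images per condition (", cc, ")")
  ct <- cellTypes()
  tab <- countTable
  tab$total <- rowSums(tab[, ct])
  groups <- c(ct, "total")
  rows <- lapply(groups, function(g) {
    ctlv <- tab[[g]][tab$condition == conditions[1]]
    infv <- tab[[g]][tab$condition == conditions[2]]
    w <- welchT(infv, ctlv)
    data.frame(cell_type = g, mean_control = mean(ctlv),
               mean_infested = mean(infv), effect = w$effect,
               statistic = w$statistic, p = w$p, note = w$note,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bhFdr(out$p)
  out
}

#' Per-class emission-ratio comparison between conditions
#'
#' For each cell type (and all nuclei pooled), a Welch t test of
#' per-nucleus emission ratios between conditions, BH-corrected across the
#' six tests.
#'
#' @param records classified records with `emission_ratio`, `cell_type`
#'   and `condition`.
#' @param conditions character(2), reference then treatment.
#' @return data.frame: cell_type (five classes plus "all"), means, effect
#'   (treatment minus reference), statistic, p, q, note.
#' @export
ratioComparison <- function(records,
                            conditions = c("control", "infested")) {
  df <- records[!records$excluded & !is.na(records$emission_ratio), ,
                drop = FALSE]
  groups <- c(cellTypes(), "all")
  rows <- lapply(groups, function(g) {
    sub <- if (g == "all") df else df[df$cell_type == g, , drop = FALSE]
    ctlv <- sub$emission_ratio[sub$condition == conditions[1]]
    infv <- sub$emission_ratio[sub$condition == conditions[2]]
    if (length(ctlv) < 2 || length(infv) < 2)
      return(data.frame(cell_type = g, mean_control = NA_real_,
                        mean_infested = NA_real_, effect = NA_real_,
                        statistic = NA_real_, p = NA_real_,
                        note = "insufficient_n", stringsAsFactors = FALSE))
    w <- welchT(infv, ctlv)
    data.frame(cell_type = g, mean_control = mean(ctlv),
               mean_infested = mean(infv), effect = w$effect,
               statistic = w$statistic, p = w$p, note = w$note,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  ok <- !is.na(out$p)
  out$q[ok] <- bhFdr(out$p[ok])
  out
}

#' Squared Pearson correlation
#'
#' @param x,y numeric vectors, n >= 3, neither constant.
#' @return R^2 in \[0, 1\].
#' @examples
#' pearsonR2(1:5, 2 * (1:5) + 1)
#' @export
pearsonR2 <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("need paired samples with n >= 3")
  if (var(x) == 0 || var(y) == 0)
    stop("constant input: correlation undefined")
  cor(x, y)^2
}
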