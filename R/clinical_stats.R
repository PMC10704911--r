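# Validation statistics: relative expression, normality-gated group
# comparison, correlation, ROC.

#' Relative expression by the 2^-ddCt method
#'
#' `dCt = ct_target - ct_ref`; `ddCt = dCt - calibrator_delta_ct`;
#' relative expression is `2^(-ddCt)`.
#'
#' @param ct_target,ct_ref Per-sample cycle thresholds (finite).
#' @param calibrator_delta_ct Calibrator delta-Ct (scalar); conventionally
#'   the control-group mean delta-Ct, which makes the control mean
#'   expression approximately 1.
#' @return Per-sample relative expression (always positive).
#' @export
ddct <- function(ct_target, ct_ref, calibrator_delta_ct) {
  if (!all(is.finite(ct_target)) || !all(is.finite(ct_ref)) ||
      !is.finite(calibrator_delta_ct))
    stop_fmt("Ct values must be finite")
  2^(-((ct_target - ct_ref) - calibrator_delta_ct))
}

#' Cohort relative expression with control-mean calibration
#'
#' @param sheet Sample sheet with `ct_target`, `ct_reference`, `group`.
#' @param calibrator `"control_mean"` (default; control-group mean
#'   delta-Ct) or a numeric delta-Ct.
#' @return An `ExpressionResult` list: `per_sample` (sample_id, group,
#'   delta_ct, rel_expr), `summary` (per-group n, mean, sd), `comparison`
#'   (see [compare_groups()]), `calibrator_delta_ct`.
#' @export
relative_expression <- function(sheet, calibrator = "control_mean") {
  sheet <- validate_sample_sheet(sheet)
  if (!all(c("ct_target", "ct_reference") %in% names(sheet)))
    stop_fmt("sample sheet lacks ct_target/ct_reference columns")
  dct <- sheet$ct_target - sheet$ct_reference
  cal <- if (identical(calibrator, "control_mean"))
    mean(dct[sheet$group == "control"]) else as.numeric(calibrator)
  rel <- ddct(sheet$ct_target, sheet$ct_reference, cal)
  per_sample <- data.frame(sample_id = sheet$sample_id, group = sheet$group,
                           delta_ct = dct, rel_expr = rel,
                           stringsAsFactors = FALSE)
  summ <- do.call(rbind, lapply(split(rel, sheet$group), function(v)
    data.frame(n = length(v), mean = mean(v), sd = stats::sd(v))))
  summ <- data.frame(group = rownames(summ), summ, row.names = NULL)
  structure(list(per_sample = per_sample, summary = summ,
                 comparison = compare_groups(rel, sheet$group),
                 calibrator_delta_ct = cal),
            class = "ExpressionResult")
}

#' Kolmogorov-Smirnov normality check with estimated parameters
#'
#' Lilliefors-style test: the KS statistic against a normal with mean and
#' SD estimated from the data, assessed with Stephens' modified-statistic
#' critical points (0.775, 0.819, 0.895, 0.955, 1.035 at levels 0.15,
#' 0.10, 0.05, 0.025, 0.01).  The returned `p` is interpolated between
#' those points and is approximate by construction (flagged).
#'
#' @param x Numeric sample (n >= 4 recommended).
#' @param alpha Gate level (default 0.05).
#' @return List: `statistic` (raw D), `modified` (Stephens' D*),
#'   `normal` (logical: passes at `alpha`), `p` (approximate),
#'   `p_is_approximate = TRUE`.
#' @export
ks_normal <- function(x, alpha = 0.05) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3 || stats::sd(x) == 0)
    return(list(statistic = NA_real_, modified = Inf, normal = FALSE,
                p = 0, p_is_approximate = TRUE))
  z <- sort((x - mean(x)) / stats::sd(x))
  pz <- stats::pnorm(z)
  D <- max(pmax(seq_len(n) / n - pz, pz - (seq_len(n) - 1) / n))
  modified <- D * (sqrt(n) - 0.01 + 0.85 / sqrt(n))
  pts <- c(`0.775` = 0.15, `0.819` = 0.10, `0.895` = 0.05,
           `0.955` = 0.025, `1.035` = 0.01)
  crit <- as.numeric(names(pts))
  # monotone log-linear interpolation of p in the modified statistic
  p <- if (modified <= crit[1]) {
    min(1, 0.15 * exp(3 * (crit[1] - modified)))
  } else if (modified >= crit[length(crit)]) {
    0.01 * exp(-10 * (modified - crit[length(crit)]))
  } else {
    exp(stats::approx(crit, log(unname(pts)), xout = modified)$y)
  }
  crit_alpha <- stats::approx(unname(pts), crit, xout = alpha, rule = 2)$y
  list(statistic = D, modified = modified, normal = modified < crit_alpha,
       p = p, p_is_approximate = TRUE)
}

#' Two-group comparison with a normality gate
#'
#' Both groups are checked for normality ([ks_normal()], level
#' `normality_alpha`); if both pass, a Student t-test is used and groups
#' are summarised as mean (SD), otherwise a Mann-Whitney U test with
#' median (25th, 75th percentile) summaries.  Constant data fails the
#' gate and falls through to Mann-Whitney.
#'
#' @param values Numeric vector.
#' @param groups Factor/character, two levels, each with n >= 2.
#' @param normality_alpha Gate level (default 0.05).
#' @return List: `test_used` (`"student_t"` or `"mann_whitney"`),
#'   `statistic`, `p`, `normal` (per-group gate results), `summaries`
#'   (per-group n, mean, sd, median, q25, q75).
#' @export
compare_groups <- function(values, groups, normality_alpha = 0.05) {
  groups <- factor(groups)
  if (nlevels(groups) != 2)
    stop_fmt("compare_groups needs exactly two groups")
  split_v <- split(values, groups)
  if (any(vapply(split_v, length, integer(1)) < 2))
    stop_fmt("each group needs >= 2 values")
  gate <- vapply(split_v, function(v) ks_normal(v, normality_alpha)$normal,
                 logical(1))
  summaries <- do.call(rbind, lapply(names(split_v), function(g) {
    v <- split_v[[g]]
    data.frame(group = g, n = length(v), mean = mean(v), sd = stats::sd(v),
               median = stats::median(v),
               q25 = unname(stats::quantile(v, 0.25)),
               q75 = unname(stats::quantile(v, 0.75)),
               stringsAsFactors = FALSE)
  }))
  if (all(gate)) {
    ht <- stats::t.test(split_v[[1]], split_v[[2]], var.equal = TRUE)
    out <- list(test_used = "student_t", statistic = unname(ht$statistic),
                p = ht$p.value)
  } else {
    ht <- suppressWarnings(
      stats::wilcox.test(split_v[[1]], split_v[[2]], exact = FALSE))
    p <- ht$p.value
    if (is.na(p)) p <- 1   # fully tied data carries no evidence
    out <- list(test_used = "mann_whitney",
                statistic = unname(ht$statistic), p = p)
  }
  c(out, list(normal = gate, summaries = summaries))
}

#' Paired correlation with automatic method choice
#'
#' `auto` uses Pearson when both variables pass the normality gate and
#' Spearman otherwise.
#'
#' @param x,y Paired numeric vectors (n >= 3).
#' @param method `"auto"`, `"pearson"`, or `"spearman"`.
#' @param normality_alpha Gate level for `auto`.
#' @return A `CorrelationResult` list: `method`, `r`, `p`, `n`.
#' @export
correlate <- function(x, y, method = c("auto", "pearson", "spearman"),
                      normality_alpha = 0.05) {
  method <- match.arg(method)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop_fmt("correlate needs n >= 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_fmt("zero variance in correlate input")
  if (method == "auto")
    method <- if (ks_normal(x, normality_alpha)$normal &&
                  ks_normal(y, normality_alpha)$normal) "pearson"
              else "spearman"
  ct <- suppressWarnings(stats::cor.test(x, y, method = method,
                                         exact = FALSE))
  structure(list(method = method, r = unname(ct$estimate), p = ct$p.value,
                 n = length(x)),
            class = "CorrelationResult")
}

as_positive_label <- function(labels) {
  if (is.logical(labels)) return(labels)
  labels <- as.character(labels)
  if (!all(labels %in% c("case", "control")))
    stop_fmt("labels must be logical or 'case'/'control'")
  labels == "case"
}

#' Empirical ROC curve and AUC
#'
#' Empirical ROC over all observed thresholds, with tied scores treated
#' as a single threshold; AUC by the trapezoid rule.  With
#' `positive_is_low = TRUE` (the default: a hypomethylated biomarker
#' marks cases) low scores predict the positive class.  The reported
#' cutoff maximises Youden's J (sensitivity + specificity - 1).
#'
#' @param score Numeric scores.
#' @param labels Logical (TRUE = positive) or `"case"`/`"control"`.
#' @param positive_is_low If `TRUE`, samples at or below a cutoff are
#'   called positive.
#' @return A `ROCResult` list: `thresholds` (original score scale,
#'   including the degenerate all-negative point as `NA`), `tpr`, `fpr`,
#'   `auc`, `youden_cutoff`, `sensitivity`, `specificity`,
#'   `positive_is_low`.
#' @export
roc <- function(score, labels, positive_is_low = TRUE) {
  pos <- as_positive_label(labels)
  if (!any(pos) || all(pos))
    stop_fmt("both classes must be present for ROC")
  s <- if (positive_is_low) -score else score
  ord <- order(s, decreasing = TRUE)
  s_sorted <- s[ord]
  pos_sorted <- pos[ord]
  # collapse ties: evaluate only at the last index of each tie group
  last <- which(!duplicated(s_sorted, fromLast = TRUE))
  tp <- cumsum(pos_sorted)[last]
  fp <- cumsum(!pos_sorted)[last]
  P <- sum(pos); N <- sum(!pos)
  tpr <- c(0, tp / P)
  fpr <- c(0, fp / N)
  thr_internal <- s_sorted[last]
  thresholds <- c(NA_real_,
                  if (positive_is_low) -thr_internal else thr_internal)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  j <- tpr - fpr
  best <- which.max(j[-1]) + 1         # never pick the degenerate origin
  structure(list(thresholds = thresholds, tpr = tpr, fpr = fpr, auc = auc,
                 youden_cutoff = thresholds[best],
                 sensitivity = tpr[best], specificity = 1 - fpr[best],
                 positive_is_low = positive_is_low),
            class = "ROCResult")
}

#' @export
print.ROCResult <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.3f; Youden cutoff = %.4g (sens %.2f, spec %.2f)%s\n",
              x$auc, x$youden_cutoff, x$sensitivity, x$specificity,
              if (x$positive_is_low) " [low score = positive]" else ""))
  invisible(x)
}

#' Per-sample composite methylation score for a probe set
#'
#' @param bm A [beta_matrix()].
#' @param dmp_ids Non-empty probe set (e.g. one gene's DMPs).
#' @param method `"mean"` (default: mean beta across the probes) or
#'   `"pc1"` (first principal component, oriented to correlate
#'   positively with the mean).
#' @return Named numeric vector, one score per sample.
#' @export
biomarker_composite <- function(bm, dmp_ids, method = c("mean", "pc1")) {
  method <- match.arg(method)
  if (length(dmp_ids) == 0) stop_fmt("empty probe id set")
  sub <- subset_probes(bm, dmp_ids)
  mb <- colMeans(sub$beta)
  if (method == "mean") return(mb)
  pc <- stats::prcomp(t(sub$beta), center = TRUE, rank. = 1)
  sc <- pc$x[, 1]
  if (length(unique(mb)) > 1 && stats::cor(sc, mb) < 0) sc <- -sc
  stats::setNames(sc, colnames(sub$beta))
}

#' Methylation-phenotype correlation grid
#'
#' Correlates each probe's beta values with each phenotype variable
#' across samples, with the automatic Pearson/Spearman gate.  Variables
#' absent from the sheet or constant across samples are skipped with a
#' warning.
#'
#' @param bm A [beta_matrix()].
#' @param sheet Sample sheet aligned to the matrix samples.
#' @param dmp_ids Probes to correlate.
#' @param variables Phenotype columns (default age, ft3, ft4, tsh).
#' @param method Passed to [correlate()].
#' @return Tidy data frame: `probe_id`, `variable`, `method`, `r`, `p`,
#'   `n`.
#' @export
phenotype_correlation_matrix <- function(bm, sheet, dmp_ids,
                                         variables = c("age", "ft3",
                                                       "ft4", "tsh"),
                                         method = "auto") {
  sheet <- validate_sample_sheet(sheet)
  idx <- match(bm$sample_ids, sheet$sample_id)
  if (anyNA(idx)) stop_fmt("sample sheet does not cover matrix samples")
  keep_var <- character(0)
  for (v in variables) {
    if (!v %in% names(sheet)) {
      warn_fmt("variable '%s' absent from sample sheet; skipped", v)
    } else if (stats::sd(sheet[[v]][idx], na.rm = TRUE) == 0) {
      warn_fmt("variable '%s' is constant; skipped", v)
    } else keep_var <- c(keep_var, v)
  }
  sub <- subset_probes(bm, dmp_ids)
  rows <- list()
  for (pid in dmp_ids) {
    for (v in keep_var) {
      cr <- correlate(sub$beta[pid, ], sheet[[v]][idx], method)
      rows[[length(rows) + 1L]] <-
        data.frame(probe_id = pid, variable = v, method = cr$method,
                   r = cr$r, p = cr$p, n = cr$n, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(probe_id = character(0), variable = character(0),
                      method = character(0), r = numeric(0), p = numeric(0),
                      n = integer(0), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
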