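#' Per-probe group means and delta-beta
#'
#' Delta-beta is defined as the case-group mean beta minus the
#' control-group mean beta; positive values indicate hypermethylation in
#' cases.
#'
#' @param bm A [beta_matrix()].
#' @param sheet Sample sheet with `sample_id` and `group` matching the
#'   matrix columns; each group needs at least two samples.
#' @return Data frame: `probe_id`, `mean_beta_case`, `mean_beta_control`,
#'   `delta_beta`.
#' @export
group_stats <- function(bm, sheet) {
  grp <- match_groups(bm, sheet)
  mc <- rowMeans(bm$beta[, grp$case, drop = FALSE], na.rm = TRUE)
  mn <- rowMeans(bm$beta[, grp$control, drop = FALSE], na.rm = TRUE)
  data.frame(probe_id = bm$probe_ids,
             mean_beta_case = mc, mean_beta_control = mn,
             delta_beta = mc - mn,
             row.names = NULL, stringsAsFactors = FALSE)
}

match_groups <- function(bm, sheet) {
  sheet <- validate_sample_sheet(sheet)
  idx <- match(bm$sample_ids, sheet$sample_id)
  if (anyNA(idx))
    stop_fmt("sample %s not present in sample sheet",
             bm$sample_ids[which(is.na(idx))[1]])
  g <- sheet$group[idx]
  case <- which(g == "case"); control <- which(g == "control")
  if (length(case) < 2 || length(control) < 2)
    stop_fmt("each group needs >= 2 samples (case: %d, control: %d)",
             length(case), length(control))
  list(case = case, control = control)
}

row_var <- function(m) {
  n <- ncol(m)
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (n - 1)
}

#' Per-probe two-group differential test
#'
#' `welch_t` is the unequal-variance two-sample t-test; `moderated_t`
#' (default) shrinks per-probe pooled variances toward a prior estimated
#' from all probes by fitting a scaled F distribution to the sample
#' variances (empirical-Bayes variance moderation), referring the
#' statistic to a t distribution with augmented degrees of freedom.
#' With `transform = "mvalue"` (default) the test runs on
#' `M = log2(beta/(1-beta))` (beta clamped to `[0.001, 0.999]`), which
#' stabilises variances across the beta range and is the
#' higher-power scale for array inference; effect sizes and the
#' delta-beta gate remain in beta space throughout.  Probes with zero
#' variance in both groups and equal means get p = 1.
#'
#' @param bm A [beta_matrix()].
#' @param sheet Sample sheet (see [group_stats()]).
#' @param method `"moderated_t"` or `"welch_t"`.
#' @param transform `"mvalue"` (test on logit-scale M-values) or
#'   `"none"` (test directly on beta).
#' @return Data frame: `probe_id`, `statistic`, `df`, `p_raw`.
#' @export
dmp_test <- function(bm, sheet, method = c("moderated_t", "welch_t"),
                     transform = c("mvalue", "none")) {
  method <- match.arg(method)
  transform <- match.arg(transform)
  grp <- match_groups(bm, sheet)
  vals <- bm$beta
  if (transform == "mvalue") {
    clamped <- pmin(pmax(vals, 1e-3), 1 - 1e-3)
    vals <- log2(clamped / (1 - clamped))
  }
  x <- vals[, grp$case, drop = FALSE]
  y <- vals[, grp$control, drop = FALSE]
  n1 <- ncol(x); n2 <- ncol(y)
  d <- rowMeans(x) - rowMeans(y)
  v1 <- row_var(x); v2 <- row_var(y)

  if (method == "welch_t") {
    se2 <- v1 / n1 + v2 / n2
    tt <- d / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else {
    s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    df0 <- n1 + n2 - 2
    sq <- squeeze_var(s2, df0)
    tt <- d / sqrt(sq$var_post * (1 / n1 + 1 / n2))
    df <- rep(df0 + sq$df_prior, length(tt))
  }
  p <- 2 * stats::pt(-abs(tt), df)
  degenerate <- !is.finite(tt)
  p[degenerate & d == 0] <- 1        # zero variance, equal means
  p[degenerate & d != 0] <- 0        # zero variance, distinct means
  tt[degenerate] <- ifelse(d[degenerate] == 0, 0, sign(d[degenerate]) * Inf)
  data.frame(probe_id = bm$probe_ids, statistic = tt, df = df, p_raw = p,
             row.names = NULL, stringsAsFactors = FALSE)
}

# Empirical-Bayes variance moderation: fit s2 ~ s0^2 * F(df, d0) by
# moment-matching on log(s2), then shrink each variance toward the prior.
squeeze_var <- function(s2, df) {
  ok <- s2 > 0
  if (!any(ok)) return(list(var_post = s2, df_prior = 0, var_prior = 0))
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  e_var <- stats::var(e) - trigamma(df / 2)
  if (is.na(e_var) || e_var <= 0) {
    df_prior <- Inf
    var_prior <- exp(mean(e))
    var_post <- rep(var_prior, length(s2))
  } else {
    df_prior <- 2 * trigamma_inverse(e_var)
    var_prior <- exp(mean(e) + digamma(df_prior / 2) - log(df_prior / 2))
    var_post <- (df_prior * var_prior + df * s2) / (df_prior + df)
  }
  list(var_post = var_post, df_prior = df_prior, var_prior = var_prior)
}

# Solve trigamma(y) = x by Newton iteration on 1/trigamma (monotone).
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif) / y < 1e-8) break
  }
  y
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up procedure: sort p ascending, multiply by m/rank, enforce
#' monotone non-decrease in the original ascending order by taking
#' running minima from the largest p, cap at 1, and return in input
#' order.
#'
#' @param p_raw Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
adjust_bh <- function(p_raw) {
  m <- length(p_raw)
  if (m == 0) return(numeric(0))
  if (any(p_raw < 0 | p_raw > 1, na.rm = TRUE))
    stop_fmt("p-values must lie in [0,1]")
  o <- order(p_raw, decreasing = TRUE)
  ranks <- m:1
  adj <- pmin(1, cummin(p_raw[o] * m / ranks))
  adj[order(o)]
}

#' Call differentially methylated positions
#'
#' A probe is a DMP when `p_adj < alpha` and `|delta_beta| > delta_min`
#' (both strict).  Direction is `hyper` for positive delta-beta, `hypo`
#' for negative.
#'
#' @param stats Output of [group_stats()].
#' @param p_raw,p_adj Aligned p-value vectors (see [dmp_test()],
#'   [adjust_bh()]).
#' @param alpha Significance threshold on the adjusted p (default 0.05).
#' @param delta_min Minimum absolute delta-beta (default 0.1).
#' @param use_adjusted If `FALSE`, gate on the raw p instead (the
#'   methods-section reading; default `TRUE`, the results-section one).
#' @return Data frame of DMP records: `probe_id`, `mean_beta_case`,
#'   `mean_beta_control`, `delta_beta`, `p_raw`, `p_adj`, `direction`.
#' @export
call_dmps <- function(stats, p_raw, p_adj, alpha = 0.05, delta_min = 0.1,
                      use_adjusted = TRUE) {
  stopifnot(nrow(stats) == length(p_adj), length(p_raw) == length(p_adj))
  gate_p <- if (use_adjusted) p_adj else p_raw
  keep <- !is.na(gate_p) & gate_p < alpha & abs(stats$delta_beta) > delta_min
  out <- stats[keep, , drop = FALSE]
  out$p_raw <- p_raw[keep]
  out$p_adj <- p_adj[keep]
  out$direction <- ifelse(out$delta_beta > 0, "hyper", "hypo")
  rownames(out) <- NULL
  out
}

#' One-call DMP analysis
#'
#' Convenience wrapper: [group_stats()] + [dmp_test()] + [adjust_bh()] +
#' [call_dmps()].
#'
#' @inheritParams dmp_test
#' @inheritParams call_dmps
#' @return List with `table` (all probes: stats, p_raw, p_adj) and `dmps`
#'   (the called subset with direction).
#' @export
find_dmps <- function(bm, sheet, method = "moderated_t",
                      alpha = 0.05, delta_min = 0.1, use_adjusted = TRUE,
                      transform = "mvalue") {
  st <- group_stats(bm, sheet)
  tst <- dmp_test(bm, sheet, method, transform)
  p_adj <- adjust_bh(tst$p_raw)
  tab <- cbind(st, p_raw = tst$p_raw, p_adj = p_adj)
  list(table = tab,
       dmps = call_dmps(st, tst$p_raw, p_adj, alpha, delta_min, use_adjusted))
}

#' Principal-component embedding of samples
#'
#' Mean-centered PCA of samples over a probe subset (samples are
#' observations, probes variables).  Variance fractions are relative to
#' the total variance over all probes, so they sum to at most 1.
#'
#' @param bm A [beta_matrix()].
#' @param k Number of components (default 2).
#' @param probe_ids Optional probe subset; default all probes.
#' @return List with `scores` (data frame `sample_id`, `PC1..PCk`) and
#'   `var_explained` (length-k fractions).
#' @export
pca_embed <- function(bm, k = 2, probe_ids = NULL) {
  if (!is.null(probe_ids)) bm <- subset_probes(bm, probe_ids)
  x <- t(bm$beta)                      # samples x probes
  if (k > min(dim(x)))
    stop_fmt("k = %d exceeds min(n_samples, n_probes) = %d", k, min(dim(x)))
  xc <- scale(x, center = TRUE, scale = FALSE)
  total_var <- sum(xc^2) / (nrow(xc) - 1)
  pc <- stats::prcomp(xc, center = FALSE, rank. = k)
  scores <- data.frame(sample_id = rownames(x),
                       pc$x[, seq_len(k), drop = FALSE],
                       row.names = NULL, stringsAsFactors = FALSE)
  list(scores = scores,
       var_explained = if (total_var > 0) pc$sdev[seq_len(k)]^2 / total_var
                       else rep(0, k))
}

region_probe_ids <- function(manifest, region) {
  gm <- manifest_gene_map(manifest)
  switch(region,
    genome = manifest$probe_id,
    promoter = unique(gm$probe_id[gm$region %in% PROMOTER_REGIONS]),
    IGR = manifest$probe_id[!nzchar(manifest$gene)],
    body = unique(gm$probe_id[gm$region == "Body"]),
    `3UTR` = unique(gm$probe_id[gm$region == "3UTR"]),
    `5UTR` = unique(gm$probe_id[gm$region == "5UTR"]),
    stop_fmt("unknown region '%s'", region))
}

#' Pooled methylation comparison within a genomic region
#'
#' Pools every probe-by-sample beta value in the region per group and
#' compares the groups with a two-sided Mann-Whitney U test (the global
#' beta distribution is bimodal, so a rank test is the honest default).
#' Promoter means TSS1500, TSS200, 5'UTR or 1st exon.
#'
#' @param bm A [beta_matrix()].
#' @param sheet Sample sheet.
#' @param manifest Manifest covering the matrix probes.
#' @param region One of `"genome"`, `"promoter"`, `"IGR"`, `"body"`,
#'   `"3UTR"`, `"5UTR"`.
#' @return List: `region`, `n_probes`, `median_case`, `median_control`,
#'   `p`.
#' @export
region_methylation_compare <- function(bm, sheet, manifest,
                                       region = c("genome", "promoter", "IGR",
                                                  "body", "3UTR", "5UTR")) {
  region <- match.arg(region)
  ids <- intersect(region_probe_ids(manifest, region), bm$probe_ids)
  if (length(ids) == 0)
    stop_fmt("no probes in region '%s'", region)
  grp <- match_groups(bm, sheet)
  sub <- bm$beta[ids, , drop = FALSE]
  case_vals <- as.vector(sub[, grp$case])
  ctrl_vals <- as.vector(sub[, grp$control])
  p <- stats::wilcox.test(case_vals, ctrl_vals, exact = FALSE)$p.value
  list(region = region, n_probes = length(ids),
       median_case = stats::median(case_vals, na.rm = TRUE),
       median_control = stats::median(ctrl_vals, na.rm = TRUE),
       p = p)
}
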