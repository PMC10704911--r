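# group statistics, differential testing, BH adjustment, DMP calling, PCA

test_that("group_stats computes delta-beta = case mean - control mean", {
  beta <- rbind(c(0.5, 0.5, 0.3, 0.3),
                c(0.2, 0.4, 0.2, 0.4))
  sheet <- data.frame(sample_id = sprintf("S%d", 1:4),
                      group = c("case", "case", "control", "control"))
  bm <- make_bm(beta)
  st <- group_stats(bm, sheet)
  expect_equal(st$delta_beta, c(0.2, 0))
  # antisymmetry under label swap
  sheet2 <- sheet
  sheet2$group <- rev(sheet$group)
  expect_equal(group_stats(bm, sheet2)$delta_beta, -st$delta_beta)
})

test_that("welch_t on beta matches the t.test oracle", {
  beta <- rbind(c(0.8, 0.9, 0.85, 0.1, 0.2, 0.15),
                c(0.5, 0.6, 0.55, 0.5, 0.6, 0.55))
  sheet <- data.frame(sample_id = sprintf("S%d", 1:6),
                      group = rep(c("case", "control"), each = 3))
  bm <- make_bm(beta)
  res <- dmp_test(bm, sheet, method = "welch_t", transform = "none")
  oracle <- t.test(beta[1, 1:3], beta[1, 4:6])
  expect_equal(res$statistic[1], unname(oracle$statistic), tolerance = 1e-12)
  expect_equal(res$p_raw[1], oracle$p.value, tolerance = 1e-12)
  expect_lt(res$p_raw[1], 0.01)
  # identical group distributions -> p ~ 1
  expect_gt(res$p_raw[2], 0.5)
})

test_that("equal group means at n=10/10 give large p", {
  set.seed(4)
  beta <- matrix(plogis(rnorm(20, 0, 0.5)), 1, 20)
  bm <- make_bm(beta)
  sheet <- make_sheet(10)
  for (m in c("welch_t", "moderated_t")) {
    # single-probe moderated test degenerates to pooled t; still valid
    p <- dmp_test(bm, sheet, m, transform = "none")$p_raw
    expect_gt(p, 0.05)
  }
})

test_that("zero-variance probes are handled", {
  beta <- rbind(rep(0.4, 6), c(rep(0.2, 3), rep(0.8, 3)))
  sheet <- data.frame(sample_id = sprintf("S%d", 1:6),
                      group = rep(c("case", "control"), each = 3))
  res <- dmp_test(make_bm(beta), sheet, "welch_t", transform = "none")
  expect_equal(res$p_raw[1], 1)   # no variance, no difference
  expect_equal(res$p_raw[2], 0)   # no variance, clear difference
})

test_that("moderated and welch t agree in ordering on a simulated null", {
  set.seed(7)
  beta <- matrix(plogis(rnorm(100 * 12, 0, 0.5)), 100, 12)
  bm <- make_bm(beta)
  sheet <- make_sheet(6)
  pw <- dmp_test(bm, sheet, "welch_t", transform = "none")$p_raw
  pm <- dmp_test(bm, sheet, "moderated_t", transform = "none")$p_raw
  expect_gt(cor(pw, pm, method = "spearman"), 0.9)
})

test_that("moderated t matches the limma oracle on a shared fixture", {
  set.seed(12)
  y <- matrix(rnorm(400 * 10), 400, 10)
  bm <- make_bm(plogis(y))   # strictly in (0,1)
  sheet <- make_sheet(5)
  mine <- dmp_test(bm, sheet, "moderated_t", transform = "none")
  design <- cbind(1, rep(c(0, 1), each = 5))  # columns: intercept, case
  fit <- limma::eBayes(limma::lmFit(bm$beta, design))
  expect_gt(cor(-log10(mine$p_raw), -log10(fit$p.value[, 2])), 0.999)
  expect_equal(mine$statistic, unname(fit$t[, 2]), tolerance = 0.02)
})

test_that("adjust_bh reproduces the step-up definition", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_bh(0.03), 0.03)           # m = 1 identity
  expect_equal(adjust_bh(numeric(0)), numeric(0))
  expect_error(adjust_bh(c(0.5, 1.2)), "0,1")
  set.seed(3)
  for (i in 1:25) {
    p <- runif(sample(1:400, 1))
    a <- adjust_bh(p)
    expect_identical(a, bh_oracle(p))
    expect_true(all(a >= p))
  }
})

test_that("call_dmps applies strict thresholds and assigns direction", {
  st <- data.frame(probe_id = sprintf("cg%d", 1:4),
                   mean_beta_case = c(0.5, 0.6, 0.2, 0.9),
                   mean_beta_control = c(0.4, 0.3, 0.5, 0.6),
                   delta_beta = c(0.10, 0.30, -0.30, 0.30))
  p_adj <- c(0.01, 0.06, 0.01, 0.01)
  out <- call_dmps(st, p_adj / 2, p_adj)
  # delta exactly 0.10 not called (strict >); p_adj 0.06 not called
  expect_equal(out$probe_id, c("cg3", "cg4"))
  expect_equal(out$direction, c("hypo", "hyper"))
  expect_equal(nrow(out),
               sum(out$direction == "hyper") + sum(out$direction == "hypo"))
  # raw-p gating flag
  out_raw <- call_dmps(st, p_adj / 2, p_adj, use_adjusted = FALSE)
  expect_true("cg2" %in% out_raw$probe_id)
})

test_that("pca_embed: degenerate cases and variance fractions", {
  beta <- matrix(c(0.1, 0.2, 0.1, 0.2, 0.1, 0.2,
                   0.8, 0.9, 0.8, 0.9, 0.8, 0.9), 4, 3, byrow = TRUE)
  bm <- make_bm(beta)
  emb <- pca_embed(bm, k = 2)
  # samples 1 and 3 are identical columns...
  expect_equal(emb$scores$PC1[1], emb$scores$PC1[3])
  expect_equal(emb$scores$PC2[1], emb$scores$PC2[3])
  expect_lte(sum(emb$var_explained), 1 + 1e-12)
  expect_error(pca_embed(bm, k = 10), "exceeds")
})

test_that("sample separation is sharper on called DMPs than on all probes", {
  co <- default_cohort(1)
  fc <- apply_filter_cascade(co$bm, co$manifest)
  res <- find_dmps(fc$retained, co$sheet)
  grp <- co$sheet$group[match(fc$retained$sample_ids, co$sheet$sample_id)]
  sil_all <- mean_silhouette(
    as.matrix(pca_embed(fc$retained, 2)$scores[, c("PC1", "PC2")]), grp)
  sil_dmp <- mean_silhouette(
    as.matrix(pca_embed(fc$retained, 2,
                        probe_ids = res$dmps$probe_id)$scores[, c("PC1", "PC2")]),
    grp)
  expect_gt(sil_dmp, sil_all)
})

test_that("region_methylation_compare pools the stated probe sets", {
  man <- make_manifest(sprintf("cg%d", 1:6),
                       gene = c("A", "A", "B", "B", "", ""),
                       gene_region = c("TSS200", "5UTR", "Body", "1stExon",
                                       "", ""))
  beta <- matrix(rep(c(0.2, 0.4, 0.6, 0.8, 0.3, 0.5), 4), 6, 4)
  bm <- make_bm(beta, probes = man$probe_id)
  sheet <- data.frame(sample_id = sprintf("S%d", 1:4),
                      group = c("case", "case", "control", "control"))
  # promoter = TSS1500 u TSS200 u 5UTR u 1stExon
  out <- region_methylation_compare(bm, sheet, man, "promoter")
  expect_equal(out$n_probes, 3L)
  expect_equal(region_methylation_compare(bm, sheet, man, "IGR")$n_probes, 2L)
  # identical groups: equal medians, p ~ 1
  expect_equal(out$median_case, out$median_control)
  expect_gt(out$p, 0.9)
  # no 3'UTR probes -> error naming the region
  expect_error(region_methylation_compare(bm, sheet, man, "3UTR"), "3UTR")
})

test_that("planted global hypomethylation shifts the genome comparison", {
  set.seed(21)
  n <- 800
  m0 <- plogis(rnorm(n, 0, 1.2))
  mu <- qlogis(pmin(pmax(m0, 0.02), 0.98))
  ctrl <- plogis(mu + matrix(rnorm(n * 8, 0, 0.5), n))
  case <- plogis(mu - 0.3 + matrix(rnorm(n * 8, 0, 0.5), n))
  bm <- make_bm(cbind(case, ctrl))
  man <- make_manifest(bm$probe_ids)
  sheet <- data.frame(sample_id = bm$sample_ids,
                      group = rep(c("case", "control"), each = 8))
  out <- region_methylation_compare(bm, sheet, man, "genome")
  expect_lt(out$median_case, out$median_control)
  expect_lt(out$p, 0.001)
})
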