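# 2^-ddCt, normality-gated comparison, correlation, ROC, composites

test_that("ddct arithmetic and algebraic laws are exact", {
  expect_identical(ddct(22, 18, 4), 1)            # dCt equals calibrator
  expect_identical(ddct(20, 18, 4), 4)            # ddCt = -2 -> 4.0
  # 2^x law: lowering ddCt by 1 doubles expression
  expect_identical(ddct(19, 18, 4), 2 * ddct(20, 18, 4))
  # shifting target and reference together leaves dCt unchanged
  expect_identical(ddct(20 + 3, 18 + 3, 4), ddct(20, 18, 4))
  # shifting target alone by c multiplies expression by 2^-c
  expect_identical(ddct(20 + 2, 18, 4), ddct(20, 18, 4) * 2^-2)
  expect_error(ddct(Inf, 18, 4), "finite")
})

test_that("relative_expression calibrates the control mean to ~1", {
  set.seed(5)
  n <- 30
  sheet <- data.frame(
    sample_id = sprintf("S%d", 1:(2 * n)),
    group = rep(c("control", "case"), each = n),
    ct_reference = rnorm(2 * n, 18, 0.2),
    stringsAsFactors = FALSE)
  # cases 2 cycles earlier on target (4-fold up)
  sheet$ct_target <- sheet$ct_reference + 4 -
    ifelse(sheet$group == "case", 2, 0) + rnorm(2 * n, 0, 0.2)
  ex <- relative_expression(sheet)
  expect_equal(ex$summary$mean[ex$summary$group == "control"], 1,
               tolerance = 0.05)
  expect_equal(ex$summary$mean[ex$summary$group == "case"], 4,
               tolerance = 0.5)
  expect_lt(ex$comparison$p, 0.001)
  expect_true(all(ex$per_sample$rel_expr > 0))
})

test_that("normality gate: normal data -> t, skewed data -> Mann-Whitney", {
  set.seed(9)
  vals_norm <- c(rnorm(30, 0), rnorm(30, 0.1))
  g <- rep(c("a", "b"), each = 30)
  out <- compare_groups(vals_norm, g)
  expect_equal(out$test_used, "student_t")

  vals_skew <- c(rlnorm(30, 0, 2), rlnorm(30, 0, 2))
  out2 <- compare_groups(vals_skew, g)
  expect_equal(out2$test_used, "mann_whitney")

  # constant data carries no evidence and falls through to Mann-Whitney
  out3 <- compare_groups(rep(1, 20), rep(c("a", "b"), each = 10))
  expect_equal(out3$test_used, "mann_whitney")
  expect_equal(out3$p, 1)

  # identical groups -> large p
  v <- rep(c(1, 2, 3, 4, 5), 2)
  expect_gt(compare_groups(v, rep(c("a", "b"), each = 5))$p, 0.9)
})

test_that("compare_groups type-I error is calibrated on normal nulls", {
  set.seed(11)
  rej <- 0
  for (i in 1:2000)
    rej <- rej + (compare_groups(rnorm(30), rep(c("a", "b"), each = 15))$p < 0.05)
  expect_gt(rej / 2000, 0.03)
  expect_lt(rej / 2000, 0.07)
})

test_that("correlate: exact, null, and gated method selection", {
  x <- c(1, 2, 3, 4, 5)
  out <- correlate(x, -x, method = "pearson")
  expect_equal(out$r, -1)

  set.seed(13)
  xn <- rnorm(1000); yn <- rnorm(1000)
  expect_lt(abs(correlate(xn, yn, "pearson")$r), 0.1)

  # auto gate: bivariate normal -> pearson; heavy skew -> spearman
  expect_equal(correlate(xn, yn, "auto")$method, "pearson")
  expect_equal(correlate(exp(3 * xn), yn, "auto")$method, "spearman")
  expect_error(correlate(rep(1, 10), rnorm(10)), "variance")
})

test_that("roc: exact small cases and curve invariants", {
  # perfect separation
  expect_equal(roc(c(1, 2, 3, 10, 11, 12),
                   c(rep("control", 3), rep("case", 3)),
                   positive_is_low = FALSE)$auc, 1)
  # pair-count example: 2 of 4 pairs concordant
  expect_equal(roc(c(0.9, 0.1, 0.8, 0.2),
                   c("case", "case", "control", "control"),
                   positive_is_low = FALSE)$auc, 0.5)
  set.seed(17)
  s <- rnorm(40); lab <- rep(c("case", "control"), 20)
  r1 <- roc(s, lab, positive_is_low = FALSE)
  r2 <- roc(-s, lab, positive_is_low = FALSE)
  expect_equal(r1$auc + r2$auc, 1)
  expect_equal(r2$auc, roc(s, lab, positive_is_low = TRUE)$auc)
  # curve endpoints and monotonicity
  expect_equal(r1$tpr[1], 0); expect_equal(r1$fpr[1], 0)
  expect_equal(r1$tpr[length(r1$tpr)], 1)
  expect_equal(r1$fpr[length(r1$fpr)], 1)
  expect_true(all(diff(r1$tpr) >= 0) && all(diff(r1$fpr) >= 0))
  expect_error(roc(s, rep("case", 40)), "classes")
})

test_that("youden cutoff reports its sensitivity/specificity pair", {
  sc <- c(0.1, 0.2, 0.3, 0.7, 0.8, 0.9)
  lab <- c(rep("case", 3), rep("control", 3))
  r <- roc(sc, lab, positive_is_low = TRUE)
  expect_equal(r$auc, 1)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)
  expect_true(r$youden_cutoff >= 0.3 && r$youden_cutoff < 0.7)
})

test_that("biomarker_composite averages probes and supports pc1", {
  beta <- rbind(c(0.1, 0.5), c(0.3, 0.7))
  bm <- make_bm(beta)
  expect_equal(unname(biomarker_composite(bm, "cg00001")), c(0.1, 0.5))
  expect_equal(unname(biomarker_composite(bm, c("cg00001", "cg00002"))),
               c(0.2, 0.6))
  expect_error(biomarker_composite(bm, character(0)), "empty")
  set.seed(19)
  bigger <- make_bm(matrix(runif(50), 5, 10))
  pc <- biomarker_composite(bigger, bigger$probe_ids, method = "pc1")
  expect_length(pc, 10)
  # oriented with the mean composite
  expect_gt(cor(pc, biomarker_composite(bigger, bigger$probe_ids)), 0)
})

test_that("composite AUC is at least the median single-probe AUC", {
  co <- default_cohort(1)
  ids <- co$truth$biomarker$probe_ids
  grp <- co$sheet$group[match(co$bm$sample_ids, co$sheet$sample_id)]
  auc_one <- vapply(ids, function(i)
    roc(co$bm$beta[i, ], as.character(grp))$auc, numeric(1))
  auc_comp <- roc(biomarker_composite(co$bm, ids), as.character(grp))$auc
  expect_gte(auc_comp, median(auc_one))
})

test_that("phenotype grid has the right shape and skips bad variables", {
  co <- default_cohort(1)
  ids <- co$truth$biomarker$probe_ids
  grid <- phenotype_correlation_matrix(co$bm, co$sheet, ids)
  expect_equal(nrow(grid), length(ids) * 4L)
  expect_setequal(unique(grid$variable), c("age", "ft3", "ft4", "tsh"))
  # planted anti-coupling: every biomarker probe correlates negatively
  # with TSH, significantly
  tsh <- grid[grid$variable == "tsh", ]
  expect_true(all(tsh$r < 0))
  expect_true(all(tsh$p < 0.05))

  sheet2 <- co$sheet
  sheet2$age <- 40
  # two distinct warnings: absent variable and constant variable
  expect_warning(expect_warning(
    grid2 <- phenotype_correlation_matrix(co$bm, sheet2, ids,
                                          variables = c("age", "tsh",
                                                        "nope")),
    "absent"), "constant")
  expect_setequal(unique(grid2$variable), "tsh")
})
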