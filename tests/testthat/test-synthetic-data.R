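# generator: determinism, planted truth, distributional shape

test_that("config validation rejects impossible worlds", {
  expect_error(sim_config(gene_region_freq = c(TSS200 = 0.5, Body = 0.4)),
               "sum to 1")
  expect_error(sim_config(biomarker = list(gene = "X", k = 2,
                                           control_mean = 0.8,
                                           case_mean = 0.15,
                                           expression_log2_slope = 3,
                                           expression_r = -0.8,
                                           tsh_coupling = 3)),
               "k >= 3")
  expect_error(sim_config(biomarker = list(gene = "X", k = 5,
                                           control_mean = 0.8,
                                           case_mean = 0.5,
                                           expression_log2_slope = 3,
                                           expression_r = -0.8,
                                           tsh_coupling = 3)),
               "opposite sides")
  expect_error(sim_config(qc_fail = c(detection_p = 1)), "five")
})

test_that("generation is deterministic under the seed", {
  cfg <- sim_config(seed = 3, n_probes = 500)
  m1 <- generate_manifest(cfg); m2 <- generate_manifest(cfg)
  expect_identical(m1, m2)
  c1 <- generate_cohort(m1, cfg); c2 <- generate_cohort(m2, cfg)
  expect_identical(c1$bm$beta, c2$bm$beta)
  expect_identical(c1$sheet, c2$sheet)
  expect_identical(c1$truth, c2$truth)
  # a different seed gives a different world
  m3 <- generate_manifest(sim_config(seed = 4, n_probes = 500))
  expect_false(identical(m1$position, m3$position))
})

test_that("planted QC failure sets have the configured disjoint sizes", {
  cfg <- sim_config(seed = 2, n_probes = 1000)
  man <- generate_manifest(cfg)
  co <- generate_cohort(man, cfg)
  sizes <- vapply(co$truth$qc_fail, length, integer(1))
  expect_equal(unname(sizes[c("detection_p", "beadcount", "non_cpg",
                              "snp_or_crossreactive", "sex_chromosome")]),
               c(7L, 5L, 3L, 4L, 6L))
  all_ids <- unlist(co$truth$qc_fail, use.names = FALSE)
  expect_false(anyDuplicated(all_ids) > 0)
  # QC-fail probes are never planted DMPs, and never biomarker probes
  expect_length(intersect(all_ids, co$truth$dmp$probe_id), 0)
  expect_length(intersect(all_ids, co$truth$biomarker$probe_ids), 0)
  # X/Y probes in the manifest are exactly the planted sex failures
  expect_setequal(man$probe_id[man$chromosome %in% c("X", "Y")],
                  co$truth$qc_fail$sex_chromosome)
})

test_that("manifest category frequencies converge to the configuration", {
  cfg <- sim_config(seed = 6, n_probes = 50000)
  man <- generate_manifest(cfg)
  isl <- table(man$island_region) / nrow(man)
  for (cat_ in names(cfg$island_freq))
    expect_lt(abs(isl[[cat_]] - cfg$island_freq[[cat_]]), 0.02)
  igr_hat <- mean(!nzchar(man$gene))
  expect_lt(abs(igr_hat - cfg$igr_frac), 0.02)
})

test_that("realized planted delta-beta is close to target on average", {
  co <- default_cohort(1)
  st <- group_stats(co$bm, co$sheet)
  idx <- match(co$truth$dmp$probe_id, st$probe_id)
  expect_lt(abs(mean(abs(st$delta_beta[idx])) -
                co$cfg$planted_delta_beta), 0.05)
  # planted signs agree with realized direction for the large majority
  agree <- sign(st$delta_beta[idx]) == sign(co$truth$dmp$delta_beta_target)
  expect_gt(mean(agree), 0.95)
})

test_that("pooled beta distribution is bimodal", {
  co <- default_cohort(1)
  d <- density(as.vector(co$bm$beta), n = 256)
  maxima <- sum(diff(sign(diff(d$y))) == -2)
  expect_gte(maxima, 2)
  # the modes sit in the expected tails
  expect_gt(mean(co$bm$beta < 0.2), 0.2)
  expect_gt(mean(co$bm$beta > 0.8), 0.2)
  expect_lt(mean(co$bm$beta > 0.4 & co$bm$beta < 0.6), 0.2)
})

test_that("a world without planted effects yields (almost) no calls", {
  cfg <- sim_config(seed = 8, n_planted_dmps = 0, biomarker = NULL)
  man <- generate_manifest(cfg)
  co <- generate_cohort(man, cfg)
  expect_null(co$truth$biomarker)
  expect_equal(nrow(co$truth$dmp), 0L)
  res <- find_dmps(co$bm, co$sheet)
  expect_lte(nrow(res$dmps), 2L)
})

test_that("biomarker probes are promoter-annotated with extreme means", {
  co <- default_cohort(1)
  tr <- co$truth$biomarker
  gm <- manifest_gene_map(co$manifest)
  reg <- gm$region[gm$gene == tr$gene]
  expect_length(tr$probe_ids, 5L)
  expect_true(all(reg %in% c("TSS1500", "TSS200", "5UTR", "1stExon")))
  st <- group_stats(co$bm, co$sheet)
  i <- match(tr$probe_ids, st$probe_id)
  expect_true(all(st$mean_beta_case[i] < 0.3))
  expect_true(all(st$mean_beta_control[i] > 0.7))
})

test_that("written cohort files round-trip through the loaders", {
  cfg <- sim_config(seed = 10, n_probes = 300, n_planted_dmps = 20)
  man <- generate_manifest(cfg)
  co <- generate_cohort(man, cfg)
  dir <- tempfile()
  write_cohort(man, co, dir)
  expect_true(all(file.exists(file.path(dir,
    c("manifest.tsv", "beta.tsv", "detp.tsv", "beads.tsv",
      "samples.csv", "truth.json")))))
  man2 <- load_manifest(file.path(dir, "manifest.tsv"))
  expect_equal(man2, man)
  bm2 <- load_beta_matrix(file.path(dir, "beta.tsv"), man2,
                          detection_p_path = file.path(dir, "detp.tsv"),
                          beadcount_path = file.path(dir, "beads.tsv"))
  expect_identical(bm2$beta, co$bm$beta)
  expect_identical(bm2$detection_p, co$bm$detection_p)
  sheet2 <- load_sample_sheet(file.path(dir, "samples.csv"))
  expect_equal(sheet2$sample_id, co$sheet$sample_id)
})
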