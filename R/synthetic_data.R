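# Seeded synthetic 850K-like cohort generator with planted truth.
#
# The generator states a world with the structure the analysis assumes:
# a bimodal beta landscape (most CpGs near-fully methylated or
# near-fully unmethylated), logit-normal array noise, a set of planted
# case/control effects, one planted promoter biomarker gene whose
# methylation anti-correlates with expression and TSH, and planted
# QC-failing probes for every exclusion-cascade stage.

#' Simulation configuration
#'
#' Defaults state the paper-like world: 10 samples per group, a
#' 0.45/0.55 Beta(2,8)/Beta(8,2) methylation mixture with logit-scale
#' noise SD 0.5, 200 planted differential positions at |delta-beta| 0.2,
#' disjoint QC failures of 7/5/3/4/6 probes (detection-P, bead count,
#' non-CpG, SNP/cross-reactive, sex chromosomes), and one biomarker gene
#' with 5 promoter CpGs at control mean 0.80 / case mean 0.15 whose
#' composite methylation is coupled to expression (Pearson r -0.8 on the
#' log2 scale) and negatively to TSH.
#'
#' @param seed Integer seed; all randomness flows from it.
#' @param n_probes Number of array probes.
#' @param n_per_group Samples per group (case and control).
#' @param mixture_weight_low Weight of the unmethylated Beta mode.
#' @param shape_low,shape_high Beta shape pairs for the two modes.
#' @param noise_sd Per-sample noise SD on the logit scale.
#' @param n_planted_dmps Number of planted differential probes.
#' @param planted_delta_beta Target |delta-beta| of planted effects.
#' @param qc_fail Named counts of planted QC failures per cascade stage.
#' @param biomarker List: `gene`, `k` (promoter probes, >= 3),
#'   `control_mean`, `case_mean` (opposite sides of the 0.3/0.7
#'   extremes), `expression_log2_slope`, `expression_r` (target Pearson
#'   r between composite beta and log2 expression), `tsh_coupling`
#'   (log-scale slope of TSH on composite beta deficit).
#' @param gene_region_freq Frequencies of the six gene-region categories
#'   among mapped probes (must sum to 1).
#' @param igr_frac Fraction of intergenic probes.
#' @param island_freq Island-relation frequencies (must sum to 1).
#' @param gene_block_size Consecutive mapped probes sharing a gene.
#' @param frac_second_mapping Fraction of mapped probes given a second
#'   (gene, region) mapping.
#' @return A validated `SimConfig` list.
#' @export
sim_config <- function(seed = 1,
                       n_probes = 5000,
                       n_per_group = 10,
                       mixture_weight_low = 0.45,
                       shape_low = c(2, 8),
                       shape_high = c(8, 2),
                       noise_sd = 0.5,
                       n_planted_dmps = 200,
                       planted_delta_beta = 0.2,
                       qc_fail = c(detection_p = 7, beadcount = 5,
                                   non_cpg = 3, snp_or_crossreactive = 4,
                                   sex_chromosome = 6),
                       biomarker = list(gene = "BMK1", k = 5,
                                        control_mean = 0.80,
                                        case_mean = 0.15,
                                        expression_log2_slope = 3,
                                        expression_r = -0.8,
                                        tsh_coupling = 3),
                       gene_region_freq = c(TSS1500 = 0.13, TSS200 = 0.08,
                                            "5UTR" = 0.12, "1stExon" = 0.05,
                                            Body = 0.56, "3UTR" = 0.06),
                       igr_frac = 0.25,
                       island_freq = c(Island = 0.20, N_Shore = 0.07,
                                       S_Shore = 0.07, N_Shelf = 0.05,
                                       S_Shelf = 0.05, OpenSea = 0.56),
                       gene_block_size = 8,
                       frac_second_mapping = 0.10) {
  cfg <- list(seed = as.integer(seed), n_probes = n_probes,
              n_per_group = n_per_group,
              mixture_weight_low = mixture_weight_low,
              shape_low = shape_low, shape_high = shape_high,
              noise_sd = noise_sd, n_planted_dmps = n_planted_dmps,
              planted_delta_beta = planted_delta_beta, qc_fail = qc_fail,
              biomarker = biomarker, gene_region_freq = gene_region_freq,
              igr_frac = igr_frac, island_freq = island_freq,
              gene_block_size = gene_block_size,
              frac_second_mapping = frac_second_mapping)
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_probes >= 100, cfg$n_per_group >= 2,
            cfg$noise_sd > 0, cfg$planted_delta_beta >= 0,
            cfg$planted_delta_beta <= 1,
            cfg$mixture_weight_low >= 0, cfg$mixture_weight_low <= 1,
            cfg$igr_frac >= 0, cfg$igr_frac < 1,
            cfg$frac_second_mapping >= 0, cfg$frac_second_mapping <= 1)
  if (abs(sum(cfg$gene_region_freq) - 1) > 1e-8 ||
      abs(sum(cfg$island_freq) - 1) > 1e-8)
    stop_fmt("category frequencies must sum to 1 per axis")
  if (!setequal(names(cfg$qc_fail),
                c("detection_p", "beadcount", "non_cpg",
                  "snp_or_crossreactive", "sex_chromosome")))
    stop_fmt("qc_fail must name all five cascade stages")
  bm <- cfg$biomarker
  if (!is.null(bm)) {
    if (bm$k < 3) stop_fmt("biomarker needs k >= 3 promoter probes")
    extreme_opposite <-
      (bm$case_mean < 0.3 && bm$control_mean > 0.7) ||
      (bm$case_mean > 0.7 && bm$control_mean < 0.3)
    if (!extreme_opposite)
      stop_fmt("biomarker case/control means must sit on opposite sides of the 0.3/0.7 extremes")
  }
  structure(cfg, class = "SimConfig")
}

#' The default paper-like configuration
#'
#' [sim_config()] defaults with a chosen seed: 10 vs 10 methylation
#' samples and one biomarker gene with 5 promoter CpGs, hypomethylated
#' in cases.  Under this configuration the screen cascade yields exactly
#' one candidate gene.
#'
#' @param seed Integer seed.
#' @return A `SimConfig`.
#' @export
default_paper_like_config <- function(seed = 1) sim_config(seed = seed)

#' Generate a synthetic probe manifest
#'
#' Probes are placed on chromosomes 1-22 at increasing positions, plus
#' the configured number of planted X/Y probes; consecutive mapped
#' probes share gene symbols in blocks; island relations follow the
#' configured frequencies.  The biomarker gene's probes are consecutive
#' promoter-annotated CpGs on chromosome 17.  Deterministic under the
#' config seed.
#'
#' @param config A [sim_config()].
#' @return A `methyl_manifest` (see [load_manifest()]).
#' @export
generate_manifest <- function(config) {
  set.seed(config$seed)
  n <- config$n_probes
  qc <- config$qc_fail
  bmk <- config$biomarker

  chrom <- sample(as.character(1:22), n, replace = TRUE,
                  prob = (22:1) / sum(22:1))
  # planted sex-chromosome probes
  flag_pool <- sample(which(chrom != "17"))  # keep chr17 clean for biomarker
  sex_idx <- flag_pool[seq_len(qc[["sex_chromosome"]])]
  flag_pool <- flag_pool[-seq_len(qc[["sex_chromosome"]])]
  chrom[sex_idx] <- sample(c("X", "Y"), length(sex_idx), replace = TRUE)
  noncpg_idx <- flag_pool[seq_len(qc[["non_cpg"]])]
  flag_pool <- flag_pool[-seq_len(qc[["non_cpg"]])]
  snpcr_idx <- flag_pool[seq_len(qc[["snp_or_crossreactive"]])]

  is_cpg <- rep(TRUE, n); is_cpg[noncpg_idx] <- FALSE
  snp <- rep(FALSE, n); crossr <- rep(FALSE, n)
  half <- seq_len(ceiling(length(snpcr_idx) / 2))
  snp[snpcr_idx[half]] <- TRUE
  crossr[setdiff(snpcr_idx, snpcr_idx[half])] <- TRUE

  # positions: increasing within chromosome
  position <- integer(n)
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    position[i] <- cumsum(sample(500:5000, length(i), replace = TRUE))
  }

  # gene blocks of consecutive mapped probes within a chromosome
  gene <- character(n); region <- character(n)
  igr <- runif(n) < config$igr_frac
  regions6 <- names(config$gene_region_freq)
  for (ch in unique(chrom)) {
    i <- which(chrom == ch & !igr)
    if (!length(i)) next
    block <- ceiling(seq_along(i) / config$gene_block_size)
    gene[i] <- sprintf("G%s_%03d", ch, block)
    region[i] <- sample(regions6, length(i), replace = TRUE,
                        prob = config$gene_region_freq)
  }
  # second mappings: same gene, a different region
  mapped <- which(nzchar(gene))
  second <- mapped[runif(length(mapped)) < config$frac_second_mapping]
  for (i in second) {
    r2 <- sample(setdiff(regions6, region[i]), 1)
    gene[i] <- paste(gene[i], gene[i], sep = ";")
    region[i] <- paste(region[i], r2, sep = ";")
  }

  # biomarker gene: k consecutive clean CpG probes on chromosome 17
  if (!is.null(bmk)) {
    bm_chrom <- "17"
    cand <- which(chrom == bm_chrom & is_cpg & !snp & !crossr)
    if (length(cand) < bmk$k) {
      # small manifests may leave chromosome 17 underpopulated; fall back
      # to the best-populated autosome
      clean_auto <- is_cpg & !snp & !crossr & chrom %in% as.character(1:22)
      bm_chrom <- names(which.max(table(chrom[clean_auto])))
      cand <- which(chrom == bm_chrom & is_cpg & !snp & !crossr)
    }
    if (length(cand) < bmk$k)
      stop_fmt("not enough clean autosomal probes for the biomarker gene")
    start <- sample(seq_len(length(cand) - bmk$k + 1), 1)
    bidx <- cand[start:(start + bmk$k - 1)]
    gene[bidx] <- bmk$gene
    region[bidx] <- rep(c("TSS200", "TSS1500", "1stExon"),
                        length.out = bmk$k)
  }

  probe_id <- sprintf("cg%07d", seq_len(n))
  probe_id[noncpg_idx] <- sprintf("ch.%07d", noncpg_idx)

  man <- data.frame(
    probe_id = probe_id, chromosome = chrom, position = position,
    probe_type = sample(c("I", "II"), n, replace = TRUE,
                        prob = c(0.16, 0.84)),
    gene = gene, gene_region = region,
    island_region = sample(names(config$island_freq), n, replace = TRUE,
                           prob = config$island_freq),
    is_cpg = is_cpg, is_snp_associated = snp, is_cross_reactive = crossr,
    stringsAsFactors = FALSE
  )
  validate_manifest(man)
}

#' Generate a synthetic case-control cohort with planted truth
#'
#' Per-probe baseline means are drawn from the bimodal Beta mixture;
#' per-sample beta values are inverse-logit of the latent mean plus
#' Gaussian noise.  Planted differential probes shift the case-group
#' latent mean so the expected group difference equals the target
#' delta-beta (sign random, flipped when infeasible); biomarker probes
#' are pinned near the configured control/case means.  Detection-P and
#' bead-count matrices carry the planted stage failures and nothing
#' else.  Expression, TSH, FT3 and FT4 are coupled to the biomarker
#' composite as configured; qPCR Ct values are emitted so the 2^-ddCt
#' route reproduces the planted expression.  All values are written at
#' fixed decimal precision, so runs are reproducible at file level.
#'
#' @param manifest Output of [generate_manifest()] (same config).
#' @param config The same [sim_config()].
#' @return List: `bm` (a [beta_matrix()] with detection-P and bead
#'   counts), `sheet` (sample sheet data frame), `truth` (planted-truth
#'   list: `dmp` table, `qc_fail` id sets, `biomarker` spec, `seed`).
#' @export
generate_cohort <- function(manifest, config) {
  set.seed(config$seed + 1L)
  n <- nrow(manifest)
  npg <- config$n_per_group
  bmk <- config$biomarker
  sample_ids <- c(sprintf("C%d", seq_len(npg)), sprintf("HT%d", seq_len(npg)))
  is_case <- c(rep(FALSE, npg), rep(TRUE, npg))

  # baseline probe means from the bimodal mixture
  low <- runif(n) < config$mixture_weight_low
  m0 <- ifelse(low,
               rbeta(n, config$shape_low[1], config$shape_low[2]),
               rbeta(n, config$shape_high[1], config$shape_high[2]))
  m0 <- pmin(pmax(m0, 0.02), 0.98)

  flags <- filter_flags(manifest)
  if (!is.null(bmk)) {
    bprobes <- manifest$probe_id[vapply(
      strsplit(manifest$gene, ";", fixed = TRUE),
      function(g) bmk$gene %in% g, logical(1))]
    if (length(bprobes) != bmk$k)
      stop_fmt("manifest/config mismatch: expected %d biomarker probes, found %d",
               bmk$k, length(bprobes))
  } else bprobes <- character(0)

  clean <- manifest$is_cpg & !manifest$is_snp_associated &
    !manifest$is_cross_reactive & manifest$chromosome %in% as.character(1:22) &
    !(manifest$probe_id %in% bprobes)

  # planted QC failures (matrix-level stages), disjoint from everything
  pool <- sample(which(clean))
  detp_idx <- pool[seq_len(config$qc_fail[["detection_p"]])]
  pool <- pool[-seq_len(config$qc_fail[["detection_p"]])]
  bead_idx <- pool[seq_len(config$qc_fail[["beadcount"]])]
  pool <- pool[-seq_len(config$qc_fail[["beadcount"]])]

  # planted DMPs: from the remaining clean pool, at most two per gene so
  # planted effects cannot fabricate a >= 3-DMP candidate gene
  gene_lists <- strsplit(manifest$gene, ";", fixed = TRUE)
  gene_count <- new.env(parent = emptyenv())
  dmp_idx <- integer(0)
  for (i in pool) {
    if (length(dmp_idx) >= config$n_planted_dmps) break
    genes <- unique(gene_lists[[i]])
    genes <- genes[nzchar(genes)]
    counts <- vapply(genes, function(g)
      if (is.null(gene_count[[g]])) 0L else gene_count[[g]], integer(1))
    if (any(counts >= 2L)) next
    for (g in genes) gene_count[[g]] <- counts[[g]] + 1L
    dmp_idx <- c(dmp_idx, i)
  }
  if (length(dmp_idx) < config$n_planted_dmps)
    stop_fmt("could not place %d planted DMPs under the per-gene cap",
             config$n_planted_dmps)

  # latent means: control column = baseline; case column adds the shift
  mu_ctrl <- logit(m0)
  mu_case <- mu_ctrl
  sign_draw <- sample(c(-1, 1), length(dmp_idx), replace = TRUE)
  target_db <- numeric(length(dmp_idx))
  for (j in seq_along(dmp_idx)) {
    i <- dmp_idx[j]
    s <- sign_draw[j]
    t1 <- m0[i] + s * config$planted_delta_beta
    if (t1 < 0.02 || t1 > 0.98) {
      s <- -s
      t1 <- m0[i] + s * config$planted_delta_beta
      if (t1 < 0.02 || t1 > 0.98)
        stop_fmt("infeasible planted delta-beta for probe %s (baseline %.3f)",
                 manifest$probe_id[i], m0[i])
    }
    mu_case[i] <- logit(t1)
    target_db[j] <- s * config$planted_delta_beta
  }

  # biomarker probes: pinned means with small per-probe jitter
  bm_i <- match(bprobes, manifest$probe_id)
  if (!is.null(bmk)) {
    ctrl_means <- bmk$control_mean + runif(bmk$k, -0.03, 0.03)
    case_means <- bmk$case_mean + runif(bmk$k, -0.05, 0.01)
    mu_ctrl[bm_i] <- logit(ctrl_means)
    mu_case[bm_i] <- logit(case_means)
  }

  # beta values
  mu <- matrix(rep(mu_ctrl, 2 * npg), nrow = n)
  mu[, is_case] <- rep(mu_case, npg)
  beta <- expit(mu + matrix(rnorm(n * 2 * npg, 0, config$noise_sd), nrow = n))
  beta <- round_via_text(beta, 6)
  dimnames(beta) <- list(manifest$probe_id, sample_ids)

  # detection P and bead counts
  detp <- matrix(round_via_text(runif(n * 2 * npg, 0, 0.005), 6), nrow = n,
                 dimnames = dimnames(beta))
  for (i in detp_idx) {
    k <- sample(1:3, 1)
    detp[i, sample(2 * npg, k)] <- round_via_text(runif(k, 0.011, 0.2), 6)
  }
  beads <- matrix(sample(5:30, n * 2 * npg, replace = TRUE), nrow = n,
                  dimnames = dimnames(beta))
  cutoff <- max(1L, ceiling(0.05 * 2 * npg))
  for (i in bead_idx)
    beads[i, sample(2 * npg, cutoff)] <- sample(0:2, cutoff, replace = TRUE)

  bm_obj <- beta_matrix(beta, detection_p = detp, beadcount = beads)

  # phenotypes and expression, coupled to the realized biomarker composite
  # (uncoupled pure-noise world when no biomarker is planted)
  if (!is.null(bmk)) {
    comp <- colMeans(beta[bm_i, , drop = FALSE])
    deficit <- mean(comp[!is_case]) - comp
  } else {
    comp <- rep(0.5, 2 * npg)
    deficit <- rep(0, 2 * npg)
  }
  tsh_coupling <- if (is.null(bmk)) 0 else bmk$tsh_coupling
  tsh <- round(exp(log(1.8) + tsh_coupling * deficit + rnorm(2 * npg, 0, 0.4)), 2)
  ft4 <- round(11 + 8 * comp + rnorm(2 * npg, 0, 1.5), 2)
  ft3 <- round(2.5 + 3 * comp + rnorm(2 * npg, 0, 0.35), 2)
  age_base <- sample(28:55, npg, replace = TRUE)
  age <- c(age_base, pmax(25, age_base + sample(-2:2, npg, replace = TRUE)))
  bmi <- round(rnorm(2 * npg, 23, 2), 2)
  tpoab <- round(ifelse(is_case, pmin(1300, exp(rnorm(2 * npg, log(600), 0.8))),
                        runif(2 * npg, 4, 40)), 1)
  tgab <- round(ifelse(is_case, runif(2 * npg, 18, 60), runif(2 * npg, 4, 9)), 1)

  if (!is.null(bmk)) {
    signal <- bmk$expression_log2_slope * deficit
    noise_sd_expr <- stats::sd(signal) * sqrt(1 / bmk$expression_r^2 - 1)
    log2e <- signal + rnorm(2 * npg, 0, noise_sd_expr)
  } else {
    log2e <- rnorm(2 * npg, 0, 0.7)
  }
  ct_ref <- round(rnorm(2 * npg, 18, 0.3), 3)
  ct_target <- round(ct_ref + 4 - log2e, 3)

  sheet <- data.frame(
    sample_id = sample_ids,
    group = ifelse(is_case, "case", "control"),
    pair_id = rep(sprintf("P%02d", seq_len(npg)), 2),
    age = age, sex = "F", bmi = bmi,
    tsh = tsh, ft3 = ft3, ft4 = ft4, tpoab = tpoab, tgab = tgab,
    ct_target = ct_target, ct_reference = ct_ref,
    stringsAsFactors = FALSE
  )

  truth <- list(
    dmp = data.frame(probe_id = manifest$probe_id[dmp_idx],
                     delta_beta_target = target_db,
                     direction = ifelse(target_db > 0, "hyper", "hypo"),
                     stringsAsFactors = FALSE),
    qc_fail = list(detection_p = manifest$probe_id[detp_idx],
                   beadcount = manifest$probe_id[bead_idx],
                   non_cpg = flags$non_cpg,
                   snp_or_crossreactive = flags$snp_or_crossreactive,
                   sex_chromosome = flags$sex_chromosome),
    biomarker = if (is.null(bmk)) NULL else
      list(gene = bmk$gene, probe_ids = bprobes,
           control_mean = bmk$control_mean,
           case_mean = bmk$case_mean,
           expression_r = bmk$expression_r,
           expression_scale = "log2",
           tsh_coupling = bmk$tsh_coupling),
    seed = config$seed
  )
  list(bm = bm_obj, sheet = sheet, truth = truth)
}

#' Write a generated cohort to a directory
#'
#' Emits `manifest.tsv`, `beta.tsv`, `detp.tsv`, `beads.tsv`,
#' `samples.csv` and `truth.json` under `out_dir`.
#'
#' @param manifest,cohort Outputs of [generate_manifest()] /
#'   [generate_cohort()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_cohort <- function(manifest, cohort, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_manifest(manifest, file.path(out_dir, "manifest.tsv"))
  write_beta_matrix(cohort$bm, file.path(out_dir, "beta.tsv"),
                    detection_p_path = file.path(out_dir, "detp.tsv"),
                    beadcount_path = file.path(out_dir, "beads.tsv"))
  utils::write.csv(cohort$sheet, file.path(out_dir, "samples.csv"),
                   row.names = FALSE)
  jsonlite::write_json(cohort$truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
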