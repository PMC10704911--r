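# Fixture builders and independent oracles shared across test files.
# All fixtures are built in code; nothing is read from disk except what a
# test itself writes to tempfiles.

# Build a manifest through the public TSV route (external column names).
make_manifest <- function(probe_id,
                          chr = "1",
                          pos = seq_along(probe_id) * 100L,
                          type = "II",
                          gene = "",
                          gene_region = "",
                          island_region = "OpenSea",
                          is_cpg = TRUE,
                          snp = FALSE,
                          cross_reactive = FALSE) {
  df <- data.frame(probe_id = probe_id, chr = chr, pos = pos, type = type,
                   gene = gene, gene_region = gene_region,
                   island_region = island_region, is_cpg = is_cpg,
                   snp = snp, cross_reactive = cross_reactive,
                   stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  load_manifest(path)
}

make_bm <- function(beta, detection_p = NULL, beadcount = NULL,
                    probes = NULL, samples = NULL) {
  if (is.null(probes)) probes <- sprintf("cg%05d", seq_len(nrow(beta)))
  if (is.null(samples)) samples <- sprintf("S%d", seq_len(ncol(beta)))
  dimnames(beta) <- list(probes, samples)
  if (!is.null(detection_p)) dimnames(detection_p) <- dimnames(beta)
  if (!is.null(beadcount)) dimnames(beadcount) <- dimnames(beta)
  beta_matrix(beta, detection_p, beadcount)
}

make_sheet <- function(n_control, n_case = n_control) {
  data.frame(
    sample_id = c(sprintf("S%d", seq_len(n_control)),
                  sprintf("S%d", n_control + seq_len(n_case))),
    group = rep(c("control", "case"), c(n_control, n_case)),
    stringsAsFactors = FALSE
  )
}

# Independent Benjamini-Hochberg oracle: literal step-up definition, one
# minimisation per element (no running minima).
bh_oracle <- function(p) {
  m <- length(p)
  if (m == 0) return(numeric(0))
  r <- rank(p)
  vapply(seq_len(m), function(i) {
    j <- which(r >= r[i])
    min(1, min(p[j] * m / r[j]))
  }, numeric(1))
}

# Closed-form Pearson chi-square for a 2x2 table (independent of the
# sum((O-E)^2/E) route used by the package).
chisq_closed_form <- function(a, b, c, d) {
  n <- a + b + c + d
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

# Mean silhouette width of labelled points (hand-rolled; tiny n only).
mean_silhouette <- function(xy, labels) {
  d <- as.matrix(stats::dist(xy))
  n <- nrow(xy)
  s <- vapply(seq_len(n), function(i) {
    same <- labels == labels[i]; same[i] <- FALSE
    a <- mean(d[i, same])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(d[i, labels == l]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

# Pairwise-comparison AUC oracle (Mann-Whitney pair counting).
auc_oracle <- function(case_scores, control_scores) {
  cmp <- outer(case_scores, control_scores, function(x, y)
    (x > y) + 0.5 * (x == y))
  mean(cmp)
}

# One generated default cohort, shared by tests that only read it.
default_cohort <- local({
  cache <- NULL
  function(seed = 1) {
    if (is.null(cache) || cache$seed != seed) {
      cfg <- default_paper_like_config(seed)
      man <- generate_manifest(cfg)
      co <- generate_cohort(man, cfg)
      cache <<- list(seed = seed, cfg = cfg, manifest = man,
                     bm = co$bm, sheet = co$sheet, truth = co$truth)
    }
    cache
  }
})
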