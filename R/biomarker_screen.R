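#' Screen parameter bundle
#'
#' @param promoter_regions Annotation categories counted as promoter.
#' @param beta_lo,beta_hi Extreme-methylation bounds: a probe survives
#'   when its group-mean beta is `< beta_lo` or `> beta_hi` (strict).
#' @param min_dmps Minimum distinct surviving DMPs per candidate gene
#'   (inclusive).
#' @param extreme_group Which group's mean the extreme filter inspects:
#'   `"case"` (default), `"control"`, `"either"`, or `"both"`.
#' @return A named list of validated parameters.
#' @export
screen_params <- function(promoter_regions = PROMOTER_REGIONS,
                          beta_lo = 0.3, beta_hi = 0.7, min_dmps = 3,
                          extreme_group = c("case", "control",
                                            "either", "both")) {
  extreme_group <- match.arg(extreme_group)
  stopifnot(beta_lo >= 0, beta_hi <= 1, beta_lo < beta_hi, min_dmps >= 1)
  list(promoter_regions = promoter_regions, beta_lo = beta_lo,
       beta_hi = beta_hi, min_dmps = min_dmps, extreme_group = extreme_group)
}

#' Promoter-resident (DMP, gene) pairs
#'
#' Keeps every gene mapping of a DMP whose region is a promoter category
#' (TSS1500, TSS200, 5'UTR, 1st exon by default); a probe may survive
#' through any one of its mappings and may support several genes.
#'
#' @param dmps DMP table (`probe_id`, group means, `delta_beta`, ...).
#' @param manifest Manifest covering the DMPs.
#' @param promoter_regions Promoter categories.
#' @return Data frame of pairs: `probe_id`, `gene`, `region`, plus the
#'   DMP's `mean_beta_case`, `mean_beta_control`, `delta_beta`.
#' @export
promoter_filter <- function(dmps, manifest,
                            promoter_regions = PROMOTER_REGIONS) {
  gm <- manifest_gene_map(manifest)
  gm <- gm[gm$probe_id %in% dmps$probe_id & gm$region %in% promoter_regions, ,
           drop = FALSE]
  idx <- match(gm$probe_id, dmps$probe_id)
  out <- data.frame(gm,
                    mean_beta_case = dmps$mean_beta_case[idx],
                    mean_beta_control = dmps$mean_beta_control[idx],
                    delta_beta = dmps$delta_beta[idx],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Extreme-methylation filter
#'
#' Keeps pairs whose group-mean beta lies outside \[beta_lo, beta_hi\]
#' (strict inequalities): strikingly unmethylated or strikingly
#' methylated probes, the levels most plausibly tied to expression loss
#' or gain.
#'
#' @param pairs Output of [promoter_filter()].
#' @param beta_lo,beta_hi Bounds (defaults 0.3 / 0.7).
#' @param group Which group mean to test (default `"case"`; `"either"`
#'   passes if either group is extreme, `"both"` requires both).
#' @return The surviving subset of `pairs`.
#' @export
extreme_beta_filter <- function(pairs, beta_lo = 0.3, beta_hi = 0.7,
                                group = c("case", "control",
                                          "either", "both")) {
  group <- match.arg(group)
  extreme <- function(m) m < beta_lo | m > beta_hi
  keep <- switch(group,
    case = extreme(pairs$mean_beta_case),
    control = extreme(pairs$mean_beta_control),
    either = extreme(pairs$mean_beta_case) | extreme(pairs$mean_beta_control),
    both = extreme(pairs$mean_beta_case) & extreme(pairs$mean_beta_control))
  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Minimum-DMP-per-gene filter
#'
#' @param pairs Surviving (probe, gene) pairs.
#' @param min_dmps Minimum count of distinct surviving probes per gene
#'   (inclusive; default 3).
#' @return Data frame `gene`, `n_dmps` for candidate genes.
#' @export
min_dmp_gene_filter <- function(pairs, min_dmps = 3) {
  if (nrow(pairs) == 0)
    return(data.frame(gene = character(0), n_dmps = integer(0),
                      stringsAsFactors = FALSE))
  n <- vapply(split(pairs$probe_id, pairs$gene),
              function(p) length(unique(p)), integer(1))
  out <- data.frame(gene = names(n), n_dmps = as.integer(n),
                    stringsAsFactors = FALSE)
  out <- out[out$n_dmps >= min_dmps, , drop = FALSE]
  rownames(out) <- NULL
  out[order(-out$n_dmps, out$gene), , drop = FALSE]
}

#' Run the three-criterion epigenetic-biomarker screen
#'
#' Cascade: (1) keep promoter-resident (DMP, gene) mappings; (2) keep
#' probes with extreme group-mean methylation (< beta_lo or > beta_hi);
#' (3) keep genes with at least `min_dmps` distinct surviving DMPs.
#' Per-stage probe and gene counts are recorded.
#'
#' @param dmps DMP table from [find_dmps()] / [call_dmps()].
#' @param manifest Manifest covering the DMPs.
#' @param params A [screen_params()] bundle.
#' @return A `ScreenReport` list: `stage_counts` (stage, n_dmps,
#'   n_genes), `candidates` (gene-level: gene, n_dmps), `candidate_pairs`
#'   (surviving pairs restricted to candidate genes), `params`.
#' @export
run_screen <- function(dmps, manifest, params = screen_params()) {
  gm_all <- manifest_gene_map(manifest)
  genes_of <- function(ids) unique(gm_all$gene[gm_all$probe_id %in% ids])

  pairs1 <- promoter_filter(dmps, manifest, params$promoter_regions)
  pairs2 <- extreme_beta_filter(pairs1, params$beta_lo, params$beta_hi,
                                params$extreme_group)
  cand <- min_dmp_gene_filter(pairs2, params$min_dmps)
  pairs3 <- pairs2[pairs2$gene %in% cand$gene, , drop = FALSE]

  stage_counts <- data.frame(
    stage = c("input", "promoter", "extreme_beta", "min_dmps_gene"),
    n_dmps = c(nrow(dmps),
               length(unique(pairs1$probe_id)),
               length(unique(pairs2$probe_id)),
               length(unique(pairs3$probe_id))),
    n_genes = c(length(genes_of(dmps$probe_id)),
                length(unique(pairs1$gene)),
                length(unique(pairs2$gene)),
                nrow(cand)),
    stringsAsFactors = FALSE
  )
  structure(list(stage_counts = stage_counts, candidates = cand,
                 candidate_pairs = pairs3, params = params),
            class = "ScreenReport")
}

#' @export
print.ScreenReport <- function(x, ...) {
  cat("Epigenetic-biomarker screen cascade:\n")
  print(x$stage_counts, row.names = FALSE)
  if (nrow(x$candidates)) {
    cat("Candidate genes:\n")
    print(x$candidates, row.names = FALSE)
  } else cat("No candidate genes.\n")
  invisible(x)
}
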