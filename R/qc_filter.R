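#' Probes failing the detection-P criterion
#'
#' A probe fails when its detection P-value is at or above `threshold`
#' (inclusive) in one or more samples.
#'
#' @param bm A [beta_matrix()] carrying a `detection_p` matrix.
#' @param threshold Detection-P cutoff (default 0.01).
#' @return Character vector of failing probe ids.  If the detection-P
#'   matrix is absent the stage is skipped with a warning and an empty
#'   set is returned.
#' @export
filter_detection_p <- function(bm, threshold = 0.01) {
  if (is.null(bm$detection_p)) {
    warn_fmt("detection-P matrix absent; detection-P stage skipped")
    return(character(0))
  }
  fail <- rowSums(bm$detection_p >= threshold, na.rm = TRUE) >= 1
  bm$probe_ids[fail]
}

#' Probes failing the bead-count criterion
#'
#' A probe fails when the number of samples with fewer than `min_beads`
#' beads reaches `ceil(sample_frac * n_samples)` (at least one sample).
#'
#' @param bm A [beta_matrix()] carrying a `beadcount` matrix.
#' @param min_beads Minimum acceptable bead count (default 3).
#' @param sample_frac Fraction of samples allowed to fall below
#'   `min_beads` before the probe is removed (default 0.05).
#' @return Character vector of failing probe ids (empty set with a
#'   warning if bead counts are absent).
#' @export
filter_beadcount <- function(bm, min_beads = 3, sample_frac = 0.05) {
  if (is.null(bm$beadcount)) {
    warn_fmt("beadcount matrix absent; beadcount stage skipped")
    return(character(0))
  }
  n_low <- rowSums(bm$beadcount < min_beads, na.rm = TRUE)
  cutoff <- max(1L, ceiling(sample_frac * ncol(bm$beadcount)))
  bm$probe_ids[n_low >= cutoff]
}

#' Annotation-flag exclusion sets
#'
#' @param manifest A manifest from [load_manifest()].
#' @return A list of three character vectors: `non_cpg` (probes not
#'   interrogating a CpG), `snp_or_crossreactive`, and `sex_chromosome`
#'   (X or Y).
#' @export
filter_flags <- function(manifest) {
  list(
    non_cpg = manifest$probe_id[!manifest$is_cpg],
    snp_or_crossreactive =
      manifest$probe_id[manifest$is_snp_associated | manifest$is_cross_reactive],
    sex_chromosome = manifest$probe_id[manifest$chromosome %in% c("X", "Y")]
  )
}

#' Apply the probe-exclusion cascade
#'
#' Stages, in order: detection-P, bead count, non-CpG, SNP/cross-reactive,
#' sex chromosomes.  A probe failing several criteria is attributed to the
#' first stage that removes it; the final retained set is order-invariant.
#'
#' @param bm A [beta_matrix()].
#' @param manifest Manifest covering the matrix probes.
#' @param detection_p_threshold,min_beads,beadcount_sample_frac Stage
#'   parameters (defaults 0.01, 3, 0.05).
#' @return A list with `retained` (the filtered `BetaMatrix`) and
#'   `report` (a `FilterReport`: `n_input`, `per_stage` data frame,
#'   `removed_ids` per-stage list, `n_retained`).
#' @export
apply_filter_cascade <- function(bm, manifest,
                                 detection_p_threshold = 0.01,
                                 min_beads = 3,
                                 beadcount_sample_frac = 0.05) {
  flags <- filter_flags(manifest)
  stage_sets <- list(
    detection_p = filter_detection_p(bm, detection_p_threshold),
    beadcount = filter_beadcount(bm, min_beads, beadcount_sample_frac),
    non_cpg = flags$non_cpg,
    snp_or_crossreactive = flags$snp_or_crossreactive,
    sex_chromosome = flags$sex_chromosome
  )

  remaining <- bm$probe_ids
  removed_ids <- list()
  per_stage <- data.frame(stage = names(stage_sets),
                          n_removed = NA_integer_, n_remaining = NA_integer_,
                          stringsAsFactors = FALSE)
  for (i in seq_along(stage_sets)) {
    hit <- intersect(remaining, stage_sets[[i]])
    remaining <- setdiff(remaining, hit)
    removed_ids[[names(stage_sets)[i]]] <- hit
    per_stage$n_removed[i] <- length(hit)
    per_stage$n_remaining[i] <- length(remaining)
  }

  report <- structure(
    list(n_input = length(bm$probe_ids), per_stage = per_stage,
         removed_ids = removed_ids, n_retained = length(remaining)),
    class = "FilterReport")
  list(retained = subset_probes(bm, remaining), report = report)
}

#' @export
print.FilterReport <- function(x, ...) {
  cat(sprintf("Probe QC cascade: %d -> %d probes\n", x$n_input, x$n_retained))
  print(x$per_stage, row.names = FALSE)
  invisible(x)
}
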