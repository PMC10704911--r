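#' Classify a position relative to a CpG island
#'
#' Inside the island is `Island`; within 2 kb of the nearest island edge
#' is a shore; 2-4 kb out is a shelf; anything farther (or no island at
#' all) is `OpenSea`.  The `N_`/`S_` prefix marks the lower-/
#' higher-coordinate side of the island.  Vectorised over `position`.
#'
#' @param position 1-based probe position(s).
#' @param island_start,island_end Nearest island interval (1-based,
#'   inclusive); `NA` means no island on the chromosome.
#' @return Character vector of island categories.
#' @export
classify_island_region <- function(position, island_start, island_end) {
  n <- length(position)
  island_start <- rep_len(island_start, n)
  island_end <- rep_len(island_end, n)
  out <- character(n)
  for (i in seq_len(n)) {
    s <- island_start[i]; e <- island_end[i]; p <- position[i]
    if (is.na(s) || is.na(e)) { out[i] <- "OpenSea"; next }
    if (s > e) stop_fmt("island_start > island_end (%d > %d)", s, e)
    if (p >= s && p <= e) { out[i] <- "Island"; next }
    north <- p < s
    d <- if (north) s - p else p - e
    out[i] <- if (d <= 2000) {
      if (north) "N_Shore" else "S_Shore"
    } else if (d <= 4000) {
      if (north) "N_Shelf" else "S_Shelf"
    } else "OpenSea"
  }
  out
}

probe_category <- function(probe_ids, manifest, axis) {
  idx <- match(probe_ids, manifest$probe_id)
  if (anyNA(idx))
    stop_fmt("probe %s not present in manifest", probe_ids[which(is.na(idx))[1]])
  switch(axis,
    gene_region = {
      # One count per probe, attributed to its first-listed mapping
      # (IGR when unmapped), so category totals equal probe counts.
      first <- sub(";.*$", "", manifest$gene_region[idx])
      ifelse(nzchar(first), first, "IGR")
    },
    island_region = manifest$island_region[idx],
    chromosome = manifest$chromosome[idx],
    stop_fmt("unknown axis '%s'", axis))
}

axis_levels <- function(axis) {
  switch(axis,
    gene_region = c(GENE_REGIONS, "IGR"),
    island_region = ISLAND_REGIONS,
    chromosome = CHROMOSOMES)
}

#' Categorical distribution of a probe set
#'
#' Tallies a probe set along one annotation axis.  For `gene_region`,
#' each probe contributes a single count to its first-listed mapping
#' (IGR if unmapped), so counts sum to the number of probes.
#'
#' @param probe_ids Probe ids (all must be in the manifest).
#' @param manifest A manifest from [load_manifest()].
#' @param axis `"gene_region"`, `"island_region"`, or `"chromosome"`.
#' @return A `DistributionTable`: data frame `category`, `count`,
#'   `percent` (0-100) with attribute `total`.
#' @export
distribution_table <- function(probe_ids, manifest,
                               axis = c("gene_region", "island_region",
                                        "chromosome")) {
  axis <- match.arg(axis)
  lev <- axis_levels(axis)
  cat_ <- if (length(probe_ids)) probe_category(probe_ids, manifest, axis)
          else character(0)
  counts <- table(factor(cat_, levels = lev))
  total <- length(probe_ids)
  out <- data.frame(category = lev, count = as.integer(counts),
                    percent = if (total > 0) 100 * as.integer(counts) / total
                              else rep(0, length(lev)),
                    stringsAsFactors = FALSE)
  attr(out, "total") <- total
  attr(out, "axis") <- axis
  class(out) <- c("DistributionTable", "data.frame")
  out
}

#' Pearson chi-square on a 2x2 table (no continuity correction)
#'
#' @param tab 2x2 integer matrix of observed counts.
#' @return List `chi2`, `p`, `expected`.
#' @export
chisq_2x2 <- function(tab) {
  if (length(tab) != 4L)
    stop_fmt("chisq_2x2 expects a 2x2 table")
  a <- tab[1L]; c_ <- tab[2L]; b <- tab[3L]; d <- tab[4L]
  r1 <- a + b; r2 <- c_ + d; c1 <- a + c_; c2 <- b + d
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0)
    stop_fmt("zero margin: category untestable",
             class = "methylscreen_untestable")
  n <- r1 + r2
  e11 <- r1 * c1 / n; e12 <- r1 * c2 / n
  e21 <- r2 * c1 / n; e22 <- r2 * c2 / n
  chi2 <- (a - e11)^2 / e11 + (b - e12)^2 / e12 +
          (c_ - e21)^2 / e21 + (d - e22)^2 / e22
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       expected = matrix(c(e11, e21, e12, e22), 2L, 2L))
}

#' Category enrichment between two probe sets
#'
#' Builds the 2x2 table (in/out of `category` by set A/set B) from two
#' distribution tables on the same axis and applies the Pearson
#' chi-square test without continuity correction.  When any expected
#' count is below 5 the result is flagged (`low_expected`) and a Fisher
#' exact p is supplied alongside.
#'
#' @param set_a_table,set_b_table [distribution_table()]s on one axis.
#' @param category Category to test.
#' @return An `EnrichmentResult` list: `category`, `table`, `chi2`, `p`,
#'   `direction` (`"over"` if A's in-category proportion exceeds B's),
#'   `low_expected`, `p_exact` (NA unless flagged).
#' @export
enrichment_chisq <- function(set_a_table, set_b_table, category) {
  if (!identical(attr(set_a_table, "axis"), attr(set_b_table, "axis")))
    stop_fmt("distribution tables are on different axes")
  get_in <- function(tab) {
    i <- match(category, tab$category)
    if (is.na(i)) stop_fmt("unknown category '%s'", category)
    tab$count[i]
  }
  a_in <- get_in(set_a_table); a_tot <- attr(set_a_table, "total")
  b_in <- get_in(set_b_table); b_tot <- attr(set_b_table, "total")
  tab <- matrix(c(a_in, a_tot - a_in, b_in, b_tot - b_in),
                nrow = 2, byrow = TRUE,
                dimnames = list(set = c("A", "B"),
                                category = c("in", "out")))
  cs <- chisq_2x2(tab)
  low <- any(cs$expected < 5)
  if (low)
    warn_fmt("expected count < 5 for category '%s'; exact p supplied", category)
  structure(list(
    category = category, table = tab, chi2 = cs$chi2, p = cs$p,
    direction = if (a_in / a_tot > b_in / b_tot) "over" else "under",
    low_expected = low,
    p_exact = if (low) stats::fisher.test(tab)$p.value else NA_real_
  ), class = "EnrichmentResult")
}

#' Per-chromosome DMP and gene tallies
#'
#' @param dmps DMP table with `probe_id` and `direction`.
#' @param manifest Manifest covering the DMP probes.
#' @return Data frame per chromosome present: `chromosome`, `n_dmps`,
#'   `n_hyper`, `n_hypo`, `n_genes` (distinct mapped gene symbols over
#'   all gene mappings of that chromosome's DMPs).
#' @export
chromosome_tally <- function(dmps, manifest) {
  if (nrow(dmps) == 0)
    return(data.frame(chromosome = character(0), n_dmps = integer(0),
                      n_hyper = integer(0), n_hypo = integer(0),
                      n_genes = integer(0), stringsAsFactors = FALSE))
  chrom <- probe_category(dmps$probe_id, manifest, "chromosome")
  gm <- manifest_gene_map(manifest)
  gm <- gm[gm$probe_id %in% dmps$probe_id, , drop = FALSE]
  gm$chromosome <- chrom[match(gm$probe_id, dmps$probe_id)]
  lev <- CHROMOSOMES[CHROMOSOMES %in% chrom]
  out <- data.frame(
    chromosome = lev,
    n_dmps = as.integer(table(factor(chrom, levels = lev))),
    n_hyper = as.integer(table(factor(chrom[dmps$direction == "hyper"],
                                      levels = lev))),
    n_hypo = as.integer(table(factor(chrom[dmps$direction == "hypo"],
                                     levels = lev))),
    stringsAsFactors = FALSE
  )
  out$n_genes <- vapply(lev, function(ch)
    length(unique(gm$gene[gm$chromosome == ch])), integer(1))
  out
}
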