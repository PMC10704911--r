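#' Read a probe annotation manifest
#'
#' Reads a tab-separated probe manifest into the internal annotation table.
#' Two dialects are accepted: the Illumina-style wide format, where the
#' `gene` and `gene_region` columns hold semicolon-delimited parallel lists
#' (one entry per transcript mapping), and a pre-exploded long format with
#' one `(probe, gene, region)` mapping per row.  Long input is collapsed
#' back to one row per probe; duplicate `(gene, region)` pairs are dropped
#' with order preserved.
#'
#' Required columns: `probe_id`, `chr`, `pos`, `type`, `gene`,
#' `gene_region`, `island_region`, `is_cpg`, `snp`, `cross_reactive`.
#' Positions are 1-based single-base coordinates (Illumina MAPINFO
#' convention).
#'
#' @param path Path to a TSV manifest.
#' @return A `data.frame` of class `methyl_manifest` with columns
#'   `probe_id`, `chromosome`, `position`, `probe_type`, `gene`,
#'   `gene_region` (semicolon lists, empty string for intergenic probes),
#'   `island_region`, `is_cpg`, `is_snp_associated`, `is_cross_reactive`.
#' @seealso [manifest_gene_map()] for the exploded (probe, gene, region)
#'   view, [write_manifest()] for the inverse operation.
#' @export
load_manifest <- function(path) {
  raw <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE, na.strings = NULL)
  required <- c("probe_id", "chr", "pos", "type", "gene", "gene_region",
                "island_region", "is_cpg", "snp", "cross_reactive")
  missing <- setdiff(required, names(raw))
  if (length(missing))
    stop_fmt("manifest is missing required column(s): %s",
             paste(missing, collapse = ", "),
             class = "methylscreen_format_error")

  if (anyDuplicated(raw$probe_id)) {
    # Long dialect: collapse mappings per probe, keeping first-row context.
    raw <- collapse_long_manifest(raw)
  }

  man <- data.frame(
    probe_id = raw$probe_id,
    chromosome = sub("^chr", "", raw$chr),
    position = as.integer(raw$pos),
    probe_type = raw$type,
    gene = raw$gene,
    gene_region = raw$gene_region,
    island_region = normalize_island_region(raw$island_region),
    is_cpg = as_flag(raw$is_cpg),
    is_snp_associated = as_flag(raw$snp),
    is_cross_reactive = as_flag(raw$cross_reactive),
    stringsAsFactors = FALSE
  )
  validate_manifest(man)
}

collapse_long_manifest <- function(raw) {
  idx <- split(seq_len(nrow(raw)), factor(raw$probe_id, levels = unique(raw$probe_id)))
  rows <- lapply(idx, function(i) {
    first <- raw[i[1], , drop = FALSE]
    first$gene <- paste(raw$gene[i], collapse = ";")
    first$gene_region <- paste(raw$gene_region[i], collapse = ";")
    first
  })
  do.call(rbind, rows)
}

validate_manifest <- function(man) {
  if (anyDuplicated(man$probe_id))
    stop_fmt("duplicate probe_id in manifest: %s",
             man$probe_id[duplicated(man$probe_id)][1])
  if (any(is.na(man$position)) || any(man$position < 1))
    stop_fmt("manifest positions must be integers >= 1")
  bad_chr <- setdiff(unique(man$chromosome), CHROMOSOMES)
  if (length(bad_chr))
    stop_fmt("unknown chromosome in manifest: %s", bad_chr[1])
  if (any(is.na(man$island_region)))
    stop_fmt("unparseable island_region for probe %s",
             man$probe_id[is.na(man$island_region)][1])

  # Normalise and validate region tokens; empty gene <=> empty region (IGR).
  norm <- normalize_region_lists(man$probe_id, man$gene, man$gene_region)
  man$gene <- norm$gene
  man$gene_region <- norm$region
  class(man) <- c("methyl_manifest", "data.frame")
  man
}

# Split semicolon lists, normalise tokens, drop duplicate (gene, region)
# pairs preserving order; re-join.  Errors name the offending probe.
normalize_region_lists <- function(probe_id, gene, region) {
  gene_out <- character(length(gene))
  region_out <- character(length(gene))
  for (i in seq_along(gene)) {
    g <- strsplit(gene[i], ";", fixed = TRUE)[[1]]
    r <- strsplit(region[i], ";", fixed = TRUE)[[1]]
    g <- g[nzchar(g)]
    r <- r[nzchar(r)]
    if (length(g) == 0L) {
      if (length(r) != 0L)
        stop_fmt("probe %s has gene regions but no gene symbols", probe_id[i])
      next
    }
    if (length(g) != length(r))
      stop_fmt("probe %s: gene list and region list lengths differ (%d vs %d)",
               probe_id[i], length(g), length(r))
    rn <- normalize_gene_region(r)
    if (any(is.na(rn)))
      stop_fmt("probe %s: unparseable gene region token '%s'",
               probe_id[i], r[which(is.na(rn))[1]])
    keep <- !duplicated(paste(g, rn, sep = "\r"))
    gene_out[i] <- paste(g[keep], collapse = ";")
    region_out[i] <- paste(rn[keep], collapse = ";")
  }
  list(gene = gene_out, region = region_out)
}

#' Exploded (probe, gene, region) mapping table
#'
#' @param manifest A manifest from [load_manifest()].
#' @return A `data.frame` with one row per gene mapping: `probe_id`,
#'   `gene`, `region`.  Intergenic probes contribute no rows.
#' @export
manifest_gene_map <- function(manifest) {
  has <- nzchar(manifest$gene)
  g <- strsplit(manifest$gene[has], ";", fixed = TRUE)
  r <- strsplit(manifest$gene_region[has], ";", fixed = TRUE)
  n <- lengths(g)
  data.frame(
    probe_id = rep(manifest$probe_id[has], n),
    gene = unlist(g, use.names = FALSE),
    region = unlist(r, use.names = FALSE),
    stringsAsFactors = FALSE
  )
}

#' Write a manifest back to TSV
#'
#' Inverse of [load_manifest()]; `load_manifest(write_manifest(m))` is the
#' identity.
#'
#' @param manifest A `methyl_manifest`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  out <- data.frame(
    probe_id = manifest$probe_id,
    chr = manifest$chromosome,
    pos = manifest$position,
    type = manifest$probe_type,
    gene = manifest$gene,
    gene_region = manifest$gene_region,
    island_region = manifest$island_region,
    is_cpg = manifest$is_cpg,
    snp = manifest$is_snp_associated,
    cross_reactive = manifest$is_cross_reactive,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a beta-value matrix container
#'
#' Bundles a probes-by-samples beta matrix with optional aligned
#' detection-P and bead-count matrices.  Beta values are methylated-signal
#' fractions in \[0, 1\]; `NA` is permitted (failed detection).
#'
#' @param beta Numeric matrix with probe rownames and sample colnames.
#' @param detection_p Optional matrix of per-probe, per-sample detection
#'   P-values, same dimnames as `beta`.
#' @param beadcount Optional matrix of non-negative bead counts, same
#'   dimnames as `beta`.
#' @return An object of class `BetaMatrix`: a list with elements `beta`,
#'   `detection_p`, `beadcount`, `probe_ids`, `sample_ids`.
#' @export
beta_matrix <- function(beta, detection_p = NULL, beadcount = NULL) {
  if (is.null(rownames(beta)) || is.null(colnames(beta)))
    stop_fmt("beta matrix must have probe rownames and sample colnames")
  rng <- range(beta, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1) {
    bad <- which(beta < 0 | beta > 1, arr.ind = TRUE)[1, ]
    stop_fmt("beta value out of [0,1] at probe %s, sample %s",
             rownames(beta)[bad[1]], colnames(beta)[bad[2]],
             class = "methylscreen_validation_error")
  }
  for (nm in c("detection_p", "beadcount")) {
    m <- get(nm)
    if (!is.null(m) && !identical(dimnames(m), dimnames(beta)))
      stop_fmt("%s matrix does not share probe/sample ordering with beta", nm)
  }
  structure(list(beta = beta, detection_p = detection_p,
                 beadcount = beadcount,
                 probe_ids = rownames(beta), sample_ids = colnames(beta)),
            class = "BetaMatrix")
}

#' @export
print.BetaMatrix <- function(x, ...) {
  cat(sprintf("BetaMatrix: %d probes x %d samples (detection P: %s, beads: %s)\n",
              nrow(x$beta), ncol(x$beta),
              if (is.null(x$detection_p)) "absent" else "present",
              if (is.null(x$beadcount)) "absent" else "present"))
  invisible(x)
}

#' @export
dim.BetaMatrix <- function(x) dim(x$beta)

#' Subset a BetaMatrix by probe ids
#'
#' @param bm A [beta_matrix()].
#' @param probe_ids Probe ids to keep, in the order given.
#' @return A `BetaMatrix` restricted to `probe_ids` (optional matrices are
#'   subset in lockstep).
#' @export
subset_probes <- function(bm, probe_ids) {
  missing <- setdiff(probe_ids, bm$probe_ids)
  if (length(missing))
    stop_fmt("probe(s) absent from beta matrix: %s", missing[1])
  sub <- function(m) if (is.null(m)) NULL else m[probe_ids, , drop = FALSE]
  beta_matrix(sub(bm$beta), sub(bm$detection_p), sub(bm$beadcount))
}

read_value_matrix <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Load a beta matrix aligned to a manifest
#'
#' Reads a probes-by-samples table (TSV or CSV; first column = probe id),
#' validates values to \[0, 1\], and restricts probes to those present in
#' the manifest, in manifest order.  Probes absent from the manifest are
#' dropped with a message (manifest-version mismatch is common in the
#' wild); out-of-range values are an error naming probe and sample.
#'
#' @param path Beta matrix file.
#' @param manifest A manifest from [load_manifest()].
#' @param detection_p_path,beadcount_path Optional aligned matrices.
#' @return A [beta_matrix()].
#' @export
load_beta_matrix <- function(path, manifest,
                             detection_p_path = NULL, beadcount_path = NULL) {
  m <- read_value_matrix(path)
  unknown <- setdiff(rownames(m), manifest$probe_id)
  if (length(unknown)) {
    message(sprintf("load_beta_matrix: dropping %d probe(s) absent from manifest",
                    length(unknown)))
    m <- m[setdiff(rownames(m), unknown), , drop = FALSE]
  }
  keep <- manifest$probe_id[manifest$probe_id %in% rownames(m)]
  m <- m[keep, , drop = FALSE]
  dp <- if (!is.null(detection_p_path)) read_value_matrix(detection_p_path)[keep, , drop = FALSE]
  bc <- if (!is.null(beadcount_path)) read_value_matrix(beadcount_path)[keep, , drop = FALSE]
  beta_matrix(m, detection_p = dp, beadcount = bc)
}

#' Write a BetaMatrix (and optional companions) to TSV
#'
#' Values are written at full precision (`%.17g`-equivalent via
#' `write.table` default formatting), so a write/read round trip is
#' bit-identical for values produced at fixed decimal precision.
#'
#' @param bm A [beta_matrix()].
#' @param path Output path for the beta matrix.
#' @param detection_p_path,beadcount_path Optional output paths.
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(bm, path,
                              detection_p_path = NULL, beadcount_path = NULL) {
  wr <- function(m, p) {
    df <- data.frame(probe_id = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wr(bm$beta, path)
  if (!is.null(detection_p_path) && !is.null(bm$detection_p))
    wr(bm$detection_p, detection_p_path)
  if (!is.null(beadcount_path) && !is.null(bm$beadcount))
    wr(bm$beadcount, beadcount_path)
  invisible(path)
}

#' Load a sample sheet
#'
#' @param path CSV with at least `sample_id` and `group` columns; optional
#'   `pair_id`, `age`, `sex`, `bmi`, `tsh`, `ft3`, `ft4`, `tpoab`, `tgab`,
#'   `ct_target`, `ct_reference`.
#' @return A validated `data.frame` (group coerced to factor with levels
#'   `control`, `case`).
#' @export
load_sample_sheet <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_sample_sheet(df)
}

validate_sample_sheet <- function(df) {
  for (col in c("sample_id", "group"))
    if (!col %in% names(df))
      stop_fmt("sample sheet is missing required column: %s", col,
               class = "methylscreen_format_error")
  if (!all(df$group %in% c("case", "control")))
    stop_fmt("sample sheet group must be 'case' or 'control'")
  df$group <- factor(df$group, levels = c("control", "case"))
  df
}

#' Export DMPs as a BED6 track
#'
#' Converts 1-based single-base manifest coordinates to BED's 0-based
#' half-open convention (`start = position - 1`, `end = position`).  Score
#' is `round(1000 * |delta_beta|)` capped at 1000; strand is `"."`.
#'
#' @param dmps A DMP table (needs `probe_id` and `delta_beta`).
#' @param manifest Manifest containing every DMP probe.
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
export_dmps_bed <- function(dmps, manifest, path) {
  if (nrow(dmps) == 0) {
    file.create(path)
    return(invisible(path))
  }
  idx <- match(dmps$probe_id, manifest$probe_id)
  if (anyNA(idx))
    stop_fmt("probe %s not present in manifest",
             dmps$probe_id[which(is.na(idx))[1]])
  bed <- data.frame(
    chrom = paste0("chr", manifest$chromosome[idx]),
    start = manifest$position[idx] - 1L,
    end = manifest$position[idx],
    name = dmps$probe_id,
    score = pmin(1000L, as.integer(round(1000 * abs(dmps$delta_beta)))),
    strand = ".",
    stringsAsFactors = FALSE
  )
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
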