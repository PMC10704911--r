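# Internal helpers shared across modules.

logit <- function(p) log(p / (1 - p))
expit <- function(x) 1 / (1 + exp(-x))

#' @noRd
stop_fmt <- function(fmt, ..., class = "methylscreen_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = sprintf(fmt, ...), call = sys.call(-1))))
}

#' @noRd
warn_fmt <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Canonical category orders used by distribution tables and the manifest.
GENE_REGIONS <- c("TSS1500", "TSS200", "5UTR", "1stExon", "Body", "3UTR")
ISLAND_REGIONS <- c("Island", "N_Shore", "S_Shore", "N_Shelf", "S_Shelf", "OpenSea")
PROMOTER_REGIONS <- c("TSS1500", "TSS200", "5UTR", "1stExon")
CHROMOSOMES <- c(as.character(1:22), "X", "Y")

# Normalise region spellings found in the wild ("5'UTR", "1st Exon", ...).
normalize_gene_region <- function(x) {
  x <- gsub("['’ ]", "", x)
  map <- c(
    "TSS1500" = "TSS1500", "TSS200" = "TSS200",
    "5UTR" = "5UTR", "1stExon" = "1stExon", "FirstExon" = "1stExon",
    "Body" = "Body", "body" = "Body", "GeneBody" = "Body",
    "3UTR" = "3UTR"
  )
  out <- unname(map[x])
  out
}

normalize_island_region <- function(x) {
  x0 <- gsub("[ _]", "", tolower(x))
  map <- c(
    "island" = "Island", "cpgisland" = "Island",
    "nshore" = "N_Shore", "northshore" = "N_Shore",
    "sshore" = "S_Shore", "southshore" = "S_Shore",
    "nshelf" = "N_Shelf", "northshelf" = "N_Shelf",
    "sshelf" = "S_Shelf", "southshelf" = "S_Shelf",
    "opensea" = "OpenSea", "none" = "OpenSea"
  )
  out <- unname(map[x0])
  out[x0 == ""] <- "OpenSea"
  out
}

# Fixed-precision rounding through the decimal text representation, so a
# value written to TSV and read back is bit-identical (round() alone can
# land one ulp away from what strtod returns for the printed decimal).
round_via_text <- function(x, digits = 6) {
  out <- as.numeric(formatC(x, digits = digits, format = "f"))
  if (is.matrix(x)) dim(out) <- dim(x)
  out
}

as_flag <- function(x) {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) return(x != 0)
  tolower(as.character(x)) %in% c("true", "t", "1", "yes")
}
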