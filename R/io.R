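# Readers and writers for the plain-text interchange formats.

#' Read protein sequences with optional taxonomy from FASTA
#'
#' Description lines may carry a `taxonomy=kingdom;class` key-value pair,
#' e.g. `>sp123 taxonomy=Metazoa;Arachnida`; missing or partial lineages
#' are returned as `NA` (downstream sampling treats them as `UNKNOWN`).
#'
#' @param path FASTA file of amino-acid sequences.
#' @return named character vector of sequences with a `data.frame`
#'   attribute `"lineage"` (`id`, `kingdom`, `class`).
#' @export
readProteinFasta <- function(path) {
  ss <- readAAStringSet(path)
  full <- names(ss)
  id <- sub("\\s.*$", "", full)
  tax <- rep(NA_character_, length(full))
  hit <- regmatches(full, regexpr("taxonomy=[^ ]+", full))
  has <- grepl("taxonomy=", full)
  tax[has] <- sub("^taxonomy=", "", hit)
  parts <- strsplit(tax, ";", fixed = TRUE)
  out <- setNames(as.character(ss), id)
  .checkAASequence(out, "FASTA sequences")
  attr(out, "lineage") <- data.frame(
    id = id,
    kingdom = vapply(parts, function(p)
      if (length(p) >= 1L) p[1L] else NA_character_, ""),
    class = vapply(parts, function(p)
      if (length(p) >= 2L) p[2L] else NA_character_, ""))
  out
}

#' Write motifs to FASTA
#'
#' Headers carry the provenance of each window as `parent|start-end`
#' (0-based half-open coordinates into the parent protein).
#'
#' @param motifs motif table from [scanCysteineMotifs()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeMotifFasta <- function(motifs, path) {
  ss <- AAStringSet(setNames(
    motifs$sequence,
    paste0(motifs$parent_id, "|", motifs$start, "-", motifs$end)))
  writeXStringSet(ss, path)
  invisible(path)
}

#' Read sort-seq read counts and bin statistics from TSV
#'
#' Expects a long-format read table (`peptide_id`, `bin`, `condition`,
#' `replicate`, `reads`) and a bin-statistics table (`bin`, `condition`,
#' `replicate`, `cell_count`, `median_fluor`); every (condition, replicate,
#' bin) combination in the reads must appear in the bin statistics.
#'
#' @param readsPath,binsPath paths to the two tab-separated files.
#' @return a [SortSeqExperiment-class].
#' @export
readSortSeq <- function(readsPath, binsPath) {
  rd <- read.delim(readsPath, stringsAsFactors = FALSE)
  bs <- read.delim(binsPath, stringsAsFactors = FALSE)
  needR <- c("peptide_id", "bin", "condition", "replicate", "reads")
  needB <- c("bin", "condition", "replicate", "cell_count", "median_fluor")
  if (!all(needR %in% colnames(rd)))
    stop("reads table needs columns: ", paste(needR, collapse = ", "))
  if (!all(needB %in% colnames(bs)))
    stop("bin stats table needs columns: ", paste(needB, collapse = ", "))
  keyR <- paste(rd$condition, rd$replicate, rd$bin, sep = ".")
  keyB <- paste(bs$condition, bs$replicate, bs$bin, sep = ".")
  if (!all(keyR %in% keyB))
    stop("reads reference bins missing from the bin statistics")
  peps <- unique(rd$peptide_id)
  mat <- matrix(0L, length(peps), nrow(bs),
                dimnames = list(peps, NULL))
  mat[cbind(match(rd$peptide_id, peps), match(keyR, keyB))] <-
    as.integer(rd$reads)
  SortSeqExperiment(mat, bs)
}

#' Read an HPLC peak table from TSV
#'
#' @param path tab-separated file with columns `peptide_id`, `condition`
#'   (`native`/`reduced`), `rt`, `area`.
#' @return `data.frame` suitable for [classifyHplc()].
#' @export
readHplcPeaks <- function(path) {
  pk <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("peptide_id", "condition", "rt", "area")
  if (!all(need %in% colnames(pk)))
    stop("HPLC table needs columns: ", paste(need, collapse = ", "))
  pk
}
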