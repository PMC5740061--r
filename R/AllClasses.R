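#' SortSeqExperiment: sorted-bin read counts with bin-level cytometry stats
#'
#' A thin [SummarizedExperiment::SummarizedExperiment] subclass holding one
#' non-negative read-count matrix (`assay(x, "reads")`, peptides x sorted
#' bins) whose columns are sorted fluorescence bins. Each column carries, in
#' `colData`, the bin label, the experimental condition (e.g. `"untreated"`
#' or `"trypsin"`), the replicate index, the number of cells sorted into the
#' bin (`cell_count`) and the bin's median surface-stain fluorescence
#' (`median_fluor`, arbitrary units). One "sample" in the sort-seq sense is
#' the set of columns sharing a `(condition, replicate)` pair; the default
#' bin labels, from dimmest to brightest, are `lowest`, `low`, `high`,
#' `highest`.
#'
#' @slot .. inherited from `SummarizedExperiment`.
#' @seealso [SortSeqExperiment()], [contentScores()], [binStats()]
#' @exportClass SortSeqExperiment
setClass("SortSeqExperiment", contains = "SummarizedExperiment")

.validSortSeq <- function(object) {
  msg <- NULL
  if (!"reads" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'reads' is required")
  else {
    r <- assay(object, "reads")
    if (any(is.na(r)) || any(r < 0))
      msg <- c(msg, "read counts must be non-negative and non-missing")
  }
  cd <- colData(object)
  need <- c("bin", "condition", "replicate", "cell_count", "median_fluor")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    msg <- c(msg, paste0("colData lacks column(s): ",
                         paste(miss, collapse = ", ")))
  if (!length(miss)) {
    if (any(cd$cell_count <= 0))
      msg <- c(msg, "cell_count must be positive for every bin")
    if (any(cd$median_fluor <= 0))
      msg <- c(msg, "median_fluor must be positive for every bin")
    key <- paste(cd$condition, cd$replicate, cd$bin)
    if (anyDuplicated(key))
      msg <- c(msg, "duplicated (condition, replicate, bin) column")
  }
  if (is.null(rownames(object)))
    msg <- c(msg, "peptide ids (rownames) are required")
  if (is.null(msg)) TRUE else msg
}
setValidity("SortSeqExperiment", .validSortSeq)

#' Construct a SortSeqExperiment
#'
#' @param reads integer matrix of read counts, peptides in rows (rownames =
#'   peptide ids), one column per sorted bin.
#' @param binStats `data.frame` with one row per column of `reads`, in the
#'   same order, with columns `bin`, `condition`, `replicate`, `cell_count`,
#'   `median_fluor`.
#' @return A [SortSeqExperiment-class] object.
#' @examples
#' reads <- matrix(c(10L, 0L, 5L, 20L), 1,
#'                 dimnames = list("pep1", NULL))
#' bs <- data.frame(bin = c("lowest", "low", "high", "highest"),
#'                  condition = "untreated", replicate = 1L,
#'                  cell_count = 1e5, median_fluor = c(10, 100, 1000, 5000))
#' sse <- SortSeqExperiment(reads, bs)
#' @export
SortSeqExperiment <- function(reads, binStats) {
  if (!is.matrix(reads))
    reads <- as.matrix(reads)
  binStats <- as.data.frame(binStats)
  if (nrow(binStats) != ncol(reads))
    stop("binStats must have one row per column of 'reads'")
  colnames(reads) <- paste(binStats$condition, binStats$replicate,
                           binStats$bin, sep = ".")
  se <- SummarizedExperiment(assays = list(reads = reads),
                             colData = DataFrame(binStats))
  new("SortSeqExperiment", se)
}

#' @describeIn SortSeqExperiment bin-level statistics (one row per sorted
#'   bin): bin label, condition, replicate, sorted cell count and median
#'   fluorescence.
#' @param x a `SortSeqExperiment`.
#' @export
binStats <- function(x) {
  stopifnot(is(x, "SortSeqExperiment"))
  colData(x)[, c("bin", "condition", "replicate",
                 "cell_count", "median_fluor")]
}

setMethod("show", "SortSeqExperiment", function(object) {
  cd <- colData(object)
  callNextMethod()
  cat("samples:",
      paste(unique(paste0(cd$condition, "/rep", cd$replicate)),
            collapse = ", "), "\n")
})

#' EnrichmentMatrix: position x substitution SSM log2 enrichment scores
#'
#' Holds the wild-type-normalised log2 enrichment score of every tracked
#' single-residue substitution from a site-saturation mutagenesis (SSM)
#' selection. Rows are 1-based positions along the wild-type peptide
#' (numbering starts after the N-terminal expression-tag `GS`), columns the
#' 19 non-cysteine amino acids. Cells where the substitution equals the
#' wild-type residue are fixed at 0 by the normalisation; substitutions
#' absent from the count table are `NA`.
#'
#' @slot scores numeric matrix, positions x substitutions.
#' @slot wtSequence the wild-type amino-acid sequence.
#' @slot variants `DataFrame` of per-variant counts and scores.
#' @seealso [enrichmentScores()], [positionAverage()], [substitutionMatrix()]
#' @exportClass EnrichmentMatrix
setClass("EnrichmentMatrix",
         representation(scores = "matrix",
                        wtSequence = "character",
                        variants = "DataFrame"))

setValidity("EnrichmentMatrix", function(object) {
  msg <- NULL
  L <- nchar(object@wtSequence)
  if (nrow(object@scores) != L)
    msg <- c(msg, "one score row per wild-type position is required")
  wt <- strsplit(object@wtSequence, "")[[1]]
  for (i in seq_len(L)) {
    if (wt[i] %in% colnames(object@scores)) {
      v <- object@scores[i, wt[i]]
      if (!is.na(v) && v != 0)
        msg <- c(msg, "wild-type identity cells must be 0")
    }
  }
  if (is.null(msg)) TRUE else msg
})

#' @describeIn EnrichmentMatrix the score matrix (positions x substitutions).
#' @param x an `EnrichmentMatrix`.
#' @export
enrichmentMatrix <- function(x) {
  stopifnot(is(x, "EnrichmentMatrix"))
  x@scores
}

#' @describeIn EnrichmentMatrix the wild-type sequence.
#' @export
wtSequence <- function(x) {
  stopifnot(is(x, "EnrichmentMatrix"))
  x@wtSequence
}

#' @describeIn EnrichmentMatrix per-variant table (id, position, wild-type
#'   and substituted residue, per-round counts, score).
#' @export
variantTable <- function(x) {
  stopifnot(is(x, "EnrichmentMatrix"))
  x@variants
}

setMethod("show", "EnrichmentMatrix", function(object) {
  cat("EnrichmentMatrix:", nchar(object@wtSequence), "positions,",
      ncol(object@scores), "substitutions,",
      sum(!is.na(object@scores)), "defined cells\n")
  cat("wild type:", object@wtSequence, "\n")
})

#' ConcordanceResult: permutation test of surface vs solution folding
#'
#' Result of [concordanceTest()]: the observed concordance statistic between
#' the binary surface-folding call (high content / trypsin resistant or not)
#' and the binary HPLC call (1-2 peaks or not), with a permutation p-value
#' obtained by uniformly shuffling the HPLC label vector.
#'
#' @slot statistic observed concordance statistic, in `[0, 1]` for the
#'   matched-fraction statistic.
#' @slot pValue permutation p-value, `(k + 1) / (nPerm + 1)` form.
#' @slot nPerm number of permutations.
#' @slot statName which statistic was used (`"fraction"` or `"mcc"`).
#' @slot n number of peptide pairs used (after dropping missing labels).
#' @slot seed RNG seed used, or `NA`.
#' @exportClass ConcordanceResult
setClass("ConcordanceResult",
         representation(statistic = "numeric", pValue = "numeric",
                        nPerm = "numeric", statName = "character",
                        n = "integer", seed = "numeric"))

setMethod("show", "ConcordanceResult", function(object) {
  cat(sprintf(
    "Concordance permutation test (%s statistic)\n  n = %d pairs, observed = %.4f, p = %.3g (%g permutations)\n",
    object@statName, object@n, object@statistic, object@pValue,
    object@nPerm))
})

#' GseaResult: unweighted gene-set enrichment of a ranked peptide list
#'
#' Result of [gseaUnweighted()]: the signed maximum deviation of the
#' Kolmogorov-Smirnov-style running sum (steps of `+1/G` at set members and
#' `-1/(N-G)` elsewhere), a two-sided permutation p-value from random
#' same-size sets, and the leading-edge members.
#'
#' @slot es enrichment score in `[-1, 1]`.
#' @slot pValue permutation p-value (two-sided on `|ES|`).
#' @slot nPerm number of random-set permutations.
#' @slot leadingEdge ids of set members at or before the running-sum
#'   extremum.
#' @slot setSize,listLength sizes of the set and the ranked list.
#' @slot seed RNG seed used, or `NA`.
#' @exportClass GseaResult
setClass("GseaResult",
         representation(es = "numeric", pValue = "numeric",
                        nPerm = "numeric", leadingEdge = "character",
                        setSize = "integer", listLength = "integer",
                        seed = "numeric"))

setMethod("show", "GseaResult", function(object) {
  cat(sprintf(
    "Unweighted GSEA: ES = %.4f (set %d of %d), p = %.3g (%g permutations), leading edge %d members\n",
    object@es, object@setSize, object@listLength, object@pValue,
    object@nPerm, length(object@leadingEdge)))
})

#' @describeIn ConcordanceResult the permutation p-value.
#' @param x a result object.
#' @export
pValue <- function(x) {
  stopifnot(is(x, "ConcordanceResult") || is(x, "GseaResult"))
  x@pValue
}

#' @describeIn GseaResult the enrichment score.
#' @param x a `GseaResult`.
#' @export
esScore <- function(x) {
  stopifnot(is(x, "GseaResult"))
  x@es
}

#' @describeIn GseaResult leading-edge member ids.
#' @export
leadingEdge <- function(x) {
  stopifnot(is(x, "GseaResult"))
  x@leadingEdge
}

#' @describeIn ConcordanceResult the observed statistic.
#' @export
statValue <- function(x) {
  stopifnot(is(x, "ConcordanceResult") || is(x, "GseaResult"))
  if (is(x, "GseaResult")) x@es else x@statistic
}
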