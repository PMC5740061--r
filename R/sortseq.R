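# Sort-seq quantitation: surface protein-content scores, trypsin
# resistance, QC, replicate concordance, signal:noise.

.selectSample <- function(x, condition, replicate) {
  cd <- colData(x)
  sel <- which(cd$condition == condition & cd$replicate == replicate)
  if (!length(sel))
    stop("no bins for condition '", condition, "', replicate ", replicate)
  sel[order(cd$median_fluor[sel])]
}

#' Estimated cells per peptide and bin
#'
#' Distributes each bin's sorted-cell count over peptides in proportion to
#' their read fractions in that bin: `c[i, b] = C_b * r[i, b] / sum_j r[j, b]`.
#' Bins with zero total reads contribute zero estimated cells. For every bin
#' with non-zero reads the estimated cells sum exactly to the bin's sorted
#' cell count (conservation).
#'
#' @param x a [SortSeqExperiment-class].
#' @param condition,replicate which sort-seq sample to use.
#' @return Numeric matrix, peptides x bins (columns ordered by increasing
#'   median fluorescence).
#' @export
estimatedCells <- function(x, condition = "untreated", replicate = 1L) {
  stopifnot(is(x, "SortSeqExperiment"))
  sel <- .selectSample(x, condition, replicate)
  r <- assay(x, "reads")[, sel, drop = FALSE]
  C <- colData(x)$cell_count[sel]
  tot <- colSums(r)
  f <- sweep(r, 2L, ifelse(tot > 0, tot, 1), "/")
  f[, tot == 0] <- 0
  sweep(f, 2L, C, "*")
}

#' Surface protein-content scores from sorted-bin read counts
#'
#' Reconstructs, for each peptide, a unitless estimate of the average
#' surface-stain fluorescence of a cell expressing it. Within each sorted
#' bin the peptide's read fraction is converted into an estimated cell count
#' (see [estimatedCells()]); the score is then the cell-weighted mean of the
#' bins' median fluorescences:
#' `S_i = sum_b c[i,b] * M_b / sum_b c[i,b]`.
#'
#' A well-expressed peptide distributes its cells into the brighter bins and
#' scores near the top bin's median; a poorly expressed one concentrates in
#' the dimmest bin. Every defined score lies between the smallest and
#' largest bin median. Peptides with no reads in the sample are flagged
#' undefined (`S = NA`), never silently zero.
#'
#' With `logDomain = TRUE` the weighted mean is taken over `log10(M_b)` and
#' `10^mean` is returned, for the case where bin medians are best averaged
#' on the log axis.
#'
#' @param x a [SortSeqExperiment-class].
#' @param condition,replicate which sort-seq sample to score.
#' @param logDomain average bin medians in log10 space.
#' @return A [S4Vectors::DataFrame] keyed by peptide id with columns `S`,
#'   `total_reads` and `defined`; `metadata()` records the sample, the
#'   bin-median range and the weighting domain.
#' @examples
#' reads <- matrix(c(0L, 0L, 0L, 50L,   10L, 10L, 10L, 10L), 2, byrow = TRUE,
#'                 dimnames = list(c("bright", "flat"), NULL))
#' bs <- data.frame(bin = c("lowest", "low", "high", "highest"),
#'                  condition = "untreated", replicate = 1L,
#'                  cell_count = 1000, median_fluor = c(10, 100, 1000, 5000))
#' contentScores(SortSeqExperiment(reads, bs))
#' @export
contentScores <- function(x, condition = "untreated", replicate = 1L,
                          logDomain = FALSE) {
  stopifnot(is(x, "SortSeqExperiment"))
  sel <- .selectSample(x, condition, replicate)
  M <- colData(x)$median_fluor[sel]
  cells <- estimatedCells(x, condition, replicate)
  denom <- rowSums(cells)
  S <- if (logDomain)
    10^(as.vector(cells %*% log10(M)) / denom)
  else
    as.vector(cells %*% M) / denom
  S[denom == 0] <- NA_real_
  out <- DataFrame(S = S,
                   total_reads = rowSums(assay(x, "reads")[, sel,
                                                           drop = FALSE]),
                   defined = denom > 0,
                   row.names = rownames(x))
  metadata(out) <- list(condition = condition, replicate = replicate,
                        fluor_range = range(M), log_domain = logDomain)
  out
}

#' Trypsin-resistance score
#'
#' Expresses the trypsin-treated surface protein content as a percentage of
#' the untreated content: `T_i = 100 * S_treated / S_untreated`. Values
#' above 100 are permitted (and flagged `super_resistant`); the score is
#' undefined -- an explicit `NA` flag, not zero -- whenever either content
#' score is undefined or the untreated score falls below `floor`, the
#' guard against division by near-noise denominators.
#'
#' @param treated,untreated content-score tables from [contentScores()]
#'   (aligned by peptide id), or plain numeric vectors.
#' @param floor minimum untreated score for a defined ratio. Defaults to 1 %
#'   of the smallest bin median recorded with the untreated scores.
#' @return [S4Vectors::DataFrame] with `T` (percent), `defined` and
#'   `super_resistant`.
#' @export
trypsinResistance <- function(treated, untreated, floor = NULL) {
  if (is.null(floor)) {
    fr <- tryCatch(metadata(untreated)$fluor_range, error = function(e) NULL)
    if (is.null(fr))
      stop("floor must be given when 'untreated' carries no bin-median range")
    floor <- 0.01 * fr[1L]
  }
  stopifnot(floor > 0)
  st <- .scoreVector(treated, "treated")
  su <- .scoreVector(untreated, "untreated")
  if (!is.null(names(st)) && !is.null(names(su))) {
    if (!setequal(names(st), names(su)))
      stop("treated and untreated cover different peptides")
    st <- st[names(su)]
  } else if (length(st) != length(su))
    stop("treated and untreated have different lengths")
  Tpct <- 100 * st / su
  Tpct[is.na(st) | is.na(su) | su < floor] <- NA_real_
  DataFrame(T = Tpct, defined = !is.na(Tpct),
            super_resistant = !is.na(Tpct) & Tpct > 100,
            row.names = names(su))
}

#' Read-abundance quality control
#'
#' A peptide passes a sort-seq sample when its summed reads across that
#' sample's bins reach `perSampleMin`; it passes overall when it passes
#' every sample *and* its summed reads over the input condition reach
#' `minInputReads`. Thresholds of zero pass everything.
#'
#' @param x a [SortSeqExperiment-class] containing all samples to screen.
#' @param perSampleMin minimum summed reads per (condition, replicate)
#'   sample.
#' @param minInputReads minimum summed reads over `inputCondition` samples.
#' @param inputCondition condition whose reads count toward
#'   `minInputReads`.
#' @return [S4Vectors::DataFrame] with one pass flag per sample, the summed
#'   input reads and the overall `pass`; `metadata()` records the thresholds
#'   and the number of passing peptides.
#' @export
qcFilter <- function(x, perSampleMin = 20L, minInputReads = 50L,
                     inputCondition = "untreated") {
  stopifnot(is(x, "SortSeqExperiment"),
            perSampleMin >= 0, minInputReads >= 0)
  cd <- colData(x)
  key <- paste0(cd$condition, "_rep", cd$replicate)
  samples <- unique(key)
  r <- assay(x, "reads")
  sums <- vapply(samples, function(k)
    rowSums(r[, key == k, drop = FALSE]), numeric(nrow(r)))
  passMat <- sums >= perSampleMin
  colnames(passMat) <- paste0("pass_", samples)
  inputReads <- rowSums(
    sums[, unique(key[cd$condition == inputCondition]), drop = FALSE])
  pass <- rowSums(!passMat) == 0L & inputReads >= minInputReads
  out <- DataFrame(passMat, input_reads = inputReads, pass = pass,
                   row.names = rownames(x))
  metadata(out) <- list(per_sample_min = perSampleMin,
                        min_input_reads = minInputReads,
                        input_condition = inputCondition,
                        n_pass = sum(pass))
  out
}

#' Replicate averaging and concordance
#'
#' Averages two independent replicate score vectors and reports their
#' squared Pearson correlation (R^2) over peptides defined in both. In the
#' linear domain the average is the arithmetic mean of the defined replicate
#' values (a peptide defined in only one replicate keeps that value); with
#' `logDomain = TRUE` averaging and correlation are done on `log10` scores
#' and the geometric mean is returned.
#'
#' @param a,b replicate scores ([contentScores()] tables or numeric
#'   vectors, aligned by name or position).
#' @param logDomain work in log10 space (scores must be positive).
#' @return list with `average` (named numeric), `r2` and `n_common`.
#' @export
replicateStats <- function(a, b, logDomain = FALSE) {
  va <- .scoreVector(a, "a"); vb <- .scoreVector(b, "b")
  if (!is.null(names(va)) && !is.null(names(vb)))
    vb <- vb[names(va)]
  if (length(va) != length(vb))
    stop("replicates cover different peptides")
  both <- !is.na(va) & !is.na(vb)
  if (sum(both) < 2L)
    stop("fewer than 2 peptides defined in both replicates")
  if (logDomain) {
    if (any(va[both] <= 0) || any(vb[both] <= 0))
      stop("log-domain statistics require positive scores")
    r2 <- cor(log10(va[both]), log10(vb[both]))^2
    avg <- 10^rowMeans(cbind(log10(va), log10(vb)), na.rm = TRUE)
  } else {
    r2 <- cor(va[both], vb[both])^2
    avg <- rowMeans(cbind(va, vb), na.rm = TRUE)
  }
  avg[is.nan(avg)] <- NA_real_
  names(avg) <- names(va)
  list(average = avg, r2 = r2, n_common = sum(both))
}

#' Signal-to-noise ratio of two fluorescence populations
#'
#' Ratio of the median fluorescence of a positive (e.g. transfected, signal)
#' population to that of a negative (untransfected, noise) population.
#'
#' @param positive,negative numeric fluorescence samples.
#' @return `median(positive) / median(negative)`.
#' @export
signalToNoise <- function(positive, negative) {
  if (!length(positive) || !length(negative))
    stop("both populations must be non-empty")
  mn <- median(negative)
  if (!is.finite(mn) || mn <= 0)
    stop("noise median must be positive")
  median(positive) / mn
}
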