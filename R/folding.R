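# Folding classification and statistics: HC/TR boundary, HPLC peak
# classes, permutation concordance, 2x2 chi-square, bin enrichment,
# unweighted GSEA.

#' Classify surface folding by a line in score space
#'
#' Splits peptides into "high content and/or trypsin resistant" (`HC_TR`)
#' versus "low content and/or trypsin sensitive" (`LC_TS`) with a straight
#' line `y = slope * x + intercept` in `(x = log10 S_untreated, y = T)`
#' space, where `S` is the untreated content score and `T` the trypsin
#' resistance percentage. The cutoff is a tunable convention, not a fitted
#' quantity; points exactly on the line are called `HC_TR`. Peptides with an
#' undefined score on either axis are left unclassified (`NA`).
#'
#' @param S untreated content scores (vector or [contentScores()] table);
#'   must be positive where defined.
#' @param T trypsin-resistance percentages (vector or
#'   [trypsinResistance()] table).
#' @param slope,intercept boundary parameters (finite).
#' @param hcAbove if `TRUE` (default) the `HC_TR` side is where
#'   `T - (slope * log10(S) + intercept) >= 0`; set `FALSE` to flip the
#'   orientation (ties remain `HC_TR`).
#' @return factor with levels `HC_TR`, `LC_TS`, named by peptide when names
#'   are available.
#' @examples
#' classifySurface(1e4, 100, slope = -50, intercept = 150)  # HC_TR
#' @export
classifySurface <- function(S, T, slope, intercept, hcAbove = TRUE) {
  if (!is.finite(slope) || !is.finite(intercept))
    stop("boundary parameters must be finite")
  s <- .scoreVector(S, "S")
  if (is(T, "DataFrame") || is.data.frame(T)) {
    tt <- setNames(as.numeric(T[["T"]]), rownames(T))
  } else tt <- T
  if (length(s) != length(tt))
    stop("S and T have different lengths")
  s[!is.na(s) & s <= 0] <- NA_real_
  resid <- tt - (slope * log10(s) + intercept)
  hc <- if (hcAbove) resid >= 0 else resid <= 0
  out <- factor(ifelse(hc, "HC_TR", "LC_TS"), levels = c("HC_TR", "LC_TS"))
  names(out) <- names(s)
  out
}

#' Fit a surface-class boundary to a reference classification
#'
#' Given a reference binary classification (for example the deposited
#' HC/TR column of a published per-peptide table), recovers boundary
#' parameters by logistic regression of the reference labels on
#' `(log10 S, T)` and converting the decision surface
#' `b0 + b1 * log10(S) + b2 * T = 0` into `slope = -b1/b2`,
#' `intercept = -b0/b2`.
#'
#' @param S,T as in [classifySurface()].
#' @param reference logical (or `HC_TR`/`LC_TS` factor) reference labels.
#' @return list with `slope` and `intercept`.
#' @export
calibrateBoundary <- function(S, T, reference) {
  s <- .scoreVector(S, "S")
  if (is.factor(reference) || is.character(reference))
    reference <- reference == "HC_TR"
  ok <- !is.na(s) & s > 0 & !is.na(T) & !is.na(reference)
  if (sum(ok) < 3L)
    stop("too few classified peptides to calibrate")
  fit <- suppressWarnings(
    glm(reference[ok] ~ log10(s[ok]) + T[ok], family = binomial()))
  b <- coef(fit)
  if (!is.finite(b[3L]) || b[3L] == 0)
    stop("reference labels carry no usable T-axis information")
  list(slope = unname(-b[2L] / b[3L]), intercept = unname(-b[1L] / b[3L]))
}

#' Classify HPLC peak profiles
#'
#' Assigns each peptide one of three reversed-phase HPLC folding classes
#' from its peak tables under native and reduced conditions:
#'
#' * `PEAKS_0` -- the peptide failed to secrete: total native peak area
#'   below `detectionFloor` (or no native peaks at all).
#' * `PEAKS_1_2` -- well folded: in *both* conditions the largest peak
#'   holds at least `dominantFrac` of the condition's total area and at
#'   most one other peak reaches `minorFrac` of the total (one dominant
#'   peak with 0 or 1 minor peaks).
#' * `PEAKS_3PLUS` -- everything else.
#'
#' Classification is invariant to uniform rescaling of all areas.
#'
#' @param peaks `data.frame` with columns `peptide_id`,
#'   `condition` (`"native"` or `"reduced"`), `rt` (retention time, unused
#'   by the rule but kept for provenance) and `area` (non-negative).
#' @param dominantFrac minimum fraction of total area for the dominant
#'   peak; must exceed `minorFrac`.
#' @param minorFrac minimum fraction of total area for a peak to count at
#'   all.
#' @param detectionFloor minimum total native area treated as secreted (in
#'   area units; 0 means only an empty/zero native table gives `PEAKS_0`).
#' @return factor (levels `PEAKS_1_2`, `PEAKS_3PLUS`, `PEAKS_0`) named by
#'   peptide id.
#' @export
classifyHplc <- function(peaks, dominantFrac = 0.5, minorFrac = 0.05,
                         detectionFloor = 0) {
  need <- c("peptide_id", "condition", "area")
  if (!all(need %in% colnames(peaks)))
    stop("peaks table needs columns: ", paste(need, collapse = ", "))
  if (any(peaks$area < 0))
    stop("peak areas must be non-negative")
  if (dominantFrac <= 0 || dominantFrac > 1 || minorFrac <= 0 ||
      minorFrac > 1 || dominantFrac <= minorFrac)
    stop("need 0 < minorFrac < dominantFrac <= 1")
  one <- function(d, id) {
    nat <- d$area[d$condition == "native"]
    if (!length(nat) || sum(nat) == 0 || sum(nat) < detectionFloor)
      return("PEAKS_0")
    red <- d$area[d$condition == "reduced"]
    if (!length(red))
      stop("peptide ", id, " is secreted but lacks a reduced-condition run")
    clean <- function(a) {
      tot <- sum(a)
      counted <- sum(a >= minorFrac * tot)
      max(a) >= dominantFrac * tot && counted <= 2L
    }
    if (clean(nat) && clean(red)) "PEAKS_1_2" else "PEAKS_3PLUS"
  }
  ids <- unique(peaks$peptide_id)
  cls <- vapply(ids, function(id)
    one(peaks[peaks$peptide_id == id, , drop = FALSE], id), "")
  factor(setNames(cls, ids),
         levels = c("PEAKS_1_2", "PEAKS_3PLUS", "PEAKS_0"))
}

.concStat <- function(k, a, b, n, statName) {
  # k = overlap of ones after shuffling; contingency: tp=k, fp=a-k,
  # fn=b-k, tn=n-a-b+k
  if (statName == "fraction")
    return((n - a - b + 2 * k) / n)
  tp <- k; fp <- a - k; fn <- b - k; tn <- n - a - b + k
  den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  out <- (tp * tn - fp * fn) / den
  out[!is.finite(out)] <- 0
  out
}

#' Permutation test of surface/solution folding concordance
#'
#' Tests whether the binary surface-folding call (HC/TR vs LC/TS) and the
#' binary HPLC call (1-2 peaks vs not) agree more often than chance. The
#' observed statistic is, by default, the fraction of peptides whose two
#' calls match; the null distribution is generated by uniformly shuffling
#' the HPLC label vector against the fixed surface labels, and
#' `p = (1 + #\{permuted >= observed\}) / (1 + nPerm)`.
#'
#' Shuffling a binary vector only changes the overlap between the two
#' label sets, which under a uniform shuffle is hypergeometric; each
#' permutation is therefore drawn as `rhyper()` and the statistic computed
#' from the implied 2x2 table -- exactly equivalent to shuffling the vector
#' itself, at O(1) cost per permutation.
#'
#' @param surface logical vector (or `classifySurface()` factor): `TRUE` /
#'   `HC_TR` = well folded on the surface. `NA` pairs are dropped.
#' @param hplc logical vector (or `classifyHplc()` factor): `TRUE` /
#'   `PEAKS_1_2` = well folded in solution.
#' @param nPerm number of shuffles; the default `1e6` makes `1e-6` the
#'   smallest attainable p-value.
#' @param seed RNG seed (`NULL` = ambient stream).
#' @param statistic `"fraction"` (matched fraction, default) or `"mcc"`
#'   (Matthews correlation); the permutation scheme is statistic-agnostic.
#' @return A [ConcordanceResult-class].
#' @export
concordanceTest <- function(surface, hplc, nPerm = 1e6, seed = NULL,
                            statistic = c("fraction", "mcc")) {
  statistic <- match.arg(statistic)
  if (is.factor(surface) || is.character(surface))
    surface <- surface == "HC_TR"
  if (is.factor(hplc) || is.character(hplc))
    hplc <- hplc == "PEAKS_1_2"
  if (length(surface) != length(hplc))
    stop("label vectors differ in length")
  ok <- !is.na(surface) & !is.na(hplc)
  x <- surface[ok]; y <- hplc[ok]
  n <- length(x)
  if (n < 2L)
    stop("fewer than 2 labelled pairs")
  if (nPerm < 1)
    stop("nPerm must be at least 1")
  a <- sum(x); b <- sum(y)
  obs <- .concStat(sum(x & y), a, b, n, statistic)
  oneClass <- b == 0L || b == n
  p <- .withSeed(seed, {
    k <- rhyper(nPerm, b, n - b, a)
    perm <- .concStat(k, a, b, n, statistic)
    (1 + sum(perm >= obs - 1e-12)) / (1 + nPerm)
  })
  if (oneClass) {
    warning("HPLC labels are one-class; every permutation ties (p = 1)")
    p <- 1
  }
  new("ConcordanceResult", statistic = obs, pValue = p, nPerm = nPerm,
      statName = statistic, n = n,
      seed = if (is.null(seed)) NA_real_ else as.numeric(seed))
}

#' Two-tailed chi-square test on a 2x2 table
#'
#' Pearson chi-square with one degree of freedom, as used for 2x2
#' cross-tabulations of folding classes against peptide features
#' (glycosite presence, context category pairs, ...). The continuity
#' correction is off by default.
#'
#' @param table 2x2 matrix of non-negative counts with positive margins.
#' @param yates apply the Yates continuity correction.
#' @return list with `statistic`, `p` and `yates`.
#' @examples
#' chiSquare2x2(matrix(c(20, 10, 10, 20), 2))  # 6.667, p ~ 0.0098
#' @export
chiSquare2x2 <- function(table, yates = FALSE) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L)))
    stop("a 2x2 table is required")
  if (any(table < 0) || any(is.na(table)))
    stop("counts must be non-negative")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("all margins must be positive")
  ht <- suppressWarnings(chisq.test(table, correct = yates))
  list(statistic = unname(ht$statistic), p = unname(ht$p.value),
       yates = yates)
}

#' Rank peptides by enrichment of a sorted bin over the input
#'
#' Log2 ratio of pseudocounted read frequencies in one sorted bin versus
#' the input pool:
#' `log2(((r_bin + pc) / (N_bin + pc * P)) / ((r_in + pc) / (N_in + pc * P)))`
#' with `P` the number of peptides. Peptides are ranked by decreasing
#' enrichment; ties break by peptide id.
#'
#' @param readsBin,readsInput named read-count vectors over the same
#'   peptide universe.
#' @param pseudocount positive pseudocount per peptide.
#' @return `data.frame` with `peptide_id`, `log2_enrichment` and `rank`,
#'   ordered by rank.
#' @export
binEnrichmentRanks <- function(readsBin, readsInput, pseudocount = 0.5) {
  if (!length(readsBin) || !length(readsInput))
    stop("empty read table")
  if (pseudocount <= 0)
    stop("pseudocount must be positive")
  if (is.null(names(readsBin)) || is.null(names(readsInput)) ||
      !setequal(names(readsBin), names(readsInput)))
    stop("bin and input tables must be named over the same peptides")
  readsInput <- readsInput[names(readsBin)]
  P <- length(readsBin)
  e <- log2(((readsBin + pseudocount) /
               (sum(readsBin) + pseudocount * P)) /
              ((readsInput + pseudocount) /
                 (sum(readsInput) + pseudocount * P)))
  ord <- order(-e, names(readsBin))
  data.frame(peptide_id = names(readsBin)[ord],
             log2_enrichment = unname(e[ord]),
             rank = seq_len(P))
}

# signed maximum running-sum deviation from the sorted positions of the
# set members; O(G) per evaluation.
.esFromPositions <- function(pos, N, G) {
  j <- seq_len(G)
  up <- j / G - (pos - j) / (N - G)        # value just after member j
  down <- (j - 1) / G - (pos - j) / (N - G) # value just before member j
  mx <- max(up); mn <- min(c(down, 0))
  if (mx >= -mn) mx else mn
}

#' Unweighted gene-set enrichment analysis over a ranked list
#'
#' Classic Kolmogorov-Smirnov-style running sum: walking down the ranked
#' list, add `1/G` at each set member and subtract `1/(N-G)` elsewhere
#' (`G` = set size, `N` = list length). The enrichment score is the signed
#' maximum-magnitude deviation, so a set occupying the top `G` ranks scores
#' exactly +1 and the bottom `G` ranks exactly -1. Significance is assessed
#' two-sided on `|ES|` against `nPerm` uniformly random same-size sets,
#' `(k + 1) / (nPerm + 1)` form. The leading edge is the set members at or
#' before the running-sum extremum.
#'
#' @param rankedIds ranked identifiers, most enriched first (unique).
#' @param geneSet non-empty strict subset of `rankedIds`.
#' @param nPerm number of random-set permutations.
#' @param seed RNG seed (`NULL` = ambient stream).
#' @return A [GseaResult-class].
#' @export
gseaUnweighted <- function(rankedIds, geneSet, nPerm = 1000L, seed = NULL) {
  if (anyDuplicated(rankedIds))
    stop("ranked ids must be unique")
  geneSet <- unique(geneSet)
  N <- length(rankedIds); G <- length(geneSet)
  if (G == 0L)
    stop("gene set is empty")
  if (!all(geneSet %in% rankedIds))
    stop("gene set is not a subset of the ranked list")
  if (G >= N)
    stop("gene set must be a strict subset of the ranked list")
  member <- rankedIds %in% geneSet
  run <- cumsum(ifelse(member, 1 / G, -1 / (N - G)))
  i_max <- which.max(run); i_min <- which.min(run)
  es <- if (run[i_max] >= -run[i_min]) run[i_max] else run[i_min]
  extremum <- if (es >= 0) i_max else i_min
  leading <- rankedIds[member & seq_len(N) <= extremum]
  p <- .withSeed(seed, {
    absPerm <- vapply(seq_len(nPerm), function(i)
      abs(.esFromPositions(sort.int(sample.int(N, G)), N, G)), 0)
    (1 + sum(absPerm >= abs(es) - 1e-12)) / (1 + nPerm)
  })
  new("GseaResult", es = es, pValue = p, nPerm = as.numeric(nPerm),
      leadingEdge = leading, setSize = G, listLength = N,
      seed = if (is.null(seed)) NA_real_ else as.numeric(seed))
}
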