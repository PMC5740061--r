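# Site-saturation mutagenesis: variant construction, exact-match counting,
# wild-type-normalised log2 enrichment.

#' Enumerate a site-saturation mutagenesis library
#'
#' Builds every single-residue substitution of the wild-type peptide,
#' excluding substitutions *to* any residue in `excluded` (cysteine by
#' default -- disulfide topology must not gain cysteines; wild-type
#' cysteine positions are still mutagenised to the other 19 residues).
#' Positions are 1-based along the peptide, whose numbering starts after
#' the N-terminal expression-tag `GS` left by tag cleavage.
#'
#' @param wtSequence wild-type amino-acid sequence.
#' @param excluded residues never introduced (default `"C"`).
#' @return `data.frame` with `variant_id` (e.g. `"G15Q"`), `position`,
#'   `wt_aa`, `mut_aa` and the full variant `sequence`, ordered by position
#'   then alphabetical substitution. Each variant differs from the wild
#'   type at exactly one site.
#' @examples
#' nrow(buildSsmLibrary("ACD"))  # 18 + 19 + 18 = 55
#' @export
buildSsmLibrary <- function(wtSequence, excluded = "C") {
  stopifnot(length(wtSequence) == 1L)
  .checkAASequence(wtSequence, "wtSequence")
  wt <- strsplit(wtSequence, "")[[1]]
  allowed <- setdiff(AA20, excluded)
  rows <- lapply(seq_along(wt), function(i) {
    muts <- sort(setdiff(allowed, wt[i]))
    if (!length(muts))
      return(NULL)
    seqs <- vapply(muts, function(m) {
      s <- wt; s[i] <- m; paste(s, collapse = "")
    }, "")
    data.frame(variant_id = paste0(wt[i], i, muts), position = i,
               wt_aa = wt[i], mut_aa = muts, sequence = seqs)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Count reads by exact sequence identity
#'
#' Maps each read to a reference variant only on full-length exact match;
#' anything else -- even a single mismatch -- is tallied as unassigned.
#' Exact matching is the appropriate mapping rule for SSM pools, whose
#' members differ by a single residue and would cross-map under tolerant
#' alignment.
#'
#' @param reads character vector of read sequences.
#' @param references named character vector, variant id -> reference
#'   sequence; sequences must be unique.
#' @return list with `counts` (named integer per reference id),
#'   `unassigned` and `total`; `counts` sums with `unassigned` to `total`.
#' @export
countExactMatches <- function(reads, references) {
  if (is.null(names(references)))
    stop("references must be named by variant id")
  if (anyDuplicated(references))
    stop("duplicate reference sequences: exact-match counts would be ambiguous")
  if (anyDuplicated(names(references)))
    stop("duplicate reference ids")
  m <- match(reads, references)
  counts <- tabulate(m, nbins = length(references))
  names(counts) <- names(references)
  list(counts = counts, unassigned = sum(is.na(m)),
       total = length(reads))
}

#' Wild-type-normalised log2 enrichment scores
#'
#' For each tracked sequence `v` with input and post-selection counts, the
#' score is the log2 fold-change of its pseudocounted frequency across the
#' selection, normalised to the wild type:
#' \deqn{E_v = \log_2\frac{(n_{v,R2}+pc)/(N_{R2}+pc V)}{(n_{v,in}+pc)/(N_{in}+pc V)} - [\mathrm{same~for~wt}]}
#' with `V` the number of tracked sequences (variants plus wild type).
#' The wild type therefore scores exactly 0, enriched variants are
#' positive, depleted ones negative. Frequencies span input to
#' after-the-final-round as a single ratio; intermediate rounds are not
#' chained.
#'
#' @param counts `data.frame` with columns `variant_id`, `n_input`,
#'   `n_round2` covering every tracked sequence including the wild type.
#' @param variants variant table from [buildSsmLibrary()] describing each
#'   non-wild-type `variant_id`.
#' @param wtSequence wild-type amino-acid sequence.
#' @param wtId the `variant_id` of the wild type in `counts`.
#' @param pseudocount positive pseudocount per sequence per round.
#' @return An [EnrichmentMatrix-class]; cells for variants missing from
#'   `counts` are `NA`, wild-type identity cells are 0.
#' @export
enrichmentScores <- function(counts, variants, wtSequence, wtId = "WT",
                             pseudocount = 0.5) {
  need <- c("variant_id", "n_input", "n_round2")
  if (!all(need %in% colnames(counts)))
    stop("counts needs columns: ", paste(need, collapse = ", "))
  if (pseudocount <= 0)
    stop("pseudocount must be positive")
  if (!wtId %in% counts$variant_id)
    stop("wild type '", wtId, "' absent from counts")
  if (anyDuplicated(counts$variant_id))
    stop("duplicated variant ids in counts")
  .checkAASequence(wtSequence, "wtSequence")
  wtRow <- counts[counts$variant_id == wtId, ]
  if (wtRow$n_input == 0)
    stop("wild type has zero input reads")
  V <- nrow(counts)
  lr <- log2((counts$n_round2 + pseudocount) /
               (sum(counts$n_round2) + pseudocount * V)) -
    log2((counts$n_input + pseudocount) /
           (sum(counts$n_input) + pseudocount * V))
  E <- lr - lr[counts$variant_id == wtId]

  wt <- strsplit(wtSequence, "")[[1]]
  L <- length(wt)
  subs <- setdiff(AA20, "C")
  mat <- matrix(NA_real_, L, length(subs),
                dimnames = list(seq_len(L), subs))
  idx <- match(variants$variant_id, counts$variant_id)
  keep <- !is.na(idx)
  mat[cbind(variants$position[keep],
            match(variants$mut_aa[keep], subs))] <- E[idx[keep]]
  diagIdx <- wt %in% subs
  mat[cbind(which(diagIdx), match(wt[diagIdx], subs))] <- 0

  vt <- DataFrame(variants[keep, c("variant_id", "position",
                                   "wt_aa", "mut_aa")],
                  n_input = counts$n_input[idx[keep]],
                  n_round2 = counts$n_round2[idx[keep]],
                  E = E[idx[keep]])
  new("EnrichmentMatrix", scores = mat, wtSequence = wtSequence,
      variants = vt)
}

#' Per-position average enrichment
#'
#' Arithmetic mean of the defined non-wild-type substitution scores at each
#' position -- the per-column summary printed alongside SSM heat maps.
#' Positions with no defined substitution are `NA`.
#'
#' @param x an [EnrichmentMatrix-class].
#' @return named numeric vector, one value per position.
#' @export
positionAverage <- function(x) {
  stopifnot(is(x, "EnrichmentMatrix"))
  mat <- x@scores
  wt <- strsplit(x@wtSequence, "")[[1]]
  out <- vapply(seq_len(nrow(mat)), function(i) {
    v <- mat[i, ]
    if (wt[i] %in% names(v))
      v <- v[names(v) != wt[i]]
    v <- v[!is.na(v)]
    if (length(v)) mean(v) else NA_real_
  }, 0)
  names(out) <- rownames(mat)
  out
}

#' Heat-map layout of an enrichment matrix
#'
#' Transposes the score matrix into the conventional SSM heat-map layout:
#' rows are amino-acid substitutions grouped by chemical category
#' (nonpolar aliphatic, aromatic, polar uncharged, positively charged,
#' negatively charged, then the conformationally special G and P), columns
#' are peptide positions labelled with the wild-type residue.
#'
#' @param x an [EnrichmentMatrix-class].
#' @param categories named list of amino-acid groups controlling row order.
#' @return numeric matrix, substitutions x positions.
#' @export
substitutionMatrix <- function(x, categories = AA_CATEGORIES) {
  stopifnot(is(x, "EnrichmentMatrix"))
  rows <- intersect(unlist(categories), colnames(x@scores))
  wt <- strsplit(x@wtSequence, "")[[1]]
  out <- t(x@scores)[rows, , drop = FALSE]
  colnames(out) <- paste0(wt, seq_along(wt))
  out
}

#' TB1G1 wild-type peptide sequence
#'
#' The 40-residue, 6-cysteine designed TEAD-binding peptide used as the
#' worked example and default SSM wild type, translated from its deposited
#' coding sequence (GenBank MF958494); residue numbering starts after the
#' expression-tag `GS`.
#'
#' @return a single amino-acid string.
#' @export
tb1g1Sequence <- function() {
  "PDEYIERAKECCKKGDIQCCLRYFEESGDPNVMLICLFCP"
}
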