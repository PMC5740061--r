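# Library curation: cysteine-motif scanning, sequon and context annotation,
# taxonomy-weighted sampling.

#' Scan a protein for cystine-dense motifs
#'
#' Enumerates every cysteine-bounded window of a protein sequence -- first
#' and last residue both cysteine -- whose length lies in
#' `[minLen, maxLen]` and whose total cysteine count is one of
#' `allowedCounts`. These are the windows a cystine-dense-peptide (CDP)
#' screening library is built from: by default 6, 8 or 10 cysteines within
#' 30-50 amino acids.
#'
#' Overlapping windows are common; with `collapseNested = TRUE` (default) a
#' window is dropped when it is strictly contained in another qualifying
#' window of the same protein, so only maximal "protein segments" are
#' reported.
#'
#' @param proteins named character vector of protein sequences (upper-case,
#'   20-letter alphabet), or an [Biostrings::AAStringSet].
#' @param allowedCounts admissible total cysteine counts per window.
#' @param minLen,maxLen inclusive window-length bounds, in residues.
#' @param collapseNested drop windows strictly contained in another
#'   qualifying window of the same parent.
#' @return A `data.frame` with one row per motif: `parent_id`, `start`,
#'   `end` (0-based half-open into the parent), `cys_count`, `length` and
#'   `sequence`, sorted by `(parent_id, start, end)`.
#' @examples
#' prot <- c(p1 = paste0(strrep("A", 5),
#'                       "CAACAAAAAAAAACAAAAAAAAACAAAAAAAAACAAAAAC",
#'                       strrep("A", 5)))
#' scanCysteineMotifs(prot)
#' @export
scanCysteineMotifs <- function(proteins, allowedCounts = c(6L, 8L, 10L),
                               minLen = 30L, maxLen = 50L,
                               collapseNested = TRUE) {
  if (is(proteins, "AAStringSet"))
    proteins <- setNames(as.character(proteins), names(proteins))
  .checkAASequence(proteins, "proteins")
  if (is.null(names(proteins)))
    names(proteins) <- paste0("protein", seq_along(proteins))
  if (minLen > maxLen)
    stop("minLen must not exceed maxLen")
  if (length(allowedCounts) == 0L)
    stop("allowedCounts must be non-empty")

  one <- function(seqc, id) {
    cpos <- which(strsplit(seqc, "")[[1]] == "C")
    nC <- length(cpos)
    if (nC < 2L)
      return(NULL)
    rows <- list()
    for (i in seq_len(nC - 1L)) {
      for (j in seq.int(i + 1L, nC)) {
        len <- cpos[j] - cpos[i] + 1L
        if (len > maxLen)
          break
        if (len < minLen)
          next
        if ((j - i + 1L) %in% allowedCounts)
          rows[[length(rows) + 1L]] <-
            c(start = cpos[i] - 1L, end = cpos[j], cys = j - i + 1L)
      }
    }
    if (!length(rows))
      return(NULL)
    m <- do.call(rbind, rows)
    if (collapseNested && nrow(m) > 1L) {
      keep <- vapply(seq_len(nrow(m)), function(k) {
        !any(m[, "start"] <= m[k, "start"] & m[, "end"] >= m[k, "end"] &
               (m[, "start"] < m[k, "start"] | m[, "end"] > m[k, "end"]))
      }, logical(1L))
      m <- m[keep, , drop = FALSE]
    }
    data.frame(parent_id = id, start = m[, "start"], end = m[, "end"],
               cys_count = m[, "cys"])
  }

  out <- do.call(rbind, Map(one, unname(proteins), names(proteins)))
  if (is.null(out))
    return(data.frame(parent_id = character(), start = integer(),
                      end = integer(), cys_count = integer(),
                      length = integer(), sequence = character()))
  out <- out[order(out$parent_id, out$start, out$end), , drop = FALSE]
  out$length <- out$end - out$start
  out$sequence <- substr(proteins[out$parent_id],
                         out$start + 1L, out$end)
  rownames(out) <- NULL
  out
}

#' Find N-linked glycosylation sequons
#'
#' Reports every position `i` (0-based) with `N` at `i` and `S` or `T` at
#' `i + 2` -- the N-X-S/T sequon. With `canonical = TRUE` the middle residue
#' must additionally differ from proline (`N-X(!=P)-S/T`), the canonical rule
#' for sites that are actually glycosylated. Overlapping sequons are all
#' reported.
#'
#' @param sequence a single amino-acid sequence.
#' @param canonical exclude sequons with proline in the X position.
#' @return Integer vector of 0-based sequon start positions.
#' @examples
#' findGlycosites("AANGSAA")            # 2
#' findGlycosites("NPT")                # 0
#' findGlycosites("NPT", canonical = TRUE)  # none
#' @export
findGlycosites <- function(sequence, canonical = FALSE) {
  stopifnot(length(sequence) == 1L)
  .checkAASequence(sequence)
  s <- strsplit(sequence, "")[[1]]
  n <- length(s)
  if (n < 3L)
    return(integer())
  i <- seq_len(n - 2L)
  hit <- s[i] == "N" & s[i + 2L] %in% c("S", "T")
  if (canonical)
    hit <- hit & s[i + 1L] != "P"
  which(hit) - 1L
}

#' Native-protein context category of a peptide
#'
#' Classifies a displayed peptide by the fraction of its full native protein
#' it covers: `LT25` (< 25 %), `P25TO50` (25-50 %) or `GE50` (>= 50 %).
#' Boundary values are assigned upward: a fraction of exactly 0.25 is
#' `P25TO50` and exactly 0.5 is `GE50`, matching the printed "< 25 %",
#' "25-50 %", ">= 50 %" labels.
#'
#' @param peptideLength,proteinLength positive integers (vectorised);
#'   `peptideLength` must not exceed `proteinLength`.
#' @return `data.frame` with `fraction` and `category` (factor with levels
#'   `LT25`, `P25TO50`, `GE50`).
#' @examples
#' contextCategory(36, 72)   # fraction 0.5 -> GE50
#' @export
contextCategory <- function(peptideLength, proteinLength) {
  if (any(peptideLength <= 0) || any(proteinLength <= 0))
    stop("lengths must be positive")
  if (any(peptideLength > proteinLength))
    stop("peptide longer than its protein")
  frac <- peptideLength / proteinLength
  cat <- cut(frac, breaks = c(0, 0.25, 0.5, 1 + 1e-9),
             labels = c("LT25", "P25TO50", "GE50"), right = FALSE)
  data.frame(fraction = frac,
             category = factor(cat, levels = c("LT25", "P25TO50", "GE50")))
}

#' Taxonomy-weighted sampling of library candidates
#'
#' Draws `n` candidates without replacement, flattening taxonomic classes
#' before weighting: each candidate's selection weight is
#' `classWeights[class] / (number of candidates in that class)`, so equal
#' class weights give every class the same expected representation
#' regardless of its size. Candidates with a missing or corrupt lineage are
#' retained under the class `"UNKNOWN"` with `defaultWeight`.
#'
#' Sampling is two-stage -- at each draw a class is picked with probability
#' proportional to its weight (among classes with members remaining), then
#' a member uniformly within it. This realises the per-candidate weights
#' above while keeping expected class counts exactly proportional to the
#' class weights, which one-shot weighted sampling without replacement does
#' not.
#'
#' @param ids candidate identifiers (unique).
#' @param classes taxonomic class label per candidate (`NA` allowed).
#' @param n number of candidates to draw (`<= length(ids)`).
#' @param classWeights named positive weights per class; classes absent from
#'   the vector get `defaultWeight`.
#' @param defaultWeight weight for unlisted or unknown classes.
#' @param seed RNG seed for reproducible draws (`NULL` = ambient stream).
#' @return Character vector of selected ids (a subset of `ids`, no
#'   duplicates), deterministic for a fixed seed.
#' @export
taxonomyWeightedSample <- function(ids, classes = NULL, n,
                                   classWeights = numeric(),
                                   defaultWeight = 1, seed = NULL) {
  if (length(ids) == 0L)
    stop("no candidates supplied")
  if (anyDuplicated(ids))
    stop("candidate ids must be unique")
  if (n > length(ids))
    stop("cannot sample ", n, " from ", length(ids), " candidates")
  if (is.null(classes))
    classes <- rep(NA_character_, length(ids))
  if (length(classes) != length(ids))
    stop("one class label per candidate is required")
  classes <- as.character(classes)
  classes[is.na(classes) | classes == ""] <- "UNKNOWN"
  if (length(classWeights) && any(classWeights <= 0))
    stop("class weights must be positive")
  pool <- split(ids, classes)
  w <- classWeights[names(pool)]
  w[is.na(w)] <- defaultWeight
  names(w) <- names(pool)
  .withSeed(seed, {
    out <- character(n)
    for (i in seq_len(n)) {
      cls <- names(pool)[sample.int(length(pool), 1L, prob = w)]
      j <- sample.int(length(pool[[cls]]), 1L)
      out[i] <- pool[[cls]][j]
      pool[[cls]] <- pool[[cls]][-j]
      if (!length(pool[[cls]])) {
        w <- w[names(pool) != cls]
        pool[[cls]] <- NULL
      }
    }
    out
  })
}

#' Annotate motifs with glycosites, context and lineage
#'
#' Convenience wrapper combining [findGlycosites()] and [contextCategory()]
#' over a motif table from [scanCysteineMotifs()].
#'
#' @param motifs motif table from [scanCysteineMotifs()].
#' @param proteinLengths named integer vector, full native protein length
#'   per `parent_id`.
#' @param lineage optional `data.frame` with columns `id`, `kingdom`,
#'   `class` keyed by `parent_id`.
#' @param canonical passed to [findGlycosites()].
#' @return The motif table with added columns `glycosites` (comma-separated
#'   0-based positions within the motif), `n_glycosites`, `context_fraction`,
#'   `context_category`, and (when `lineage` is given) `kingdom`, `class`.
#' @export
annotateMotifs <- function(motifs, proteinLengths, lineage = NULL,
                           canonical = FALSE) {
  gl <- lapply(motifs$sequence, findGlycosites, canonical = canonical)
  motifs$glycosites <- vapply(gl, paste, "", collapse = ",")
  motifs$n_glycosites <- lengths(gl)
  ctx <- contextCategory(motifs$length,
                         as.numeric(proteinLengths[motifs$parent_id]))
  motifs$context_fraction <- ctx$fraction
  motifs$context_category <- ctx$category
  if (!is.null(lineage)) {
    i <- match(motifs$parent_id, lineage$id)
    motifs$kingdom <- lineage$kingdom[i]
    motifs$class <- lineage$class[i]
  }
  motifs
}
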