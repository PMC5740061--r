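# Shared validation helpers and RNG scoping.

# canonical 20-letter amino-acid alphabet
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Amino acids grouped by chemical category; used to order heat-map rows.
AA_CATEGORIES <- list(
  `nonpolar aliphatic`  = c("A", "V", "L", "I", "M"),
  aromatic              = c("F", "W", "Y"),
  `polar uncharged`     = c("S", "T", "N", "Q"),
  `positively charged`  = c("K", "R", "H"),
  `negatively charged`  = c("D", "E"),
  special               = c("G", "P"),
  cysteine              = "C")

.checkAASequence <- function(x, what = "sequence") {
  if (!is.character(x) || length(x) == 0L)
    stop(what, " must be a non-empty character vector")
  if (any(is.na(x)) || any(nchar(x) == 0L))
    stop(what, " contains empty or missing sequences")
  bad <- grepl(paste0("[^", paste(AA20, collapse = ""), "]"), x)
  if (any(bad))
    stop(what, " contains non-canonical amino-acid letters (first offender: ",
         x[which(bad)[1L]], ")")
  invisible(x)
}

# Evaluate `expr` under a local RNG stream seeded with `seed`, restoring the
# caller's .Random.seed afterwards. seed = NULL uses the ambient stream.
.withSeed <- function(seed, expr) {
  if (is.null(seed))
    return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single finite number or NULL")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
              rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

.scoreVector <- function(x, what = "scores") {
  if (is(x, "DataFrame") || is.data.frame(x)) {
    if (!"S" %in% colnames(x))
      stop(what, " must be a numeric vector or a content-score table ",
           "with an 'S' column")
    out <- setNames(as.numeric(x[["S"]]), rownames(x))
    return(out)
  }
  if (is.logical(x) && all(is.na(x)))
    x <- as.numeric(x)
  if (!is.numeric(x))
    stop(what, " must be numeric")
  x
}
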