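# Independent oracles and fixture builders used across the suite.

AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
        "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# random protein with approximately nC cysteines at random positions
randomProtein <- function(len, nC) {
  s <- sample(setdiff(AA, "C"), len, replace = TRUE)
  s[sample.int(len, min(nC, len))] <- "C"
  paste(s, collapse = "")
}

# exhaustive enumeration of every cysteine-bounded substring with length
# and cysteine-count constraints; no collapsing
bruteMotifs <- function(seqc, allowed = c(6, 8, 10), minLen = 30,
                        maxLen = 50) {
  s <- strsplit(seqc, "")[[1]]
  n <- length(s)
  out <- list()
  for (i in seq_len(n)) {
    if (s[i] != "C") next
    for (j in i:n) {
      len <- j - i + 1
      if (len > maxLen) break
      if (len < minLen || s[j] != "C") next
      if (sum(s[i:j] == "C") %in% allowed)
        out[[length(out) + 1]] <- c(start = i - 1, end = j)
    }
  }
  if (!length(out))
    return(data.frame(start = integer(), end = integer()))
  as.data.frame(do.call(rbind, out))
}

# exact tail probability of the concordance statistic under uniform
# shuffling of y, by enumerating every arrangement of its ones
exhaustiveConcordanceTail <- function(x, y, statistic = "fraction") {
  n <- length(x); b <- sum(y)
  obsK <- sum(x & y)
  stat <- function(k) {
    if (statistic == "fraction")
      return((n - sum(x) - b + 2 * k) / n)
    a <- sum(x); tp <- k; fp <- a - k; fn <- b - k; tn <- n - a - b + k
    den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
    if (den == 0) 0 else (tp * tn - fp * fn) / den
  }
  obs <- stat(obsK)
  sets <- combn(n, b)
  tails <- apply(sets, 2, function(pos) {
    yy <- logical(n); yy[pos] <- TRUE
    stat(sum(x & yy)) >= obs - 1e-12
  })
  mean(tails)
}

chisqClosedForm <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  N <- sum(tab)
  N * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
}

# naive per-peptide loop reconstruction of the content score
contentScoreOracle <- function(reads, C, M) {
  n <- nrow(reads)
  S <- numeric(n)
  for (i in seq_len(n)) {
    num <- 0; den <- 0
    for (bb in seq_along(C)) {
      tot <- sum(reads[, bb])
      cells <- if (tot > 0) reads[i, bb] / tot * C[bb] else 0
      num <- num + cells * M[bb]
      den <- den + cells
    }
    S[i] <- if (den > 0) num / den else NA_real_
  }
  S
}

# small ready-made SortSeqExperiment
makeSse <- function(reads, M = c(10, 100, 1000, 5000), C = rep(1000, 4),
                    condition = "untreated", replicate = 1L) {
  bs <- data.frame(bin = c("lowest", "low", "high", "highest"),
                   condition = condition, replicate = replicate,
                   cell_count = C, median_fluor = M)
  SortSeqExperiment(reads, bs)
}
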