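smallCfg <- function(...)
  sortSeqSimConfig(nPeptides = 150L, totalCells = 1.5e4,
                   readsPerGate = 5e4, ...)

test_that("generators are bitwise reproducible for a fixed seed", {
  cfg <- smallCfg()
  a <- simulateSortSeq(cfg, seed = 7)
  b <- simulateSortSeq(cfg, seed = 7)
  expect_identical(SummarizedExperiment::assay(a$experiment, "reads"),
                   SummarizedExperiment::assay(b$experiment, "reads"))
  expect_identical(a$truth, b$truth)

  ta <- simulateTrypsinCondition(a$truth, cfg, seed = 8)
  tb <- simulateTrypsinCondition(a$truth, cfg, seed = 8)
  expect_identical(SummarizedExperiment::assay(ta$experiment, "reads"),
                   SummarizedExperiment::assay(tb$experiment, "reads"))

  expect_identical(simulateHplcLabels(a$truth, seed = 9),
                   simulateHplcLabels(a$truth, seed = 9))

  eff <- setNames(c(0, 1, -1), c("WT", "v1", "v2"))
  expect_identical(simulateSsmSelection(eff, seed = 10),
                   simulateSsmSelection(eff, seed = 10))

  expect_identical(simulateLibrarySequences(5, seed = 11),
                   simulateLibrarySequences(5, seed = 11))
})

test_that("sort-seq bookkeeping: cells and reads are exactly conserved", {
  cfg <- smallCfg()
  sim <- simulateSortSeq(cfg, seed = 3)
  cellCols <- paste0("cells_", c("lowest", "low", "high", "highest"))
  expect_equal(sum(as.matrix(sim$truth[, cellCols])), cfg$totalCells)
  reads <- SummarizedExperiment::assay(sim$experiment, "reads")
  expect_equal(unname(colSums(reads)), rep(cfg$readsPerGate, 4))
  # bins ordered by strictly increasing median fluorescence
  bs <- as.data.frame(binStats(sim$experiment))
  expect_true(all(diff(bs$median_fluor[order(match(bs$bin,
    c("lowest", "low", "high", "highest")))]) > 0))
})

test_that("a noise-free single-mean library collapses into one gate", {
  cfg <- sortSeqSimConfig(nPeptides = 50L, totalCells = 5e3,
                          readsPerGate = 2e4, mixingFraction = 1,
                          foldedSdLog10 = 0, cellNoiseSd = 0)
  expect_warning(simulateSortSeq(cfg, seed = 5), "no cells")
  sim <- suppressWarnings(simulateSortSeq(cfg, seed = 5))
  reads <- SummarizedExperiment::assay(sim$experiment, "reads")
  nonEmpty <- which(colSums(reads) > 0)
  expect_length(nonEmpty, 1L)
  cs <- contentScores(sim$experiment)
  gateMedian <-
    as.data.frame(binStats(sim$experiment))$median_fluor[nonEmpty]
  expect_equal(unname(cs$S), rep(gateMedian, 50))
})

test_that("generator marginals match the configured parameters", {
  # large enough that each mixture component has >= 1e4 draws
  cfg <- sortSeqSimConfig(nPeptides = 60000L, totalCells = 6e4,
                          readsPerGate = 1e4)
  sim <- simulateSortSeq(cfg, seed = 13)
  tr <- sim$truth
  n <- nrow(tr)
  # mixing fraction within 3 MC standard errors
  se <- sqrt(0.17 * 0.83 / n)
  expect_lt(abs(mean(tr$folded) - 0.17), 3 * se)
  # component means of the true log10 fluorescence
  expect_lt(abs(mean(tr$true_log10_mean[tr$folded]) - 3.5),
            3 * 0.3 / sqrt(sum(tr$folded)))
  expect_lt(abs(mean(tr$true_log10_mean[!tr$folded]) - 2.5),
            3 * 0.3 / sqrt(sum(!tr$folded)))
  # Beta survival means: 8/(8+2) = 0.8 folded, 2/(2+5) ~ 0.286 unfolded
  sdB <- function(a, b) sqrt(a * b / ((a + b)^2 * (a + b + 1)))
  expect_lt(abs(mean(tr$survival[tr$folded]) - 0.8),
            3 * sdB(8, 2) / sqrt(sum(tr$folded)))
  expect_lt(abs(mean(tr$survival[!tr$folded]) - 2 / 7),
            3 * sdB(2, 5) / sqrt(sum(!tr$folded)))
})

test_that("HPLC label generator follows its confusion matrix", {
  truth <- data.frame(peptide_id = sprintf("p%05d", 1:8000),
                      folded = rep(c(TRUE, FALSE), each = 4000))
  # deterministic confusion: labels coincide with the folding state
  det <- rbind(c(1, 0, 0), c(0, 1, 0))
  lab <- simulateHplcLabels(truth, det, seed = 14)
  expect_equal(unname(lab == "PEAKS_1_2"), truth$folded)
  # stochastic rows reproduce their probabilities within 3 SE
  conf <- rbind(c(0.8, 0.1, 0.1), c(0.2, 0.55, 0.25))
  lab2 <- simulateHplcLabels(truth, conf, seed = 15)
  p1 <- mean(lab2[truth$folded] == "PEAKS_1_2")
  expect_lt(abs(p1 - 0.8), 3 * sqrt(0.8 * 0.2 / 4000))
  p2 <- mean(lab2[!truth$folded] == "PEAKS_0")
  expect_lt(abs(p2 - 0.25), 3 * sqrt(0.25 * 0.75 / 4000))
  expect_error(simulateHplcLabels(truth, rbind(c(1, 1, 0), c(0, 1, 0))),
               "row-stochastic")
})

test_that("SSM selection plants recoverable effects", {
  vars <- buildSsmLibrary("ACDEFGHIKL")
  eff <- setNames(rep(0, nrow(vars) + 1), c("WT", vars$variant_id))
  cnt <- simulateSsmSelection(eff, depth = 1e6, seed = 16)
  em <- enrichmentScores(cnt, vars, "ACDEFGHIKL")
  expect_lt(max(abs(as.data.frame(variantTable(em))$E)), 0.1)

  eff2 <- eff
  eff2["A1W"] <- 2
  cnt2 <- simulateSsmSelection(eff2, depth = 1e6, seed = 17)
  em2 <- enrichmentScores(cnt2, vars, "ACDEFGHIKL")
  vt <- as.data.frame(variantTable(em2))
  expect_lt(abs(vt$E[vt$variant_id == "A1W"] - 2), 0.15)
})

test_that("planted library motifs and sequons are fully recoverable", {
  lib <- simulateLibrarySequences(30, glycositeRate = 0.6, seed = 18)
  hits <- scanCysteineMotifs(lib$sequences)
  found <- merge(lib$truth, hits,
                 by.x = c("id", "motif_start", "motif_end"),
                 by.y = c("parent_id", "start", "end"))
  expect_equal(nrow(found), nrow(lib$truth))   # 100 % sensitivity
  expect_equal(found$cys_count.x, found$cys_count.y)
  # planted sequons are reported by the scanner at the planted offset
  withGly <- lib$truth[!is.na(lib$truth$glycosite_pos), ]
  for (i in seq_len(nrow(withGly))) {
    motif <- substr(lib$sequences[withGly$id[i]],
                    withGly$motif_start[i] + 1, withGly$motif_end[i])
    expect_true(withGly$glycosite_pos[i] %in% findGlycosites(motif))
  }
  # with the sequon rate at zero nothing is planted, and any sequon found
  # is a verifiable chance occurrence
  lib0 <- simulateLibrarySequences(15, glycositeRate = 0, seed = 19)
  expect_true(all(is.na(lib0$truth$glycosite_pos)))
  for (id in lib0$truth$id) {
    s <- lib0$sequences[[id]]
    for (g in findGlycosites(s))
      expect_true(substr(s, g + 1, g + 1) == "N" &&
                    substr(s, g + 3, g + 3) %in% c("S", "T"))
  }
})
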