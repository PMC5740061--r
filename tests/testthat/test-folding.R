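test_that("surface classification evaluates the boundary line with upward ties", {
  # worked example: y = -50 x + 150 at (S = 1e4, T = 100)
  expect_equal(as.character(classifySurface(1e4, 100, -50, 150)), "HC_TR")
  # a point exactly on the line is HC_TR
  expect_equal(as.character(classifySurface(100, 50, -50, 150)), "HC_TR")
  # undefined inputs stay unclassified
  expect_true(is.na(classifySurface(NA, 50, -50, 150)))
  expect_error(classifySurface(10, 10, Inf, 0), "finite")

  # sign-evaluation oracle over random points, both orientations
  set.seed(21)
  S <- 10^runif(1000, 0, 5)
  T <- runif(1000, 0, 150)
  for (hcAbove in c(TRUE, FALSE)) {
    got <- classifySurface(S, T, -30, 120, hcAbove = hcAbove)
    resid <- T - (-30 * log10(S) + 120)
    want <- ifelse(if (hcAbove) resid >= 0 else resid <= 0,
                   "HC_TR", "LC_TS")
    expect_equal(as.character(got), want)
  }
})

test_that("boundary calibration recovers a separating line", {
  set.seed(22)
  x <- runif(500, 1, 5); T <- runif(500, 0, 150)
  ref <- T - (-40 * x + 160) >= 0
  fit <- calibrateBoundary(10^x, T, ref)
  relabel <- classifySurface(10^x, T, fit$slope, fit$intercept)
  expect_gt(mean((relabel == "HC_TR") == ref), 0.98)
})

test_that("HPLC classes follow the dominant/minor peak rule in both conditions", {
  one <- function(id, cond, areas)
    data.frame(peptide_id = id, condition = cond,
               rt = seq_along(areas), area = areas)
  # one peak native, one peak reduced
  pk <- rbind(one("p", "native", 100), one("p", "reduced", 90))
  expect_equal(as.character(classifyHplc(pk)), "PEAKS_1_2")
  # dominant peak plus a single minor peak still counts as 1-2 peaks
  pk12 <- rbind(one("p", "native", c(90, 8)), one("p", "reduced", 100))
  expect_equal(as.character(classifyHplc(pk12)), "PEAKS_1_2")
  # total native area below the detection floor: failed to secrete
  pk0 <- rbind(one("p", "native", c(1, 1)), one("p", "reduced", 100))
  expect_equal(as.character(classifyHplc(pk0, detectionFloor = 10)),
               "PEAKS_0")
  # four equal native peaks: no dominant peak
  pk4 <- rbind(one("p", "native", rep(25, 4)), one("p", "reduced", 100))
  expect_equal(as.character(classifyHplc(pk4)), "PEAKS_3PLUS")
  # a dominant peak with two >= 5 % minors violates "0 or 1 minor peaks"
  pk3 <- rbind(one("p", "native", c(80, 10, 10)),
               one("p", "reduced", 100))
  expect_equal(as.character(classifyHplc(pk3)), "PEAKS_3PLUS")
  # classification is invariant to uniform scaling of all areas
  pkS <- pk3; pkS$area <- pkS$area * 1e4
  expect_equal(classifyHplc(pkS), classifyHplc(pk3))
  # secreted peptide without a reduced run is a hard error
  expect_error(classifyHplc(one("p", "native", 100)), "reduced")
})

test_that("concordance permutation p-values match exhaustive enumeration", {
  # six perfectly concordant pairs at 3/3 balance: the exact tail is 1/20
  x <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  r <- concordanceTest(x, x, nPerm = 2e5, seed = 31)
  expect_equal(r@statistic, 1)
  tail6 <- exhaustiveConcordanceTail(x, x)
  expect_equal(tail6, 1 / 20)
  expect_lt(abs(r@pValue - tail6), 4 * sqrt(tail6 * (1 - tail6) / 2e5) +
              2 / 2e5)

  # an arbitrary n = 7 case, fraction and mcc statistics
  set.seed(33)
  x7 <- c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, TRUE)
  y7 <- c(TRUE, FALSE, FALSE, TRUE, TRUE, FALSE, TRUE)
  for (st in c("fraction", "mcc")) {
    t7 <- exhaustiveConcordanceTail(x7, y7, st)
    r7 <- concordanceTest(x7, y7, nPerm = 2e5, seed = 34, statistic = st)
    expect_lt(abs(r7@pValue - t7),
              4 * sqrt(t7 * (1 - t7) / 2e5) + 2 / 2e5)
  }

  # identical HPLC labels everywhere: permutation-invariant, p = 1
  expect_warning(r1 <- concordanceTest(x, rep(TRUE, 6), nPerm = 100,
                                       seed = 1), "one-class")
  expect_equal(r1@pValue, 1)

  # deterministic for a fixed seed
  a <- concordanceTest(x7, y7, nPerm = 5000, seed = 99)
  b <- concordanceTest(x7, y7, nPerm = 5000, seed = 99)
  expect_identical(a@pValue, b@pValue)
})

test_that("concordance p-values are super-uniform under the null", {
  set.seed(35)
  ps <- replicate(500, {
    x <- runif(300) < 0.5
    y <- runif(300) < 0.5
    concordanceTest(x, y, nPerm = 999)@pValue
  })
  for (alpha in c(0.01, 0.05, 0.1)) {
    se <- sqrt(alpha * (1 - alpha) / 500)
    expect_lte(mean(ps <= alpha), alpha + 3 * se)
  }
})

test_that("2x2 chi-square matches the closed form and textbook values", {
  h <- chiSquare2x2(matrix(c(10, 10, 10, 10), 2))
  expect_equal(h$statistic, 0)
  expect_equal(h$p, 1)

  h2 <- chiSquare2x2(matrix(c(20, 10, 10, 20), 2))
  expect_equal(h2$statistic, 20 / 3, tolerance = 1e-12)
  expect_equal(h2$p, 0.0098, tolerance = 1e-2)

  tab <- matrix(c(20, 10, 10, 20), 2)
  expect_equal(chiSquare2x2(tab[2:1, ])$statistic, h2$statistic)
  expect_equal(chiSquare2x2(tab[, 2:1])$statistic, h2$statistic)

  set.seed(36)
  for (i in 1:50) {
    tab <- matrix(rpois(4, 20) + 1, 2)
    expect_equal(chiSquare2x2(tab)$statistic, chisqClosedForm(tab),
                 tolerance = 1e-12)
  }
  expect_error(chiSquare2x2(matrix(c(0, 0, 5, 5), 2)), "margins")
})

test_that("bin enrichment is a pseudocounted log2 frequency ratio", {
  ids <- sprintf("p%02d", 1:20)
  r <- setNames(rpois(20, 50) + 1, ids)
  # identical frequencies: all zero
  e0 <- binEnrichmentRanks(r, r)
  expect_equal(e0$log2_enrichment, rep(0, 20))

  # doubled *frequency* at large counts is ~ +1 (other peptides shrink so
  # the focal one holds twice its input share of the bin)
  big <- setNames(rep(1e6, 20), ids)
  twice <- big
  twice[] <- 18e6 / 19
  twice["p01"] <- 2e6
  e1 <- binEnrichmentRanks(twice, big)
  expect_lt(abs(e1$log2_enrichment[e1$peptide_id == "p01"] - 1), 0.01)

  # zero bin count evaluated against the formula directly
  zb <- big; zb["p05"] <- 0
  e2 <- binEnrichmentRanks(zb, big, pseudocount = 0.5)
  P <- 20
  want <- log2(((0 + 0.5) / (sum(zb) + 0.5 * P)) /
                 ((1e6 + 0.5) / (sum(big) + 0.5 * P)))
  expect_equal(e2$log2_enrichment[e2$peptide_id == "p05"], want,
               tolerance = 1e-12)
  # descending order with id tie-break
  expect_true(all(diff(e2$log2_enrichment) <= 0))
  expect_error(binEnrichmentRanks(numeric(), numeric()), "empty")
})

test_that("unweighted GSEA attains +/-1 at the extremes and matches fgsea", {
  ids <- sprintf("g%03d", 1:100)
  top <- gseaUnweighted(ids, ids[1:10], nPerm = 200, seed = 41)
  expect_equal(top@es, 1)
  expect_setequal(top@leadingEdge, ids[1:10])
  bottom <- gseaUnweighted(ids, ids[91:100], nPerm = 200, seed = 41)
  expect_equal(bottom@es, -1)

  # antisymmetry under list reversal
  set.seed(42)
  set <- sample(ids, 15)
  fwd <- gseaUnweighted(ids, set, nPerm = 10, seed = 1)@es
  rev_ <- gseaUnweighted(rev(ids), set, nPerm = 10, seed = 1)@es
  expect_equal(rev_, -fwd, tolerance = 1e-12)

  # independent implementation: fgsea's unweighted statistic
  st <- setNames(seq(100, 1, length.out = 100), ids)
  for (i in 1:10) {
    sel <- sort(sample(100, sample(5:30, 1)))
    ours <- gseaUnweighted(ids, ids[sel], nPerm = 10, seed = 1)@es
    ref <- fgsea::calcGseaStat(st, sel, gseaParam = 0)
    expect_equal(ours, ref, tolerance = 1e-12)
  }

  expect_error(gseaUnweighted(ids, c(ids[1], "nope"), 10), "subset")
  expect_error(gseaUnweighted(ids, ids, 10), "strict subset")
})
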