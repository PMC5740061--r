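# Seeded generators of synthetic sort-seq, HPLC and SSM selection data
# with known ground truth.

#' Configuration for the sort-seq simulator
#'
#' Defines the study conditions emulated by [simulateSortSeq()]: a peptide
#' library whose true mean surface fluorescences follow a two-component
#' (folded / unfolded) log-normal mixture, cells carrying log-normal
#' per-cell noise around their peptide's mean plus an additive
#' autofluorescence floor, four contiguous sorting gates placed at
#' quantiles of the pooled cell fluorescence, and multinomial read sampling
#' within each gate.
#'
#' Defaults: 2000 peptides; 17 % folded with mean log10 fluorescence 3.5
#' (SD 0.3) versus 2.5 (SD 0.3) for the unfolded component; per-cell noise
#' SD 0.2 (log10); autofluorescence floor at 1 % of the folded-component
#' mean; 4e5 sorted cells; gates at the pooled 25/50/75 % quantiles;
#' 2e6 reads per gate; trypsin-survival factors Beta(8, 2) for folded and
#' Beta(2, 5) for unfolded peptides.
#'
#' @param nPeptides library size.
#' @param mixingFraction fraction of peptides in the folded component.
#' @param foldedMeanLog10,foldedSdLog10 folded-component mean and SD of the
#'   per-peptide true mean, log10 fluorescence units.
#' @param unfoldedMeanLog10,unfoldedSdLog10 unfolded-component parameters.
#' @param cellNoiseSd per-cell log10 fluorescence SD around the peptide
#'   mean.
#' @param autofluorFloor additive background fluorescence per cell
#'   (arbitrary units).
#' @param totalCells cells sorted per condition.
#' @param gateQuantiles three strictly increasing cut points in (0, 1)
#'   defining four contiguous, exhaustive gates.
#' @param readsPerGate sequencing reads drawn per gate.
#' @param survivalBetaFolded,survivalBetaUnfolded `c(shape1, shape2)` of the
#'   Beta trypsin-survival distribution per folding state.
#' @param binNames gate labels, dimmest first.
#' @param seed default RNG seed carried into the generators.
#' @return a validated `SortSeqSimConfig` list.
#' @export
sortSeqSimConfig <- function(nPeptides = 2000L,
                             mixingFraction = 0.17,
                             foldedMeanLog10 = 3.5, foldedSdLog10 = 0.3,
                             unfoldedMeanLog10 = 2.5, unfoldedSdLog10 = 0.3,
                             cellNoiseSd = 0.2,
                             autofluorFloor = 0.01 * 10^3.5,
                             totalCells = 4e5,
                             gateQuantiles = c(0.25, 0.5, 0.75),
                             readsPerGate = 2e6,
                             survivalBetaFolded = c(8, 2),
                             survivalBetaUnfolded = c(2, 5),
                             binNames = c("lowest", "low", "high",
                                          "highest"),
                             seed = NULL) {
  cfg <- list(nPeptides = as.integer(nPeptides),
              mixingFraction = mixingFraction,
              foldedMeanLog10 = foldedMeanLog10,
              foldedSdLog10 = foldedSdLog10,
              unfoldedMeanLog10 = unfoldedMeanLog10,
              unfoldedSdLog10 = unfoldedSdLog10,
              cellNoiseSd = cellNoiseSd,
              autofluorFloor = autofluorFloor,
              totalCells = totalCells,
              gateQuantiles = gateQuantiles,
              readsPerGate = readsPerGate,
              survivalBetaFolded = survivalBetaFolded,
              survivalBetaUnfolded = survivalBetaUnfolded,
              binNames = binNames, seed = seed)
  with(cfg, {
    stopifnot(nPeptides > 0, totalCells > 0, readsPerGate > 0,
              mixingFraction >= 0, mixingFraction <= 1,
              cellNoiseSd >= 0, autofluorFloor >= 0,
              foldedSdLog10 >= 0, unfoldedSdLog10 >= 0,
              length(binNames) == length(gateQuantiles) + 1L)
    if (any(diff(gateQuantiles) <= 0) || any(gateQuantiles <= 0) ||
        any(gateQuantiles >= 1))
      stop("gateQuantiles must be strictly increasing within (0, 1)")
  })
  structure(cfg, class = "SortSeqSimConfig")
}

# Sort one condition: instantiate cells, gate at pooled-fluorescence
# quantiles, record bin stats, draw reads multinomially per gate.
.simulateCondition <- function(trueLog10Mean, multiplier, config,
                               condition, replicate = 1L) {
  n <- length(trueLog10Mean)
  nGates <- length(config$binNames)
  cellsPer <- as.vector(rmultinom(1L, config$totalCells, rep(1 / n, n)))
  idx <- rep.int(seq_len(n), cellsPer)
  fl <- multiplier[idx] *
    10^rnorm(length(idx), trueLog10Mean[idx], config$cellNoiseSd) +
    config$autofluorFloor
  bounds <- quantile(fl, config$gateQuantiles, names = FALSE)
  gate <- findInterval(fl, bounds) + 1L
  cellCount <- tabulate(gate, nGates)
  medFluor <- vapply(seq_len(nGates), function(b) {
    v <- fl[gate == b]
    if (length(v)) median(v) else NA_real_
  }, 0)
  cellMat <- matrix(0, n, nGates)
  tb <- table(factor(idx, levels = seq_len(n)),
              factor(gate, levels = seq_len(nGates)))
  cellMat[] <- as.numeric(tb)
  reads <- matrix(0L, n, nGates)
  for (b in seq_len(nGates)) {
    if (cellCount[b] == 0L) {
      warning("gate '", config$binNames[b],
              "' received no cells; its reads are zero")
      next
    }
    reads[, b] <- rmultinom(1L, config$readsPerGate, cellMat[, b])
  }
  # a gate can only be empty in degenerate configs; give it a harmless
  # positive placeholder so the container's positivity invariants hold
  empty <- cellCount == 0L
  cellCount[empty] <- 1L
  medFluor[empty] <- min(medFluor, na.rm = TRUE)
  list(reads = reads, cellMat = cellMat,
       binStats = data.frame(bin = config$binNames,
                             condition = condition,
                             replicate = as.integer(replicate),
                             cell_count = cellCount,
                             median_fluor = medFluor),
       gates = bounds)
}

#' Simulate a sort-seq screen of the untreated condition
#'
#' Draws per-peptide true mean log10 fluorescences from the configured
#' folded/unfolded mixture, instantiates cells with log-normal per-cell
#' noise plus the autofluorescence floor, sorts them into contiguous gates
#' at the pooled-fluorescence quantiles, and samples reads multinomially
#' within each gate in proportion to the gate's per-peptide cell counts.
#' Per-peptide trypsin-survival factors and the latent folding state are
#' drawn here and recorded in the truth table for the downstream
#' generators. Fully deterministic given `seed`.
#'
#' @param config a [sortSeqSimConfig()].
#' @param seed RNG seed (defaults to `config$seed`).
#' @param replicate replicate index recorded in the bin stats.
#' @param truth optional truth table from an earlier run: reuse the same
#'   library (true means, folding states, survival factors) and only
#'   re-draw cells, gates and reads -- an independent replicate of the
#'   complete experiment.
#' @return list with `experiment` (a [SortSeqExperiment-class], condition
#'   `"untreated"`), `truth` (`data.frame`: peptide id, folding state, true
#'   log10 mean and linear-scale median fluorescence, survival factor, and
#'   per-gate true cell counts summing to `totalCells`) and `gates` (the
#'   fluorescence cut points).
#' @export
simulateSortSeq <- function(config = sortSeqSimConfig(),
                            seed = config$seed, replicate = 1L,
                            truth = NULL) {
  stopifnot(inherits(config, "SortSeqSimConfig"))
  .withSeed(seed, {
    if (is.null(truth)) {
      n <- config$nPeptides
      ids <- sprintf("PEP%05d", seq_len(n))
      folded <- runif(n) < config$mixingFraction
      mu <- ifelse(folded,
                   rnorm(n, config$foldedMeanLog10, config$foldedSdLog10),
                   rnorm(n, config$unfoldedMeanLog10,
                         config$unfoldedSdLog10))
      survival <- ifelse(folded,
                         rbeta(n, config$survivalBetaFolded[1L],
                               config$survivalBetaFolded[2L]),
                         rbeta(n, config$survivalBetaUnfolded[1L],
                               config$survivalBetaUnfolded[2L]))
    } else {
      ids <- truth$peptide_id
      n <- length(ids)
      folded <- truth$folded
      mu <- truth$true_log10_mean
      survival <- truth$survival
    }
    sim <- .simulateCondition(mu, rep(1, n), config, "untreated", replicate)
    rownames(sim$reads) <- ids
    truth <- data.frame(peptide_id = ids, folded = folded,
                        true_log10_mean = mu,
                        true_median_fluor = 10^mu,
                        survival = survival)
    cellCols <- as.data.frame(sim$cellMat)
    colnames(cellCols) <- paste0("cells_", config$binNames)
    truth <- cbind(truth, cellCols)
    list(experiment = SortSeqExperiment(sim$reads, sim$binStats),
         truth = truth, gates = sim$gates)
  })
}

#' Simulate the trypsin-treated condition of a sort-seq screen
#'
#' Re-sorts the library with each peptide's surface fluorescence multiplied
#' by its trypsin-survival factor (autofluorescence is unaffected by the
#' protease and stays additive). Cells are re-drawn -- the treated aliquot
#' is an independent sample of the same culture -- and gates are re-placed
#' at the treated pool's quantiles, as each sort is gated on its own
#' fluorescence distribution. The recovered resistance percentage
#' `T = 100 * S_treated / S_untreated` estimates `100 *` the survival
#' factor.
#'
#' @param truth truth table from [simulateSortSeq()].
#' @param config the same [sortSeqSimConfig()].
#' @param seed RNG seed.
#' @param replicate replicate index recorded in the bin stats.
#' @return list with `experiment` (condition `"trypsin"`) and `gates`.
#' @export
simulateTrypsinCondition <- function(truth, config = sortSeqSimConfig(),
                                     seed = config$seed, replicate = 1L) {
  stopifnot(inherits(config, "SortSeqSimConfig"),
            all(c("peptide_id", "true_log10_mean", "survival") %in%
                  colnames(truth)))
  .withSeed(seed, {
    sim <- .simulateCondition(truth$true_log10_mean, truth$survival,
                              config, "trypsin", replicate)
    rownames(sim$reads) <- truth$peptide_id
    list(experiment = SortSeqExperiment(sim$reads, sim$binStats),
         gates = sim$gates)
  })
}

#' Simulate HPLC folding-class labels from the latent folding state
#'
#' Draws each peptide's HPLC class from the row of a 2 x 3 row-stochastic
#' confusion matrix selected by its folding state. An identity-like matrix
#' yields labels concordant with surface folding; uniform rows yield the
#' independence null used for permutation-test calibration.
#'
#' @param truth truth table from [simulateSortSeq()] (or any data frame
#'   with a logical `folded` column).
#' @param confusion 2 x 3 matrix, rows = (folded, unfolded), columns =
#'   (`PEAKS_1_2`, `PEAKS_3PLUS`, `PEAKS_0`), each row summing to 1. The
#'   default emulates the observed association: well-folded surface
#'   peptides usually run as one dominant peak.
#' @param seed RNG seed (`NULL` = ambient stream).
#' @return factor of HPLC classes named by peptide id.
#' @export
simulateHplcLabels <- function(truth,
                               confusion = rbind(folded = c(0.8, 0.1, 0.1),
                                                 unfolded = c(0.2, 0.55,
                                                              0.25)),
                               seed = NULL) {
  confusion <- as.matrix(confusion)
  if (!all(dim(confusion) == c(2L, 3L)) ||
      any(abs(rowSums(confusion) - 1) > 1e-8) || any(confusion < 0))
    stop("confusion must be a 2 x 3 row-stochastic matrix")
  folded <- if (is.data.frame(truth)) truth$folded else truth
  stopifnot(is.logical(folded))
  lev <- c("PEAKS_1_2", "PEAKS_3PLUS", "PEAKS_0")
  out <- .withSeed(seed, {
    vapply(folded, function(f)
      sample(lev, 1L, prob = confusion[if (f) 1L else 2L, ]), "")
  })
  out <- factor(out, levels = lev)
  if (is.data.frame(truth))
    names(out) <- truth$peptide_id
  out
}

#' Simulate a two-round SSM selection with planted effects
#'
#' Input counts are multinomial from uniform frequencies over all tracked
#' sequences; each selection round multiplies a variant's relative
#' abundance by `2^(effect / rounds)` and resamples `depth` reads, so after
#' all rounds a variant's expected frequency fold-change relative to a
#' zero-effect wild type is `2^effect` -- the expected estimated enrichment
#' score equals the planted effect.
#'
#' @param plantedEffects named numeric vector of per-sequence log2 effects,
#'   covering every tracked sequence (include the wild type, typically with
#'   effect 0).
#' @param rounds number of selection rounds.
#' @param depth reads drawn per round (and for the input).
#' @param seed RNG seed (`NULL` = ambient stream).
#' @return `data.frame` with `variant_id`, `n_input`, `n_round2`.
#' @export
simulateSsmSelection <- function(plantedEffects, rounds = 2L, depth = 1e6,
                                 seed = NULL) {
  if (is.null(names(plantedEffects)) || !all(is.finite(plantedEffects)))
    stop("plantedEffects must be a named, finite numeric vector")
  stopifnot(depth > 0, rounds >= 1)
  .withSeed(seed, {
    V <- length(plantedEffects)
    nInput <- as.vector(rmultinom(1L, depth, rep(1 / V, V)))
    freq <- nInput / depth
    gain <- 2^(plantedEffects / rounds)
    nRound <- nInput
    for (r in seq_len(rounds)) {
      freq <- freq * gain
      freq <- freq / sum(freq)
      nRound <- as.vector(rmultinom(1L, depth, freq))
      freq <- nRound / depth
    }
    data.frame(variant_id = names(plantedEffects),
               n_input = nInput, n_round2 = nRound)
  })
}

#' Simulate proteins with planted cystine-dense motifs
#'
#' Generates random background proteins (cysteine-free outside the planted
#' region, so every planted motif is the unique maximal cysteine-bounded
#' window) each carrying one planted motif: first and last residue
#' cysteine, a configured total cysteine count, length drawn from
#' `lengthRange` intersected with the 30-50 residue screening window, and
#' optionally one N-X-S/T sequon planted at a recorded position.
#'
#' @param n number of proteins.
#' @param proteinLengthRange min/max full protein length.
#' @param motifLengthRange min/max planted motif length.
#' @param cysCounts candidate cysteine counts per motif.
#' @param glycositeRate probability a motif carries a planted sequon.
#' @param seed RNG seed (`NULL` = ambient stream).
#' @return list with `sequences` (named character vector) and `truth`
#'   (`data.frame`: id, 0-based half-open motif coordinates, cysteine
#'   count, planted sequon position within the motif or `NA`).
#' @export
simulateLibrarySequences <- function(n = 25L,
                                     proteinLengthRange = c(80L, 200L),
                                     motifLengthRange = c(30L, 50L),
                                     cysCounts = c(6L, 8L, 10L),
                                     glycositeRate = 0.5, seed = NULL) {
  stopifnot(n > 0, glycositeRate >= 0, glycositeRate <= 1,
            motifLengthRange[1L] >= 3L,
            proteinLengthRange[1L] >= motifLengthRange[2L])
  bg <- setdiff(AA20, "C")
  pick1 <- function(x) x[sample.int(length(x), 1L)]  # safe for length-1 x
  .withSeed(seed, {
    seqs <- character(n); truth <- vector("list", n)
    for (i in seq_len(n)) {
      plen <- pick1(seq(proteinLengthRange[1L], proteinLengthRange[2L]))
      mlen <- pick1(seq(motifLengthRange[1L], motifLengthRange[2L]))
      k <- pick1(cysCounts)
      motif <- sample(bg, mlen, replace = TRUE)
      motif[c(1L, mlen)] <- "C"
      motif[sample(seq(2L, mlen - 1L), k - 2L)] <- "C"
      glyPos <- NA_integer_
      if (runif(1L) < glycositeRate) {
        free <- which(motif[seq_len(mlen - 2L)] != "C" &
                        motif[seq_len(mlen - 2L) + 1L] != "C" &
                        motif[seq_len(mlen - 2L) + 2L] != "C")
        if (length(free)) {
          g <- if (length(free) == 1L) free else sample(free, 1L)
          motif[g] <- "N"
          motif[g + 1L] <- sample(setdiff(bg, c("P", "N")), 1L)
          motif[g + 2L] <- sample(c("S", "T"), 1L)
          glyPos <- g - 1L
        }
      }
      offset <- sample.int(plen - mlen + 1L, 1L) - 1L
      full <- sample(bg, plen, replace = TRUE)
      full[seq_len(mlen) + offset] <- motif
      seqs[i] <- paste(full, collapse = "")
      truth[[i]] <- data.frame(id = sprintf("SYN%04d", i),
                               motif_start = offset,
                               motif_end = offset + mlen,
                               cys_count = k,
                               glycosite_pos = glyPos,
                               protein_length = plen)
    }
    names(seqs) <- sprintf("SYN%04d", seq_len(n))
    list(sequences = seqs, truth = do.call(rbind, truth))
  })
}
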