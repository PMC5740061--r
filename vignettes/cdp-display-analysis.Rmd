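---
title: "Quantitative analysis of mammalian-display CDP screens"
author: "cdpscreen authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative analysis of mammalian-display CDP screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdpscreen)
```

# The experiment this package models

Cystine-dense peptides (CDPs) are small peptides whose tertiary structure
is pinned by several intra-chain disulfide bonds. In a mammalian
surface-display screen, each library member is expressed as a fusion
tethered to the cell exterior; proper folding is read out two ways:

1. **Surface protein content** -- cells displaying a well-folded peptide
   stain brightly with an antibody against the construct's epitope tag.
2. **Trypsin resistance** -- a folded, disulfide-locked peptide survives
   limited proteolysis; a floppy one is clipped and loses its tag.

Stained cells are flow-sorted into four contiguous fluorescence gates
(`lowest`, `low`, `high`, `highest`) and each gate is deep-sequenced.
`cdpscreen` turns those per-gate read counts -- together with each gate's
sorted-cell count and median fluorescence -- into per-peptide scores,
folding classes, and the statistics used to interpret such screens. A
saturation-mutagenesis module scores single-residue variants of a binder
across selection rounds, and a synthetic-data module generates the whole
experiment with known ground truth.

# The content-score model

Let $r_{ib}$ be the reads of peptide $i$ in gate $b$, $C_b$ the number of
cells sorted into gate $b$ and $M_b$ the gate's median fluorescence. Reads
within a gate are treated as a multinomial sample of that gate's cells, so
the estimated cells of peptide $i$ in gate $b$ are

$$\hat c_{ib} = C_b \frac{r_{ib}}{\sum_j r_{jb}},$$

and the surface protein-content score is the cell-weighted mean of the
gate medians,

$$S_i = \frac{\sum_b \hat c_{ib} M_b}{\sum_b \hat c_{ib}}.$$

This is a deliberately coarse estimator of the average fluorescence of a
cell expressing peptide $i$: it assumes (i) reads are proportional to
cells within a gate, (ii) a gate's cells are adequately summarised by its
median, and (iii) no peptide-specific amplification bias. Its key
algebraic properties, all enforced by tests, are conservation
($\sum_i \hat c_{ib} = C_b$ for every gate with reads), boundedness
($\min_b M_b \le S_i \le \max_b M_b$), scale equivariance in the medians,
and invariance to rescaling any single gate's read counts. Peptides with
no reads are flagged undefined (`NA`), never zero. A `logDomain` option
averages $\log_{10} M_b$ instead and returns $10^{\text{mean}}$, for
analyses that prefer geometric averaging across decades of fluorescence;
the linear form is the default because the target quantity is itself a
linear average.

Trypsin resistance is the guarded percentage
$T_i = 100\, S_i^{\mathrm{treated}} / S_i^{\mathrm{untreated}}$, left
undefined when the untreated score sits below a floor (default 1 % of the
smallest bin median) so that near-noise denominators cannot manufacture
spurious resistance. Values above 100 % are legitimate sampling outcomes
and are flagged `super_resistant` rather than clipped.

Quality control follows the screen's read-abundance logic: a peptide must
reach `perSampleMin` summed reads in every (condition, replicate) sample
and `minInputReads` in the input condition (defaults 20 and 50). The
thresholds are configuration, not constants -- they were chosen
semi-arbitrarily in screens of this kind and must be stated with any
result.

# Folding classes and the statistics around them

**Surface classification.** The HC/TR ("high content and/or trypsin
resistant") versus LC/TS split is a straight line in
$(\log_{10} S,\ T)$ space. The line is an explicit, arbitrary convention:
`classifySurface()` takes `slope` and `intercept` as configuration, ties
on the line go to HC/TR, and `calibrateBoundary()` can recover parameters
from a reference classification by logistic regression when one is
supplied.

**HPLC classes.** A soluble peptide is called well folded (`PEAKS_1_2`)
when, in *both* native and reduced runs, the largest peak holds at least
`dominantFrac` (default 0.5) of the total area and at most one other peak
exceeds `minorFrac` (default 0.05) -- one dominant peak with 0 or 1 minor
peaks. Total native area under `detectionFloor` means failure to secrete
(`PEAKS_0`); everything else is `PEAKS_3PLUS`. The dominant/minor
fractions quantify a qualitative bench rule, so they are exposed as
parameters; requiring both conditions (rather than native only) is the
stricter of the two defensible readings and is the one implemented.

**Concordance permutation test.** The association between surface and
solution folding is tested by the fraction of peptides whose two binary
calls agree, against a null built by uniformly shuffling the HPLC label
vector. Shuffling a binary vector against fixed binary labels only moves
the overlap count of the two "well-folded" sets, which under a uniform
shuffle is hypergeometric; each permutation is therefore drawn with
`rhyper()` and the statistic computed from the implied 2x2 table. This is
distribution-identical to physically permuting the vector (verified in
the tests against exhaustive enumeration for $n \le 7$) and makes the
default $10^6$ permutations -- chosen so the smallest attainable p-value
is $10^{-6}$ -- essentially free. The matched-fraction statistic is the
simplest one consistent with "concordance"; a Matthews-correlation
variant is available through `statistic = "mcc"` and the permutation
scheme is agnostic to the choice. P-values use the
$(k+1)/(n_{\mathrm{perm}}+1)$ estimator, which is slightly conservative;
with one-class HPLC labels every permutation ties and the test returns
$p = 1$ with a warning.

**Chi-square.** Feature cross-tabulations (glycosite presence, native
protein context) use the standard Pearson 2x2 chi-square
(`stats::chisq.test`), two-tailed, continuity correction off by default
since published values of this kind may be computed either way; both
modes are exposed.

**Unweighted GSEA.** Peptides are ranked within each gate by
pseudocounted log2 enrichment over the input pool, and a peptide set
(e.g. the `PEAKS_1_2` class) is tested for clustering at either end with
the classic running sum: $+1/G$ at members, $-1/(N-G)$ elsewhere. The
enrichment score is the signed extremum (ties between equal positive and
negative deviations resolve positive), reaching exactly $\pm 1$ when the
set occupies the top or bottom $G$ ranks; significance is two-sided on
$|ES|$ over random same-size sets. The leading edge is defined as the
members at or before the extremum. The implementation is checked in the
tests against `fgsea`'s unweighted statistic (`gseaParam = 0`).

# Saturation-mutagenesis enrichment

`buildSsmLibrary()` enumerates every single-residue substitution that
does not *introduce* a cysteine; wild-type cysteines are still
mutagenised to the other 19 residues, since removing a disulfide partner
is an informative perturbation. Reads map to variants only on full-length
exact identity (`countExactMatches()`): SSM members differ by one
residue, so tolerant alignment would cross-assign reads; anything not
exactly matching is counted unassigned.

With $V$ tracked sequences (variants plus wild type), pseudocount
$pc = 0.5$ per sequence per round, and counts $n$ over input and the
final round, the score of variant $v$ is

$$E_v = \log_2\frac{(n_{v,R2}+pc)/(N_{R2}+pc\,V)}
{(n_{v,in}+pc)/(N_{in}+pc\,V)} \;-\;
\bigl[\text{the same ratio for the wild type}\bigr].$$

The wild type scores exactly 0 by construction. Enrichment spans input to
after-the-final-round as one ratio -- intermediate rounds are not chained
-- and frequencies are computed over all tracked sequences including the
wild type. `positionAverage()` gives the per-column mean over defined
non-wild-type cells, and `substitutionMatrix()` lays the matrix out as a
conventional heat map with rows grouped by chemical category (nonpolar
aliphatic, aromatic, polar uncharged, positively charged, negatively
charged, then G and P).

# Library curation choices

Motif extraction reports **cysteine-bounded** windows (first and last
residue cysteine) of 30-50 residues containing 6, 8 or 10 cysteines. A
window merely containing the cysteines within a wider span is the other
defensible reading; bounding on cysteines is reproducible and closest to
the idea of a self-contained cystine-dense segment, and the choice is
confined to `scanCysteineMotifs()`. Overlapping windows are collapsed to
maximal ones (a window strictly inside another reported window is
dropped) with a flag to disable collapsing; the exhaustive-substring
oracle in the tests covers both modes.

Sequon scanning defaults to the literal N-X-S/T rule
(`canonical = FALSE`); the canonical rule excluding proline at X is a
flag, and canonical sites are always a subset of literal ones. Context
categories split at 25 % and 50 % of the native protein length with
boundary values assigned upward (0.25 is `P25TO50`, 0.5 is `GE50`).

Taxonomy-weighted sampling flattens classes before weighting: a
candidate's weight is its class weight divided by the class size.
Sampling is two-stage -- pick a class by weight, then a member uniformly
-- because one-shot weighted sampling without replacement does not keep
expected class counts proportional to weights at realistic draw
fractions; the two-stage scheme does, exactly, until a class is
exhausted. Candidates with missing or corrupt lineages are retained as
class `UNKNOWN` with weight 1. Toxin exclusion is an id-blocklist the
caller supplies; no regulatory list ships with the package.

# What the synthetic generator emulates

`simulateSortSeq()` draws per-peptide true mean $\log_{10}$ fluorescences
from a two-component mixture, instantiates cells with log-normal
per-cell noise plus an additive autofluorescence floor, gates the pooled
cells at configured quantiles, and samples reads multinomially per gate.
Defaults define the validation conditions used throughout the tests:

| parameter | default | rationale |
|---|---|---|
| peptides | 2000 | enough for stable rank statistics at test scale |
| folded fraction | 0.17 | matches the observed share of well-folded members in diverse native libraries |
| folded / unfolded mean | $10^{3.5}$ / $10^{2.5}$ a.u. | a 10-fold stain contrast, typical of tag-stained display populations |
| component SDs | 0.3 log10 | broad overlap between states, as in real libraries |
| per-cell noise SD | 0.2 log10 | cell-to-cell expression spread |
| autofluorescence floor | 1 % of folded mean | background staining unaffected by trypsin |
| cells / reads per gate | $4\times10^5$ / $2\times10^6$ | read depth well above cell count, as in sequencing-limited-by-cells designs |
| gates | pooled 25/50/75 % quantiles | four contiguous, exhaustive gates |
| survival factors | Beta(8,2) folded, Beta(2,5) unfolded | resistant-but-imperfect vs mostly-sensitive |

The trypsin condition re-draws cells (an independent aliquot), multiplies
each peptide's surface signal -- not the floor -- by its survival factor,
and re-gates on its own pooled distribution, as a sorter gates each sort.
HPLC labels come from a 2x3 confusion matrix over the latent folding
state: identical rows give exact independence (the calibration null),
an 80 %-diagonal matrix the powered alternative. The SSM generator plants
per-variant log2 effects $e_v$ by multiplying relative abundance by
$2^{e_v/\text{rounds}}$ each round and resampling at depth, so the
expected estimated score equals the planted effect.

The generator does **not** emulate sequencing error profiles, PCR
amplification bias, cytometer spillover or compensation, spike-in
normalisation, or doublets. Passing recovery tests on this synthetic
data therefore demonstrates that the estimators are correct for the
sampling processes they assume, not that those assumptions exhaust real
screens.

Two generator-vs-estimator interactions are worth knowing. First, the
additive autofluorescence floor biases $T$ upward for peptides whose
signal approaches background -- exactly as background staining does in a
real ratio of stains -- so survival-recovery error grows for the dimmest
peptides. Second, four gate medians coarsen the fluorescence axis;
peptides far above the top cut are mutually indistinguishable. Both
effects are visible but small at the default conditions.

# Validation experiments and problem sizes

The test suite re-derives every operation against an independent oracle
(exhaustive substring enumeration, naive per-peptide loops, closed forms,
exhaustive permutation enumeration, `fgsea`, generator ground truth). The
end-to-end experiments, with the sizes the package runs them at:

* content-score recovery at the default conditions: Spearman correlation
  of score vs true mean $\ge 0.95$ among peptides with $\ge 200$ reads;
  cell conservation to $10^{-9}$ relative;
* survival recovery with factors planted at $\{0.25, 0.5, 1\}$: median
  absolute error of $T/100$ at most 0.1;
* permutation-test calibration: type-I error within $[0.03, 0.07]$ at
  $\alpha = 0.05$ over 1000 independent-label datasets of 500 peptides,
  and $p < 10^{-3}$ in $\ge 95\%$ of 200 datasets of 600 peptides at
  80 % planted concordance;
* GSEA null uniformity over 200 random sets (KS test), and extremal
  $ES = \pm 1$;
* SSM recovery at $10^6$ reads per round over the 726 variants of the
  40-residue example wild type: Pearson $r \ge 0.95$, mean absolute
  error $\le 0.15$, wild-type score identically 0.

# Numerical conventions and degenerate inputs

* Undefined scores are `NA` flags everywhere; they propagate, they are
  never imputed as zeros.
* Zero-read gates contribute zero estimated cells.
* A simulation gate that receives no cells (possible only in degenerate
  noise-free configs) yields zero reads with a warning.
* Division floors: trypsin ratio floor defaults to 1 % of the smallest
  bin median; pseudocounts default to 0.5 per sequence.
* Tie-breaks: boundary ties classify HC/TR; GSEA extremum ties resolve
  positive; enrichment rank ties break by peptide id.
* All generators take explicit seeds, restore the caller's RNG state,
  and are bitwise reproducible.

# Limitations

The content score reconstructs a population mean from four medians; it is
a rank-faithful, bounded estimator, not an unbiased mean. Exact-match
variant counting discards reads with indels or sequencing errors rather
than rescuing them. The HC/TR boundary and the HPLC dominant/minor
fractions are conventions to be reported alongside results, not fitted
quantities. The concordance statistic treats peptides as exchangeable;
phylogenetic or family structure in a real library is ignored.
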