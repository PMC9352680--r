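---
title: "Thermodynamic modeling of Pumilio-RNA binding with pufbind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermodynamic modeling of Pumilio-RNA binding with pufbind}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pufbind)
```

## The model

Pumilio-family proteins such as yeast PUF4 recognize single-stranded RNA
through eight pseudo-repeats, each reading out one base, plus a weakly
contributing ninth 3' position. `pufbind` represents this recognition as an
*additive non-consecutive* energy model with 56 terms, all in kcal/mol and
relative to the consensus sequence UGUAUAUAU:

* **Bound terms** $\Delta\Delta G_b^X$ for base $X$ at recognition position
  $b \in 1..9$. Each position's consensus base is 0 by construction
  (consensus normalization), so the consensus sequence scores exactly 0.
* **Flip terms** $\Delta\Delta G_f^Y$ for extruding ("flipping") residues
  between adjacent positions. Only junctions 3/4, 4/5, 5/6 and 6/7 carry
  terms; flips at the remaining junctions are either unmeasurably costly
  (1/2, 2/3) or never competitive (7/8, 8/9), so those junctions contribute
  no configurations. A junction has four single-base terms plus an `NN`
  term for two adjacent residues of any identity.
* Optional **coupling terms** (non-additive corrections for specific
  residue combinations) are applied when a supplied parameter table
  contains them, but are never fitted here — the packaged PUF4 model has
  none.
* An optional **5' extension** adds positions $-2$ and $-1$ (8 more
  single-base terms), used for PUF3-style models that prefer a C two bases
  upstream.

A *binding configuration* is one placement of the bound positions on the
query: a register offset plus a mode (consecutive; one single flip; one NN
double flip; or two single flips at distinct junctions). The relative
ensemble affinity of a sequence is the partition function over all
geometrically valid configurations,

$$\Delta\Delta G_{\mathrm{ensemble}}
  = -RT\,\ln \sum_{r} e^{-\Delta\Delta G_r / RT},$$

with $RT = 0.59248$ kcal/mol (25 °C). Free energies relate to dissociation
constants by $\Delta G = RT \ln (K_D / 1\,\mathrm{M})$; tighter binding is
more negative. With this convention a 2.32 µM dissociation constant is
$-7.69$ kcal/mol, the measurability limit of a titration reaching 409.6 nM
with a 15% minimum detectable bound fraction. (Where a source states
$\Delta G = -RT \ln K_D$ we read it as a sign typo: only the positive-log
convention reproduces that printed pair.)

The hallmark of PUF4 in this parameterization is a *favorable* single-base
flip between positions 6 and 7 (e.g. $-1.34$ for U), so PUF4 prefers the
non-contiguous 10-mer UGUAUAU\*U\*AU over the contiguous 9-mer; all other
flips are penalties. The packaged parameter table is available as
`puf4_model()`; censored terms (lower limits such as ">2.00") are flagged
and, by default, enter predictions at their point values — this keeps the
partition function finite and is conservative for site discovery; a policy
switch (`mode_policy(censored_limit_handling = "infinite")`) removes such
configurations instead. Which choice the original analysis used is not
recoverable from its description; the point-value default changes ensemble
values only in the rare windows where a censored configuration is
energetically competitive.

```{r}
m <- puf4_model()
ensemble_ddg("UGUAUAUAU", m)    # consensus: 0 by construction
ensemble_ddg("UGUAUAUUAU", m)   # flipped consensus: ~ -1.34
```

## Binding-curve inference

Cluster-level fluorescence titrations follow a two-site isotherm with a
specific site and a weak non-specific site (protein binding to the
RNA-protein complex at high concentration):

$$f([P]) = f_{\min} + f_{\max}\,
  \frac{[P]}{[P]+K_D}\left(1 + \frac{[P]}{[P]+K_{D,NS}}\right).$$

Inference is staged as in array-binding practice:

1. **Single-cluster fits** (`fit_single_cluster`): all four parameters
   free, bounded Levenberg-Marquardt on a log-$K_D$ scale with jittered
   restarts plus one deterministic mid-titration start — the
   weak-binding initialization ($K_D$ at the top concentration) otherwise
   has a local optimum for tight binders. $f_{\min}, f_{\max} \ge 0$.
2. **Variant-independent parameters** (`estimate_global_params`): the
   global $f_{\min}$ is the median over per-variant medians; a gamma
   distribution is fitted by maximum likelihood to $f_{\max}$ of the
   tight/precise subset (per-variant SE of $\Delta G$ < 1 kcal/mol, SE of
   $f_{\max}$ below $f_{\max}$, fitted $K_D$ below 15% of the top
   concentration). The subset must beat a 25% chance-pass null at binomial
   p < 0.01, otherwise estimation aborts. Per-variant standard errors are
   computed across that variant's single-cluster fitted values; a variance
   floor (scale $\ge 10^{-6}$) keeps noiseless data from collapsing the
   gamma. The global non-specific energy is the median of per-variant
   medians over converged fits — the per-variant values vary little, so
   the choice of central statistic is immaterial.
3. **Per-variant refit** (`refit_variant`): a single curve is refit to the
   per-concentration median fluorescence with $f_{\min}$ and $K_{D,NS}$
   fixed at their global values. If the median fluorescence at the top
   concentration falls below the lower edge of the central 99.7% interval
   of the $f_{\max}$ gamma, the variant is non-saturated and $f_{\max}$ is
   resampled from that distribution (both for the point fit and per
   bootstrap iteration); otherwise $f_{\max}$ is free. Clusters are
   resampled with replacement 100 times over a canonical sorted order
   (making the result independent of input row order); the 95% CI is the
   percentile interval, widened if necessary to contain the point
   estimate, and $\Delta G_{\mathrm{error}}$ is its width.

## Filtering, replicates, and relative affinities

`filter_variants` applies the three precision filters with strict
inequalities exactly as printed: $\Delta G_{\mathrm{error}} < 1.0$
kcal/mol, $\ge 5$ clusters, $\Delta G < -7.69$ kcal/mol.
`combine_replicates` estimates the systematic between-replicate offset on
the tightest 5% of shared variants (the "highest-affinity binders" are not
defined more precisely by the source; the quantile is configurable),
shifts replicate B, and combines by the inverse-variance weighted mean
with $\sigma_{\mathrm{comb}} = (1/\sigma_1^2 + 1/\sigma_2^2)^{-1/2}$.
`reference_ddg` subtracts the median $\Delta G$ of reference-sequence
occurrences that pass a stricter structural cutoff
($\Delta G_{\mathrm{fold}} > -0.2$), applied after the global $-0.5$
structure filter — the ordering is not stated in the source; applying the
reference-specific cutoff on the already-filtered set is the reproducible
reading.

The structure filter itself (`assess_structure`) is a pluggable *folding
oracle*: a function taking a sequence and a constraint string ('.' free,
'x' forced single-stranded) and returning an ensemble free energy at
25 °C. $\Delta G_{\mathrm{fold}}$ is the unconstrained minus the
constrained energy (never positive); variants with
$\Delta G_{\mathrm{fold}} < -0.5$ kcal/mol are dropped. The default test
oracle is a deterministic mock; `vienna_fold_oracle()` wraps the RNAfold
command line (`-p0 -T25 -C`) when it is installed. For hairpin-stem
scaffolds only the loop region is folded and scored.

## Fitting the energy model

Every configuration's energy is a 0/1 combination of the 56 parameters, so
a dataset's configurations form a sparse design matrix and the ensemble
prediction is a grouped soft-min with an analytic gradient
(`build_design`, internal). Fitting is bounded quasi-Newton (L-BFGS-B)
minimization of the squared prediction error, optionally multi-started
with jittered initializations; the result is never accepted if it is worse
than its initialization.

* `fit_flip_terms`: the 20 flip terms are refit with bound terms fixed,
  initialized at the base model's flips, bounded to $\pm 4$ kcal/mol.
* `fit_full_model`: all 53 non-consensus terms are refit. Bound terms are
  initialized at their observed single-mutant penalties and restricted to
  the larger of $\pm 0.75$ kcal/mol or the penalty's 95% CI half-width;
  mutations unavailable in the data initialize at 0 with $\pm 2.5$; flips
  start at 0 with $\pm 4$; variants are split 50/50 into seeded train and
  test halves, the fit uses the training half, and reports are produced
  for train, test and pooled data (which of these a single published
  statistic refers to is ambiguous, so all three are reported).

**Single-mutant probes are taken in the flipped frame.** Single mutants of
the contiguous 9-mer are poor probes of the bound terms under this model:
a deleterious substitution 3' of the 6/7 junction can be rescued by the
favorable flip (the position-8 U mutant's ensemble penalty is ~0.3 against
a bound term of 1.33), so windows of $\pm 0.75$ around such observations
exclude the truth and the error propagates into the fitted flips.
`single_mutant_table` therefore measures each penalty on mutants of the
*flipped 10-mer consensus* UGUAUAUUAU, referenced to the flipped consensus
in the same scaffold — in that frame the flip is part of the designed
register and the difference isolates the bound term. Position 7 is
frame-ambiguous in the flipped consensus (the flipped residue and bound
position 7 can exchange roles), so its single-mutant values are excluded
from initialization — it initializes at 0 within data-derived bounds.

`sensitivity_scan` varies one term over a grid with the rest fixed and
records the RMSE. Large deleterious terms give asymmetric curves — the
RMSE is flat above the optimum because ensemble alternatives cap the
effective penalty and such substitutions are rare among measurable
variants. When no distinct minimum exists within the grid tolerance
(`plateau_tol`, default 0.005 kcal/mol RMSE), the reported value is the
plateau onset, the grid point nearest the rising side at which the curve
first comes within tolerance of its minimum.

## Genome scanning

`scan_sequence` slides an 11-nt window (13-nt for 5'-extended models) over
both strands of every contig, scoring each window's ensemble over all
registers and enabled modes inside the window; minus-strand windows are
scored on the reverse complement read 5'→3', and windows containing
non-ACGU characters are skipped with a count. The implementation is
vectorized per contig (per-mode score arrays plus sliding Boltzmann sums),
and its output is tested for equality against per-window enumeration.
`select_top_sites` sorts by affinity and greedily removes windows
overlapping a better window (ties broken by coordinate then strand),
keeping sites with $\Delta\Delta G < 4$ kcal/mol (strict; a stated ">4"
retention in one place is read as a typo for the rule used everywhere
else). Overlap is strand-agnostic on genomic coordinates by default — the
source's "overlap in sequence" does not say whether opposite-strand
windows sharing bases compete, and the strand-aware alternative is a flag.
`utr_best_sites` assigns sites fully contained in a same-strand 3'UTR
(longest annotation per gene; partial-overlap assignment is off by
default), `pair_landscape` joins two models' affinities by window or by
per-gene best site, and `bin_enrichment` averages enrichment in 0.5
kcal/mol bins with normal 95% CIs, substituting 0 for predicted-but-
unlisted genes below the 4 kcal/mol threshold.

## The synthetic-data generator

Because the raw array data are not redistributable, every pipeline stage
is exercised against `design_library` / `simulate_true_affinities` /
`simulate_cluster_data`, which emulate the designed-library regime:

* Four scaffolds (two linear, two hairpin-stem whose loop is the scored
  region). Scored flanks are cytidine runs: C is the most uniformly
  penalized base across recognition positions, so flanks neither complete
  cheap alternative registers for mutants nor perturb the consensus
  ensemble — the library-design analogue of using scaffolds to control
  context.
* Variant classes: consensus and flipped consensus; all single mutants in
  the flipped frame (bound-term probes) and the linear frame (register
  analyses); all 324 distinct double mutants plus sampled triples and
  quadruples; 1-5 nt insertions at every junction (all four bases singly;
  sampled pairs and longer runs); 0-3 nt flanking variants. Defaults give
  roughly 4,600 distinct variants, about 2,800 of them within the
  measurable window.
* Ground truth: $\Delta\Delta G$ is the ensemble of the scored sequence
  minus the ensemble of the consensus in the same scaffold, so consensus
  variants are exactly 0; $\Delta G = -12.35 + \Delta\Delta G$ (a 0.88 nM
  consensus). Titrations follow the two-site isotherm with $f_{\min} =
  0.0134$, $\Delta G_{NS} = -8.49$ kcal/mol, cluster counts of 5 plus a
  Poisson(15) excess, per-cluster $f_{\max}$ drawn from a Gamma with mean
  1 and CV 10% (the fitted distribution's parameters are not published;
  this is a realistic array-to-array spread), and additive Gaussian
  fluorescence noise.
* Replicate pairs shift replicate B's true $\Delta G$ by a systematic 0.1
  kcal/mol before simulation.

What the generator does *not* emulate: secondary-structure effects on
binding (the structure filter is tested with a mock oracle; an engine can
be attached for real data), sequence-dependent cluster intensity,
position-specific noise, or coupling between recognition positions.
Passing tests therefore demonstrate correctness of the inference machinery
under the stated generative model, not robustness to every artifact of
real array data.

## Problem sizes and numerical choices

Test and acceptance runs use deliberately chosen problem sizes: full-model
recovery uses the default ~4,600-variant library with $\sigma = 0.3$
kcal/mol observation noise (the replicate-level uncertainty regime); the
20-seed flip-sign check uses a reduced per-seed library (singles,
insertions, flanks, and the 324 doubles — about 1,500 measurable variants)
with the flip-refit stage, which pins the flip signs as well as the full
fit at a fraction of the cost; curve-fitting calibrations use tens of
variants with 5-20 clusters each. Optimizer settings: L-BFGS-B with
`factr = 1e6` and up to 3,000 iterations (looser tolerances demonstrably
stall short of the SSE optimum on this likelihood); curve fits use
`nls.lm` with up to 300 iterations. Ties in `best_register` and in greedy
site selection resolve to the smallest offset/coordinate. Ambiguous bases
make a window unbindable rather than erroring, so genome scans skip
N-runs. All randomness flows from explicit integer seeds through a
restore-on-exit RNG guard, so library calls never perturb the caller's
RNG stream.

## Known limitations

* Coupling terms are applied but never fitted; datasets generated with
  coupling will fit systematically worse.
* The bootstrap CI is the percentile interval; bias-corrected variants are
  not implemented (the method description does not specify one).
* The per-variant "standard error of $\Delta G$" entering the tight-subset
  rule is computed across single-cluster fits; with very few clusters it
  is itself noisy.
* Censored flip limits as point values understate those penalties; the
  infinite-penalty policy overstates them. Windows where this matters are
  rare but exist.
* The genome scanner holds per-contig score arrays in memory; contigs of
  hundreds of megabases should be scanned in chunks.
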