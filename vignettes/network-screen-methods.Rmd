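---
title: "Methods: network-centric screening for NF-kB pathway inhibitors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network-centric screening for NF-kB pathway inhibitors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nfkbscreen)
```

## The problem

Target-centric drug discovery struggles with signaling pathways whose
activity depends on protein-protein interactions rather than a single
druggable enzyme. TNF-induced NF-kB signaling is the motivating case: after
TNF ligates its receptor, a multi-protein complex (TRADD, TRAF2/5, RIP1,
ubiquitin machinery, IKK) assembles and drives nuclear translocation of the
transcription factor RelA. `nfkbscreen` implements a network-centric
alternative: find compounds whose *transcriptional* consequences resemble
the consequences of genetically removing pathway proteins, then verify
candidate hits biophysically (thermal shift) and functionally (live-cell
NF-kB dynamics).

The package is organised as an analysis workflow: every computation lives in
exported functions, and the numbered drivers under `analysis/` narrate one
simulated end-to-end screen.

## Connectivity features

The screen's unit of evidence is a differential-expression z-score
*signature*: one vector over a fixed gene universe per (perturbagen, cell
line), where a perturbagen is either a compound treatment or a gene
knockdown (KD). For each compound--KD pair in each shared cell line the
package computes five features:

* **direct correlation** — the Pearson correlation between the two
  signatures over the *full* gene universe. No gene filtering is applied:
  the correlation is a signature-level statement, and subsetting would
  entangle it with pathway annotation quality.
* **indirect correlation** — the fraction of the KD protein's interaction
  partners (from an undirected protein-interaction network) whose own KD
  signatures in that cell line correlate with the compound signature at or
  above a threshold `r_threshold`. The default is 0.3; because no canonical
  cutoff for "highly correlated" exists, the threshold is an explicit
  config knob and the test suite checks that the feature is monotonically
  non-increasing in it, so downstream conclusions are threshold-robust.
  Partners without a KD signature in the relevant cell line are excluded
  from the *denominator*: the feature is a fraction of observable partners,
  which avoids penalising sparse libraries. A KD gene with no observable
  partner yields `NA`, never 0 — a missing fraction and a fraction of zero
  are different statements.
* **baseline activity** — the mean |z| of the compound signature, a
  magnitude summary of how transcriptionally active the compound is at all.
* **max / mean pathway differential expression** — the maximum and mean |z|
  of the compound signature restricted to a pathway gene set (here, the
  NF-kB/TNFR1 genes).

Features are computed per cell line ("cell-specific"); perturbagens must be
profiled in at least `min_cell_lines = 4` cell lines to enter the table. At
the full scale of the motivating screen (1680 compounds, 3104 KDs, all
surviving the filter) the enumeration is 1680 x 3104 = 5,214,720 pairs,
which `full_scale_pair_count()` reproduces by arithmetic on the metadata.

## Target prediction and candidate ranking

A random forest (`randomForest`, 500 trees by default, seeded) maps the
five features of labeled (compound, target) pairs to an interaction
probability. Per-cell-line rows are reduced to one row per pair before
training; the reduction (mean by default; median and max available) is a
config knob because scoring happens at pair level while features are
cell-specific. Missing indirect correlations are filled with the training
median of the feature — an explicit, recorded imputation rather than a
silent zero.

Downstream of the classifier:

* `top_predicted_targets()` extracts the k highest-probability targets per
  compound (k = 100 by default at screen scale). All ties everywhere are
  broken by lexicographic id so that reruns are bit-identical.
* `pathway_target_enrichment()` scores the overlap of a predicted-target
  list with the pathway set by the upper-tail hypergeometric probability —
  the standard null for set overlap; the test suite pins it to exhaustive
  enumeration on small universes.
* `seed_gene_filter()` implements the initial screen: a compound passes if
  its mean direct correlation with the KDs of *each* seed gene (the
  receptor-proximal adaptors) reaches `r_min`. The conjunctive reading is
  the default because the screen demands resemblance to every adaptor
  knockdown; an "any" mode is available.
* `rank_by_mean_pathway_correlation()` ranks surviving candidates by their
  mean Pearson correlation with all pathway KD signatures across shared
  cell lines. Compounds with no shared cell line are flagged and placed
  last rather than dropped.

## Single-cell NF-kB dynamics

Live-cell experiments report nuclear fluorescence of tagged RelA every 5
minutes. Each cell is self-normalised: fold change is intensity divided by
the mean intensity over a 30-minute pre-stimulus window (the imaging
protocol acquires at least 30 min of baseline). Five descriptors summarise
each fold-change trajectory: AUC, Max, t_max, Rate_in and Rate_out.

Numerical choices, made once and recorded here:

* AUC integrates (fold change − 1), not fold change, from the stimulus to
  the last frame (trapezoidal rule): a non-responding cell must score 0.
  Negative excursions are included. If the stimulus falls between frames,
  the curve is linearly interpolated at the stimulus time so the interval
  starts exactly there.
* Rates are maximal single-interval finite differences — Rate_in on
  [stimulus, t_max], Rate_out (magnitude) on [t_max, end] — without
  smoothing by default, because "maximal rate" is the definition; a
  3-frame moving-average pre-filter is available for noisy data.
* Ties in the maximum resolve to the earliest frame; a trace ending at its
  maximum gets Rate_out = 0 with `decay_observed = FALSE`.
* Cells with max fold change below 1.05 are flagged non-responders but
  retained, mirroring how flat trajectories remain in published single-cell
  plots. Cells failing structural preconditions (no pre-stimulus frame,
  fewer than 3 frames, non-positive baseline) are dropped with a recorded
  reason and counted.

## Permutation testing

Conditions are compared per descriptor with a permutation test on the
difference of means: pool both groups, redistribute into size-preserving
pseudo-groups without replacement, and count permutations at least as
extreme as the observation. Two design points deserve emphasis:

* The test is **two-tailed via |delta|**: a permutation counts when
  |Δmean_perm| ≥ |Δmean_obs|. A literal directional rule
  (Δmean_perm ≥ Δmean_obs) is available as `alternative = "greater"`, but
  the two-tailed absolute-value rule is the default because the reported
  quantity is a two-tailed p value; equality (ties) counts as exceedance,
  which is conservative.
* Monte-Carlo p values use the **add-one estimator**
  (exceed + 1)/(B + 1), so p is never 0 and the smallest reportable value
  at B = 10^6 permutations is just above 10^-6 — the natural floor for
  "p < 10^-6" claims. `exhaustive_permutation_test()` enumerates all
  partitions exactly (pooled size ≤ 20) and reports the raw fraction; it is
  the oracle against which the Monte-Carlo path is tested, and the type-I
  error of the Monte-Carlo test is calibrated against the nominal level
  over a thousand null simulations in the acceptance suite.

The default B = 10^6 matches the intended use; the test suite uses
10^4--10^5 for speed. The inner loop is compiled (Rcpp) and driven by R's
RNG, so results are reproducible from `set.seed()` semantics.

## Melt-curve analysis

Thermal-shift assays ramp temperature (25--99 °C at 0.05 °C steps by
default) while recording dye fluorescence; ligand binding shifts the
unfolding midpoint Tm to higher temperature. The pipeline:

1. **Truncate after the global fluorescence maximum** (on by default):
   real dye curves decay after the transition as unfolded protein
   aggregates, and retaining the decay would corrupt min-max scaling.
   Truncation is a flag because a clean sigmoid makes it a no-op.
2. **Min-max normalise** the retained segment to exactly [0, 1].
3. **Estimate Tm.** The default reads the midpoint literally: the first
   upward 0.5 crossing, linearly interpolated between bracketing samples
   (later crossings set a flag). A **Boltzmann-fit mode**
   (`method = "fit"`, via `minpack.lm`) fits
   a + (b − a)/(1 + exp(−(T − Tm)/k)) and reports the fitted Tm. The fit
   mode is the right estimator for noisy curves: with ~1500 grid points, a
   point-wise threshold rule is an extreme-value statistic — some early
   point fluctuates above 0.5 well before the true midpoint — and its
   early-crossing bias exceeds the acceptable error already at noise
   levels of a few percent of the amplitude, while the fit pools all
   points and recovers Tm to well under 0.1 °C at 2% noise.
4. **ΔTm** is Tm(sample) − Tm(reference), antisymmetric by construction;
   replicate pairs are summarised as mean ± range (not SD), the honest
   summary for n = 2.

## The synthetic-data generators

Every stage is exercised on generated data with planted ground truth; the
generators are first-class, tested code, and their defaults are the study
conditions used throughout.

**Signatures** are low-rank plus noise: genes belong to latent modules
(round-robin assignment, so the KD panel covers modules evenly and module
membership is transparent), each module has a dense Gaussian loading vector
over the whole universe, and a perturbation of gene g expresses
`effect_size x loading[module(g)]` plus i.i.d. N(0, noise_sd²) per gene.
A compound with planted target t expresses t's module loading; decoys are
pure noise. Defaults: 978 genes (the landmark-gene scale), effect_size = 3
and noise_sd = 1, i.e. strong-perturbation z-scores of a few units against
unit noise. The low-rank construction is deliberate: the pipeline consumes
only correlations, and this is the simplest model whose correlation
structure is controllable — a compound correlates with its target's KD
*and* with KDs of the target's module co-members, which is exactly the
guilt-by-association confound the classifier must tolerate.

**Networks** are planted-partition graphs: dense within declared modules
(`intra_module_prob`), sparse elsewhere (`edge_prob`), undirected, no
self-loops.

**Traces** follow 1 + A·f_inh·u·e^(1−u) with u = (t − t0)/τ_r — a smooth
pulse that is exactly 1 + A at t0 + τ_r, the canonical transient of
TNF-driven nuclear RelA. Defaults: τ_r = 30 min and t0 = 30 min (nuclear
RelA peaks roughly half an hour after TNF, and imaging acquires ≥ 30 min
of baseline), A = 2 (2--3x nuclear accumulation typical of tagged-RelA
reporters), 5-min frames, 360-min movies (so the integration window
exceeds 10 rise times and the truncated AUC tail is negligible),
measurement noise SD 0.05 fold-change units. Cell-to-cell variability is
lognormal jitter on A (sdlog 0.25) and τ_r (sdlog 0.15) — two parameters
that reproduce the visual spread of published single-cell trajectories —
and compound pretreatment is a multiplicative `inhibition_factor` on A.

**Melt curves** are logistic sigmoids on the instrument's ramp with
additive Gaussian noise; slope k = 2 °C gives transitions of realistic
width.

Seeding: all generators take explicit seeds and `derive_seed(master,
offset)` derives per-stage substreams from one master seed, so stages can
be regenerated independently and every analysis is reproducible from one
integer.

### What the generators do not emulate

The signature model has no replicate structure, no moderated-z
preprocessing, no batch or plate effects, no landmark-to-transcriptome
imputation, and module loadings are Gaussian rather than biological
co-expression. The trace model has no oscillatory late-phase NF-kB
dynamics, no segmentation or tracking artifacts, and Gaussian rather than
heavy-tailed measurement noise. The melt model is strictly two-state.
Passing tests therefore demonstrate that the *computations* are correct
and that planted signal of stated strength is recovered under controlled
conditions — not that the pipeline's biological conclusions transfer to
any particular real dataset.

## Problem sizes and tolerances

The simulation studies use library sizes chosen to make planted-signal
recovery a meaningful statistical question while keeping any run casually
repeatable on a laptop: 300-gene universes with 60 compounds (30 planted)
and a 40-KD panel across 4 cell lines for classifier recovery; 20
replicates of a 60-compound ranking study; 1000 null datasets at 10^4
permutations for type-I calibration; 50 noisy melt curves for Tm recovery.
Closed-form descriptor checks tolerate 1% on the AUC (the documented
trapezoid discretisation error at 5-min frames and τ_r = 30 is ~0.25%, and
the >10·τ_r window bounds the truncated tail at ~0.14%). Floating-point tie
detection in the permutation kernel uses a relative 10^-12 guard.

## Known limitations

* The quantitative definitions behind two screen-level constants of the
  motivating study — the exact correlation cutoff that defines a "strong"
  seed-gene correlation, and the enrichment threshold used to shortlist
  compounds — are not published; both are config knobs here
  (`r_min`, and the caller's p-value cutoff), not reproduced constants.
* `baseline_activity` formalises "baseline drug activity" as mean |z|, the
  simplest magnitude summary consistent with that phrase; alternatives
  (signature norm, count of |z| > 2) would be drop-in replacements.
* The classifier aggregates cell lines before training; a per-cell-line
  model with late fusion is a possible extension the config deliberately
  leaves open.
* Permutation tests are reported without multiple-testing correction
  across descriptors, matching the intended reporting convention; callers
  comparing many conditions should adjust externally.
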