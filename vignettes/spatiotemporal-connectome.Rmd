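---
title: "Spatiotemporal connectome analysis: model, metrics and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatiotemporal connectome analysis: model, metrics and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stconnectome)
```

## The model

Static functional connectivity averages away the temporal structure of
brain activity. The spatiotemporal connectome recovers it by treating
activity as discrete events propagating over the anatomical backbone.
Three ingredients define the model:

1. **A point process per region.** Each parcellated BOLD series is
   z-scored with its own mean and sample (n − 1) SD and binarized at
   `z >= 2` (one-sided). The 2 SD convention comes from the point-process
   literature for resting-state fMRI; at that threshold i.i.d. Gaussian
   noise activates `1 − Φ(2) ≈ 2.28%` of cells, a useful calibration
   check. Only positive deflections count: supra-threshold events, not
   de-activations, carry the propagation signal. Zero-variance regions are
   defined inactive rather than undefined.

2. **A structurally constrained multilayer graph.** Nodes are active
   cells `(region, frame)`. Edges require temporal proximity
   (`|Δt| <= 1`) *and* anatomical support: either the two regions share a
   binarized structural edge (same frame or consecutive frames), or they
   are the same region in consecutive frames. The self-continuity edge is
   a deliberate addition — without it a persistently active region would
   fragment into disconnected per-frame pieces — and can be switched off
   (`include_self = FALSE`).

3. **Weakly connected components (CCs).** Each component is a transient
   event, summarised by its spatial activation vector `x` (frames active
   per region), its **length** = `t_max − t_min + 1` (we use the inclusive
   frame span, not the count of distinct active frames; the two coincide
   for temporally contiguous events and the span better matches
   "duration"), its **height** = involved regions / N, and its size.
   Components with fewer than `min_cc_size = 2` nodes are discarded but
   counted: a single-node "component" carries no connectivity information.
   All group statistics can be re-run at `min_cc_size = 1` to test
   sensitivity to this choice.

## Diversity metrics

Regions are labelled with eight functional systems (VIS, SM, DA, VA, LIM,
FP, DM, CBL). A component's **system embedding** is its activation mass
summed per system; mass is conserved (the embedding sums to the component
size).

**System diversity (SD)** is the mean over pooled components of the
normalized entropy `−Σ p_f ln p_f / ln 8` of each component's system
distribution. We use the natural log normalized by `ln 8` so SD lives in
[0, 1] regardless of how many systems are present. SD is the *mean of
per-component entropies*, not the entropy of the pooled histogram — the
metric asks how integrated individual events are, not how evenly the
group's total activity covers systems. The pooled-histogram variant is
available (`sd_variant = "pooled_hist"`). A convenient corollary of the
mean form: a merged pool's SD is the component-count-weighted mean of its
sub-pools' SDs.

**Spatiotemporal diversity (STD)** asks how *polyvalent* regions are: for
each region occurring in at least two pooled components, compute the mean
pairwise cosine similarity between the unit embeddings of those
components, subtract from 1, and average over qualifying regions. Low STD
means a region keeps appearing in events of the same system composition —
stability over time. Because embeddings are nonnegative, cosines lie in
[0, 1] and so does STD. The mean pairwise cosine of unit vectors
`u_1..u_n` is computed in closed form as `(||Σu||² − n) / (n(n − 1))`,
which the tests verify against an explicit all-pairs loop to 1e−10. An
all-component-pairs variant that ignores region anchoring is exposed as
`std_variant = "all_pairs"`. STD is implemented as a *dissimilarity*
(1 − cosine): that orientation is the only one under which "lower STD"
and "higher stability" are the same statement.

Both metrics are group-level: single subjects rarely contribute enough
components for stable estimates, which is also why the permutation test
reassigns whole subjects.

**System scales.** Each component is attributed to every system containing
at least 20% of its involved regions (share of *distinct* regions, not of
activation mass). Attribution is multi-membership by design — a genuinely
bi-system component belongs to both scales. The maximal-share system is
always attributed even below 20%, so no component is orphaned; the cases
where this fires are logged in the attribution matrix. SD and STD are then
computed per system on the attributed sub-pools, with sub-pools too small
for a metric flagged `insufficient_data` rather than erroring.

## Group inference

**Permutation test.** The observed statistic is the difference in a pooled
group metric (SD or STD, at one scale). The null distribution reassigns
whole subjects to groups, preserving group sizes — subjects, not
components, are exchangeable, because components within a subject are
dependent. The two-tailed p-value uses add-one smoothing,
`p = (1 + #{|Δ_perm| >= |Δ_obs|}) / (n_valid + 1)`, so `p > 0` always and
`p >= 1/(n_valid+1)`. Permutations for which a metric is undefined (an
empty sub-pool after relabeling) are dropped and counted; the observed
pools must be defined or the test errors. A with-replacement bootstrap
variant exists behind `method = "bootstrap"` but the label permutation is
the default and the calibrated choice. Default 1000 permutations.

**FDR.** The eight per-system p-values are BH-adjusted separately for SD
and for STD (two families of eight), matching how per-metric system tests
are conventionally reported; a pooled-16 correction would mix two
different hypotheses families.

**ANCOVA.** Per-subject component number, mean length and mean height are
each regressed on group, mean-centered age and their interaction, with
effect-coded group (+1/−1) and Type-III marginal F tests. Under this
parameterization every term has `F(1, n − 4)` regardless of group
imbalance. Subjects with undefined responses (no retained components) are
excluded and counted. The implementation (base `lm` + `drop1`) is verified
against explicit projection-matrix F statistics to 1e−8.

## The synthetic cohort generator

No raw imaging data ships with the pipeline, so validation rests on a
generator that emulates the essential structure of the real inputs:

* **Parcellation and structural template.** Regions are assigned to the
  eight systems (default 506 regions split 66/66/60/60/50/70/90/44) and a
  stochastic block model draws one symmetric streamline-count matrix
  shared by all subjects (within-system edge probability `p_in = 0.35`,
  between `p_out = 0.05`), mirroring the use of a single group-mean
  structural connectome.

* **Cascades.** Activity is a superposition of events: seeds arrive as a
  Poisson stream (rate `0.002 · N` per frame — constant per-region rate so
  reduced-size studies keep the full-size sparsity of a few percent of
  cells, comparable to the 2 SD tail mass), each cascade has a *home
  system* and spreads per frame along binarized structural edges with
  probability `spread_prob = 0.25` into its home system, damped by the
  cross-system coupling `eta` (default 0.1) elsewhere. Active regions
  survive per frame with `persist_prob = 0.5`. Only never-involved regions
  can be recruited, and each cascade's distinct-region count is capped, so
  every event has finite duration and bounded extent. Because spreading
  never leaves the binarized structural graph, every within-cascade
  co-activation is structurally backed — planted ground truth for the
  component extractor.

* **Planted contrasts.** `eta` raises the off-home activation mass of
  components, hence SD. `drift_prob` (rho) is the stability knob: with
  that per-frame probability a cascade re-homes onto a structurally
  adjacent region of another system and goes silent for one frame, so its
  continuation — the new seed plus one carried-over old region — forms a
  *separate* component dominated by the new system but sharing regions
  with the old one. That is precisely what raises region-anchored STD.
  (Design note: variants in which the drifted continuation carries many
  old regions, or none, fail to raise STD — they either converge to
  similar multi-system blends or produce pure pieces that dilute each
  region's component list with self-similar entries. The single-region
  carryover with a fresh extent budget is the variant whose STD response
  is monotone across the tested grid, and the package pins that
  monotonicity in a property test.) An `age_effect` coefficient shrinks
  the extent cap multiplicatively, `cap = max_extent · exp(age_effect ·
  (age − 10))`, planting an age effect on component height; the validation
  suite plants `age_effect = −0.10` (≈ 10% shrink per year), which yields
  > 80% ANCOVA power at n = 200 while the group term stays at its nominal
  5% size. Cascade parameters may be given per group (length-2 vectors).

* **BOLD mode.** The binary raster is convolved with a fixed
  gamma-difference kernel (unit peak one frame after the event, mild
  undershoot) and Gaussian noise is added. At noise up to 0.2 × the kernel
  peak, thresholding the result at 2 SD recovers > 80% of planted cells at
  the kernel's one-frame lag with < 5% of all cells spuriously active.
  Note one inherent property: z-scoring is scale-invariant, so rows with
  no events activate at the 2.28% Gaussian tail rate no matter how small
  the noise — the spurious-cell bound is a bound on that fraction, not
  zero.

**What the generator does not emulate:** haemodynamic variability across
regions, head motion, physiological noise structure, spatial
autocorrelation of the BOLD field, or empirically realistic component
size distributions (no published distribution exists to match). Passing
tests therefore demonstrate correctness of the *pipeline mechanics and
statistics* — extraction equals a brute-force oracle, the permutation
test is calibrated, planted effects of known direction are recovered —
not that real cohorts will show any particular effect.

## Numerical and design choices

* Threshold comparisons are inclusive (`z >= threshold`); structural
  binarization is strict (`weight > sc_threshold`, default 0).
* Region indices are 0-based in files, 1-based internally; frames are
  columns; component length is an inclusive frame span.
* Entropy terms with `p_f = 0` contribute zero; embeddings are normalized
  only when nonzero.
* Cosine means are clamped to [0, 1] against floating-point drift before
  the 1 − · step.
* All randomness flows through explicit seeds in local RNG scopes;
  identical configuration + seed reproduces cohorts and written reports
  byte for byte (reports exclude paths and carry a config hash).
* Permutation streams inside a full study derive one seed per test
  (`seed + test index`) so single tests can be reproduced in isolation.

## Problem sizes used in validation

The validation suite runs at reduced dimensions chosen to preserve the
full-size activation sparsity: oracle comparisons at N ≤ 12, T ≤ 15 (200
random instances); null calibration with 500 replicate studies of 10 + 10
subjects at N = 40, T = 120 and 200 permutations; effect recovery with 10
replicate studies of 20 + 20 subjects at N = 64, T = 120; ANCOVA power
with 200 replicates of 200 subjects at N = 40, T = 60. The per-region
seeding rate makes these regimes comparable to a 506-region, 720-frame
study in density and component geometry, at a small fraction of the cost.

## Known limitations

* SD/STD have no subject-level analogue here (by construction of the
  pooled metrics), so brain–behaviour correlations are out of reach.
* The 20% attribution rule can assign one component to several systems;
  per-system pools therefore overlap and their tests are not independent
  — another reason FDR is applied within metric families.
* `length` uses the frame span; a component that goes silent mid-span
  (possible via multi-path reconnection) counts the silent frames.
* The permutation test conditions on the observed component sets; it does
  not model within-subject resampling variability.
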