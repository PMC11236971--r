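# stconnectome

Spatiotemporal connectome analysis of parcellated brain activity in R.

Resting-state fMRI is usually summarised as a static connectivity matrix,
which discards when and how activity propagates. The spatiotemporal
connectome keeps that information: regional time series are reduced to a
binary point process, joined across space and time under a structural
(white-matter) prior, and decomposed into transient co-activation events
whose system composition can be compared between groups. This package
implements that pipeline end to end for parcellated data (no imaging
formats required), together with the group statistics used in developmental
cohort comparisons and a synthetic cohort generator with plantable effects,
so every stage can be validated against ground truth without any scan data.

## The method

**Point process.** Each region's series is z-scored (own mean, sample SD);
region *i* is *active* at frame *t* when `z(i,t) >= 2` (one-sided,
threshold configurable). Zero-variance regions are never active.

**Multilayer graph.** Nodes are active cells `(i, t)`. An undirected edge
joins `(i,t)` and `(j,t')` iff `|t - t'| <= 1` and either `i = j`
(temporal self-continuity) or regions *i* and *j* are structurally
connected (binarized weight > 0 in a shared structural connectome).

**Connected components (CCs).** Weakly connected components of this graph
are transient activity events. For each CC: the spatial activation vector
`x` (`x_i` = number of frames in which region *i* is active within the
CC), its **length** (inclusive frame span), **height** (fraction of all N
regions involved) and **size** (node count). Components below a minimum
size (default 2) are discarded but logged.

**System diversity (SD).** Each region belongs to one of eight functional
systems (VIS, SM, DA, VA, LIM, FP, DM, CBL). A CC's activation mass per
system gives a distribution `p_f`; its normalized entropy is
`H = -Σ p_f ln p_f / ln 8`, and SD of a pool of CCs is the mean `H`.
Higher SD = more cross-system integration.

**Spatiotemporal diversity (STD).** For every region appearing in ≥ 2
pooled CCs, 1 − (mean pairwise cosine similarity between the unit system
embeddings of those CCs), averaged over qualifying regions. Lower STD =
more stable system composition over time.

Both metrics run at the global scale and per system, attributing each CC
to every system holding ≥ 20% of its involved regions (the maximal-share
system is always attributed).

**Group inference.** Two-group comparison by subject-level permutation
(whole subjects are reassigned, CC pools rebuilt, metric difference
recomputed; two-tailed p with add-one smoothing), BH-FDR across the eight
per-system tests separately per metric, and ANCOVAs of per-subject CC
number / mean length / mean height on group, age and their interaction
(Type-III F, effect coding, centered age: `F(1, n − 4)` per term).

## Worked example

```r
library(stconnectome)

# two groups of 20 subjects; group A has stronger cross-system coupling
p <- sim_params(n_regions = 64, regions_per_system = rep(8L, 8),
                n_subjects_A = 20, n_subjects_B = 20, n_frames = 120,
                cross_system_coupling = c(0.8, 0.1), seed = 1)
cohort <- generate_cohort(p, mode = "raster")
study  <- analyze_cohort(cohort, list(n_perm = 1000, seed = 1))
print(study)
```

```
Spatiotemporal connectome study: 40 subjects, 407 components
  global SD: A = 0.5412, B = 0.1691, p = 0.000999
  global STD: A = 0.4212, B = 0.3659, p = 0.000999
  ANCOVA height ~ age: F(1, 36) = 0.069, p = 0.7942
```

Group A's pooled components spread their activation mass across systems
(SD 0.54 vs 0.17; permutation p at the 1/(1000+1) floor), as planted. The
age ANCOVA is null here because no age effect was planted. Per-scale
tables live in `study$tests` (18 permutation tests with q-values) and
`study$group_metrics`; `write_study(study, "out/")` writes the CSV report.

A file-based workflow is available through the bundled CLI
(`inst/scripts/stconnectome`): `simulate`, `extract`, `metrics`, `stats`,
`run` subcommands over TSV/CSV inputs; see `--help` for flags and
coordinate conventions.

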