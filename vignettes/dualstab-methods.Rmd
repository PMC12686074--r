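---
title: "Dual-state stability profiles for missense variant prioritization: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-state stability profiles for missense variant prioritization: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualstab)
```

## The model

`dualstab` prioritizes missense variants of conformationally regulated
proteins — the motivating case is a Janus-family kinase whose pseudokinase
(PK) domain autoinhibits the tyrosine kinase (TK) domain in a *closed*
state that is in equilibrium with a catalytically active *open* state.
The working hypothesis is that pathogenic (often gain-of-function)
variants separate from benign ones in a feature space combining:

* sequence-based pathogenicity and functional scores (CADD,
  AlphaMissense, ESM1b, PolyPhen-2, SIFT, MutFunc, ClinPred), and
* the computed change in folding free energy (ΔΔG) of *each*
  conformational state upon mutation.

No supervised training is involved. Variants are clustered two ways in
standardized feature space, and the cluster identity is interpreted
through external evidence: population-catalog membership (frequent
presence in a gnomAD-style catalog marks the *benign-like* cluster) and
known gain-of-function *anchor* variants (expected in the
*pathogenic-like* cluster). Query variants are then classified by nearest
cluster centroid.

All ΔΔG values are normalized on ingestion to a single internal
convention — **negative = destabilizing** — because stability predictors
disagree on sign; every input table must declare its convention, and
flipping a convention twice restores the original values.

## Pipeline stages and their parameters

| Stage | Parameter | Default | Why |
|---|---|---|---|
| imputation | policy | per-feature median | robust; keeps all `19 × L` rows clusterable; every imputed cell is masked |
| standardization | sd denominator | `n − 1` (sample sd) | stated explicitly so recomputation is unambiguous |
| kNN graph | `k` | 6 | the network-display convention of joining each variant to its 6 nearest neighbors |
| clustering | method | `kmeans2`, 25 seeded restarts | centroid-based two-way split; deterministic given a seed |
| clustering (alt.) | `knn_community` | Louvain on the kNN graph, merged to 2 | graph-native alternative; communities merged by centroid-linkage hierarchy |
| stability classes | `tau` | 1.0 tabulated energy units | magnitude below which a ΔΔG is treated as neutral; no published cutoff exists, so it is configurable |
| ligand affinity | `tau_lig` | 0.5 in −log10(KD/Ki) | roughly a 3-fold affinity change; inclusive at the boundary |
| contacts | `cutoff_contact` | 5.0 Å | common heavy-atom contact radius |
| hydrogen bonds | `cutoff_hbond` | 3.5 Å | donor/acceptor (N/O) heavy-atom distance proxy, no angle term |
| superposition | `prune_cutoff` | off (2.0 Å typical) | iterative worst-pair removal emulates "pruned-atom" robust fits |

Distances are Euclidean on z-scored features: unit variance makes the
metric scale-free across heterogeneous score ranges, and nothing in the
problem motivates a different metric. Features are z-scored but **not**
sign-reoriented before clustering — clustering is orientation-agnostic —
while each feature's declared orientation (higher- vs lower-is-damaging)
is kept as metadata for reporting.

Determinism is a design requirement, not an afterthought: every stochastic
stage takes a mandatory seed that is recorded in its result, distance ties
in the kNN graph break toward the lexicographically smaller variant key,
cluster ids are renumbered so cluster 1 contains the smallest variant key,
and identical inputs plus seed reproduce results byte-for-byte.

## Stability classification

Given `(ΔΔG_open, ΔΔG_closed)` in the internal convention and a threshold
`tau`, [classify_stability()] maps the plane exhaustively and mutually
exclusively:

* `open_shift_stabilizing` if `ΔΔG_open ≥ +tau` — the variant stabilizes
  the active conformation. This takes precedence over concurrent
  closed-state destabilization because an open-shift is the
  mechanistically decisive signal for gain of function; the compound
  pattern is still visible as `closed_destab_open_shift` in the detailed
  record.
* `destabilizes_both` if both values `≤ −tau`;
* `destabilizes_closed_only` / `destabilizes_open_only` if exactly that
  state crosses `−tau`;
* `neutral` otherwise (including a *stabilized* closed state, which is
  not a recognized pathogenic pattern here).

Per-predictor classes are combined by strict-majority vote
([consensus_stability()]); without a strict majority the consensus is
`ambiguous`. The vote is permutation-invariant in predictor order.

## Cluster labelling and enrichment

The benign-like cluster is the one with the higher *fraction* of
catalog-flagged variants. Anchors are never used to relabel silently: an
anchor found in the benign-like cluster is reported as a conflict with a
warning. An exact 50/50 flag split falls back to the anchor majority and
is an error when no anchors exist.

Enrichment is tested on the 2×2 table (flagged × cluster) with the exact
hypergeometric two-sided test; the odds ratio is the plain cross-product
ratio `ad/bc`, with the Haldane–Anscombe `+0.5` applied to all cells only
when some cell is zero. In reports, the benign-like cluster is printed
first ("Cluster 1"), matching the usual orientation of such tables.

## Structural geometry

* **Superposition** pairs atoms by (chain, residue number, atom name) —
  no alignment fallback in this version — and uses the Kabsch SVD fit
  with a proper-rotation determinant correction. With a prune cutoff, the
  single worst pair above the cutoff is removed and the fit repeated until
  stable (never below 3 pairs). Near-collinear atom sets are fitted but
  flagged as degenerate.
* **Hydrogens are ignored** throughout: predicted models are heavy-atom
  reliable at best, so hydrogen-bond capability is a donor/acceptor
  (N/O) heavy-atom distance criterion without angles, documented as a
  proxy rather than a bond assignment.
* **Pocket distances** are measured from a residue's side-chain centroid
  (heavy atoms beyond the backbone; CA fallback for glycine) to the
  centroid of the pocket-defining atoms (ligand heavy atoms or a residue
  set). Coordinates are in Å, residue numbering follows the input file.
* **RMSF** is `sqrt(mean_t |r_i(t) − r̄_i|²)` per CA atom over the models
  of a multi-model file. Whether frames should first be superposed onto
  frame 1 is genuinely ambiguous when fluctuation is computed "per
  structure independently", so it is exposed as a flag (`fit`), default
  off; for isotropic jitter both variants converge to the same value.

## What the synthetic generator emulates — and what it does not

[simulate_feature_matrix()] draws two populations of variants from the
saturation space of a seeded random protein and samples each feature
independently from a per-population Gaussian. The defaults *are* the
study conditions of the motivating full-scale analysis:

* populations of 7559 (benign-like) and 14,367 (pathogenic-like)
  variants, together the full 21,926-variant saturation space of a
  1154-residue protein;
* per-population means for CADD (20.99 / 26.68), ESM1b (−4.47 / −10.75)
  and closed-state ΔΔG (−2.05 / −6.36) taken from the reported
  per-cluster means; the remaining feature means, and all standard
  deviations, are this package's one-time choices of realistic predictor
  scales (e.g. CADD sd 4.5, damaging-probability scores on [0, 1] with
  sd ≈ 0.2, ΔΔG sd ≈ 2 energy units);
* catalog-flag probabilities 214/7559 and 75/14,367, so the expected
  flagged counts reproduce the reported 214-vs-75 split;
* four pseudokinase-domain GOF anchors (`p.H596D`, `p.A634D`, `p.S703I`,
  `p.C787F`) pinned into the sequence and forced into the pathogenic
  population.

Features are simulated **independently** per population because only
marginal means are reported for the real feature table; real predictor
panels are substantially correlated (CADD and AlphaMissense, for
instance), which makes the synthetic problem *easier* than the real one
at equal marginal separation. A passing recovery test therefore
demonstrates that the pipeline is correct and well-calibrated on the
structure it assumes — two separable populations with the reported
marginal means — not that real variant tables separate this cleanly.
Likewise the generator says nothing about score miscalibration,
position-dependent missingness, or annotation errors in real inputs.

## Problem sizes used in the checks

The test suite exercises: the full 21,926-variant saturation space and a
full-scale clustering of the default synthetic table; 20-seed parameter
recovery at n = 1000 + 2000; brute-force kNN verification up to N = 500;
exhaustive truth-table and 6⁵ consensus-vote enumeration; 500-frame
ensembles for the RMSF closed form; and ≤ 200-atom fixtures for
brute-force geometry scans. These sizes make every check exact or tightly
bounded while keeping the default run lightweight.

The full-scale check runs on the synthetic emulation above. The deposited
per-variant score table of the motivating study is an external
supplementary download, and its clustering script is not described at the
level of algorithm, metric or feature weighting, so exact reproduction of
its 7559 / 14,367 split is not a portable target; the synthetic
emulation, whose truth is set to exactly those conditions, is the
reproducible stand-in and is labelled as synthetic everywhere.

## Known limitations

* Residue numbering is 1-based on the supplied sequence; no isoform or
  transcript mapping. Only the 20 canonical amino acids; missense only.
* Domain boundaries ship only as an illustrative approximate map
  ([jak1_domains_approx()]); analyses that depend on exact boundaries
  must supply their own.
* ClinPred is included in the default feature set but configurable —
  whether it belongs in the clustering features or only in post-hoc
  characterization is a judgment call; excluding it is one
  `assemble_features()` argument away.
* ΔΔG, ligand-affinity and interaction values are ingested, never
  computed from structure; the package deliberately contains no
  molecular-dynamics or ΔΔG engine.
* The hydrogen-bond criterion is a distance proxy; superposition has no
  sequence-alignment fallback; >2-way clustering and embedding layouts
  are out of scope.
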