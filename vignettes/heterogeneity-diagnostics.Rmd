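---
title: "Heterogeneity diagnostics and model adequacy for mitogenome phylogenomics"
author: "hetphylo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heterogeneity diagnostics and model adequacy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(hetphylo)
```

## The problem this package addresses

Concatenated mitochondrial genomes are a workhorse for insect phylogenetics,
but they violate the assumptions of the standard homogeneous substitution
models in two systematic ways. First, base composition is not stationary:
mitogenomes are AT-rich overall, and individual lineages drift to different
equilibria. Second, substitution rates differ sharply among lineages —
parasitic lice, booklice, thrips and sternorrhynchan bugs evolve 1.5–2×
faster than their relatives. A model that assumes one composition and one
process for all sites and branches interprets the resulting convergence
(similar composition, shared saturation) as phylogenetic signal, and the
fast lineages are attracted into a single artifactual group.

`hetphylo` implements the diagnostic workflow around this problem:
quantifying the heterogeneity (composition, rate, pairwise divergence
structure), measuring whether a site-heterogeneous model fits measurably
better (site cross-validation), checking what each model fails to predict
(posterior-predictive composition and homoplasy, saturation slopes), and
probing specific artifact hypotheses (slow–fast site stripping, long-branch
extraction). Because the real demonstration of each diagnostic requires
knowing the true answer, the package is built around a synthetic-data
generator with complete ground truth.

## The generator and what it emulates

`simulate_dataset()` evolves sites independently down a tree under a
reversible GTR model with:

* **discrete-gamma rate variation** (K = 4 mean-normalized categories;
  shape `gamma_shape`, default 0.5 — mitochondrial protein-coding data are
  strongly rate-heterogeneous);
* **codon-position rate scalers** (default 0.7 / 0.45 / 1.85 — third
  positions fastest, second slowest, the universal protein-coding pattern);
* **lineage overrides**: inside a designated clade, every branch (including
  the stem) uses a longer effective length (`rate` multiplier) and,
  optionally, a replacement composition. The composition switch changes the
  rate matrix's equilibrium at the stem, i.e. a genuinely non-stationary
  process: tip composition converges toward the override target at a speed
  set by the post-switch path length.

`make_paraneoptera_fixture()` instantiates the study geometry: 29 taxa (25
ingroup + 4 outgroup), 13 protein-coding genes totalling 10,749 nt, and 2
rRNA + 17 tRNA genes totalling 3,264 nt (the five tRNAs that cannot be
aligned across all taxa are dropped by a config-level exclusion list before
concatenation, leaving 17 of 22). The base composition targets A+T = 0.74;
four clades (parasitic lice ×1.9, booklice ×1.85, thrips ×1.6,
sternorrhynchans ×1.55) are accelerated, and two mutually non-sister clades
(lice, sternorrhynchans) additionally carry a shifted composition with
A+T = 0.82, so global mean A+T lands near 0.75. The multipliers are chosen
to reproduce the qualitative Ka ordering (lice/booklice highest, then
thrips/sternorrhynchans, then the rest); no empirical per-lineage branch
lengths exist to calibrate against, so only that ordering, not absolute Ka
values, is a design target.

What the generator deliberately does **not** emulate: indels (gaps enter
only via masking tests), codon-level selection (no dN/dS machinery — Ka on
simulated data reflects raw divergence, not selective constraint),
among-gene rate differences beyond the gene table, and alignment error.
Passing tests on this generator therefore validate the *statistical
machinery*, not robustness to misalignment or selection.

## Dataset assembly

The eight dataset recipes (`PCG`, `PCG12`, `PCGRNA`, `PCG12RNA`, `AA`, and
masked `*_Al` variants) are compositions of four primitives: concatenation
(missing taxa filled with `?`), codon-position extraction (RNA columns are
always kept), translation under the invertebrate mitochondrial code
(codons with gaps → `-`, with ambiguity → `X`; simulated stop codons are
rendered `X` rather than resimulated, preserving site independence —
downstream Ka skips them), and a two-threshold masking rule (drop a column
when its gap fraction exceeds 0.5 or its non-majority fraction among
ungapped residues exceeds 0.8). The masking rule is this package's own
heuristic: it is *not* a re-implementation of any published trimmer, so
masked dataset lengths are not comparable to any published figure. Masking
is applied per gene before concatenation.

## The likelihood core

All model-based stages share one engine: Felsenstein pruning over compressed
site patterns, generic in the state space (4 or 20 states), with per-node
rescaling. Transition probabilities come from the symmetrized
eigen-decomposition of the reversible rate matrix. The engine is verified in
the test suite against brute-force enumeration of internal states on 4-leaf
trees (|Δ log L| < 1e-8) and against an independent likelihood
implementation at fixed parameters.

`fit_model()` treats model families declaratively (`model_spec()`):

* **C = 1 (homogeneous)**: branch lengths, gamma shape, and any free
  exchangeabilities/frequencies are optimized jointly by L-BFGS-B on log /
  log-ratio scales.
* **C > 1 (profile mixture, the "CAT-like" family)**: branch lengths and
  gamma shape are first fitted under C = 1 and then held fixed — at the
  small problem sizes this package targets, re-optimizing branch lengths
  inside EM destabilizes the fit for negligible likelihood gain. Class
  profiles and weights are then fitted by generalized EM: the E-step
  computes per-site class responsibilities, the M-step re-optimizes each
  profile numerically under the responsibility weights (a short BFGS run —
  any improvement suffices for monotone ascent). One restart always starts
  every class at the homogeneous solution, which is an EM fixed point; this
  guarantees the mixture log-likelihood can never fall below the
  homogeneous one. Additional restarts (k-means on per-site composition,
  then random draws) guard against local optima. Convergence: Δ log L <
  1e-6 or 500 iterations (callers may loosen both through `model_spec()`).
* With equal exchangeabilities the mixture is the "CAT" analogue; with
  shared free exchangeabilities it is the "CAT+GTR" analogue. This finite
  mixture is a desk-scale surrogate for Dirichlet-process implementations:
  it preserves the operative distinction (site-specific compositions versus
  a single profile) without MCMC.
* For amino-acid data a fixed empirical mitochondrial-protein
  exchangeability matrix (`spec_mtart()`) plays the homogeneous reference
  role.

## The adequacy procedures

**Cross-validation** (`cross_validate()`): 90% learning / 10% test splits,
both models fitted on identical learning columns, scored by held-out
log-likelihood, 10 replicates. Scores are reported as model 2 − model 1, so
negative means the reference (model 1) fits better. Both the total and the
per-site difference are reported, since the literature is ambiguous about
which scale is printed; the sign convention is what carries the conclusion.

**Posterior-predictive composition** (`ppred_composition_test()`): the
per-taxon statistic is the L1 distance between the taxon's composition and
the pooled composition. The cited inference suites use a max-based z-score;
L1 was chosen as more robust to single-residue noise, and is documented as
a variant. p-values use the add-one Monte-Carlo estimator
`(1 + #{sim ≥ obs})/(R + 1)`; defaults R = 100, α = 0.05 (no published
values exist for either, so conventional Monte-Carlo choices are used).
The χ² companion test (`chi2_homogeneity()`) is exact only for independent
sequences; on a tree it is anti-conservative, which is why the calibrated
posterior-predictive test is the primary instrument.

**Posterior-predictive homoplasy** (`ppred_homoplasy()`): the statistic is
parsimony homoplasy excess — Fitch tree length minus the per-site minimum
(distinct unambiguous states − 1). A homogeneous model fitted to
composition-mixture data simulates replicates with *less* homoplasy than
observed (positive z): the model underestimates convergence.

**Saturation slopes** (`saturation_analysis()`): OLS (with intercept — the
intercept is reported rather than suppressed, since distance vectors need
not pass through the origin) of each compared distance vector on the
reference patristic distances. Slope 1 against itself is an exact identity
and is asserted as such in the tests.

## Artifact probes

**Slow–fast** (`slowfast_rates()`, `strip_fastest()`, `slowfast_scan()`):
site rates are the sum of within-group Fitch steps over user-defined groups
(the classic slow–fast definition; group subtrees come from NJ on
within-group p-distances, and for 2–3 taxa topology is irrelevant).
Stripping keeps the lowest-rate `⌈f·L⌉` sites with leftmost tie-breaking,
making the ladder of datasets strictly nested. The demonstration fixture
(`make_slowfast_fixture()`) plants *competing* signal: half the sites evolve
fast on a tree whose short central edge supports the focal clade, half
evolve slowly on a tree supporting a conflicting arrangement. With all data
the fast-borne focal signal wins; by 50% stripping the conflicting slow
signal is what remains — signal loss after removing roughly half the
fastest sites, with a cherry that both regimes share serving as the stable
control.

**Long-branch extraction** (`lbe_test()`): remove taxon set A, re-infer,
and ask whether B's sister group matches what the baseline tree (restricted
to the remaining taxa) predicts; then the converse. Both staying put means
the baseline grouping was not an attraction artifact. Sister groups are
read off after rooting at the alphabetically first tip outside the focal
set, so the comparison is invariant to the tip orderings different
inferences produce. The Felsenstein-zone fixture (`make_lba_fixture()`)
uses long branches of 1.0 substitutions/site against an internal branch of
0.1 (a standard 10:1 zone geometry; at 5,000 sites the corrected-distance
sampling noise is several-fold smaller than the NJ decision margin, while
uncorrected p-distances still attract the long branches essentially
always). The 8-taxon variant adds a third cherry outside the two
long-branch clades — with only two short cherries the tree is symmetric
around the artifact and "staying put" is not observable.

## Numerical choices and degenerate inputs

* Frequencies passed into the eigen-decomposition are floored at 1e-9 and
  renormalized; optimizer bounds keep branch lengths in [1e-7, 20] and the
  gamma shape in [0.02, 100].
* Pattern likelihoods are rescaled per node (by column sums) to prevent
  underflow on deep trees.
* Ties in site-rate stripping break by original column order; NJ negative
  branch estimates are clamped to zero with a warning; logdet entries with
  singular joint matrices are `NA` and must be handled by the caller
  (the pipeline substitutes 1.5× the maximum defined distance).
* Zero-length internal branches (star trees) are legal simulator input;
  downstream inference simply cannot recover the corresponding split.
* `?`/`N`/`X` are missing data everywhere; `-` is distinguished from
  missing only in masking statistics. Gapped or ambiguous positions never
  contribute to composition denominators, distance comparisons, divergence
  scoring, or parsimony state sets.

## Problem sizes

The test suite and the acceptance script run everything at desk scale,
chosen so each check has clear statistical margins while the full suite
stays fast: oracle comparisons at 4–6 taxa; calibration at 6 taxa × 400
sites with 200 outer replicates and R = 49; cross-validation preference at
6 taxa × 600 sites, 10 experiment repetitions of 10 splits each; the
long-branch experiments at 4–8 taxa × 5,000 sites over 50 seeds; the
29-taxon fixture at its native 14,013 columns for dataset arithmetic,
composition, and Ka. The 29-taxon homogeneous fit used by the
posterior-predictive composition test estimates parameters on a 3,000-column
subsample (parameter estimates stabilize well before that; the test
statistic itself is then evaluated on the full matrix).

## Known limitations

* The profile mixture is a finite, EM-fitted surrogate; it does not explore
  the number of classes, and with `C` close to the number of informative
  patterns it will overfit (hence the 50·C-sites precondition).
* Branch lengths are frozen during EM; on data where rate and composition
  heterogeneity interact strongly, joint optimization would fit better.
* The divergence scorer and the masking rule are in-house variants; their
  absolute scores are not comparable to any published tool's output — only
  their orderings and signs are meaningful.
* `exhaustive_ml_topology()` is limited to 8 taxa by design; there is no
  heuristic tree search in this package, and none is intended.
* Bootstrap proportions from distance methods are support *proxies*; they
  are not posterior probabilities.
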