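---
title: "A variable-spacer mixture model for nuclear export signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A variable-spacer mixture model for nuclear export signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nologo)
```

## The problem

Crm1-dependent nuclear export signals (NESs) are short linear motifs of
roughly 7–15 residues built from four hydrophobic anchor residues (Leu, Ile,
Val, Met, Phe and occasionally Ala, Trp, Tyr) separated by three short
spacers of variable length. The anchors dock into hydrophobic pockets of the
export receptor Crm1; the spacers, weakly biased toward acidic and polar
residues, set the register. Because the spacers vary between one and three
residues, NESs of different "classes" have different lengths and different
anchor layouts, and a single fixed-length position-specific scoring matrix
(PSSM) describes them poorly: aligned without gaps, the anchor columns smear
into each other.

`nologo` models this family directly. The motif architecture is summarized
by a *spacer configuration* `C = (c1, c2, c3)`, each spacer 1–3 residues, so
there are 27 configurations spanning motif lengths 7 (`1-1-1`) to 13
(`3-3-3`).

## The model

Given a configuration `C`, a motif sequence `X` factorizes over positions:

$$P(X \mid C) \;=\; \prod_{i \in \Phi_C} p_\Phi(X_i) \prod_{j \in S_C} p_S(X_j)$$

where `Φ_C` are the four anchor offsets `{0, 1+c1, 2+c1+c2, 3+c1+c2+c3}`,
`S_C` the spacer offsets, and `p_Φ`, `p_S` are two categorical residue
distributions *shared by all configurations*. The configuration is rarely
known, so it is treated as a hidden variable and marginalized:

$$P(X) \;=\; \sum_{C} P(X \mid C)\, P(C), \qquad
P(C) = p_{C_1}(c_1)\, p_{C_2}(c_2)\, p_{C_3}(c_3)$$

with a 3×3 spacer-length probability table (each spacer length drawn
independently). The result is a 27-component mixture in which all components
share the same 44 free parameters (2 × 19 residue parameters + 3 × 2
spacer-length parameters) — versus 19 per column for a PSSM (190 for length
10). Sharing is what lets the model train on a few dozen annotated motifs.

Because components have different lengths, each component's probability is
padded with background-generated residues out to the longest allowed
configuration (13 for the full set), so every component is a probability
over the same number of residues and their posterior weights are
comparable. Scoring uses the log-likelihood ratio

$$\mathrm{llr}(X) = \log \frac{P(X)}{\prod_{i=1}^{13} P(X_i \mid bg)}$$

in natural log (the working threshold, llr > 0, is base-invariant; a log2
display option exists). The background mixture over configurations with
uniform weights collapses to the plain background product because the
weights sum to one; the package implements the collapsed form and the test
suite checks the identity against the explicit sum.

Restricting `allowed_configs` (e.g. to the canonical consensus classes,
supplied as `"c1-c2-c3"` labels from a config file, with
`reverse_configs()` for reverse-orientation classes) renormalizes the prior
over the restricted set; the padding width follows the longest *allowed*
configuration.

## Training

**Supervised** (`estimate_from_alignment()`): given annotated windows (id,
window, 1-based anchor start, configuration triple — the machine-readable
form of a hand alignment), the anchor distribution pools residues over all
four anchor positions of all motifs, the spacer distribution over all
spacer positions, and each spacer-length row counts its slot's observed
sizes. All estimates are smoothed with a pseudocount of 1 per amino acid or
spacer size (denominators `4N + 20`, `n_S + 20`, `N + 3`).

**Unsupervised** (`em_fit()`): from unaligned windows,
expectation-maximization with the motif start position *and* the
configuration as latent variables. For a window of length `L`, starts range
over `1 .. min(L − 13 + 1, 12)` with a uniform prior, matching the scanning
convention. Choices that matter:

* *Initialization.* The spacer-length table starts uniform, so the fit is
  unbiased with respect to expected motif architecture. The two residue
  distributions are unidentifiable from a symmetric start, so the default
  initialization up-weights the hydrophobic class {L, I, V, M, F, A, W, Y}
  threefold over background in `p_Φ`; a seeded random-perturbation mode is
  the alternative.
* *M-step smoothing.* The same pseudocount rule as supervised training is
  applied inside every M-step, preventing collapse onto zero counts.
* *Stopping.* Relative change in total data log-likelihood below 1e-6, or
  500 iterations, both configurable. The trace is returned and is
  non-decreasing (the suite asserts this to 1e-9 relative per step).
* *Orientation guard.* If the fitted "spacer" distribution ends up more
  hydrophobic than the "anchor" distribution (label switching), the two are
  swapped and the spacer-length rows reversed, giving a canonical
  orientation comparable across runs.

A note on attainable accuracy: with `n` training motifs the anchor
distribution is estimated from `4n` draws and the spacer distribution from
roughly `6n`, so the L1 error of even the *supervised* estimator has a
multinomial floor of a few hundredths at `n` in the hundreds; E-M adds
placement ambiguity on top. Recovery assertions in the test suite are read
against that floor.

## Scanning and posterior decoding

`scan_protein()` scores the llr of the 13-residue stretch starting at every
position (positions that cannot host 13 residues are not scored) and
reports the maximum-posterior configuration per start. Candidate motifs are
the windows with llr above 0.

Within a 25-residue peptide window the conventional questions are answered
by three posteriors:

* `posterior_configurations()` — Bayes over configurations at a fixed
  start.
* `posterior_start()` — normalized marginal likelihoods over starts
  1..12 (clamped with a warning for windows shorter than 25; the smallest
  window is the padded length, 13).
* `posterior_hydrophobic()` — the per-residue probability of being an
  anchor, summing the configuration posterior through the start posterior.
  Each (start, configuration) pair contributes exactly four anchors, so the
  vector always sums to 4.

Two views are exposed because both are useful: decoding at the llr-best
start (ties to the smallest index), and full marginalization over starts;
`posterior_profile()` bundles them. `align_profiles_for_heatmap()` shifts
each profile so its best start sits at column 6 for heat-map display,
edge-anchoring profiles that cannot be shifted fully;
`cluster_posteriors()` (Euclidean distance, average linkage) orders the
rows.

All user-facing coordinates are 1-based inclusive; internal computation is
0-based half-open.

## The PSSM baseline

`estimate_pssm()` / `scan_protein_pssm()` implement the standard
fixed-length comparator with the same pseudocount rule and the same
background. The default alignment length in the NES literature is 12
columns. A structural identity pins the two models together: a mixture
restricted to a single maximal-length configuration (no padding) scores
identically to the PSSM whose columns are `p_Φ`/`p_S` laid out along that
configuration — the suite tests this equivalence exactly.

## Evaluation protocol

`label_predictions()` implements the overlap-based labelling heuristics
used for NES benchmarking: a prediction overlapping a truth motif by at
least one residue counts toward it, each truth motif keeps its
highest-scoring overlapping prediction as its one true-positive
representative (a prediction spanning two truth motifs may represent both;
an exclusive mode is available), and the remaining predictions are chained
into tiles by transitive one-residue overlap, each tile contributing one
false positive at its maximum score. The operation is idempotent.

ROC curves sweep thresholds over the distinct representative scores; FPR
divides false-positive tiles by the count of negative residues (total
residues minus truth-motif residues, `negative_residues()` — e.g. 145,512 −
2,989 = 142,523 for a 279-motif truth set). Because this protocol only ever
reaches tiny absolute FPR values, `roc_auc()` normalizes the trapezoid area
by the observed curve extent (`max(fpr) · max(tpr)`), putting a random
predictor near 0.5 and a perfect separator at 1. One caveat the suite
documents: a *dense* random track thresholded at 0 chains nearly a whole
protein into a single tile, and the max-of-many representative biases the
normalized AUC far below 0.5 — an artifact of the tiling rule, not of the
scorer; chance-level behaviour is recovered at realistic (sparse) candidate
densities.

`proteome_fpr()` reproduces the proteome-scale operating-point arithmetic:
the substrate fraction of the proteome (700 / 5917 ≈ 0.12, rounded to two
decimals by convention) divided by the average protein length (495
residues) gives 2.42 × 10⁻⁴ per residue. `compare_predictors()` is the
two-sided Fisher's exact test on paired recall counts.

## Synthetic data

`synthetic_nes_model()` is a fixed, fully synthetic generating model with
the qualitative features reported for NESs: anchors dominated by leucine
(p(L) = 0.6, then I/V/F/M), spacers moderately acidic/polar, spacer lengths
favouring `3-2-1`, over an average-composition background
(`typical_background()`). `generate_proteome()` draws protein lengths from
a clipped normal (mean 495, sd 150 — the average-protein-length context of
the proteome-rate arithmetic), fills them with background residues, and
plants sampled motifs at recorded coordinates at least 25 residues apart so
one window never spans two truths. Everything is reproducible from the
recorded seed.

What the simulator does *not* emulate: real proteome composition
heterogeneity, intrinsic disorder context, domain structure, homologous
redundancy, or any correlation between residues. Tests passing on this
synthetic data therefore validate the *machinery* — likelihood algebra,
training estimators, the labelling/ROC protocol — not predictive
performance on real proteomes, which in this motif family is limited by
signal weakness and context features outside the model.

Problem sizes used by the test suite (chosen to exercise the estimators
meaningfully at desk scale): 500 windows for E-M recovery, 2000 annotations
for supervised recovery, 10–20 simulated proteomes of 20 proteins for the
end-to-end harness, 100 random model/window instances per oracle
equivalence, 200 planted-motif localization trials.

## Numerical choices

* All likelihood computation is in log space with log-sum-exp; exact zero
  probabilities are −∞ logs. Inside mask-matrix products a −1e9 sentinel
  stands in for −∞ (0 · −∞ is NaN in floating point) and is restored
  afterwards; no legitimate 13-residue log-likelihood approaches it.
* Non-canonical residues (X, B, Z, U, \*) receive an identical flat factor
  under the anchor, spacer and background components, so they contribute
  exactly zero to every llr — windows containing them are scored, not
  discarded, and never inflated. A warning is raised per sequence.
* Model JSON serialization writes 17 significant digits with an explicit
  alphabet order, so a model file reproduces scores bit-for-bit.
* Ties in `best_start()` break toward the smallest index; tile and
  truth-group representatives break score ties toward the earliest record.

## Limitations

* The model scores primary sequence only; disorder propensity, solvent
  accessibility, conservation and other meta-features known to help NES
  prediction are out of scope by design.
* Reverse-orientation motif classes are represented by reversing the
  spacer triple scored on the forward sequence; emission asymmetries of
  true reverse binding are not modelled.
* The architecture is fixed at four anchors and three spacers of 1–3
  residues; additional flanking hydrophobic positions are handled by
  posterior analysis (the per-residue anchor posterior), not by enlarging
  the state space.
* No Bayesian/Dirichlet estimation and no stochastic or online E-M.
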