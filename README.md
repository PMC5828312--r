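# nologo

Probabilistic modelling and prediction of Crm1-dependent nuclear export
signals (NESs) — and other short protein motifs whose length varies because
the gaps between their anchor residues vary.

## The model

An NES is four hydrophobic anchor residues (Φ) separated by three spacers
of 1–3 residues each. The spacer-length triple `C = (c1, c2, c3)` — the
*spacer configuration* — fixes the motif's architecture; with each spacer
allowed 1–3 residues there are 27 configurations and motif lengths run from
7 to 13 residues. Given the configuration, the sequence factorizes over two
shared residue distributions:

    P(X | C) = ∏_{i ∈ Φ_C} p_Φ(X_i) · ∏_{j ∈ S_C} p_S(X_j)

and since the configuration is not observed it is marginalized with a
product prior over the three spacer lengths:

    P(X) = Σ_C P(X | C) · P(C),    P(C) = p_C1(c1) p_C2(c2) p_C3(c3)

Every component is padded with background residues to the longest allowed
configuration (13), so the 27 mixture components are comparable
probabilities over the same number of residues. Candidate motifs are
windows whose log-likelihood ratio against the background,
`llr = log P(X) / P(X | bg)`, exceeds 0. The whole mixture has 44 free
parameters (2 × 19 residue + 3 × 2 spacer-length), versus 190 for a
length-10 PSSM, so it trains from a few dozen annotated motifs.

The package provides:

* model construction, likelihoods, llr scoring (`nologo_model`,
  `likelihood`, `llr`), JSON serialization;
* supervised training from annotated alignments
  (`estimate_from_alignment`) and expectation-maximization from unaligned
  windows (`em_fit`), both with pseudocount smoothing;
* protein scanning and posterior decoding of configurations, start
  positions and per-residue anchor probabilities (`scan_protein`,
  `posterior_configurations`, `posterior_start`, `posterior_hydrophobic`,
  `align_profiles_for_heatmap`, `cluster_posteriors`);
* a fixed-length PSSM baseline (`estimate_pssm`, `scan_protein_pssm`);
* the overlap-based benchmarking protocol for motif predictors
  (`collect_candidates`, `label_predictions`, `roc_points`, `roc_auc`,
  `proteome_fpr`, `compare_predictors`);
* a generative simulator producing proteomes with planted motifs and
  exact truth tables (`synthetic_nes_model`, `generate_proteome`).

## Worked example

Simulate a 20-protein proteome with one planted NES each, train on the
planted annotations, scan, and evaluate:

```r
library(nologo)

model <- synthetic_nes_model()                       # known generating model
sim   <- generate_proteome(simulation_spec(model, n_proteins = 20, seed = 1))
trained <- estimate_from_alignment(sim$annotations,
                                   background = model$background)
print(trained)
#> Variable-spacer NES mixture model
#>   27 allowed configurations, motif lengths 7-13 (padded to 13)
#>   44 free parameters
#>   phi   : L=0.56 V=0.07 I=0.06
#>   spacer: E=0.20 D=0.13 S=0.13
#>   most probable configuration: 3-2-1 (prior 0.114)

track <- scan_proteins(sim$sequences, trained)
lab   <- label_predictions(collect_candidates(track), sim$truth)
print(lab)
#> Labelled predictions: 20/20 truth motifs recovered, 229 false-positive tiles

nneg <- negative_residues(sum(nchar(sim$sequences)),
                          sum(sim$truth$end - sim$truth$start + 1))
roc_auc(roc_points(lab, nneg))
#> [1] 0.8721249
```

Twenty annotated motifs already recover a leucine-dominated anchor
distribution, an acidic spacer preference and `3-2-1` as the most probable
architecture; scanning with that model recovers all 20 planted motifs, and
the ROC (false positives counted as merged tiles per negative residue)
gives a normalized AUC of 0.87.

Posterior decoding of one annotated window shows the per-residue anchor
probabilities and the configuration posterior:

```r
prof <- posterior_profile(sim$annotations$window[1], trained)
print(prof)
#> Posterior decoding of 25 residue window
#>   best start: 1
#>   top configurations: 3-2-2 (0.954), 3-2-1 (0.014), 1-1-2 (0.011)
round(prof$hydrophobic_posterior, 2)
#>  [1] 0.88 0.00 0.06 0.01 0.97 0.00 0.01 0.99 0.00 0.01 0.97 0.01 0.01 0.01 0.06
#> [16] 0.00 0.00 0.00 0.01 0.00 0.00 0.00 0.00 0.00 0.00
```

This window was planted with configuration `3-2-2` starting at position 1:
the decoder concentrates 95% of the posterior on the true architecture, and
the four anchor positions (1, 5, 8, 11) carry essentially all the anchor
mass — the kind of read-out used to ask whether a known NES fits a
canonical class, occupies several architectures at once, or carries extra
flanking hydrophobic positions.

A thin command-line front end over the same functions is installed at
`inst/cli/nologo.R` with `train`, `em`, `scan`, `posterior`, `eval` and
`simulate` subcommands (run it with `Rscript`).

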