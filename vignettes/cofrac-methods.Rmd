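---
title: "Models and methods behind cofrac"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cofrac}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`cofrac` analyses dynamic co-fractionation interactomics (PCP-SILAC over a
size-exclusion or blue-native separation) together with a matched TAILS
N-terminome. This vignette explains the models each stage assumes, the
tunable parameters that matter, what the synthetic-data generator emulates
and deliberately does not, and the numerical and design choices made where
the design was genuinely open. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## 1. The measurement model

A separation resolves assemblies by molecular mass; fractions map onto mass
log-linearly between calibrated endpoints (default: 2 MDa at fraction 1 to
100 kDa at fraction 55, `mass_calibration()`). Each protein's fraction-wise
SILAC ratio (channel over a spiked reference) forms a chromatogram, modelled
as a sum of Gaussian peaks

$$y(f) = \sum_i A_i \exp\!\left(-\frac{(f-\mu_i)^2}{2\sigma_i^2}\right),$$

one peak per assembly state the protein occupies (complex, supercomplex or
subcomplex state, monomer). Species lighter than the calibrated floor elute
after the last collected fraction and are simply not observed — a property
the generator reproduces and the fitter must tolerate (edge-truncated peaks
are allowed centres up to 5 fractions beyond the range).

## 2. Chromatogram cleaning and Gaussian deconvolution

Cleaning (`clean_chromatogram()`) removes isolated single measurements
(spikes, both neighbours missing in the original pattern), then imputes
single interior gaps as the neighbour mean; remaining missing values become
zeros for fitting while the presence mask is kept for distance computations.
Spikes are judged before gap bridging so that a lone value flanked by a
bridgeable gap does not rescue itself.

Fitting (`fit_gaussians()`) runs box-constrained Levenberg–Marquardt over
`k = 1..5` components with bounds `A >= 1e-6` (and a post-hoc floor of
5% of the profile maximum), `0.5 <= sigma <= 20`, `mu` within 5 fractions of
the axis. Numerical choices, each load-bearing:

* **Weighted residuals.** SILAC ratio noise is multiplicative, so residuals
  are scaled by `max(y_f, 0.1 * max(y))`; zero-filled censored fractions get
  three times the baseline scale. Unweighted fitting chases the large
  absolute residuals on peak tops and splits single peaks.
* **AICc with validity gates.** The component count is chosen by
  small-sample-corrected AIC among *selectable* models: centres at least 2
  fractions apart and every amplitude at least 3 raw residual standard
  deviations. At 55 points the plain AIC penalty is weaker than the residual
  reduction a spurious noise component buys; the gates encode that a
  component closer than the co-apex window to its neighbour, or smaller than
  the noise, is not evidence for extra model complexity.
* **Deterministic initialisation.** Centres come from a signal-weighted 1-D
  k-means started at quantiles of the cumulative signal, with three fixed
  jittered restarts; identical input therefore always yields identical
  features, without any RNG involvement.
* Acceptance requires model R² of at least 0.5 (sensitivity over
  parsimony); profiles with fewer than 5 measurements are skipped.

## 3. Replicate alignment

Independent fractionations drift; feature centres of replicate *r* relate to
the reference by `mu_rep = a * mu_ref + b`. Anchors are proteins with exactly
one well-fitted feature (R² ≥ 0.9) in both replicates, restricted to centres
in `[3, F-3]` because edge-truncated peaks carry unreliable centre estimates.
The map is fitted by iteratively trimmed least squares (drop residuals beyond
3×MAD, refit, at most 5 rounds) seeded with a Theil–Sen line, so a dense
cloud of noisy edge anchors cannot steer the first trim. A fitted map outside
`0.8 <= a <= 1.25`, `|b| <= 10` is treated as a failed alignment and the
replicate excluded — drift beyond that range is not a plausible single-gradient
distortion. When several channels are fitted per replicate, anchors are taken
within one channel (`anchor_channel`), since proteins then rarely carry
exactly one feature overall.

## 4. Interaction scoring and precision calibration

Candidate pairs must co-apex (`|delta mu| <= 2` fractions, matching visual
co-apex practice) and share at least 10 co-quantified fractions. Each pair is
scored by the Euclidean distance between unit-maximum-scaled cleaned profiles
over the shared fractions, plus the co-apex distance; the combined score is
the within-channel rank sum — a non-parametric combination robust to the two
statistics' different scales that yields a single sweepable axis. Pairs are
labelled against a gold-standard complex database (positives co-occur in a
complex; negatives are database-covered pairs never seen together — the
standard protocol that makes precision and FPR well defined). Calibration
(`calibrate_threshold()`) sweeps the cutoff from best to worst and keeps the
largest accepted prefix whose running precision over labelled members stays
at or above the target (the study's operating points were 70/60/50%);
unlabelled pairs inside the cutoff become predictions. The global network is
the deduplicated union across channels and replicates with support recorded;
its FPR denominator is every labelled negative candidate evaluated.

## 5. Complex assembly

Accepted edges enter Markov clustering with near-binary weights
(`1 - score/max(score)`, floored at 0.1). `mcl()` follows the canonical
algorithm (expansion by squaring, inflation with renormalisation, pruning at
1e-5, convergence at 1e-8, attractor read-out, overlapping attractor systems
merged so the output is a partition, singletons discarded) with the canonical
inflation default of 2. Complex assembly via `cluster_network()` defaults to
**inflation 3**: on rank-weighted co-elution graphs at realistic complex
density, mass-coincident complexes chain into one cluster at inflation 2 and
the precision gain that motivates the clustering stage reverses; inflation 3
restores it. Cluster elution centres average each member's feature nearest
the cluster median (reported to 0.1 fraction); clusters sharing members
within 1.0 fraction merge into supercomplexes.

A known limitation, quantified by the failing-by-design recovery check in
`tests/testthat/test-acceptance.R`: with 60 complexes sharing 1.3 decades of
calibrated mass and peak widths of ~2 fractions, distinct complexes routinely
co-elute. Clusters then either chain such neighbours (diluting the overlap
score) or split sparse large complexes, so the fraction of planted complexes
recovered at overlap `O = |C∩G|²/(|C||G|) >= 0.5` plateaus around 0.5–0.65 at
the default study scale across the operating points examined (inflation 2–4,
one- or two-channel networks, support weighting). Network-level precision is
unaffected; the limit is about reconstructing complete member sets.

## 6. Differential testing

Stimulation-induced changes are tested per cross-replicate feature group
(features of one protein matched within 2 aligned fractions). Each member
contributes the per-fraction `log2(treated/untreated)` measurements inside
its own `mu ± 2 sigma` window; the pooled measurements (duplicate
(replicate, fraction) pairs removed) are tested against 0 by a one-sample
t-test with Bonferroni control over tested groups, and significance further
requires support from at least two replicates. Pooling fraction-level
measurements rather than three replicate means is deliberate: it is the only
way per-protein p-values many orders of magnitude below the replicate-level
limit are attainable with three biological replicates.

Two bias controls matter. Windows are fitted on the *channel-averaged*
profile (`combine_channels()`): selecting fractions where one channel's
noise ran high biases the ratio inside the window (regression to the mean)
and measurably inflates the test's null rejection rate. And the generator's
missingness acts on the underlying signal rather than the noisy measurement;
value-dependent dropout is informative censoring that no downstream ratio
test can undo.

## 7. Peptide evenness and proteoform segmentation

Within one protein, fraction and replicate, peptide ratios `r_i` are
normalised to proportions and summarised by the Shannon index
`H = -sum p_i ln p_i` and Pielou evenness `E = H / ln(n)` (natural log;
normalisation makes the base irrelevant). Fractions need at least 3
quantified peptides (the `ln 2` normalisation is unstable). A protein's
unevenness is `U = 1 - min_f E` — the most extreme fraction, because a stable
cleavage fragment perturbs the peptide population only where the fragment
elutes. The permutation null shuffles peptide ratios across proteins within
each (replicate, fraction) stratum; p-values use the `(b+1)/(m+1)` convention
with BH adjustment. Note the resolution floor: with `m` permutations and `P`
proteins the smallest attainable BH q is `P/(m+1)`, so calling at `q < 0.05`
among 200 proteins needs ~5000 permutations. Entropy-based unevenness is
maximised by a single dominant peptide, so a balanced bimodal cleavage
signature is only separable from a permutation that hands a protein one
extreme value when protein coverage is high (≈12+ peptides) — evenness is a
high-coverage statistic, and the generator's planted fragments are localised
to a few fractions around the fragment's own elution position accordingly.

Proteoform segmentation orders a protein's peptides by start position and
places a single change point maximising the between-segment t statistic
(accepted at p < 0.01, at least 6 quantified peptides), reporting the residue
interval between the flanking peptides.

## 8. The N-terminome stage

Termini starting at position 1–2 with an alpha-amine modification (acetyl in
vivo, dimethyl from the TAILS chemistry) are mature protein N-termini; any
terminus at position 3 or later is a neo-N-terminus with P1 the residue
before the cut and an 11-residue P5..P6' window (gap-padded at sequence
ends). The neo-terminus log2 ratio distribution is modelled as a k-component
normal mixture fitted by EM (5 seeded k-means restarts, best log-likelihood
kept, sd floor 1e-3 so degenerate input collapses gracefully; the
monotonicity of the log-likelihood is asserted on every iteration).
Direction calls use strict ±1 log2 thresholds on replicate-averaged ratios.
Inhibitor (pan-caspase) sensitivity is operationalised as: stimulated-arm
ratio exceeds the inhibitor-arm ratio by ≥1 log2 unit *and* the
stimulated-arm change is BH-significant at 0.2 — the outcome (a stabilised
terminus set) is what the underlying study reports; this rule is this
package's explicit construction. Positional motif enrichment tests each
(position, residue) cell binomially against proteome background frequencies
computed from the supplied FASTA (keeping the module self-contained for
synthetic proteomes), BH-adjusted at 0.02, and flags the canonical
executioner-caspase D-E-x-D|G pattern when P4, P3, P1 and P1' are all
enriched. The cleavage–interactome comparison forms all combinations of each
shared protein's terminus ratios and feature fold changes and reports the
Spearman rank correlation (average-rank ties).

## 9. What the generator emulates, and what it does not

`simulate_truth()` plants: 500 proteins (monomer masses lognormal, median
70 kDa, so most monomers elute beyond the calibrated window — as in the real
separation, where fractions below 100 kDa are not analysed); 60 complexes of
2–10 members with assembly mass = member sum × a supercomplex stoichiometry
factor of 1–3, half of them eluting in two assembly states, and a
per-complex peak-width factor (lognormal, sd 0.25) shared by members. These
give co-complex pairs a shared multi-peak, width-matched fingerprint;
without such texture, complexes at coincident mass are literally
indistinguishable by any co-elution method. Perturbations: 15% of complexes
change abundance (log2 fold change centred at −1.3, sd 0.6, the
condensin-like response), 10% disassemble fully (assembly amplitude moved to
the monomer peak, conserving total signal); replicate drift `f' = a_r f +
b_r` with `a_r` in [0.97, 1.03] and `b_r` in [−2, 2] (the true
inter-replicate drift is unstated in the source material; these are desk
defaults); multiplicative lognormal noise (sd 0.15) and intensity-dependent
Bernoulli missingness (logistic in the log signal, baseline 0.2) applied
last. Cleavage events (12% of proteins) carry a P1 residue (enriched for Asp
and Arg), caspase dependence for 60% of Asp events, a fragment fold change
drawn from the planted ratio mixture, and a fragment elution position near
the parent's peak. The matched proteome embeds P1 residues and the DEVD|G
context for caspase-dependent events; the terminome draws neo termini from a
two-component mixture centred at log2 −0.9 and +1.6 (weights 753:411) with
86% natural termini, and attenuates caspase-dependent events towards 0 in
the inhibitor arm.

Not emulated: MS acquisition, peptide detectability, protease kinetics,
retention-time chromatographic artefacts, shared subunits between complexes
(each protein belongs to at most one planted complex), and correlated
biological replicate effects. Passing tests therefore demonstrate that the
*computation* behaves as specified under the stated statistical structure;
they do not certify performance on real spectra.

## 10. Problem sizes and reproducibility

All randomness flows through explicit integer seeds (`with_seed` semantics:
the caller's RNG stream is untouched). The test suite and the acceptance
script use desk-scale designs chosen to keep the statistical checks
well-powered: the full default study (500 proteins) for calibration
properties, 200–400 proteins for reproducibility, terminome and correlation
checks, 50 seeded repetitions for detection-rate properties, 999–4999
permutations for the evenness caller, and 20 graphs for the Markov-cluster
oracle comparison. `run_cofrac()` chains every stage on one simulated study;
`scripts/acceptance.R --seed N --out file.json` recomputes the pipeline's
headline quantities from scratch.
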