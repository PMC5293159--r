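# cofrac

Dynamic co-fractionation interactomics and N-terminome analysis in R.

## The problem

Protein correlation profiling with SILAC (PCP-SILAC) infers protein–protein
interactions from co-migration: intact complexes are resolved by a
non-denaturing separation (size-exclusion chromatography for the cytosol,
blue-native PAGE for membranes) into fractions, and each protein's
fraction-wise SILAC ratio traces an elution chromatogram. Proteins in the same
complex co-elute, so their chromatograms peak together. Because the SILAC
channels carry different conditions through the same fractionation, the same
experiment also measures how the interactome *changes* — e.g. which complexes
disassemble when apoptosis is triggered. A companion N-terminome experiment
(TAILS) quantifies proteolytic cleavage in the same samples, so the question
"does proteolysis drive complex disassembly?" can be answered by correlating
the two.

`cofrac` implements that entire computational pipeline as tidyverse-style R
functions, together with a ground-truthed synthetic-data generator that
emulates the full study design (3-channel SILAC, 55 fractions, 3 biological
replicates, complex-driven co-elution with perturbations, peptide-level
cleavage structure, bimodal N-terminus ratios), so every stage is testable
without raw mass-spectrometry data.

## The model at the core

Each chromatogram is deconvolved into Gaussian features

y(f) = Σᵢ Aᵢ · exp( −(f − μᵢ)² / 2σᵢ² )

by box-constrained weighted least squares with AICc model selection. Feature
centres are re-aligned across biological replicates through a robust affine
fraction map μ′ = (μ − b)/a. Protein pairs whose features co-apex are scored
by the Euclidean distance of their unit-scaled profiles plus the co-apex
distance (rank-sum combined), and a score cutoff is calibrated against a
gold-standard complex database so the accepted network reaches a target
precision (TP/(TP+FP), with the false-positive rate counted over all labelled
negative candidate pairs). Accepted edges are assembled into complexes by
Markov clustering. Condition-induced changes are tested per feature by a
one-sample t-test on pooled per-fraction log₂(treated/untreated) measurements
with Bonferroni control; peptide-level heterogeneity is quantified by Shannon
evenness E = H/ln(n), H = −Σ pᵢ ln pᵢ, with a fraction-wise permutation null.
N-termini are classified (natural vs neo, P1 residue, P5..P6′ window), their
log₂ ratio distribution modelled by a two-component normal mixture fitted by
EM, cleavage-site composition tested against proteome background frequencies,
and cleavage changes correlated with interactome changes by Spearman rank
correlation over all (terminus, feature) combinations per protein.

## Worked example

```r
library(cofrac)
library(dplyr)

truth <- simulate_truth(n_proteins = 150, n_complexes = 18, seed = 22)
sim   <- simulate_profiles(truth, seed = 23, peptides = FALSE)

feats <- fit_profiles(sim$chromatograms, channels = "untreated")
al    <- align_features(feats)
fr    <- feature_ratio(al$features, sim$chromatograms)

db    <- truth_complex_db(truth)   # planted complexes as the gold standard
cand  <- label_pairs(score_candidate_pairs(fr, sim$chromatograms), db)
local <- calibrate_threshold(cand, target_precision = 0.70)
glob  <- global_report(local$edges, cand)

local$report |> select(replicate, tp, fp, precision, fpr, recall)
#>   replicate  tp fp precision   fpr recall
#> 1         3 167 71     0.702 0.074  0.616
#> 2         1 183 78     0.701 0.118  0.859
#> 3         2 174 74     0.702 0.101  0.809

glob$report |> select(tp, fp, precision, fpr, recall)
#>    tp  fp precision   fpr recall
#> 1 262 140     0.652 0.109  0.879
```

Each local (per-channel) network is calibrated to 70% precision against the
gold standard; their union — the global network — lands at 65.2% precision,
because the channels accept partly different false positives. Markov
clustering then tightens it again:

```r
clusters <- cluster_network(glob$edges, fr)
complex_precision(clusters, db)$precision
#> [1] 0.681
```

The end-to-end driver `run_cofrac(seed = 1)` chains every stage (profiles,
alignment, differential tests, network, clusters, peptide evenness, terminome,
cleavage–interactome correlation) on one simulated study and returns all
intermediate results.

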