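---
title: "Ranking candidate causal genes in QTL intervals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking candidate causal genes in QTL intervals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qtgrank)
library(dplyr)
```

## The problem

A QTL found by linkage mapping is an interval between two genetic markers,
often 200 kb to several Mb wide, containing tens to hundreds of genes — any
one of which might be the causal gene. Fine mapping narrows the interval by
screening recombinants, but can require genotyping thousands of progeny.
qtgrank instead ranks the genes of the interval by how much they *look like*
known causal genes, so that experimental effort can concentrate on the top
fraction of candidates.

"Looking like a causal gene" is operationalised as a supervised
classification problem over genome-scale features: per-gene polymorphism
summaries from re-sequencing panels (nonsynonymous SNP load normalised to
protein length, flags for deleterious, start/stop-disrupting, splice-site and
cis-regulatory variants), coarse functional categories (transporter,
transcription factor, receptor, kinase, metabolic domains), weighted degree
in a co-function network, paralog copy number and predicted essentiality.
Curated causal genes — a few dozen per species — are the positives.

## Positive-unlabeled learning by negative resampling

There is no clean negative set: any gene not yet shown to be causal might
still be causal for some trait. The working assumption is that causal genes
are rare, so a random draw from the genome is almost entirely non-causal.
Every model is therefore trained on **all known positives plus a fresh random
draw of "negatives"** from the genome minus the positives. A single draw is
arbitrary; the remedy is iteration:

* **Cross-validation** (`cross_validate()`): positives are randomly re-split
  4:1 into training and testing sets `R` times; for each re-split the
  negatives are re-drawn `S` times, giving `R × S` train/test iterations
  (defaults `R = S = 50`). Training sets carry `train_neg_ratio` negatives
  per positive — 20 for the Arabidopsis-scale profile, 5 for rice, values
  selected by this same cross-validation; test sets use 200 per positive to
  mimic the causal:non-causal ratio of a real QTL. Performance is the mean
  rank-statistic AUC-ROC across iterations, with the ROC curves averaged
  vertically on a fixed 101-point false-positive-rate grid.
* **Production ranking** (`train_ensemble()` + `rank_qtl_genes()`): all
  positives are kept, and `n_models` classifiers (default 5,000) are trained
  on independently resampled negative draws. A candidate gene's score is its
  **prediction frequency** — the fraction of models voting it "causal" at the
  0.5 probability threshold. Genes in a QTL are ranked by that frequency, and
  a gene's **rank percentile** is the percentage of QTL genes with strictly
  higher frequency (0 = best), so rankings are comparable across QTL of very
  different sizes.

Are the iteration counts enough? The chance that a given positive and a
given negative ever co-occur in a training or testing set is
`1 − ((N − n)/N)^(R·C·S)`, where `N` is the candidate-negative pool, `n` the
per-iteration draw, and `C` the number of folds containing the positive (4
for training, 1 for testing). At genome scale
(`N = 27,000`, `n = 960`, `R = S = 50`, `C = 4`) this exceeds 99%, and 5,000
ensemble draws of ~1,200 negatives likewise select every pool gene at least
once with probability above 99% (`cooccurrence_probability()`). The
probability can also be written as a telescoping product of `n` per-draw
terms, `∏_{i=0}^{n−1} (1 − 1/(N−i)) = (N−n)/N`; the package computes the
closed form directly.

The base classifier is a probability random forest (100 trees, at most 9
candidate features per split — `classifier_spec()`), fitted with `ranger`.
The classifier is a seam: a logistic alternative exists for quick
experiments, but all reported behaviour uses the forest.

### Leakage control

Within a cross-validation iteration the test negatives are drawn from the
genome minus all positives *minus that iteration's training negatives*;
nothing forces this choice, but allowing collisions would let a model be
tested on genes it was trained to call negative, so we forbid them. Similarly, when a known causal gene
is being validated inside its own QTL, `train_ensemble(exclude = )` bars it
from the negative pool, and the leave-one-out trait-category test removes it
from the positives entirely.

## Feature importance and enrichment

A random forest uses feature interactions, so single-feature enrichment does
not measure what the model relies on. `leave_one_out_importance()` refits
the model once per feature with that feature withheld, **on the same
train/test split** as the full model, and reports
`ΔAUC = AUC(full) − AUC(leave-one-out)` averaged over all iterations.
Caveats inherent to the approach: two strongly correlated informative columns
mask each other (each copy's ΔAUC ≈ 0 because the other compensates), which
is why `feature_correlation()` is part of feature QC; and ΔAUC near zero does
not prove a feature useless, only redundant. `enrichment_ratio()` provides
the complementary univariate view: the positive-set mean over the genome
mean (a frequency ratio for binary features).

## Recall at a cutoff and multiple QTL

Validation against independent causal genes asks: if we test the top `c`% of
each QTL, what fraction of causal genes do we catch?
`recall_at_cutoff()` counts genes whose rank percentile is strictly below the
cutoff. For a study with `N` QTL, assuming each QTL's causal gene is
recovered independently with that single-QTL probability `p`,
`multi_qtl_recall_probability(p, N, K)` gives the binomial tail
`P(X ≥ K) = Σ_{x=K}^{N} C(N,x) p^x (1−p)^{N−x}` — the chance of catching at
least `K` causal genes. These are exact closed forms; the test suite checks
them against exhaustive enumeration of all `2^N` outcomes.

## The synthetic fixture generator

`generate_fixture()` builds a complete, fully offline test world: a
multi-chromosome gene annotation, effect-annotated variants, co-function
edges, a functional category map, passthrough columns, a causal-gene catalog
with trait categories, and marker-bounded QTL intervals each containing
exactly one causal gene (causal genes are placed at least one QTL-width apart
in gene order to guarantee this). The feature table is *recomputed from the
raw artifacts through the package's own extraction functions*, so generation
and extraction cannot drift apart.

Features are generated independently given the causal label (mirroring the
mostly weak, |r| < 0.2, correlations seen between real features):

* binary flags are Bernoulli draws whose causal frequency is
  `background × enrichment ratio` (capped at 1 only if explicitly
  acknowledged via `cap_binary`);
* count features (paralog copy number) are Poisson; the per-length
  nonsynonymous SNP rate is Poisson with mean proportional to protein
  length, and the feature is count/length, so the planted value is exactly
  recoverable from the emitted variant records;
* the deleterious flag is drawn only for genes with at least one
  nonsynonymous variant, since a deleterious call presupposes one;
* network weight is computed from the generated edge list and carries no
  planted signal by default — realising arbitrary per-gene edge-weight sums
  exactly would complicate the generator for little testing value.

The default effect specification plants signal on the features that are most
informative for real causal genes — paralog copy number (rate ratio 2.5),
transporter (4×), transcription factor (3×), premature stop codons (3×),
receptor (2×), nonsynonymous SNP load (2×), and a mild depletion of
essential genes (0.5×) — with magnitudes in the 2–4× range typical of
causal-vs-background enrichment contrasts. `null_effect_spec()` sets every
ratio to 1 for negative controls. Default scale is 2,000 genes on 5
chromosomes with 40 causal genes and 40-gene QTLs: large enough for stable
behaviour, small enough that a full simulate–train–rank cycle takes seconds.

Because the generative model is fully known, `bayes_optimal_score()` returns
each gene's exact log-likelihood ratio of causal vs background. By the
Neyman–Pearson lemma no classifier can out-rank it out-of-sample, so it
calibrates expectations: under the default effect specification the
LLR-ranking AUC is ≈ 0.98, which is why a cross-validated forest is expected
to clear 0.75 comfortably, and the planted effect sizes were chosen against
this oracle rather than against any trained model.

What the fixtures do **not** emulate: linkage disequilibrium and
recombination structure, correlated features, annotation errors, the
ascertainment bias of curated causal-gene lists, and real genome scale
(27,000+ genes). Passing tests on fixtures therefore demonstrate that the
machinery is correct and unbiased, not that a given species model will reach
any particular real-data AUC.

## Numerical and design choices

* **AUC** is the Mann–Whitney rank statistic with midranks for ties —
  identical to the trapezoidal area under the empirical ROC (asserted
  against an independent trapezoid implementation in the tests).
* **ROC averaging** is vertical: mean true-positive rate at each grid
  false-positive rate, linearly interpolating each iteration's step curve.
* **Confusion matrix** pools all test predictions at the 0.5 decision
  threshold (exposed in the configs; no threshold was prescribed upstream).
* **Degenerate iterations** (a single-class test split) are skipped with a
  warning and excluded from the mean, not imputed.
* **Ties in ranking** break by gene id after frequency, so output is
  deterministic; tied genes share a rank percentile under the
  strictly-higher-frequency rule, and a QTL whose genes all score equally
  has every percentile 0.
* **Seeds**: every random step derives its seed arithmetically from the
  master seed and the iteration/model index, so whole runs are
  bit-reproducible, any iteration can be re-run in isolation, and ensemble
  prediction frequencies are invariant to how models are batched.
* **Genes missing from the feature table** are ranked last with frequency 0
  and flagged, never dropped silently; missing passthrough feature cells are
  filled with 0 and counted in a message.
* **Pearson correlation with a constant column** is undefined; it is
  reported as 0 with a warning.
* **"200 flanking genes"** in the trait-category test means the nearest
  genes in gene order, half upstream and half downstream, borrowing from the
  other side at chromosome ends so the total stays at `min(k, available)`.
* **QTL membership** uses inclusive interval overlap: any overlap between
  gene body and the marker interval counts, since "genes between the
  markers" leaves partial overlap undefined.
* **Fixture-scale testing** uses `test_neg_ratio = 40` instead of the
  production 200: a 2,000-gene fixture leaves only 1,960 candidate
  negatives, which cannot supply 200 test negatives per positive alongside
  the training draw. AUC is insensitive to this ratio; it changes only the
  precision of the false-positive-rate axis.
* **Problem sizes in the test suite** were chosen for a single-CPU
  minutes-scale run: the null-vs-planted cross-validation checks use
  `R = S = 10` on the default 2,000-gene fixture, the ensemble recovery
  check uses 200-model ensembles over 50 generator replicates, and the
  importance check uses 20 iterations. One statistical subtlety is worth
  recording: with only 40 positives, a *single* null fixture's mean CV AUC
  is itself a random variable with spread ≈ 0.06 around 0.5 (the model
  partly memorises whichever genes happened to be declared positive), so
  the no-leakage check averages over 10 replicate null fixtures rather than
  trusting one.

## Limitations

The ranking inherits every bias of its training catalog: over-represented
trait categories and gene families rank better (the trait-category rank test
exists precisely to quantify this); genes absent from the reference
annotation cannot be ranked at all; and the negative pool inevitably
contains some unknown causal genes, which deflates apparent performance.
The binomial multi-QTL model assumes independent recall across QTL, which
ignores shared pathway membership among causal genes of one trait. Species-scale results cannot be reproduced without the original
genome-scale feature matrices and curated catalogs; this package ships the
machinery and validates it on synthetic data with known truth.
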