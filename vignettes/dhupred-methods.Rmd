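---
title: "Predicting dihydrouridine sites from sequence context: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting dihydrouridine sites from sequence context: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Dihydrouridine (D) is one of the most abundant tRNA modifications — a
uridine whose C5–C6 double bond has been reduced — and transcriptome-wide
profiling based on reverse-transcription arrest has recently placed it on
mRNA as well. Those protocols yield a list of modified uridines on
transcripts. `dhupred` asks the downstream question: *given only the local
sequence context of a candidate uridine, can we predict whether it is
dihydrouridylated?* The package implements the complete supervised pipeline
for that question — dataset construction, feature encoding, filter-based
feature selection, SVM training with hyperparameter search, and rank-based
evaluation including cross-species transfer — together with a synthetic
data generator that makes every stage testable without sequencing data.

## Dataset construction

A candidate site is a uridine at a known transcript position. Each site is
represented by its **41-nt window**: the uridine plus 20 nt of flank on
each side, a window size widely used for RNA-modification prediction.
Windows that would run past a transcript end are padded with `N` rather
than discarded, so dataset sizes are deterministic; every encoder treats
`N` as "no information" (below), so padding cannot fabricate signal. DNA
input (`T`) is silently normalized to RNA (`U`); any other character
outside `{A,C,G,U,N}` is a parse error.

Negatives are unmodified uridines drawn uniformly without replacement,
disjoint from the positive set, at a 1:1 ratio — a balanced design, so
accuracy-type metrics are interpretable and AUROC's null sits at 0.5. By
default the draw is restricted to transcripts that carry at least one
positive site (which matches how detection protocols constrain where
negatives are credible); `scope = "all"` widens it to the whole
transcriptome. The profiling literature does not settle this choice, so
both are supported and the default is documented here.

Near-duplicate windows inflate cross-validation estimates, so the dataset
is pruned the way CD-HIT prunes sequence sets: greedy clustering in input
order, where a window joins the first retained representative it matches
at ≥ 85% identity. Because all windows share one length and are aligned on
their central uridine, identity is plain ungapped positional identity; `N`
matches nothing (not even another `N`), so heavily padded windows are
conservatively retained. No word-index heuristics are needed at this
scale. Finally, a stratified 80/20 split (canonical-order shuffle, so the
partition depends only on content and seed) reserves the independent test
set.

## Feature encoders

Eight encoders map a window to a fixed-length numeric vector; columns are
named `ENCODER.descriptor` so provenance survives subsetting. At L = 41:

| encoder | dimension | what it measures |
|---|---|---|
| `ONE_HOT` | 164 | per-position base identity, A=(1,0,0,0), U=(0,1,0,0), G=(0,0,1,0), C=(0,0,0,1) |
| `ChemProper` | 123 | per-position chemical triple A=(1,1,1), U=(0,0,1), G=(0,1,0), C=(1,0,0) (ring / functional group / H-bond classes) |
| `EIIP` | 41 | electron–ion interaction pseudopotential per base: A 0.1260, U 0.1335, G 0.0806, C 0.1340 |
| `CONPOSI` | 16 | dinucleotide composition over the 40 overlapping steps |
| `Frequency` | 41 | accumulated nucleotide frequency, f_i = (count of the base at i among positions 1..i) / i |
| `autoCor` | 12 | dinucleotide auto-covariance, 6 properties × lags 1–2 |
| `crossCor` | 60 | dinucleotide cross-covariance, 6×5 ordered property pairs × lags 1–2 |
| `PseKNC` | 19 | type-1 pseudo dinucleotide composition, 16 k-mer frequencies + λ = 3 correlation tiers, w = 0.1 |

`N` handling is explicit per encoder: positional channels emit zeros at
`N`; composition and covariance terms exclude `N`-containing
(di)nucleotides from numerator *and* denominator; accumulated frequency
skips `N` positions entirely.

The covariance encoders need a per-dinucleotide physicochemical table.
The bundled default (`dhu_properties()`, a TSV under `inst/extdata/`)
carries six properties whose values are exactly specifiable: Watson–Crick
nearest-neighbour stacking free energy (kcal/mol), GC content, purine
content, keto content, mean EIIP and 5'→3' EIIP asymmetry. The first and
last are order-sensitive, so AU and UA differ. These defaults are this
package's choice — any table in the same TSV layout (e.g. helical step
parameters) can be substituted — and every property row is standardized to
mean 0, sd 1 across the 16 dinucleotides before use, so only relative
patterns matter. Auto-covariance for property *u* at lag *g* is

$$AC(u,g) = \frac{1}{L-1-g}\sum_{i=1}^{L-1-g}
  \big(P_u(d_i)-\bar P_u\big)\big(P_u(d_{i+g})-\bar P_u\big),$$

with $\bar P_u$ the within-window mean; cross-covariance replaces the
second factor's property. PseKNC's correlation tiers use the standard
type-1 definition (mean squared property difference between dinucleotides
*j* steps apart), so they are defined for k = 2; other k require λ = 0.

## Feature selection

Each feature is ranked by the classical two-class **F-score**

$$F_i=\frac{(\bar x_i^{+}-\bar x_i)^2+(\bar x_i^{-}-\bar x_i)^2}
 {\tfrac{1}{n_+-1}\sum_d (x_{d,i}^{+}-\bar x_i^{+})^2+
  \tfrac{1}{n_--1}\sum_d (x_{d,i}^{-}-\bar x_i^{-})^2},$$

with the convention F = 0 when the denominator vanishes. **Incremental
feature selection (IFS)** then walks prefixes of the ranking and scores
each prefix by pooled stratified 5-fold CV AUROC of an SVM with libsvm
default parameters (C = 1, γ = 1/n features); the chosen size is the first
maximum of the curve. One fold assignment is reused across all prefix
sizes so curve points are comparable. The default prefix grid is dense
(step 1) up to 12 features and then a geometric ladder (factor 1.35) up to
the full width: at desk scale the IFS curve is smooth, the ladder locates
the plateau at a fraction of the CV cost, and `grid =`/`stride =` restore
a step-1 scan when exact curve resolution matters.

Because a small site collection cannot support hundreds of redundant
features, the pipeline then searches **all combinations of 3 encoders**
(C(8,3) = 56), concatenating each encoder's IFS-chosen subset and scoring
by the same CV; ties break toward fewer features, then lexicographic
combination name.

## Models and tuning

The principal classifier is an RBF-kernel SVM (libsvm via `e1071`).
Features are standardized with training-partition statistics only — the
scaling is stored in the model and applied to any new data, so nothing
leaks from test windows into scaling. The (C, γ) search covers the log
grid C = 2^e, e ∈ {−5, −3, …, 15} and γ = 2^e, e ∈ {−15, −14, …, 5} — 231
points under one shared fold assignment, selected by CV AUROC with AUPRC,
then smaller C, then smaller γ as tie-breakers (both metrics are reported
for every point; selection uses AUROC as the primary criterion). The step
specifications are read as exponent increments (2 for C, 1 for γ),
libsvm's customary log-grid; both exponent vectors are arguments.

SVM scores are decision values mapped through the logistic function: this
is rank-preserving (so AUROC/AUPRC are unaffected by the choice), fully
deterministic, and places the 0.5 hard-label threshold exactly at the
margin sign. Platt-style recalibration was deliberately avoided — it adds
an internal cross-validation whose folds would have to be seeded and whose
benefit is nil for rank-based evaluation. Logistic regression (`glm`),
random forest (`randomForest`, 500 trees, seeded) and Gaussian naive Bayes
(`e1071`) baselines expose the same [0,1]-score interface; the random
forest consumes raw (unstandardized) features, as is conventional.

## Evaluation

AUROC is computed in its Mann–Whitney form (probability a positive
outscores a negative, ties counting one half) and AUPRC by the step-wise
non-interpolated rule. Sensitivity TP/(TP+FN), specificity TN/(TN+FP) and
accuracy use hard labels at the fixed 0.5 threshold (a tunable argument;
`youden_threshold()` offers the J-optimal alternative for exploratory
use, and `roc_curve()`/`pr_curve()` export the underlying curve points). Cross-validation pools out-of-fold
scores into a single curve and also retains per-fold reports; note the
pooled AUROC is *not* guaranteed to lie inside the range of per-fold
AUROCs, so no such invariant is asserted or assumed.

Two harness-level evaluations matter for interpretation:

* `dhu_cv()` wraps the *entire* pipeline — encoding, F-score, IFS,
  combination search, final SVM — inside outer stratified folds, so
  selection never sees the evaluation windows. This is the honest
  generalization estimate: on motif-free data it concentrates around 0.5,
  whereas the selection stage's own "best CV AUROC" is optimistically
  biased (it is a maximum over 56 combinations of a maximum over prefix
  sizes) and can sit near 0.7 on pure noise at n = 400. The package
  reports both, and the difference is itself a useful diagnostic.
  `dhu_cv()` keeps default SVM parameters inside the folds (the same
  defaults the selection stage uses); the grid search is reserved for
  final models.
* `cross_species()` applies one species' frozen pipeline — its chosen
  features, tuned (C, γ) and training scaling, with no refitting — to
  another species' windows; diagonal cells use only the target species'
  independent test partition.

Chance bands come from `auroc_null_band()`: a Monte-Carlo permutation of
class labels against uninformative scores for the given class sizes
(optionally for the mean of several replicates). For 200+200 the central
95% band is ≈ 0.5 ± 0.057.

## The synthetic generator

`synthetic_config()` / `generate_windows()` emulate the study design:
41-nt uridine-centered windows, 200 positives + 200 negatives by default,
uniform background (a GC-skewed background is one argument away), and a
GA-rich motif — default `GAGA` starting 6 nt upstream of the center —
planted *probabilistically*, each motif position independently with
probability `motif_strength` (default 0.9). Probabilistic planting makes
difficulty continuous: strength 0 is an exact null, strength 1 a
deterministic motif. Both classes have a central U, so the center itself
carries no signal. `generate_transcriptome()` splices the positive windows
into background transcripts with a site table, exercising the full
FASTA-extraction path; extraction reproduces the planted windows exactly.

What the generator does *not* emulate: real transcriptome base
composition and codon structure, sequence-family redundancy, detection
biases of the profiling protocols, position-dependent motif degeneracy,
and any structure-level signal. Passing tests on synthetic data therefore
demonstrate that the machinery recovers planted sequence signal and is
calibrated under the null — not that any particular organism's D sites are
predictable at a given AUROC.

## Problem sizes and numerical choices

The bundled tests and the acceptance script run at desk scale, chosen
once: null calibration uses ten 200+200 replicates under nested 5-fold
evaluation; signal recovery uses one 200+200 dataset with an 80/20 split
and the full 231-point grid; cross-species fixtures use 150+150 per
species. Fold assignments, generator draws and tree seeds all flow from
explicit integer seeds, and every routine restores the caller's RNG
state. Ties in the F-score ranking resolve by column order (canonical:
position-major, channel-minor; lexicographic k-mers), IFS ties by the
smallest prefix, grid ties as above — all deterministic. Constant
training features are scaled to zero with a warning rather than dropped,
so column bookkeeping stays aligned; the GLM and naive Bayes fits exclude
them internally.

## Known limitations

* Feature selection inside `dhu_fit()` is performed once on the training
  partition; its reported selection AUROCs are optimistic, and `dhu_cv()`
  is the supported way to estimate honest pipeline performance.
* The redundancy stage assumes equal-length center-aligned windows; it is
  not a general-purpose clusterer (no gaps, no variable lengths).
* PseKNC correlation tiers require the dinucleotide property table
  (k = 2); trinucleotide property sets are out of scope.
* Only transcript-relative coordinates are handled — no genome
  coordinates, strands or isoform mapping.
* The default property table is a pragmatic, exactly-reproducible set;
  users studying structure-sensitive hypotheses should substitute a
  curated helical-parameter table via `dhu_properties(path = ...)`.
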