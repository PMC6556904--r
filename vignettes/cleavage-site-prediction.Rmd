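---
title: "Predicting protease substrate cleavage sites with procleave"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting protease substrate cleavage sites with procleave}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(procleave)
```

## The problem

Proteases hydrolyse peptide bonds in specific protein substrates. In
Schechter--Berger nomenclature the cleaved (scissile) bond lies between the
P1 and P1' residues, with P2, P3, ... extending N-terminally and P2', P3',
... C-terminally. Substrate specificity is encoded, to a useful first
approximation, in the residues flanking the bond: caspases, for example,
require Asp at P1 and often prefer Asp at P4 (the canonical DXXD motif),
while matrix metallopeptidases show a diffuse Gly-rich preference across
many positions. `procleave` frames cleavage-site prediction as supervised
classification of candidate bonds: every bond of a substrate is represented
by the 16-residue P8--P8' window around it, encoded as a numeric feature
vector, and scored by a per-protease support vector regression (SVR) model
trained on annotated cleavage events.

## Samples and windows

Positive samples are the annotated P1 positions of a protease; candidate
negatives are all remaining bonds of the same substrates, excluding
positions annotated for that same protease (sites of *other* proteases may
serve as negatives, since models are protease-specific). Because negatives
vastly outnumber positives, they are down-sampled uniformly at random to a
fixed ratio of **3 negatives per positive**. When per-residue solvent
accessibility predictions are available, candidate negatives are first
restricted to bonds whose P1 residue is predicted buried, on the rationale
that genuinely accessible uncleaved bonds are less reliable non-examples;
without such tracks, plain random down-sampling is used and recorded in the
sample set's provenance.

Windows near a terminus are padded with the 21st letter `X`, which also
absorbs non-standard residues (B, Z, U, O, J, `*`, `-`) at input
normalization. One consequence worth knowing: padded windows occur only at
sequence termini, and annotated sites rarely sit there, so the `X` indicator
carries a small amount of genuine class signal in down-sampled training
sets. This is a property of the sampling design, not a bug; it is visible
as a null AUC slightly above 0.5 in motif-free simulations (see below).

Substrate sets can be de-duplicated before splitting with
`reduce_redundancy()`, a greedy longest-first clustering under a shared
5-mer identity estimate (a CD-HIT-style word filter; precomputed cluster
files from an external tool can be substituted upstream). Train/test
splitting is always at substrate level, by default 5/6 : 1/6.

## Feature schemes

Eleven encoding schemes are available; enabled schemes are concatenated in
a fixed canonical order. With all eleven enabled a window is represented by
`r sum(scheme_dims())` components:

```{r}
scheme_dims()
```

* **BINARY** (336): per-position one-hot over the 21-letter alphabet.
* **CKSAAP** (2400): composition of k-spaced residue pairs for k = 0..5;
  each count is divided by the number of k-spaced pairs in the window,
  `16 - (k + 1)`; pairs touching `X` contribute to the denominator but to
  no pair type.
* **KNN** (5): for K equal to 1, 3, 5, 7 and 9 % of a labelled reference
  set, the fraction of positives among the K reference windows most similar
  to the query under clipped BLOSUM62 similarity
  (`sum(max(BLOSUM62(a, b), 0))`). A reference window identical to the
  query is excluded from its own ranking.
* **AAC** (20): residue composition over the window (`X` uncounted).
* **PSSM** (320): the 20 profile scores per position from a PSI-BLAST
  ASCII PSSM, logistic-squashed (`1/(1 + exp(-s))`); padded positions give
  zero rows. The log-odds score block of the PSSM file is used.
* **BLOSUM** (336): the BLOSUM62 row of each position's residue; the `X`
  row is all zeros.
* **AAINDEX** (1024): 64 physicochemical indices per position, each
  min-max scaled to [0, 1] over its 20 residue values; `X` takes the
  per-index mean. Because the canonical choice of 64 indices is not fixed
  anywhere, `choose_aaindex_subset()` selects them deterministically from
  any supplied AAindex table by greedy maximum-minimum-distance
  (accession-order tie-breaks), and the resulting list is version-stamped
  so a model refuses feature vectors built under a different list.
* **CHR** (9): net charge (K, R, H: +1; D, E: -1), summed Kyte--Doolittle
  hydropathy, and `charge / (|hydropathy| + 1)` over the N-side (P8--P1),
  C-side (P1'--P8') and full window. The 3 x 3 construction is this
  package's concrete reading of a "charge/hydrophobicity ratio" block of
  dimension 9 and is documented as non-canonical.
* **SS / SA / DISO** (48 / 32 / 32): per-position one-hots of 3-state
  secondary structure and 2-state solvent accessibility, and the pair
  `(p, 1 - p)` of the disorder probability. Padded positions take uniform
  state priors. These tracks are pluggable inputs (e.g. from SABLE or
  DISOPRED2 runs); the package never invokes the predictors itself.

`encoding_context()` bundles the providers each scheme needs and
`build_feature_matrix()` produces the sample-by-feature matrix with a
column manifest naming every component.

## Feature selection

Selection is two-step. First, `mrmr_rank()` ranks features by the greedy
minimum-redundancy--maximum-relevance criterion in its difference (MID)
form: the first feature maximizes mutual information with the labels; each
next feature maximizes relevance minus mean redundancy against the already
chosen set. Mutual information is estimated from empirical joint
frequencies (0 log 0 = 0) on three-level discretized columns: values at or
beyond one population standard deviation from the column mean map to the
outer levels. The inclusive comparison and population (rather than sample)
standard deviation are deliberate so that a balanced 0/1 indicator, which
sits exactly on its thresholds, still spans two levels. The top 100 ranked
features are the *optimal feature candidates* (OFCs).

Second, `forward_select()` grows prefixes of the ranking one feature at a
time, recording mean 5-fold cross-validated AUC of the SVR pipeline at each
size with the fold assignment held fixed throughout (otherwise points on
the curve would not be comparable), and keeps the smallest prefix attaining
the maximum — selection curves typically plateau, and the smallest-k rule
makes the choice deterministic. One set of SVR hyperparameters, tuned by a
single grid search on the full OFC matrix, is reused at every prefix size;
re-tuning at every size would multiply cost roughly a hundredfold for
little benefit on plateaued curves.

## Models, scoring and thresholds

`train_model()` min-max scales each column to [0, 1] using training data
only, fits an RBF-kernel epsilon-SVR against 0/1 targets, and tunes
`(C, gamma, epsilon)` by grid search maximizing mean 5-fold CV AUC with
shared folds. The default grid crosses `C = 2^{-5, -3, ..., 5}` with
`gamma = 2^{-7, -5, ..., 3}` and `epsilon in {0.01, 0.1}` (powers-of-two
steps of 4x, the usual libsvm practice-guide pattern); examples in this
vignette and the package's own end-to-end checks use a smaller explicit
grid of the same shape, which on the simulated data changes CV AUC by less
than a point. Raw regression outputs are clipped to [0, 1] and read as
cleavage propensity scores — the minimal calibration consistent with
treating the SVR output as a probability-like score.

During cross-validation the KNN scheme's reference is the full training
set with exact-duplicate self-exclusion (a window never votes for itself),
rather than per-fold re-encoding; self-exclusion removes the dominant
leakage path while keeping the feature matrix fixed across folds, which
the forward-selection contract requires.

Evaluation uses sensitivity, specificity, accuracy and Matthews
correlation, each computed in both of their standard printed formulations
(TP/TN/FP/FN and class-total/misclassification-count forms) with an
internal equality assertion, plus trapezoidal ROC AUC, which on tied
scores equals the Mann--Whitney statistic `U / (n+ n-)`. One degenerate
corner deserves a note: at total misclassification the class-total
formulation yields accuracy 0 (and MCC -1); a reader of the intuitive
formulas might expect otherwise, but 0 is what the accuracy definition
gives and what this package returns. When a confusion marginal is zero the
MCC denominator vanishes; the MCC is then reported as 0 and flagged
`mcc_defined = FALSE`.

For proteome scanning, `threshold_at_specificity()` converts a target
specificity into a score threshold on the training negatives; at target
1.0 (the "100 % specificity" operating point used for whole-proteome
scans) the threshold is the maximum negative score plus one score-grid
increment (1e-6), so no defining negative passes. `scan_sequences()`
scores every bond of every input sequence with every supplied model —
scores always come from the full P8--P8' feature window, while the
reported display segment is the conventional P4--P4' string with `|` at
the bond — and reports N-/C-fragment sizes (`p1` and `length - p1`).
A soft cap of 50 sequences per scan mirrors common server limits; the cap
warns but never truncates.

## What the synthetic generator emulates — and what it does not

`generate_substrates()` produces MEROPS-like substrate sets: i.i.d.
uniform background residues with 16-residue windows around annotated P1
positions redrawn from a position weight matrix, interpolated toward
background by a `strength` in [0, 1]. Two stock motifs are provided:
`caspase_like_motif()` (Asp-dominated P1 and P4, with weaker Glu/Val/Gly
preferences at P3, P2 and P1' after the canonical DEVD|G specificity) and
`gly_rich_motif()` (Gly elevated at P7, P4, P2, P1, P3' and P6', after the
diffuse MMP pattern). The uniform background keeps composition-based null
tests exact (a chi-squared test on strength-0 windows is calibrated);
real proteomes have non-uniform residue usage, positional autocorrelation,
domain structure and homology between substrates, none of which is
simulated. Optional structural tracks come from simple Markov chains and
are plausible only in their marginal statistics. Passing tests on this
generator therefore demonstrates that the machinery recovers planted
signal under controlled conditions — not that any particular real
protease reaches a particular AUC.

Problem sizes used by the package's end-to-end checks, chosen as sensible
desk-scale defaults: the motif-recovery experiment uses 150 substrates of
120--240 residues with two planted sites each (300 positives, 900
down-sampled negatives) at motif strength 0.9, where the sequence-only
pipeline reaches CV AUC about 0.98; the same pipeline on strength-0 data
scores near chance (0.51 at the fixed seed; across seeds roughly
0.48--0.59, the upward drift being the terminal-padding artefact noted
above). The feature-selection recovery experiment plants 5 informative
columns among 50 (100 positives, 300 negatives, 1.5-SD effect); forward
selection over the mRMR ranking recovers all five at the fixed seed. The
proteome-scan experiment trains on 100 substrates and scans 25 held-out
single-site substrates; its planted sites use motif strength 1, emulating
experimentally verified canonical sites — at strength 0.9 about 14 % of
"true" sites lack the P1 Asp altogether, and no scanner could rank such a
site first. At the fixed seed the top-ranked candidate is the planted P1
in 21/25 substrates (84 %); across independent training and proteome draws
the rate varies widely for so small a proteome, roughly between 0.65 and
0.9, because a planted window can still miss its secondary motif positions
by chance and be outranked by a background near-motif.

## Numerical choices and degenerate inputs

* Ties at the decision threshold count as predicted positive; every
  confusion count depends on this convention, so it is fixed and stated.
* KNN ranking ties are broken by stable reference order; `K` is
  `max(1, round(f * N))` against the full reference size.
* mRMR ties resolve to the lowest column index; grid-search ties keep the
  earliest grid row; the forward-selection plateau resolves to the
  smallest prefix.
* Constant feature columns discretize to the middle level and min-max
  scale to 0 (range treated as 1).
* Homology reduction, with no randomness, is deterministic given the
  input; all sampling steps (splits, down-sampling, folds, simulation)
  take explicit seeds and are bit-reproducible under them.
* AAindex entries containing missing values are dropped at parse time,
  before subset selection.

## Known limitations

Exosite- and allostery-regulated proteases (several MMPs, thrombin)
violate the core assumption that flanking sequence determines cleavage;
no window encoding can fully capture them. The homology-reduction
identity estimate is a word filter, coarser than banded alignment, and is
meant for de-duplication rather than precise identity computation. The
CHR block construction and the AAindex subset are deterministic package
conventions, not community standards; both are recorded in model bundles
so results remain reproducible across versions.
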