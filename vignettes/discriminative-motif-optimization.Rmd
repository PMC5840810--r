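---
title: "Discriminative motif optimization: models, protocol and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discriminative motif optimization: models, protocol and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(damo)
```

## The model

A transcription factor's binding preference over a fixed width $w$ is
represented three ways in this package:

* **PFM** — a $4 \times w$ column-stochastic matrix $p(b, i)$ of base
  probabilities; the form motif databases distribute. Its natural scan
  score is the log-likelihood $\sum_i \log p(s_i, i)$.
* **PWM** — a $4 \times w$ matrix of unconstrained additive weights
  $W(b, i)$; a site scores $\sum_i W(s_i, i)$. Every PFM's
  log-likelihood scorer is a PWM, but not conversely: freed from the
  column-stochastic constraint, PWMs express trade-offs between
  positions that probabilistic matrices cannot.
* **Dinucleotide PWM** — $16 \times (w-1)$ weights over adjacent base
  pairs, $\sum_{i<w} W(s_i s_{i+1}, i)$. This is the smallest additive
  relaxation of position independence: it captures nearest-neighbour
  dependence while remaining a linear model. `embed_mono_in_dinuc()`
  maps any PWM to a dinucleotide PWM with *identical* scores on every
  site (pair column $i$ carries the first base's weight; the final
  column carries both), so the dinucleotide family strictly contains
  the mononucleotide one and can be seeded from the same matrix.

Conversions: `pfm_to_seed_pwm()` is the natural-log log-odds transform
against a background (uniform by default); `pwm_to_pfm()` treats
column weights as energies and applies a column-wise softmax
(Boltzmann normalization), stabilized by subtracting the column
maximum. With a uniform background the two are exact inverses, and the
softmax is invariant to per-column constant shifts — which is also why
training needs no weight normalization: AUROC only sees the ranking,
and adding a constant to a column shifts every site score equally.

## Training: perceptron AUROC maximization

`train_damo()` seeds a PWM (or its dinucleotide embedding) from a PFM
and then iterates perceptron error correction:

1. score all positive and negative training sites with the current
   matrix;
2. the **misclassified** sites are the positives scoring strictly
   below the maximum negative score and the negatives scoring strictly
   above the minimum positive score — exactly the sites involved in
   ranking errors; ties are left alone;
3. each misclassified positive adds the learning rate to the weights
   of its observed features (bases, or adjacent pairs in dinucleotide
   mode); each misclassified negative subtracts it.

The training AUROC is recorded after every epoch, with the seed itself
as epoch 0, and the returned model is the snapshot attaining the best
training AUROC — not the final matrix. Because epoch 0 is always a
candidate, the result can never rank worse than the seed on the
training set.

Choices the algorithm's published description leaves open, fixed here
as defaults:

| parameter | default | rationale |
|---|---|---|
| learning rate | 0.01 | small relative to log-odds seed weights (order 1), so early epochs refine rather than overwrite the seed |
| max epochs | 500 | training AUROC plateaus far earlier on all datasets we generate |
| patience | 45 | epochs without a new best before stopping; generous relative to observed plateau onset |
| update scheme | batch | misclassified sites are identified once per epoch, then applied in seeded-shuffled order; as the updates are additive, the result is order-independent and reproducible |
| seed transform | log-odds, uniform background | makes PFM→PWM→PFM an exact round trip and gives the seed the same ranking as the PFM's log-likelihood scan |
| pseudocount | 1 (Laplace), at read time | guarantees strictly positive probabilities so the log-odds seed is finite |
| dinucleotide features | pairs only (16 × (w−1)) | the mono model embeds exactly, so mono+pair concatenation would add nothing but redundancy |

A stop is also triggered when training AUROC reaches 1, since no
further epoch can improve it.

## The evaluation protocol

`extract_windows()` builds the dataset geometry: the positive window is
the 100 bp interval centered on each peak's point-source (narrowPeak
summit when present, floored midpoint otherwise; for odd widths the
extra base falls right of the point-source), and the paired negative
is the same-width window 100 bp downstream of the positive's end
(5000 bp reproduces the distal-negative variant). Coordinates are
0-based half-open throughout; pairs that would leave the chromosome
are dropped whole.

`build_site_dataset()` then freezes the unit of all later computation:
each window is scanned once with the seed matrix, on both strands,
skipping windows containing ambiguous bases, and only the best site is
kept (ties break to the smaller offset, then the forward strand).
Training never re-scans — models of different complexity are compared
on identical, predefined sites, so the benchmark measures
classification, not site discovery. A sequence with no scannable
window raises an error rather than vanishing silently.

`make_folds()` shuffles pairs with a seeded generator and deals them
round-robin into k = 10 folds; a positive and its paired negative
always share a fold, fold sizes differ by at most one pair, and each
training split is 9× its test fold. `small_training_variant()` draws
two disjoint subsets of one-tenth of the pairs each, to expose the
sensitivity of complex models to training-set size.

Metrics are tie-exact by construction, because matrix scores over
short sites tie constantly:

* `auroc()` uses the rank-sum identity and counts tied pairs as ½,
  identical to exhaustive pair counting;
* `auprc()` is non-interpolated average precision with tied scores
  grouped, so no threshold can split a tie.

Standard deviations use the $n-1$ denominator. `comparison_report()`
renders a list of cross-validated summaries as a `mean (sd)` table
(3 decimals), per-model train−test gap box plots, and pairwise
scatter plus sorted-difference plots for chosen model pairs.

## Feature-vector classifiers

For the non-linear baselines, `assemble_features()` builds per-site
vectors in a fixed block order — matrix score (1), 4-bit one-hot
sequence (4w; bit order A=1000, T=0100, G=0010, C=0001), DNA shape
(8w) — for the variants `4bit`, `4bit+shape`, `shape_only` and
`matrixscore+shape`. Shape values (HelT, MGW, ProT, Roll and their
second-order variants) are **consumed from files, never computed**:
predicting structure from sequence is an external resource's job, and
the second-order features are treated as four additional opaque
tracks. `normalize_shape()` min-max scales each feature over all
positions of the *training* tracks only, clamps test values to
[0, 1], and maps constant features to 0.5.

The classifier itself is a contract — `fit(x, y, seed)` /
`predict_score(fitted, x)`, deterministic given the seed, scores used
only for ranking — with two adapters: `classifier_logistic()` (base
`glm`, deterministic, adequate for linear read-outs of the feature
blocks) and `classifier_gbm()` (xgboost gradient-boosted trees,
single-threaded with a fixed seed). Since a PWM is a linear function
of the 4-bit encoding, the `4bit` variant's hypothesis space contains
every PWM of the same width.

## Synthetic data: what it emulates, what it does not

`generate_dataset()` mirrors the structure of the ChIP-seq benchmark:
positives are i.i.d. background (GC content configurable, default
0.5) with exactly one site sampled from a generating PFM planted at a
uniform random offset in a 100 bp window; negatives are pure
background. The generating PFM's columns come from a symmetric
Dirichlet whose concentration sets motif sharpness — 0.1 yields
sharp, information-rich columns typical of curated motifs, and is the
package's standard planted-motif condition (with 500+500 sequences
for recovery experiments).

An optional **adjacent-pair coupling** multiplies the joint
distribution of one neighbouring position pair by $e^{\lambda}$ on
selected dinucleotides and renormalizes. The
`dinuc_advantage_experiment()` condition sets the coupled pair's PFM
columns to uniform and puts weight +3 on the four matching pairs (AA,
CC, GG, TT): the pair joint is then strongly assortative while both
single-base marginals stay uniform, so the injected information is
*invisible to any mononucleotide PWM* but available to the
dinucleotide model. With coupling enabled the dinucleotide mode wins
on held-out AUROC on average (≈ +0.01–0.02 under the default
condition); with coupling disabled the coupled pair carries no
information at all and the two modes tie up to Monte-Carlo noise.
An earlier draft of this experiment used a much softer motif
(concentration 1.0); best-site preprocessing over 100 bp of
background then yields a near-chance classification problem in which
neither mode can show anything, which is why the condition matches
the sharp recovery setting instead.

`genome_fixture()` exercises the coordinate logic (random
chromosomes, narrowPeak records with summit columns, deliberate
off-chromosome edge peaks), and `fabricate_shape_tracks()` stands in
for external shape predictions with base-dependent means plus
Gaussian noise — keeping the property that structure determines
sequence up to noise, which is what lets `shape_only` classifiers
discriminate at all.

What the generators deliberately do **not** model: peak-calling
noise, chromatin or nucleosome context, GC- or repeat-biased
negatives (the protocol's negatives are positional offsets only), and
real DNA-shape physics. Passing tests on this synthetic family
certifies the algorithmic machinery — scoring, training dynamics,
protocol mechanics, metric exactness — not biological performance on
real ENCODE data, whose headline numbers require the full 396-dataset
corpus.

## Numerical and degenerate-input choices

* Softmax stabilization by column-max subtraction; no exponentials of
  large positive weights.
* Best-site ties break deterministically (smaller offset, then `+`
  strand); windows with N are skipped rather than scored.
* `misclassified_sites()` uses strict inequalities, so exact ties are
  never "corrected" — a tied dataset is a fixed point, not an
  oscillation.
* Problem sizes in the test and acceptance suites (e.g. 200–500 pairs,
  ≤ 300 epochs, 10 replicate seeds) are chosen as the smallest sizes
  at which the measured properties are stable across seeds.
* Sums are floating-point: the dinucleotide embedding preserves
  scores to summation-order precision (≪ 1e-12), and serialization
  uses 17 significant digits so write/read round trips are bit-exact.

## Known limitations

* The perceptron step optimizes ranking errors greedily; it carries
  no convergence guarantee on non-separable data beyond the recorded
  best-snapshot property, and different seeds can return different
  (equally scoring) matrices.
* Trained PWMs are rank-based discriminators; their scores are not
  calibrated binding affinities and should not be interpreted as such
  without external rescaling.
* Shape tracks are positional values keyed to fixed-width sites;
  flanking context beyond the site is not represented.
* The gradient-boosting adapter exposes a minimal hyperparameter
  surface (rounds, depth, learning rate); tuning beyond that is out
  of scope.
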