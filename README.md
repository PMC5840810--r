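# damo

Discriminative optimization of transcription-factor binding motifs from
positive and negative sequence sets, as produced by ChIP-seq experiments.

## The problem

Databases such as JASPAR describe a transcription factor's sequence
preference as a **position frequency matrix** (PFM): per-position base
probabilities estimated from known binding sites. A PFM is a generative
model; it was not fitted to *discriminate* bound from unbound genomic
sequence, and on that task it leaves performance on the table.

`damo` trains a **position weight matrix** (PWM) — an additive matrix
`W` (4 × w) scoring a site `s` as

    score(s) = Σᵢ W(sᵢ, i)

directly for discrimination. Starting from the log-odds transform of a
seed PFM, a perceptron error-correction loop repeatedly

1. scores all positive and negative sites,
2. finds the misclassified sites — positives scoring below the best
   negative, and negatives scoring above the worst positive,
3. adds the learning rate to the weights of each misclassified
   positive's observed bases and subtracts it for each misclassified
   negative,

recording the training AUROC after every epoch and returning the
matrix snapshot that maximized it. An **adjacent-dinucleotide mode**
replaces the 4 × w weights with 16 × (w−1) weights over neighbouring
base pairs, capturing nearest-neighbour dependence while staying an
additive model; the mono model embeds exactly into this space, so
nothing is lost by switching.

Around that core the package implements the full evaluation protocol:

- **Window extraction** — 100 bp positive windows centered on peak
  point-sources (narrowPeak summits, else interval midpoints), with
  paired negatives 100 bp (or 5000 bp) downstream;
- **Best-site preprocessing** — each window is scanned once, on both
  strands, with the seed matrix; the best width-w site is frozen and
  used for all downstream training and testing;
- **Ten-fold cross-validation** over positive/negative pairs (9:1
  train:test), with AUROC and **AUPRC** (non-interpolated average
  precision, tie-group exact) reported as mean ± sd per split;
- **Feature-vector classifiers** — 4-bit one-hot sequence encoding
  (A=1000, T=0100, G=0010, C=0001), matrix-score and DNA-shape feature
  blocks (HelT, MGW, ProT, Roll + second-order variants, consumed from
  files and min-max normalized on training data), behind a pluggable
  binary-classifier contract with logistic and gradient-boosting
  adapters;
- **Comparison reports** — summary tables (`mean (sd)` per model),
  train−test gap box plots, and pairwise scatter / sorted-difference
  plots;
- **Synthetic generators** — seeded planted-motif sequence sets
  (optionally with adjacent-pair coupling), toy genomes with peak
  files, and fabricated shape tracks, so everything above is testable
  without downloads.

## Worked example

A synthetic E-box-like motif ships with the package. We simulate 200
positive windows with one planted site each plus 200 background
negatives, hand the pipeline a *degraded* seed (two informative columns
flattened to uniform — an imperfect database motif), and compare the
seed with the discriminatively trained PWM under ten-fold CV:

```r
library(damo)

motif <- read_pfm(system.file("extdata", "synthetic_ebox.pfm",
                              package = "damo"))

cfg <- sim_config(width = motif$width, n_pos = 200, n_neg = 200,
                  seq_len = 100, concentration = 0.1, seed = 42)
ds <- generate_dataset(cfg, generating_pfm = motif)

pr <- motif$probs
pr[, 3] <- 0.25                    # the seed is blind to positions 3
pr[, 5] <- 0.25                    # and 5 of the true motif
seed_pfm <- pfm(pr, name = "flattened_seed")

sites <- build_site_dataset(list(positive = ds$positive,
                                 negative = ds$negative),
                            pfm_to_seed_pwm(seed_pfm))
sites <- make_folds(sites, k = 10, seed = 1)

ev_seed <- cross_validate(scorer_factory_model(pfm_to_seed_pwm(seed_pfm)),
                          sites, "seed_pfm")
ev_damo <- cross_validate(
  scorer_factory_damo(seed_pfm, damo_config(seed = 7, max_epochs = 200,
                                            patience = 45)),
  sites, "trained_pwm")
ev_seed
ev_damo
```

```
eval_summary 'seed_pfm' (10 folds)
  AUROC train 0.723 (0.008)  test 0.720 (0.077)
  AUPRC train 0.672 (0.010)  test 0.691 (0.078)
eval_summary 'trained_pwm' (10 folds)
  AUROC train 0.789 (0.009)  test 0.769 (0.094)
  AUPRC train 0.794 (0.010)  test 0.792 (0.072)
```

The untrained seed ranks held-out sites at AUROC 0.720; perceptron
training on the same frozen sites lifts it to 0.769 (AUPRC 0.691 →
0.792) by re-learning the two flattened positions from the data. The
small train−test gap is characteristic of linear matrix models.
`comparison_report()` turns a list of such summaries into the summary
table and figures.

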