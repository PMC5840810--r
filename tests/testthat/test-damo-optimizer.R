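test_that("misclassified_sites applies the strict ranking rule", {
  m <- misclassified_sites(c(5, 1), c(3, 2))
  expect_equal(m$pos, 2L)            # the positive scoring 1
  expect_equal(m$neg, c(1L, 2L))     # both negatives outscore min(pos)

  # perfect separation: nothing misclassified
  m2 <- misclassified_sites(c(5, 4), c(3, 2))
  expect_length(m2$pos, 0L)
  expect_length(m2$neg, 0L)

  # exact ties are not misclassified (strict inequalities)
  m3 <- misclassified_sites(2, 2)
  expect_length(m3$pos, 0L)
  expect_length(m3$neg, 0L)

  expect_error(misclassified_sites(numeric(0), 1), "non-empty")
})

test_that("perceptron_epoch updates only misclassified-site features", {
  m <- pwm(matrix(c(1, 0, 0, 0,
                    0, 1, 0, 0), 4, 2))
  # "AC" scores 2, "GG" scores 0: separated, model unchanged
  out <- perceptron_epoch(m, pos_sites = "AC", neg_sites = "GG",
                          learning_rate = 0.5)
  expect_identical(out$weights, m$weights)

  # single misclassified positive: +lr at its observed bases
  z <- pwm(matrix(0, 4, 2))
  set.seed(1)
  up <- perceptron_epoch(z, pos_sites = "AC", neg_sites = "AC",
                         learning_rate = 0.5)
  # identical pos and neg site: tie, neither misclassified
  expect_identical(up$weights, z$weights)

  up2 <- perceptron_epoch(z, pos_sites = c("AC", "GG"),
                          neg_sites = "AG", learning_rate = 0.5)
  # scores all 0: ties everywhere, no update
  expect_identical(up2$weights, z$weights)

  m3 <- pwm(matrix(c(0, 0, 0, 1,
                     0, 0, 0, 1), 4, 2))
  set.seed(2)
  up3 <- perceptron_epoch(m3, pos_sites = "AC", neg_sites = "TT",
                          learning_rate = 0.5)
  want <- m3$weights
  want["A", 1] <- 0.5       # misclassified positive "AC": +lr
  want["C", 2] <- 0.5
  want["T", ] <- want["T", ] - 0.5  # misclassified negative "TT": -lr
  expect_equal(up3$weights, want)

  # a sequence misclassified as positive AND as negative cancels
  # exactly. Per-position weights A=0, C=1, G=2: scores AA=0, CC=2,
  # GG=4. pos {AA, CC}, neg {CC, GG}: max(neg)=4 so both positives are
  # misclassified; min(pos)=0 so both negatives are. The two "CC"
  # updates (+lr and -lr) cancel, leaving +lr on AA and -lr on GG.
  m4 <- pwm(matrix(c(0, 1, 2, 0,
                     0, 1, 2, 0), 4, 2))
  set.seed(3)
  up4 <- perceptron_epoch(m4, pos_sites = c("AA", "CC"),
                          neg_sites = c("CC", "GG"), learning_rate = 0.5)
  want4 <- m4$weights
  want4["A", ] <- want4["A", ] + 0.5
  want4["G", ] <- want4["G", ] - 0.5
  expect_equal(up4$weights, want4)
})

test_that("dinucleotide epochs update pair features", {
  z <- dinuc_pwm(matrix(0, 16, 2))
  bias <- z
  bias$weights["TT", 1] <- 1
  set.seed(4)
  up <- perceptron_epoch(bias, pos_sites = "ACG", neg_sites = "TTT",
                         learning_rate = 0.25)
  expect_equal(unname(up$weights["AC", 1]), 0.25)
  expect_equal(unname(up$weights["CG", 2]), 0.25)
  expect_equal(unname(up$weights["TT", 1]), 1 - 0.25)
  expect_equal(unname(up$weights["TT", 2]), -0.25)
})

test_that("train_damo separates separable toy data and tracks the best", {
  p <- read_pfm(c("8 8 8 8", "1 1 1 1", "1 1 1 1", "0 0 0 0"))
  tr <- train_damo(p, rep("AAAA", 6), rep("CCCC", 6),
                   damo_config(seed = 1L, max_epochs = 50L,
                               patience = 10L))
  expect_equal(tr$best_auroc, 1)

  # trace invariants: best is the max and first attainment
  expect_equal(tr$best_auroc, max(tr$epoch_auroc))
  expect_equal(tr$best_epoch,
               which(tr$epoch_auroc == tr$best_auroc)[[1L]] - 1L)

  # the snapshot reproduces the recorded best AUROC
  got <- auroc(score_sites(tr$best_model, rep("AAAA", 6)),
               score_sites(tr$best_model, rep("CCCC", 6)))
  expect_equal(got, tr$best_auroc)

  expect_error(train_damo(p, character(0), "CCCC",
                          damo_config(seed = 1L)), "at least one")
})

test_that("best_auroc never falls below the seed matrix's AUROC", {
  set.seed(13)
  for (i in 1:8) {
    w <- sample(3:6, 1L)
    gen <- sample_pfm(w, 0.5)
    seedp <- pfm((gen$probs * 20 + 1) / 24)
    pos <- random_sites(25, w)
    neg <- random_sites(25, w)
    for (mode in c("mono", "dinuc")) {
      cfg <- damo_config(seed = i, max_epochs = 30L, patience = 30L,
                         mode = mode)
      tr <- train_damo(seedp, pos, neg, cfg)
      seed_model <- pfm_to_seed_pwm(seedp)
      if (mode == "dinuc") seed_model <- embed_mono_in_dinuc(seed_model)
      seed_auroc <- auroc(score_sites(seed_model, pos),
                          score_sites(seed_model, neg))
      expect_gte(tr$best_auroc, seed_auroc)
      expect_equal(tr$epoch_auroc[[1L]], seed_auroc)
    }
  }
})

test_that("best_auroc is monotone in the epoch budget", {
  set.seed(19)
  gen <- sample_pfm(5L, 0.3)
  seedp <- pfm((gen$probs * 20 + 1) / 24)
  cfgds <- sim_config(width = 5L, n_pos = 40L, n_neg = 40L,
                      seq_len = 30L, concentration = 0.3, seed = 6L)
  ds <- generate_dataset(cfgds, generating_pfm = gen)
  sdat <- build_site_dataset(
    list(positive = ds$positive, negative = ds$negative),
    pfm_to_seed_pwm(seedp))
  pos <- sdat$positives$site_seq
  neg <- sdat$negatives$site_seq
  prev <- -Inf
  for (budget in c(5L, 20L, 60L)) {
    tr <- train_damo(seedp, pos, neg,
                     damo_config(seed = 2L, max_epochs = budget,
                                 patience = budget))
    expect_gte(tr$best_auroc, prev)
    prev <- tr$best_auroc
  }
})

test_that("the dinucleotide seed scores exactly like the mono seed", {
  set.seed(23)
  gen <- sample_pfm(6L, 0.5)
  seedp <- pfm((gen$probs * 20 + 1) / 24)
  pos <- random_sites(30, 6L)
  neg <- random_sites(30, 6L)
  tr_m <- train_damo(seedp, pos, neg,
                     damo_config(seed = 3L, max_epochs = 1L,
                                 patience = 1L, mode = "mono"))
  tr_d <- train_damo(seedp, pos, neg,
                     damo_config(seed = 3L, max_epochs = 1L,
                                 patience = 1L, mode = "dinuc"))
  # epoch-0 (seed) AUROC identical: the embedding preserves scores
  expect_equal(tr_d$epoch_auroc[[1L]], tr_m$epoch_auroc[[1L]])
})

test_that("trace serialization writes one row per epoch", {
  p <- read_pfm(c("5 5", "1 1", "1 1", "1 1"))
  tr <- train_damo(p, c("AA", "AG"), c("CC", "CT"),
                   damo_config(seed = 1L, max_epochs = 10L,
                               patience = 5L))
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_trace(tr, tmp)
  df <- read.delim(tmp)
  expect_equal(nrow(df), length(tr$epoch_auroc))
  expect_equal(df$epoch[[1L]], 0L)
  expect_equal(df$train_auroc, tr$epoch_auroc)
})
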