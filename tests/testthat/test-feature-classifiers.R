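test_that("encode_4bit follows the A=1000,T=0100,G=0010,C=0001 order", {
  expect_equal(unname(encode_4bit("A")[1L, ]), c(1, 0, 0, 0))
  expect_equal(unname(encode_4bit("T")[1L, ]), c(0, 1, 0, 0))
  expect_equal(unname(encode_4bit("G")[1L, ]), c(0, 0, 1, 0))
  expect_equal(unname(encode_4bit("C")[1L, ]), c(0, 0, 0, 1))
  expect_equal(unname(encode_4bit("AT")[1L, ]),
               c(1, 0, 0, 0, 0, 1, 0, 0))

  # one-hot property: row sums equal the width
  x <- encode_4bit(random_sites(20, 7))
  expect_equal(unname(rowSums(x)), rep(7, 20))
  expect_true(all(x %in% c(0, 1)))

  # injective: distinct sites yield distinct vectors (exhaustive w <= 3)
  for (w in 1:3) {
    kmers <- all_kmers(w)
    enc <- encode_4bit(kmers)
    expect_equal(nrow(unique(enc)), length(kmers))
  }

  expect_error(encode_4bit("ANT"), "non-ACGT")
})

test_that("normalize_shape fits min-max on training and clamps test", {
  tr <- shape_track("s1", matrix(rep(c(2, 3, 4), each = 8), 8, 3))
  norm <- normalize_shape(list(tr))
  expect_equal(unname(norm$tracks[[1L]]$values[1L, ]), c(0, 0.5, 1))

  # constant features map to 0.5
  const <- shape_track("s2", matrix(7, 8, 3))
  nc <- normalize_shape(list(const))
  expect_true(all(nc$tracks[[1L]]$values == 0.5))

  # train-time stats applied to test values, clamped to [0, 1]
  test_track <- shape_track("s3", matrix(rep(c(1, 3, 9), each = 8), 8, 3))
  nt <- normalize_shape(list(test_track), stats = norm$stats)
  expect_equal(unname(nt$tracks[[1L]]$values[1L, ]), c(0, 0.5, 1))

  # idempotent once statistics are fixed
  again <- normalize_shape(norm$tracks, stats = data.frame(
    feature = rownames(tr$values), min = 0, max = 1))
  expect_equal(again$tracks[[1L]]$values, norm$tracks[[1L]]$values)

  expect_error(normalize_shape(list()), "empty")
})

test_that("assemble_features produces the documented block layouts", {
  sites <- random_sites(6, 10)
  tracks <- fabricate_shape_tracks(sites, seed = 1L)
  tracks <- normalize_shape(tracks)$tracks

  fv <- assemble_features(sites, "shape_only", shape_tracks = tracks)
  expect_equal(ncol(fv$x), 80L)              # 8 features x 10 positions
  expect_equal(fv$layout$block, "shape")

  fv2 <- assemble_features(sites, "4bit")
  expect_equal(ncol(fv2$x), 40L)             # 4 x 10

  set.seed(2)
  model <- random_pwm(10L)
  fv3 <- assemble_features(sites, "matrixscore+shape", model = model,
                           shape_tracks = tracks)
  expect_equal(ncol(fv3$x), 81L)             # 1 + 80
  expect_equal(fv3$layout$block, c("matrix_score", "shape"))
  expect_equal(fv3$x[, 1L], score_sites(model, sites),
               ignore_attr = TRUE)

  fv4 <- assemble_features(sites, "4bit+shape", shape_tracks = tracks)
  expect_equal(ncol(fv4$x), 120L)            # 40 + 80
  expect_equal(sum(fv4$layout$extent), 120L)

  expect_error(assemble_features(sites, "matrixscore+shape",
                                 shape_tracks = tracks), "model")
  expect_error(assemble_features(sites, "4bit+shape"), "shape")
})

test_that("shape tracks round-trip through the TSV format", {
  sites <- random_sites(4, 6)
  tracks <- fabricate_shape_tracks(sites, seed = 3L)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_shape_tracks(tracks, tmp)
  back <- read_shape_tracks(tmp)
  expect_equal(length(back), length(unique(sites)))
  id <- tracks[[1L]]$site_id
  expect_equal(back[[id]]$values, tracks[[1L]]$values,
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("classifier adapters satisfy the contract", {
  set.seed(17)
  # single perfectly label-correlated feature
  x <- cbind(feat = c(rnorm(40, 3), rnorm(40, -3)))
  y <- rep(c(1L, 0L), each = 40L)
  for (clf in list(classifier_logistic(), classifier_gbm())) {
    fit <- clf$fit(x, y, seed = 1L)
    s <- clf$predict_score(fit, x)
    expect_equal(auroc(s[y == 1L], s[y == 0L]), 1)

    # determinism: same seed + same data -> identical predictions
    fit2 <- clf$fit(x, y, seed = 1L)
    expect_equal(clf$predict_score(fit2, x), s)
  }

  # shuffled labels give chance-level performance over replicates
  set.seed(23)
  clf <- classifier_logistic()
  null_auroc <- replicate(15, {
    yp <- sample(y)
    fit <- clf$fit(x, yp, seed = 1L)
    s <- clf$predict_score(fit, x)
    auroc(s[yp == 1L], s[yp == 0L])
  })
  expect_lt(abs(mean(null_auroc) - 0.5), 0.1)
})

test_that("shape-only classification discriminates planted sites", {
  set.seed(31)
  # sized so the training rows comfortably exceed the 8 x width shape
  # features; smaller designs leave logistic regression rank-deficient
  cfg <- sim_config(width = 8L, n_pos = 100L, n_neg = 100L,
                    seq_len = 40L, concentration = 0.1, seed = 12L)
  ds <- generate_dataset(cfg)
  seedp <- pfm((ds$truth$pfm$probs * 100 + 1) / 104)
  sdat <- build_site_dataset(
    list(positive = ds$positive, negative = ds$negative),
    pfm_to_seed_pwm(seedp))
  sdat <- make_folds(sdat, k = 5L, seed = 2L)
  all_sites <- unique(c(sdat$positives$site_seq, sdat$negatives$site_seq))
  tracks <- fabricate_shape_tracks(all_sites, seed = 5L, noise_sd = 0.2)
  ev <- cross_validate(
    scorer_factory_classifier("shape_only",
                              classifier = classifier_logistic(),
                              shape_tracks = tracks),
    sdat, "shape_only")
  # shape encodes sequence up to noise, so it must beat chance clearly
  expect_gt(ev$test_auroc_mean, 0.7)
})

test_that("any PWM is a linear function of the 4-bit encoding", {
  # the linear-classifier feature space therefore subsumes every PWM of
  # the same width: lay the trained PWM's weights over the 4-bit layout
  # and the linear score reproduces score_sites exactly
  set.seed(41)
  gen <- sample_pfm(4L, 0.3)
  seedp <- pfm((gen$probs * 20 + 1) / 24)
  pos <- random_sites(30, 4L)
  neg <- random_sites(30, 4L)
  tr <- train_damo(seedp, pos, neg,
                   damo_config(seed = 5L, max_epochs = 120L,
                               patience = 120L))
  m <- tr$best_model$weights
  # 4-bit order within each position block is A, T, G, C
  beta <- as.vector(apply(m[c("A", "T", "G", "C"), , drop = FALSE],
                          2L, identity))
  x <- encode_4bit(c(pos, neg))
  expect_equal(unname(x %*% beta)[, 1L],
               score_sites(tr$best_model, c(pos, neg)))
})
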