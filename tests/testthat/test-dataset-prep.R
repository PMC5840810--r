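make_toy_genome <- function(len = 10000L, seed = 1L) {
  set.seed(seed)
  g <- Biostrings::DNAStringSet(paste(
    sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""))
  names(g) <- "chr1"
  g
}

test_that("extract_windows applies the window/offset arithmetic", {
  g <- make_toy_genome()
  peaks <- data.frame(chrom = "chr1", point_source = 500L)
  w <- extract_windows(peaks, g, window = 100L, negative_offset = 100L)
  pos <- w[w$label == "positive", ]
  neg <- w[w$label == "negative", ]
  expect_equal(c(pos$start, pos$end), c(450L, 550L))
  expect_equal(c(neg$start, neg$end), c(650L, 750L))
  expect_equal(pos$pair_id, neg$pair_id)
  expect_equal(nchar(w$seq), rep(100L, 2L))
  expect_equal(pos$seq, as.character(Biostrings::subseq(g[[1]], 451, 550)))

  # distal-negative variant
  w5k <- extract_windows(peaks, g, window = 100L, negative_offset = 5000L)
  neg5k <- w5k[w5k$label == "negative", ]
  expect_equal(c(neg5k$start, neg5k$end), c(5550L, 5650L))

  # odd window width: extra base to the right of the point-source
  w7 <- extract_windows(peaks, g, window = 7L, negative_offset = 10L)
  pos7 <- w7[w7$label == "positive", ]
  expect_equal(c(pos7$start, pos7$end), c(497L, 504L))
})

test_that("pairs whose windows leave the chromosome are dropped together", {
  g <- make_toy_genome()
  peaks <- data.frame(chrom = "chr1",
                      point_source = c(30L, 500L, 9950L))
  w <- extract_windows(peaks, g, window = 100L, negative_offset = 100L)
  # peak at 30: positive start < 0; peak at 9950: negative end > 10000
  expect_equal(sum(w$label == "positive"), 1L)
  expect_equal(w$start[w$label == "positive"], 450L)

  expect_error(extract_windows(data.frame(chrom = "chrX",
                                          point_source = 500L), g),
               "chrX")
})

test_that("negative windows sit exactly negative_offset downstream", {
  fx <- genome_fixture(n_chroms = 2L, chrom_len = 20000L, n_peaks = 40L,
                       seed = 8L)
  for (off in c(100L, 500L)) {
    peaks <- data.frame(chrom = fx$peaks$chrom,
                        point_source = fx$peaks$start + fx$peaks$summit)
    w <- extract_windows(peaks, fx$genome, window = 100L,
                         negative_offset = off)
    pos <- w[w$label == "positive", ]
    neg <- w[w$label == "negative", ]
    neg <- neg[match(pos$pair_id, neg$pair_id), ]
    expect_true(all(neg$start - pos$end == off))
  }
})

test_that("narrowPeak summits are used as point-sources", {
  fx <- genome_fixture(n_chroms = 1L, chrom_len = 5000L, n_peaks = 10L,
                       seed = 3L)
  dir <- withr::local_tempdir()
  paths <- write_genome_fixture(fx, dir)
  peaks <- read_peaks(paths$peaks)
  expect_equal(nrow(peaks), 10L)
  expect_equal(peaks$point_source, fx$peaks$start + fx$peaks$summit)

  # BED3 falls back to the floored midpoint
  bed3 <- file.path(dir, "plain.bed")
  writeLines(c("chr1\t100\t201", "chr1\t300\t400"), bed3)
  p3 <- read_peaks(bed3)
  expect_equal(p3$point_source, c(150L, 350L))
})

test_that("best_site matches exhaustive enumeration and handles edges", {
  # single candidate window
  m <- pwm(matrix(rnorm(16), 4, 4))
  b <- best_site(m, "ACGT")
  expect_equal(b$offset, 0L)

  # planted strong site
  fav <- pwm(10 * diag(4)[, c(1, 2, 3, 4)])  # favors ACGT
  b2 <- best_site(fav, "TTACGTTT")
  expect_equal(b2$offset, 2L)
  expect_equal(b2$strand, "+")
  expect_equal(b2$site_seq, "ACGT")

  # windows containing N are skipped, not scored
  b3 <- best_site(fav, "NNNNACGTTT")
  expect_equal(b3$site_seq, "ACGT")
  expect_error(best_site(fav, "ANNNA"), "ambiguous")
  expect_error(best_site(fav, "ACG"), "shorter")

  set.seed(31)
  for (i in 1:60) {
    w <- sample(3:8, 1L)
    model <- random_pwm(w)
    seqlen <- sample(w:60, 1L)
    s <- paste(sample(c("A", "C", "G", "T"), seqlen, replace = TRUE),
               collapse = "")
    got <- best_site(model, s)
    want <- best_site_oracle(model, s)
    expect_equal(got$score, want$score)

    # mirror identity: scanning the reverse complement gives the same
    # best score (offsets mirror up to exact-tie breaking)
    mir <- best_site(model, reverse_complement(s))
    expect_equal(mir$score, got$score)
    mirrored_window <- substr(reverse_complement(s),
                              seqlen - w - got$offset + 1L,
                              seqlen - got$offset)
    expect_equal(max(score_sites(model, mirrored_window),
                     score_sites(model,
                                 reverse_complement(mirrored_window))),
                 got$score)
  }
})

test_that("make_folds deals pairs round-robin into balanced folds", {
  ds100 <- toy_site_dataset(random_sites(100, 4), random_sites(100, 4))
  f <- make_folds(ds100, k = 10L, seed = 17L)
  expect_equal(as.integer(table(f$fold)), rep(10L, 10L))

  # train:test is 9:1 for every fold
  for (k in 1:10) {
    expect_equal(sum(f$fold != k) / sum(f$fold == k), 9)
  }

  # determinism
  f2 <- make_folds(ds100, k = 10L, seed = 17L)
  expect_identical(f$fold, f2$fold)

  # remainder handling: 101 pairs -> one fold of 11
  ds101 <- toy_site_dataset(random_sites(101, 4), random_sites(101, 4))
  f3 <- make_folds(ds101, k = 10L, seed = 1L)
  expect_equal(sort(as.integer(table(f3$fold))), c(rep(10L, 9L), 11L))

  expect_error(make_folds(toy_site_dataset("AAAA", "CCCC"), k = 10L,
                          seed = 1L), "at least")
})

test_that("small_training_variant draws disjoint paired subsets", {
  ds <- toy_site_dataset(random_sites(100, 4), random_sites(100, 4))
  sp <- small_training_variant(ds, fraction = 0.1, seed = 5L)
  expect_equal(nrow(sp$train$positives), 10L)
  expect_equal(nrow(sp$test$positives), 10L)
  expect_length(intersect(sp$train$positives$parent_id,
                          sp$test$positives$parent_id), 0L)
  # pairing is preserved: positives and negatives line up
  expect_equal(sp$train$positives$pair_id, sp$train$negatives$pair_id)

  sp2 <- small_training_variant(ds, fraction = 0.1, seed = 5L)
  expect_identical(sp2$train$positives$parent_id,
                   sp$train$positives$parent_id)

  ds10 <- toy_site_dataset(random_sites(10, 4), random_sites(10, 4))
  half <- small_training_variant(ds10, fraction = 0.5, seed = 2L)
  ids <- c(half$train$positives$parent_id, half$test$positives$parent_id)
  expect_setequal(ids, ds10$positives$parent_id)

  expect_error(small_training_variant(ds, fraction = 0.6, seed = 1L),
               "fraction")
})

test_that("build_site_dataset freezes seed-matrix best sites", {
  set.seed(41)
  gen <- sample_pfm(6L, 0.1)
  seedp <- pfm((gen$probs * 100 + 1) / 104)
  model <- pfm_to_seed_pwm(seedp)
  pos <- random_sites(15, 40)
  neg <- random_sites(15, 40)
  ds <- build_site_dataset(list(positive = pos, negative = neg), model)
  expect_equal(nrow(ds$positives), 15L)
  expect_equal(nchar(ds$positives$site_seq), rep(6L, 15L))
  # stored scores are the seed-model scores of the stored sites
  expect_equal(ds$positives$score,
               score_sites(model, ds$positives$site_seq))
  # each site really is the parent subsequence (or its reverse complement)
  for (i in 1:15) {
    row <- ds$positives[i, ]
    sub <- substr(pos[[i]], row$offset + 1L, row$offset + 6L)
    expect_equal(row$site_seq,
                 if (row$strand == "+") sub else reverse_complement(sub))
  }

  tmp <- withr::local_tempfile(fileext = ".tsv")
  ds <- make_folds(ds, k = 3L, seed = 1L)
  write_sites(ds, tmp)
  back <- read_sites(tmp)
  expect_equal(back$positives$site_seq, ds$positives$site_seq)
  expect_equal(back$fold, ds$fold)
  expect_equal(back$negatives$score, ds$negatives$score)
})
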