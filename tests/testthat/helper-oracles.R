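# Independent oracles and small fixture builders. These deliberately use
# the slowest, most literal formulation of each quantity so they stay
# independent of the implementation they check.

# AUROC by exhaustive pair counting.
auroc_oracle <- function(pos, neg) {
  wins <- 0
  for (p in pos) for (n in neg) {
    wins <- wins + (p > n) + 0.5 * (p == n)
  }
  wins / (length(pos) * length(neg))
}

# Average precision by sweeping a threshold over every distinct score.
auprc_oracle <- function(pos, neg) {
  np <- length(pos)
  thresholds <- sort(unique(c(pos, neg)), decreasing = TRUE)
  ap <- 0
  prev_recall <- 0
  for (t in thresholds) {
    tp <- sum(pos >= t)
    fp <- sum(neg >= t)
    recall <- tp / np
    precision <- tp / (tp + fp)
    ap <- ap + precision * (recall - prev_recall)
    prev_recall <- recall
  }
  ap
}

# Best site by literal enumeration of every offset and strand.
best_site_oracle <- function(model, sequence, both_strands = TRUE) {
  w <- motif_width(model)
  n <- nchar(sequence)
  best <- NULL
  for (off in seq_len(n - w + 1L)) {
    win <- substr(sequence, off, off + w - 1L)
    if (grepl("[^ACGT]", win)) next
    strands <- if (both_strands) c("+", "-") else "+"
    for (st in strands) {
      seq_used <- if (st == "+") win else reverse_complement(win)
      sc <- score_sites(model, seq_used)
      if (is.null(best) || sc > best$score) {
        best <- list(offset = off - 1L, strand = st, site_seq = seq_used,
                     score = sc)
      }
    }
  }
  best
}

random_pwm <- function(width) {
  pwm(matrix(stats::rnorm(4L * width), 4L, width))
}

random_dinuc_pwm <- function(width) {
  dinuc_pwm(matrix(stats::rnorm(16L * (width - 1L)), 16L, width - 1L))
}

random_sites <- function(n, width) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), width, replace = TRUE),
          collapse = "")
  }, "")
}

all_kmers <- function(width) {
  do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")), width),
                              stringsAsFactors = FALSE))
}

# A quick paired site_dataset built directly from site strings.
toy_site_dataset <- function(pos_sites, neg_sites) {
  n <- length(pos_sites)
  mk <- function(sites, label, prefix) {
    data.frame(parent_id = paste0(prefix, seq_len(n)), offset = 0L,
               strand = "+", site_seq = sites, score = 0,
               label = label, pair_id = seq_len(n),
               stringsAsFactors = FALSE)
  }
  structure(list(positives = mk(pos_sites, "positive", "p"),
                 negatives = mk(neg_sites, "negative", "n"),
                 fold = rep(NA_integer_, n)),
            class = "site_dataset")
}
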