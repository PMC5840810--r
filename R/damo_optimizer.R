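#' Training configuration for the perceptron motif optimizer
#'
#' @param learning_rate additive step applied per misclassified site
#'   feature (default 0.01, small relative to log-odds seed magnitudes).
#' @param max_epochs hard epoch cap (default 500).
#' @param patience epochs without a new best training AUROC before
#'   stopping (default 45); must not exceed `max_epochs`.
#' @param seed integer seed for the per-epoch shuffle (required).
#' @param mode `"mono"` (4 x w single-base PWM) or `"dinuc"`
#'   (16 x (w-1) adjacent-pair PWM).
#' @return a `damo_config` list.
#' @export
damo_config <- function(learning_rate = 0.01, max_epochs = 500L,
                        patience = 45L, seed, mode = c("mono", "dinuc")) {
  mode <- match.arg(mode)
  if (!is.numeric(learning_rate) || length(learning_rate) != 1L ||
      learning_rate <= 0) {
    stop("'learning_rate' must be a positive number")
  }
  max_epochs <- check_count(max_epochs, "max_epochs")
  patience <- check_count(patience, "patience")
  if (patience > max_epochs) stop("'patience' must be <= 'max_epochs'")
  if (missing(seed)) stop("'seed' is required")
  structure(list(learning_rate = learning_rate, max_epochs = max_epochs,
                 patience = patience, seed = as.integer(seed), mode = mode),
            class = "damo_config")
}

#' Identify misclassified sites for perceptron error correction
#'
#' A positive site is misclassified when its score is strictly below the
#' best (maximum) negative score; a negative site is misclassified when
#' its score is strictly above the worst (minimum) positive score. Ties
#' are not misclassified. These are the sites whose ranking errors bound
#' the ROC curve away from perfection.
#'
#' @param pos_scores,neg_scores non-empty numeric score vectors.
#' @return list with integer index vectors `pos` and `neg`.
#' @examples
#' misclassified_sites(c(5, 1), c(3, 2))
#' @export
misclassified_sites <- function(pos_scores, neg_scores) {
  if (length(pos_scores) == 0L || length(neg_scores) == 0L) {
    stop("both score vectors must be non-empty")
  }
  list(pos = which(pos_scores < max(neg_scores)),
       neg = which(neg_scores > min(pos_scores)))
}

# Aggregate one-hot update counts for a set of encoded sites: returns the
# feature-count matrix (4 x w or 16 x (w-1)) summing each site's one-hot
# encoding. Updates are additive, so aggregated counts give the same
# result as site-by-site application.
feature_counts <- function(idx, n_rows) {
  w <- nrow(idx)
  out <- matrix(0, n_rows, w)
  for (j in seq_len(w)) {
    out[, j] <- tabulate(idx[j, ], nbins = n_rows)
  }
  out
}

#' One perceptron error-correction epoch
#'
#' Scores all sites with the current model, identifies the misclassified
#' sites once at epoch start, visits them in seeded-shuffled order, and
#' for each adds `learning_rate` to the model weights at the site's
#' observed features (bases for mono, adjacent pairs for dinuc) for a
#' misclassified positive, or subtracts it for a misclassified negative.
#'
#' @param model a `pwm` or `dinuc_pwm`.
#' @param pos_sites,neg_sites character vectors of sites of the model
#'   width.
#' @param learning_rate positive step size.
#' @return the updated model.
#' @examples
#' m <- pwm(matrix(0, 4, 2))
#' perceptron_epoch(m, pos_sites = "AC", neg_sites = "GG",
#'                  learning_rate = 0.5)
#' @export
perceptron_epoch <- function(model, pos_sites, neg_sites,
                             learning_rate = 0.01) {
  stopifnot(inherits(model, c("pwm", "dinuc_pwm")))
  pos_idx <- site_index_matrix(pos_sites, model$width)
  neg_idx <- site_index_matrix(neg_sites, model$width)
  if (inherits(model, "dinuc_pwm")) {
    pos_idx <- pair_index_matrix(pos_idx)
    neg_idx <- pair_index_matrix(neg_idx)
  }
  perceptron_epoch_idx(model, pos_idx, neg_idx, learning_rate)
}

perceptron_epoch_idx <- function(model, pos_idx, neg_idx, learning_rate) {
  dinuc <- inherits(model, "dinuc_pwm")
  n_rows <- if (dinuc) 16L else 4L
  score <- if (dinuc) score_index_dinuc else score_index_mono
  ps <- score(model$weights, pos_idx)
  ns <- score(model$weights, neg_idx)
  mis <- misclassified_sites(ps, ns)
  if (length(mis$pos) == 0L && length(mis$neg) == 0L) return(model)
  # the visit order (shuffled for parity with online updating) does not
  # change the additive result, so updates are applied as aggregated
  # feature counts
  sample(length(mis$pos) + length(mis$neg))
  delta <- matrix(0, n_rows, ncol(model$weights))
  if (length(mis$pos)) {
    delta <- delta + feature_counts(pos_idx[, mis$pos, drop = FALSE], n_rows)
  }
  if (length(mis$neg)) {
    delta <- delta - feature_counts(neg_idx[, mis$neg, drop = FALSE], n_rows)
  }
  model$weights <- model$weights + learning_rate * delta
  model
}

#' Train a discriminative PWM by perceptron AUROC maximization
#'
#' Seeds a PWM from the supplied PFM by log-odds transform (and, in dinuc
#' mode, embeds it in the adjacent-dinucleotide space), then repeatedly
#' applies perceptron error correction to the misclassified sites,
#' recording the training AUROC after every epoch. The returned model is
#' the snapshot with the best training AUROC seen (the seed itself is
#' epoch 0 and always a candidate), not the final matrix. Training stops
#' at `max_epochs` or after `patience` consecutive epochs without a new
#' best AUROC.
#'
#' @param seed_pfm the seed [pfm] (strictly positive entries).
#' @param pos_sites,neg_sites character vectors of fixed-width sites
#'   (length = PFM width), at least one each.
#' @param config a [damo_config].
#' @param background length-4 background for the log-odds seed.
#' @return a `damo_trace`: list with `epoch_auroc` (index 1 = epoch 0 =
#'   seed), `best_epoch` (0-based, first attainment), `best_auroc`,
#'   `best_model` (a `pwm` or `dinuc_pwm`) and `n_epochs`.
#' @examples
#' p <- read_pfm(c("8 8 8 8", "1 1 1 1", "1 1 1 1", "0 0 0 0"))
#' tr <- train_damo(p, rep("AAAA", 5), rep("CCCC", 5),
#'                  damo_config(seed = 1, max_epochs = 50, patience = 10))
#' tr$best_auroc
#' @export
train_damo <- function(seed_pfm, pos_sites, neg_sites, config,
                       background = rep(0.25, 4)) {
  stopifnot(inherits(seed_pfm, "pfm"), inherits(config, "damo_config"))
  if (length(pos_sites) == 0L || length(neg_sites) == 0L) {
    stop("need at least one positive and one negative site")
  }
  w <- seed_pfm$width
  pos_idx <- site_index_matrix(pos_sites, w)
  neg_idx <- site_index_matrix(neg_sites, w)

  model <- pfm_to_seed_pwm(seed_pfm, background = background)
  dinuc <- config$mode == "dinuc"
  if (dinuc) {
    model <- embed_mono_in_dinuc(model)
    pos_idx <- pair_index_matrix(pos_idx)
    neg_idx <- pair_index_matrix(neg_idx)
  }
  score <- if (dinuc) score_index_dinuc else score_index_mono

  maybe_set_seed(config$seed)
  eval_auroc <- function(m) {
    ps <- score(m$weights, pos_idx)
    ns <- score(m$weights, neg_idx)
    if (!all(is.finite(ps)) || !all(is.finite(ns))) {
      stop("internal error: non-finite site scores during training")
    }
    auroc(ps, ns)
  }

  epoch_auroc <- numeric(config$max_epochs + 1L)
  epoch_auroc[[1L]] <- eval_auroc(model)          # epoch 0: the seed
  best_auroc <- epoch_auroc[[1L]]
  best_epoch <- 0L
  best_model <- model
  stale <- 0L
  n_done <- 0L

  for (e in seq_len(config$max_epochs)) {
    model <- perceptron_epoch_idx(model, pos_idx, neg_idx,
                                  config$learning_rate)
    a <- eval_auroc(model)
    epoch_auroc[[e + 1L]] <- a
    n_done <- e
    if (a > best_auroc) {
      best_auroc <- a
      best_epoch <- e
      best_model <- model
      stale <- 0L
    } else {
      stale <- stale + 1L
    }
    if (best_auroc >= 1 || stale >= config$patience) break
  }

  structure(
    list(epoch_auroc = epoch_auroc[seq_len(n_done + 1L)],
         best_epoch = best_epoch, best_auroc = best_auroc,
         best_model = best_model, n_epochs = n_done),
    class = "damo_trace"
  )
}

#' @export
print.damo_trace <- function(x, ...) {
  cat(sprintf(
    "damo training trace: %d epochs, best AUROC %.4f at epoch %d (seed %.4f)\n",
    x$n_epochs, x$best_auroc, x$best_epoch, x$epoch_auroc[[1L]]))
  invisible(x)
}

#' Write a training trace as tab-delimited text
#'
#' Columns `epoch` (0 = seed) and `train_auroc`.
#'
#' @param trace a `damo_trace`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "damo_trace"))
  utils::write.table(
    data.frame(epoch = seq_along(trace$epoch_auroc) - 1L,
               train_auroc = trace$epoch_auroc),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
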