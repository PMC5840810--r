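#' Area under the ROC curve
#'
#' Computed via the rank-sum (Mann-Whitney) identity: the probability that
#' a random positive outscores a random negative, with tied pairs counted
#' as one half. Contractually identical to exhaustive pair counting,
#' `(#\{pos > neg\} + 0.5 #\{pos == neg\}) / (n_pos * n_neg)`.
#'
#' @param pos_scores,neg_scores non-empty finite numeric score vectors.
#' @return AUROC in \[0, 1\].
#' @examples
#' auroc(c(3, 1), c(2, 0))  # 0.75
#' @export
auroc <- function(pos_scores, neg_scores) {
  np <- length(pos_scores)
  nn <- length(neg_scores)
  if (np == 0L || nn == 0L) stop("both score vectors must be non-empty")
  if (!all(is.finite(pos_scores)) || !all(is.finite(neg_scores))) {
    stop("scores must be finite")
  }
  r <- rank(c(pos_scores, neg_scores), ties.method = "average")
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' Area under the precision-recall curve (average precision)
#'
#' Non-interpolated average precision: sites are ranked by descending
#' score, tied scores are grouped so a threshold can never split a tie,
#' and precision is accumulated against recall increments after each tie
#' group: `AP = sum_g precision_g * (recall_g - recall_{g-1})`.
#'
#' @param pos_scores,neg_scores finite numeric score vectors;
#'   `pos_scores` must be non-empty.
#' @return AUPRC in (0, 1\].
#' @examples
#' auprc(c(4, 2), c(3, 1))  # 5/6
#' @export
auprc <- function(pos_scores, neg_scores) {
  np <- length(pos_scores)
  if (np == 0L) stop("positive score vector must be non-empty")
  if (!all(is.finite(pos_scores)) || !all(is.finite(neg_scores))) {
    stop("scores must be finite")
  }
  scores <- c(pos_scores, neg_scores)
  labels <- rep(c(1L, 0L), c(np, length(neg_scores)))
  # one step per distinct score, descending; ties evaluated as one group
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  l <- labels[o]
  grp_end <- cumsum(rle(s)$lengths)
  tp <- cumsum(l)[grp_end]
  n_seen <- grp_end
  precision <- tp / n_seen
  recall <- tp / np
  sum(precision * diff(c(0, recall)))
}

#' Cross-validated evaluation of a scorer factory
#'
#' Runs the k-fold protocol over a fold-assigned [build_site_dataset]
#' dataset: for each fold, the factory is trained on the other k-1 folds
#' and the returned scoring function is applied to the train and test
#' sites; AUROC and AUPRC are recorded for both splits. Untrained models
#' (e.g. the raw seed PFM) are factories that ignore the training data.
#'
#' @param scorer_factory `function(train_dataset)` returning
#'   `function(sites)` -> numeric scores; `train_dataset` is a
#'   `site_dataset` restricted to the training pairs. See
#'   [scorer_factory_model] and [scorer_factory_damo].
#' @param dataset a `site_dataset` with folds assigned ([make_folds]).
#' @param model_name label used in summaries and reports.
#' @return an `eval_summary`: `per_fold` data.frame (fold, train_auroc,
#'   test_auroc, train_auprc, test_auprc) plus mean/sd fields per metric
#'   and split (sd uses the n-1 denominator).
#' @export
cross_validate <- function(scorer_factory, dataset, model_name = "model") {
  stopifnot(inherits(dataset, "site_dataset"))
  if (all(is.na(dataset$fold))) {
    stop("dataset has no fold assignments; call make_folds() first")
  }
  folds <- sort(unique(dataset$fold))
  rows <- lapply(folds, function(f) {
    tr_idx <- which(dataset$fold != f)
    te_idx <- which(dataset$fold == f)
    if (length(tr_idx) == 0L || length(te_idx) == 0L) {
      stop(sprintf("fold %d has an empty train or test split", f))
    }
    train <- subset_pairs(dataset, tr_idx)
    test <- subset_pairs(dataset, te_idx)
    scorer <- scorer_factory(train)
    tr_p <- scorer(train$positives$site_seq)
    tr_n <- scorer(train$negatives$site_seq)
    te_p <- scorer(test$positives$site_seq)
    te_n <- scorer(test$negatives$site_seq)
    data.frame(fold = f,
               train_auroc = auroc(tr_p, tr_n),
               test_auroc = auroc(te_p, te_n),
               train_auprc = auprc(tr_p, tr_n),
               test_auprc = auprc(te_p, te_n))
  })
  per_fold <- do.call(rbind, rows)
  summ <- list(model_name = model_name, per_fold = per_fold)
  for (m in c("auroc", "auprc")) {
    for (s in c("train", "test")) {
      v <- per_fold[[paste(s, m, sep = "_")]]
      summ[[paste(s, m, "mean", sep = "_")]] <- mean(v)
      summ[[paste(s, m, "sd", sep = "_")]] <- stats::sd(v)
    }
  }
  structure(summ, class = "eval_summary")
}

#' @export
print.eval_summary <- function(x, ...) {
  cat(sprintf("eval_summary '%s' (%d folds)\n", x$model_name,
              nrow(x$per_fold)))
  cat(sprintf("  AUROC train %.3f (%.3f)  test %.3f (%.3f)\n",
              x$train_auroc_mean, x$train_auroc_sd,
              x$test_auroc_mean, x$test_auroc_sd))
  cat(sprintf("  AUPRC train %.3f (%.3f)  test %.3f (%.3f)\n",
              x$train_auprc_mean, x$train_auprc_sd,
              x$test_auprc_mean, x$test_auprc_sd))
  invisible(x)
}

#' Scorer factory for a fixed (untrained) motif model
#'
#' Wraps a `pfm`, `pwm` or `dinuc_pwm` as a [cross_validate] factory that
#' ignores the training split, as appropriate for database matrices that
#' are evaluated as-is.
#'
#' @param model the motif model.
#' @return a scorer factory.
#' @export
scorer_factory_model <- function(model) {
  force(model)
  function(train) {
    function(sites) score_sites(model, sites)
  }
}

#' Scorer factory that trains a discriminative PWM per fold
#'
#' Each fold's factory call runs [train_damo] on that fold's training
#' sites and scores with the best-AUROC snapshot.
#'
#' @param seed_pfm the seed [pfm].
#' @param config a [damo_config].
#' @return a scorer factory for [cross_validate].
#' @export
scorer_factory_damo <- function(seed_pfm, config) {
  force(seed_pfm); force(config)
  function(train) {
    tr <- train_damo(seed_pfm, train$positives$site_seq,
                     train$negatives$site_seq, config)
    model <- tr$best_model
    function(sites) score_sites(model, sites)
  }
}

#' Model-comparison report
#'
#' Produces the three comparison artifacts of the evaluation protocol on
#' user data: (a) a tab-delimited summary table, one row per model with
#' train and test metric formatted as `mean (sd)` to three decimals;
#' (b) a box plot of per-dataset (or per-fold) train - test gaps per
#' model, a measure of overfitting; (c) pairwise scatter plots of test
#' metric values and the corresponding sorted per-dataset differences.
#'
#' `summaries` may be a flat list of `eval_summary` objects (one dataset)
#' or a list of same-length lists of `eval_summary` (one element per
#' dataset, same dataset order for every model).
#'
#' @param summaries evaluations to compare (>= 2 models over the same
#'   dataset collection).
#' @param out_dir output directory, created if needed.
#' @param metric `"auprc"` (default) or `"auroc"`.
#' @param pairs list of 2-element character vectors of model names to
#'   compare pairwise; default: every model against the first.
#' @param device `"png"` or `"svg"` for plots.
#' @return (invisibly) list with the table data.frame, the long
#'   per-dataset data.frame, and the written file paths.
#' @export
comparison_report <- function(summaries, out_dir, metric = c("auprc", "auroc"),
                              pairs = NULL, device = c("png", "svg")) {
  metric <- match.arg(metric)
  device <- match.arg(device)
  # normalize: list of models -> list of eval_summary per dataset
  if (all(vapply(summaries, inherits, TRUE, "eval_summary"))) {
    summaries <- lapply(summaries, list)
  }
  if (length(summaries) < 2L) stop("need >= 2 model summaries to compare")
  n_ds <- unique(lengths(summaries))
  if (length(n_ds) != 1L) {
    stop("models were evaluated on different dataset collections")
  }
  models <- vapply(summaries, function(s) s[[1L]]$model_name, "")
  if (anyDuplicated(models)) {
    models <- make.unique(models)
  }

  long <- do.call(rbind, lapply(seq_along(summaries), function(i) {
    do.call(rbind, lapply(seq_len(n_ds), function(d) {
      s <- summaries[[i]][[d]]
      data.frame(model = models[[i]], dataset = d,
                 train = s[[paste0("train_", metric, "_mean")]],
                 test = s[[paste0("test_", metric, "_mean")]],
                 stringsAsFactors = FALSE)
    }))
  }))
  long$model <- factor(long$model, levels = models)
  long$gap <- long$train - long$test

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(m, s) sprintf("%.3f (%.3f)", m, s)
  tab <- do.call(rbind, lapply(seq_along(summaries), function(i) {
    ss <- summaries[[i]]
    if (n_ds > 1L) {
      tr <- vapply(ss, function(s) s[[paste0("train_", metric, "_mean")]], 0)
      te <- vapply(ss, function(s) s[[paste0("test_", metric, "_mean")]], 0)
      data.frame(model = models[[i]],
                 training = fmt(mean(tr), stats::sd(tr)),
                 testing = fmt(mean(te), stats::sd(te)))
    } else {
      s <- ss[[1L]]
      data.frame(model = models[[i]],
                 training = fmt(s[[paste0("train_", metric, "_mean")]],
                                s[[paste0("train_", metric, "_sd")]]),
                 testing = fmt(s[[paste0("test_", metric, "_mean")]],
                               s[[paste0("test_", metric, "_sd")]]))
    }
  }))
  table_path <- file.path(out_dir, sprintf("summary_%s.tsv", metric))
  utils::write.table(tab, table_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  save_plot <- function(p, name, width = 7, height = 5) {
    path <- file.path(out_dir, paste0(name, ".", device))
    ggplot2::ggsave(path, p, width = width, height = height, dpi = 120)
    path
  }

  gap_plot <- ggplot2::ggplot(long,
      ggplot2::aes(x = .data$model, y = .data$gap)) +
    ggplot2::geom_boxplot(outlier.size = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = NULL,
                  y = sprintf("train - test %s", toupper(metric)),
                  title = "Train-test gap per model") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
  gap_path <- save_plot(gap_plot, sprintf("gap_%s", metric))

  if (is.null(pairs)) {
    pairs <- lapply(models[-1L], function(m) c(models[[1L]], m))
  }
  wide <- stats::reshape(long[, c("model", "dataset", "test")],
                         idvar = "dataset", timevar = "model",
                         direction = "wide")
  names(wide) <- sub("^test\\.", "", names(wide))
  pair_paths <- character(0)
  for (pr in pairs) {
    if (!all(pr %in% models)) {
      stop(sprintf("unknown model in pair: %s", paste(pr, collapse = " vs ")))
    }
    df <- data.frame(x = wide[[pr[[2L]]]], y = wide[[pr[[1L]]]])
    lim <- range(c(df$x, df$y))
    sc <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
      ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
      ggplot2::geom_point(alpha = 0.7) +
      ggplot2::coord_fixed(xlim = lim, ylim = lim) +
      ggplot2::labs(x = sprintf("%s test %s", pr[[2L]], toupper(metric)),
                    y = sprintf("%s test %s", pr[[1L]], toupper(metric))) +
      ggplot2::theme_bw()
    diffs <- data.frame(rank = seq_len(nrow(df)),
                        diff = sort(df$y - df$x))
    sd_plot <- ggplot2::ggplot(diffs,
        ggplot2::aes(x = .data$rank, y = .data$diff)) +
      ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
      ggplot2::geom_point(size = 0.8) +
      ggplot2::labs(x = "dataset (sorted)",
                    y = sprintf("%s - %s %s", pr[[1L]], pr[[2L]],
                                toupper(metric))) +
      ggplot2::theme_bw()
    slug <- gsub("[^A-Za-z0-9]+", "_", paste(pr, collapse = "_vs_"))
    pair_paths <- c(pair_paths,
                    save_plot(sc, paste0("scatter_", slug), 5, 5),
                    save_plot(sd_plot, paste0("diff_", slug), 5, 4))
  }

  invisible(list(table = tab, long = long,
                 files = c(table_path, gap_path, pair_paths)))
}
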