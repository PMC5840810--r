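SHAPE_FEATURES <- c("HelT", "MGW", "ProT", "Roll",
                    "HelT2", "MGW2", "ProT2", "Roll2")

#' 4-bit one-hot sequence encoding
#'
#' Encodes each base as four bits in the order A = 1000, T = 0100,
#' G = 0010, C = 0001, concatenated across positions; a width-w site
#' yields a 4w-vector containing exactly w ones.
#'
#' @param sites character vector of equal-length A/C/G/T strings.
#' @return numeric matrix, one row per site, `4 * width` columns.
#' @examples
#' encode_4bit("AT")
#' @export
encode_4bit <- function(sites) {
  idx <- site_index_matrix(sites)           # codes 1..4 for A,C,G,T
  # bit position within each 4-block for each base code:
  # A -> 1, C -> 4, G -> 3, T -> 2
  bit_of <- c(1L, 4L, 3L, 2L)
  w <- nrow(idx)
  n <- ncol(idx)
  out <- matrix(0, n, 4L * w)
  for (j in seq_len(w)) {
    out[cbind(seq_len(n), (j - 1L) * 4L + bit_of[idx[j, ]])] <- 1
  }
  colnames(out) <- paste0("pos", rep(seq_len(w), each = 4L), "_",
                          rep(c("A", "T", "G", "C"), w))
  out
}

#' Construct a DNA-shape track
#'
#' Eight structural features per site position, in the fixed order HelT,
#' MGW, ProT, Roll and their second-order variants HelT2, MGW2, ProT2,
#' Roll2. Shape values are consumed from external predictions (or the
#' [fabricate_shape_tracks] generator); this package never computes them
#' from sequence.
#'
#' @param site_id identifier linking the track to a site.
#' @param values numeric 8 x width matrix (rows in `SHAPE_FEATURES`
#'   order), finite values only.
#' @return a `shape_track`.
#' @export
shape_track <- function(site_id, values) {
  values <- as.matrix(values)
  if (nrow(values) != 8L) stop("a shape track needs exactly 8 feature rows")
  if (!all(is.finite(values))) stop("shape values must be finite")
  rownames(values) <- SHAPE_FEATURES
  structure(list(site_id = as.character(site_id), values = values),
            class = "shape_track")
}

#' Min-max normalization of shape tracks
#'
#' Per feature, values are mapped linearly so the training minimum is 0
#' and the training maximum is 1; statistics are fitted over all
#' positions of all training tracks when `stats` is NULL, and reused
#' (with clamping to \[0, 1\]) otherwise. A feature that is constant in
#' training maps to 0.5 everywhere.
#'
#' @param tracks list of [shape_track].
#' @param stats NULL to fit on `tracks`, or the `stats` element of a
#'   previous call (train-time fit applied to test data).
#' @return list with `tracks` (normalized) and `stats` (data.frame of
#'   per-feature min/max).
#' @export
normalize_shape <- function(tracks, stats = NULL) {
  if (length(tracks) == 0L && is.null(stats)) {
    stop("cannot fit normalization statistics on an empty track list")
  }
  if (is.null(stats)) {
    all_vals <- do.call(cbind, lapply(tracks, function(t) t$values))
    stats <- data.frame(feature = SHAPE_FEATURES,
                        min = apply(all_vals, 1L, min),
                        max = apply(all_vals, 1L, max))
  }
  rng <- stats$max - stats$min
  norm1 <- function(t) {
    v <- (t$values - stats$min) / ifelse(rng > 0, rng, 1)
    v[rng == 0, ] <- 0.5
    v <- pmin(pmax(v, 0), 1)
    shape_track(t$site_id, v)
  }
  list(tracks = lapply(tracks, norm1), stats = stats)
}

#' Read shape tracks from tab-delimited text
#'
#' One row per (site_id, feature); a header row `site_id feature
#' pos1 ... posW`. Features must be the 8 names in `SHAPE_FEATURES`.
#'
#' @param path TSV path.
#' @return named list of [shape_track] (names = site ids).
#' @export
read_shape_tracks <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("site_id", "feature") %in% names(df)))
  ids <- unique(df$site_id)
  out <- lapply(ids, function(id) {
    sub <- df[df$site_id == id, ]
    m <- as.matrix(sub[match(SHAPE_FEATURES, sub$feature),
                       -(1:2), drop = FALSE])
    shape_track(id, m)
  })
  stats::setNames(out, ids)
}

#' Write shape tracks as tab-delimited text
#'
#' @param tracks list of [shape_track].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_shape_tracks <- function(tracks, path) {
  w <- ncol(tracks[[1L]]$values)
  rows <- do.call(rbind, lapply(tracks, function(t) {
    data.frame(site_id = t$site_id, feature = SHAPE_FEATURES,
               t$values, stringsAsFactors = FALSE)
  }))
  names(rows)[-(1:2)] <- paste0("pos", seq_len(w))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Assemble classifier feature vectors for sites
#'
#' Builds the feature matrix for one of the classifier variants, with a
#' fixed block order: the matrix score (1 column) when present, then the
#' 4-bit encoding (4w columns) when present, then the normalized shape
#' values (8w columns, position-major per feature) when present.
#'
#' Variants: `"4bit"` (sequence one-hot only), `"4bit+shape"`,
#' `"shape_only"`, `"matrixscore+shape"` (model score plus shape, the
#' form used with a seed PFM or a trained PWM).
#'
#' @param sites character vector of equal-width sites.
#' @param variant feature layout, see above.
#' @param model a `pfm`/`pwm`/`dinuc_pwm`; required for
#'   `"matrixscore+shape"`.
#' @param shape_tracks list of normalized [shape_track], one per site in
#'   order; required for variants including shape.
#' @return list with `x` (numeric matrix, one row per site) and `layout`
#'   (data.frame of block names and extents).
#' @export
assemble_features <- function(sites,
                              variant = c("4bit", "4bit+shape",
                                          "shape_only", "matrixscore+shape"),
                              model = NULL, shape_tracks = NULL) {
  variant <- match.arg(variant)
  w <- nchar(sites[[1L]])
  blocks <- list()
  layout <- data.frame(block = character(0), extent = integer(0))

  if (variant == "matrixscore+shape") {
    if (is.null(model)) {
      stop("variant 'matrixscore+shape' requires a motif model")
    }
    blocks$matrix_score <- matrix(score_sites(model, sites), ncol = 1L,
                                  dimnames = list(NULL, "matrix_score"))
    layout <- rbind(layout, data.frame(block = "matrix_score", extent = 1L))
  }
  if (variant %in% c("4bit", "4bit+shape")) {
    blocks$fourbit <- encode_4bit(sites)
    layout <- rbind(layout, data.frame(block = "fourbit", extent = 4L * w))
  }
  if (variant %in% c("4bit+shape", "shape_only", "matrixscore+shape")) {
    if (is.null(shape_tracks)) {
      stop(sprintf("variant '%s' requires shape tracks", variant))
    }
    if (length(shape_tracks) != length(sites)) {
      stop("need one shape track per site, in site order")
    }
    sh <- t(vapply(shape_tracks, function(t) {
      if (ncol(t$values) != w) stop("shape track width != site width")
      as.vector(t(t$values))    # feature-major blocks of w positions
    }, numeric(8L * w)))
    colnames(sh) <- paste0(rep(SHAPE_FEATURES, each = w), "_pos",
                           rep(seq_len(w), 8L))
    blocks$shape <- sh
    layout <- rbind(layout, data.frame(block = "shape", extent = 8L * w))
  }
  list(x = do.call(cbind, blocks), layout = layout)
}

#' Logistic-regression classifier adapter
#'
#' A deterministic linear classifier satisfying the pluggable-classifier
#' contract: `fit(x, y, seed)` then `predict_score(object, x)` returning
#' scores monotone in positive-class confidence. Fitting is penalized
#' maximum likelihood via `glm` (ridge-free); it is deterministic, so the
#' seed is accepted and ignored.
#'
#' @return a `damo_classifier` contract object with elements `name`,
#'   `fit(x, y, seed)` and `predict_score(fitted, x)`.
#' @export
classifier_logistic <- function() {
  structure(list(
    name = "logistic",
    fit = function(x, y, seed = NULL) {
      stopifnot(nrow(x) == length(y))
      df <- as.data.frame(x)
      names(df) <- paste0("f", seq_len(ncol(x)))
      df$.y <- as.integer(y)
      suppressWarnings(
        stats::glm(.y ~ ., family = stats::binomial(), data = df)
      )
    },
    predict_score = function(fitted, x) {
      df <- as.data.frame(x)
      names(df) <- paste0("f", seq_len(ncol(x)))
      as.numeric(stats::predict(fitted, newdata = df, type = "link"))
    }
  ), class = "damo_classifier")
}

#' Gradient-boosting classifier adapter
#'
#' Wraps xgboost's gradient-boosted trees behind the same contract.
#' Single-threaded with a fixed seed, so fits are reproducible.
#'
#' @param nrounds boosting rounds (default 100).
#' @param max_depth tree depth (default 3).
#' @param eta learning rate (default 0.1).
#' @return a `damo_classifier` contract object.
#' @export
classifier_gbm <- function(nrounds = 100L, max_depth = 3L, eta = 0.1) {
  if (!requireNamespace("xgboost", quietly = TRUE)) {
    stop("the gradient-boosting adapter needs the 'xgboost' package")
  }
  structure(list(
    name = "gbm",
    fit = function(x, y, seed = 0L) {
      set.seed(as.integer(seed))
      dtrain <- xgboost::xgb.DMatrix(as.matrix(x),
                                     label = as.integer(y))
      xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      max_depth = max_depth, eta = eta, nthread = 1L,
                      seed = as.integer(seed)),
        data = dtrain, nrounds = nrounds, verbose = 0
      )
    },
    predict_score = function(fitted, x) {
      as.numeric(stats::predict(fitted,
                                xgboost::xgb.DMatrix(as.matrix(x))))
    }
  ), class = "damo_classifier")
}

#' Scorer factory for a feature-vector classifier
#'
#' Builds a [cross_validate] factory for the classifier variants: per
#' fold it assembles training feature vectors (fitting shape
#' normalization on the training tracks only), fits the classifier, and
#' returns a scoring closure that assembles test features with the
#' train-time statistics.
#'
#' @param variant see [assemble_features].
#' @param classifier a `damo_classifier` (default [classifier_logistic]).
#' @param model motif model for `"matrixscore+shape"`.
#' @param shape_tracks named list of raw (unnormalized) [shape_track]
#'   keyed by site sequence id; required for shape variants. Tracks are
#'   looked up by the site sequences themselves when names are site
#'   sequences.
#' @param seed seed forwarded to `fit`.
#' @return a scorer factory for [cross_validate].
#' @export
scorer_factory_classifier <- function(variant,
                                      classifier = classifier_logistic(),
                                      model = NULL, shape_tracks = NULL,
                                      seed = 0L) {
  force(variant); force(classifier); force(model); force(shape_tracks)
  needs_shape <- variant %in% c("4bit+shape", "shape_only",
                                "matrixscore+shape")
  lookup <- function(sites) {
    if (!needs_shape) return(NULL)
    tr <- shape_tracks[sites]
    if (any(vapply(tr, is.null, TRUE))) {
      stop("missing shape track for one or more sites")
    }
    tr
  }
  function(train) {
    sites <- c(train$positives$site_seq, train$negatives$site_seq)
    y <- rep(c(1L, 0L), c(nrow(train$positives), nrow(train$negatives)))
    stats <- NULL
    tracks <- NULL
    if (needs_shape) {
      norm <- normalize_shape(lookup(sites))
      tracks <- norm$tracks
      stats <- norm$stats
    }
    fv <- assemble_features(sites, variant, model = model,
                            shape_tracks = tracks)
    fitted <- classifier$fit(fv$x, y, seed)
    function(new_sites) {
      tr <- if (needs_shape) {
        normalize_shape(lookup(new_sites), stats = stats)$tracks
      }
      fv2 <- assemble_features(new_sites, variant, model = model,
                               shape_tracks = tr)
      classifier$predict_score(fitted, fv2$x)
    }
  }
}
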