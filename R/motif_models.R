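#' Position frequency matrix
#'
#' A PFM stores per-position base probabilities for a fixed-width motif:
#' a 4 x width matrix with rows A, C, G, T whose columns each sum to 1.
#' PFMs are the probabilistic motif model distributed by databases such as
#' JASPAR and serve here as the seed for discriminative optimization.
#'
#' @param probs numeric 4 x width matrix of probabilities (rows A,C,G,T).
#' @param name label for the motif.
#' @return an object of class `pfm` with fields `probs`, `width`, `name`.
#' @examples
#' p <- pfm(matrix(0.25, 4, 3), name = "uniform3")
#' motif_width(p)
#' @export
pfm <- function(probs, name = "pfm") {
  probs <- as.matrix(probs)
  if (nrow(probs) != 4L) stop("a PFM needs exactly 4 rows (A,C,G,T)")
  if (ncol(probs) < 1L) stop("a PFM needs width >= 1")
  if (!all(is.finite(probs))) stop("PFM entries must be finite")
  if (any(probs < 0)) stop("PFM entries must be >= 0")
  cs <- colSums(probs)
  if (any(abs(cs - 1) > 1e-9)) {
    stop("every PFM column must sum to 1 (within 1e-9)")
  }
  dimnames(probs) <- list(DNA_BASES, NULL)
  structure(
    list(probs = probs, width = ncol(probs), name = as.character(name)),
    class = "pfm"
  )
}

#' Position weight matrix
#'
#' A PWM is an additive motif model: a 4 x width matrix of unbounded real
#' weights (rows A,C,G,T). The score of a width-length site is the sum of
#' the weights of its bases, one per position. PWMs are the objects the
#' perceptron optimizer trains.
#'
#' @param weights numeric 4 x width matrix of finite weights (rows A,C,G,T).
#' @param name label for the motif.
#' @return an object of class `pwm` with fields `weights`, `width`, `name`.
#' @examples
#' m <- pwm(matrix(0, 4, 2))
#' score_sites(m, "AC")
#' @export
pwm <- function(weights, name = "pwm") {
  weights <- as.matrix(weights)
  if (nrow(weights) != 4L) stop("a PWM needs exactly 4 rows (A,C,G,T)")
  if (ncol(weights) < 1L) stop("a PWM needs width >= 1")
  if (!all(is.finite(weights))) stop("PWM weights must be finite")
  dimnames(weights) <- list(DNA_BASES, NULL)
  structure(
    list(weights = weights, width = ncol(weights), name = as.character(name)),
    class = "pwm"
  )
}

#' Adjacent-dinucleotide position weight matrix
#'
#' An additive motif model over adjacent base pairs: a 16 x (width-1) matrix
#' whose rows are the dinucleotides AA, AC, AG, AT, CA, ..., TT
#' (first-base-major) and whose column i holds the weights for the pair of
#' site positions (i, i+1). A `dinuc_pwm` of width w scores sites of length
#' w (not w-1). Adjacent-pair features capture nearest-neighbour dependence
#' that single-base PWMs cannot represent.
#'
#' @param weights numeric 16 x (width-1) matrix of finite weights.
#' @param name label for the motif.
#' @return an object of class `dinuc_pwm` with fields `weights`, `width`
#'   (= ncol(weights) + 1), `name`.
#' @examples
#' d <- dinuc_pwm(matrix(0, 16, 2))  # width 3
#' score_sites(d, "ACG")
#' @export
dinuc_pwm <- function(weights, name = "dinuc_pwm") {
  weights <- as.matrix(weights)
  if (nrow(weights) != 16L) {
    stop("a dinucleotide PWM needs exactly 16 rows (AA..TT)")
  }
  if (ncol(weights) < 1L) stop("a dinucleotide PWM needs width >= 2")
  if (!all(is.finite(weights))) stop("weights must be finite")
  dimnames(weights) <- list(DNA_PAIRS, NULL)
  structure(
    list(weights = weights, width = ncol(weights) + 1L,
         name = as.character(name)),
    class = "dinuc_pwm"
  )
}

#' @export
print.pfm <- function(x, ...) {
  cat(sprintf("PFM '%s' (width %d)\n", x$name, x$width))
  print(round(x$probs, 3))
  invisible(x)
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("PWM '%s' (width %d)\n", x$name, x$width))
  print(round(x$weights, 3))
  invisible(x)
}

#' @export
print.dinuc_pwm <- function(x, ...) {
  cat(sprintf("Dinucleotide PWM '%s' (width %d, %d pair columns)\n",
              x$name, x$width, ncol(x$weights)))
  print(round(x$weights, 3))
  invisible(x)
}

#' Motif width
#'
#' The number of bases a motif model spans (and the length of the sites it
#' scores).
#'
#' @param model a `pfm`, `pwm` or `dinuc_pwm`.
#' @return integer width.
#' @export
motif_width <- function(model) {
  stopifnot(inherits(model, c("pfm", "pwm", "dinuc_pwm")))
  model$width
}

#' Read a position frequency matrix
#'
#' Reads JASPAR-style motif text: either four unlabeled numeric rows of
#' counts or probabilities (`dialect = "jaspar-raw"`), or four rows labeled
#' `A [ 12 3 ... ]` etc. (`dialect = "jaspar-pfm"`), optionally preceded by
#' a `>` header line carrying the motif name. Counts are converted to
#' probabilities per column with a Laplace pseudocount:
#' `(c + pseudocount) / (sum(c) + 4 * pseudocount)`. The default
#' pseudocount of 1 guarantees strictly positive probabilities, which the
#' log-odds seed transform requires.
#'
#' @param source path to a motif file, or a character vector of its lines.
#' @param dialect `"jaspar-raw"` (rows in file order A,C,G,T),
#'   `"jaspar-pfm"` (row order taken from the `A [ ... ]` labels), or
#'   `"auto"` (default: labeled when the rows carry `A [ ... ]` labels,
#'   raw otherwise).
#' @param pseudocount non-negative count added to every cell before
#'   normalization (default 1).
#' @param name motif name; defaults to the `>` header if present.
#' @return a [pfm].
#' @examples
#' lines <- c(">toy", "8 0", "1 8", "1 0", "0 2")
#' read_pfm(lines)
#' @export
read_pfm <- function(source, dialect = c("auto", "jaspar-raw", "jaspar-pfm"),
                     pseudocount = 1, name = NULL) {
  dialect <- match.arg(dialect)
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L ||
      pseudocount < 0) {
    stop("'pseudocount' must be a single non-negative number")
  }
  lines <- if (length(source) == 1L && file.exists(source)) {
    readLines(source, warn = FALSE)
  } else {
    as.character(source)
  }
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  header <- grepl("^>", lines)
  if (is.null(name)) {
    name <- if (any(header)) sub("^>\\s*", "", lines[header][1L]) else "pfm"
  }
  body <- lines[!header]
  if (length(body) != 4L) {
    stop(sprintf("expected 4 matrix rows, found %d", length(body)))
  }
  if (dialect == "auto") {
    labeled <- all(grepl("^[ACGTacgt]\\s*\\[", body))
    dialect <- if (labeled) "jaspar-pfm" else "jaspar-raw"
  }

  if (dialect == "jaspar-pfm") {
    m <- regmatches(body, regexec("^([ACGTacgt])\\s*\\[(.*)\\]\\s*$", body))
    if (any(lengths(m) != 3L)) {
      stop("jaspar-pfm rows must look like 'A [ 1 2 ... ]'")
    }
    row_base <- toupper(vapply(m, `[[`, "", 2L))
    if (!setequal(row_base, DNA_BASES)) {
      stop("jaspar-pfm rows must be labeled A, C, G and T exactly once each")
    }
    nums <- lapply(m, function(g) strsplit(trimws(g[[3L]]), "\\s+")[[1L]])
  } else {
    row_base <- DNA_BASES
    nums <- strsplit(body, "\\s+")
  }

  vals <- lapply(nums, function(v) suppressWarnings(as.numeric(v)))
  if (any(vapply(vals, anyNA, TRUE))) stop("non-numeric matrix entry")
  lens <- lengths(vals)
  if (length(unique(lens)) != 1L) {
    stop(sprintf("rows have unequal lengths (%s)",
                 paste(lens, collapse = ", ")))
  }
  counts <- do.call(rbind, vals)[match(DNA_BASES, row_base), , drop = FALSE]
  if (any(counts < 0)) stop("negative counts are not allowed")

  probs <- sweep(counts + pseudocount, 2L,
                 colSums(counts) + 4 * pseudocount, "/")
  pfm(probs, name = name)
}

#' Write a position frequency matrix
#'
#' Emits the labeled JASPAR dialect (`A [ ... ]` rows) with a `>` header.
#'
#' @param x a [pfm].
#' @param path output file path.
#' @param digits significant digits for the probabilities.
#' @return `path`, invisibly.
#' @export
write_pfm <- function(x, path, digits = 6) {
  stopifnot(inherits(x, "pfm"))
  rows <- vapply(seq_len(4L), function(i) {
    sprintf("%s [ %s ]", DNA_BASES[[i]],
            paste(format(x$probs[i, ], digits = digits, trim = TRUE),
                  collapse = " "))
  }, "")
  writeLines(c(paste0(">", x$name), rows), path)
  invisible(path)
}

#' Seed a PWM from a PFM by log-odds transform
#'
#' Converts per-position probabilities into additive weights,
#' `weight(b, i) = log(prob(b, i) / background(b))` (natural log). With a
#' uniform background this is the exact inverse of [pwm_to_pfm], so the
#' seed PWM ranks sites identically to the PFM's log-probability score.
#'
#' @param x a [pfm] with strictly positive entries (use a positive
#'   pseudocount in [read_pfm]).
#' @param background length-4 base probabilities (A,C,G,T) summing to 1;
#'   default uniform.
#' @return a [pwm] of the same width.
#' @examples
#' p <- read_pfm(c("8 0", "1 8", "1 0", "0 2"))
#' pfm_to_seed_pwm(p)
#' @export
pfm_to_seed_pwm <- function(x, background = rep(0.25, 4)) {
  stopifnot(inherits(x, "pfm"))
  if (length(background) != 4L || any(background <= 0) ||
      abs(sum(background) - 1) > 1e-9) {
    stop("'background' must be 4 positive probabilities summing to 1")
  }
  if (any(x$probs == 0)) {
    stop(paste0("PFM contains zero probabilities; re-read the matrix with ",
                "a pseudocount > 0 before log-odds seeding"))
  }
  pwm(log(x$probs / background), name = x$name)
}

#' Convert a PWM to a PFM by Boltzmann normalization
#'
#' Treats the column weights as energies and maps each column through a
#' softmax: `prob(b, i) = exp(weight(b, i)) / sum_b' exp(weight(b', i))`,
#' stabilized by subtracting the column maximum before exponentiation.
#' Shifting a column by a constant leaves the result unchanged.
#'
#' @param x a [pwm].
#' @return a [pfm] of the same width.
#' @examples
#' pwm_to_pfm(pwm(matrix(c(log(2), 0, 0, 0), 4, 1)))
#' @export
pwm_to_pfm <- function(x) {
  stopifnot(inherits(x, "pwm"))
  w <- sweep(x$weights, 2L, apply(x$weights, 2L, max), "-")
  e <- exp(w)
  pfm(sweep(e, 2L, colSums(e), "/"), name = x$name)
}

#' Score fixed-width sites with a motif model
#'
#' Computes one score per site. For a `pwm` the score is the sum over
#' positions of the weight of the observed base; for a `dinuc_pwm` the sum
#' over adjacent position pairs of the weight of the observed dinucleotide;
#' for a `pfm` the sum of per-position log probabilities (the standard
#' log-likelihood scan score).
#'
#' @param model a `pfm`, `pwm` or `dinuc_pwm`.
#' @param sites character vector of A/C/G/T strings, each of length equal
#'   to the model width.
#' @return numeric vector of scores, one per site.
#' @examples
#' m <- pwm(matrix(c(1, 0, 0, -1, 0, 2, 0, 0), 4, 2))
#' score_sites(m, c("AC", "TA"))
#' @export
score_sites <- function(model, sites) {
  UseMethod("score_sites")
}

#' @export
score_sites.pwm <- function(model, sites) {
  idx <- site_index_matrix(sites, model$width)
  score_index_mono(model$weights, idx)
}

#' @export
score_sites.dinuc_pwm <- function(model, sites) {
  idx <- site_index_matrix(sites, model$width)
  score_index_dinuc(model$weights, pair_index_matrix(idx))
}

#' @export
score_sites.pfm <- function(model, sites) {
  if (any(model$probs == 0)) {
    stop(paste0("PFM has zero probabilities; log-probability scoring needs ",
                "a pseudocount > 0 at read time"))
  }
  idx <- site_index_matrix(sites, model$width)
  score_index_mono(log(model$probs), idx)
}

# Internal fast paths over pre-encoded base/pair index matrices (w x n).
score_index_mono <- function(weights, idx) {
  n <- ncol(idx)
  s <- numeric(n)
  for (j in seq_len(nrow(idx))) {
    s <- s + weights[idx[j, ] + (j - 1L) * 4L]
  }
  s
}

score_index_dinuc <- function(weights, pidx) {
  n <- ncol(pidx)
  s <- numeric(n)
  for (j in seq_len(nrow(pidx))) {
    s <- s + weights[pidx[j, ] + (j - 1L) * 16L]
  }
  s
}

#' Reverse complement a motif model
#'
#' Returns the model of the opposite strand: for every site `s`,
#' `score_sites(reverse_complement_model(m), s)` equals
#' `score_sites(m, reverse_complement(s))` exactly. Applying the operation
#' twice returns the original model.
#'
#' @param model a `pfm`, `pwm` or `dinuc_pwm`.
#' @return a model of the same class and width.
#' @export
reverse_complement_model <- function(model) {
  UseMethod("reverse_complement_model")
}

rc_mono_matrix <- function(m) {
  m[4:1, rev(seq_len(ncol(m))), drop = FALSE]
}

#' @export
reverse_complement_model.pwm <- function(model) {
  pwm(rc_mono_matrix(model$weights), name = model$name)
}

#' @export
reverse_complement_model.pfm <- function(model) {
  pfm(rc_mono_matrix(model$probs), name = model$name)
}

#' @export
reverse_complement_model.dinuc_pwm <- function(model) {
  # pair (x, y) at column j maps to (comp(y), comp(x)) at column w - j
  comp <- 5L - seq_len(4L)                     # A<->T, C<->G on codes 1..4
  # from_pair[p] is the source row for target row p: target pair (x, y)
  # reads source pair (comp(y), comp(x)). Rows are first-base-major, so
  # p = (x-1)*4 + y and the source row is (comp(y)-1)*4 + comp(x).
  second <- rep(seq_len(4L), times = 4L)
  first <- rep(seq_len(4L), each = 4L)
  from_pair <- (comp[second] - 1L) * 4L + comp[first]
  w <- model$weights
  out <- w[from_pair, rev(seq_len(ncol(w))), drop = FALSE]
  dinuc_pwm(out, name = model$name)
}

#' Embed a mononucleotide PWM in the dinucleotide model space
#'
#' Lifts a 4 x w PWM into a 16 x (w-1) adjacent-dinucleotide PWM that
#' assigns every site exactly the same score: pair column i takes the
#' first-base weight `mono(x, i)` for i < w-1, and the final pair column
#' takes `mono(x, w-1) + mono(y, w)`. This makes the mono model a special
#' case of the dinucleotide model, so dinucleotide training can start from
#' the same seed and never loses expressiveness.
#'
#' @param x a [pwm] of width >= 2.
#' @return a [dinuc_pwm] of the same width.
#' @export
embed_mono_in_dinuc <- function(x) {
  stopifnot(inherits(x, "pwm"))
  w <- x$width
  if (w < 2L) stop("dinucleotide embedding needs width >= 2")
  m <- x$weights
  out <- matrix(0, 16L, w - 1L)
  first_base <- rep(seq_len(4L), each = 4L)   # row -> first base code
  second_base <- rep(seq_len(4L), times = 4L) # row -> second base code
  for (j in seq_len(w - 1L)) {
    out[, j] <- m[first_base, j]
  }
  out[, w - 1L] <- m[first_base, w - 1L] + m[second_base, w]
  dinuc_pwm(out, name = x$name)
}

#' Write a weight-matrix model to tab-delimited text
#'
#' One header line (`model type, width, name`, tab-separated) followed by
#' the weight rows at full decimal precision, so a write/read round trip is
#' bit-exact.
#'
#' @param x a [pwm] or [dinuc_pwm].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pwm <- function(x, path) {
  stopifnot(inherits(x, c("pwm", "dinuc_pwm")))
  type <- class(x)[[1L]]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(type, x$width, x$name, sep = "\t"), con)
  m <- x$weights
  rows <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[[i]], sprintf("%.17g", m[i, ])), collapse = "\t")
  }, "")
  writeLines(rows, con)
  invisible(path)
}

#' Read a weight-matrix model written by [write_pwm]
#'
#' @param path file path.
#' @return a [pwm] or [dinuc_pwm], as recorded in the header.
#' @export
read_pwm <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (length(hdr) != 3L || !hdr[[1L]] %in% c("pwm", "dinuc_pwm")) {
    stop("not a PWM file: bad header line")
  }
  body <- strsplit(lines[-1L], "\t", fixed = TRUE)
  labels <- vapply(body, `[[`, "", 1L)
  vals <- do.call(rbind, lapply(body, function(r) as.numeric(r[-1L])))
  if (hdr[[1L]] == "pwm") {
    pwm(vals[match(DNA_BASES, labels), , drop = FALSE], name = hdr[[3L]])
  } else {
    dinuc_pwm(vals[match(DNA_PAIRS, labels), , drop = FALSE],
              name = hdr[[3L]])
  }
}
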