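#' Simulation configuration for planted-motif datasets
#'
#' Describes a synthetic ChIP-seq-like dataset: positive sequences are
#' i.i.d. background with one motif site planted at a random offset,
#' negatives are pure background. An optional adjacent-pair coupling
#' injects nearest-neighbour dependence into the planted sites — the
#' structure an adjacent-dinucleotide model can capture but a single-base
#' PWM cannot.
#'
#' @param width motif width.
#' @param n_pos,n_neg numbers of positive / negative sequences.
#' @param seq_len sequence length (default 100, the standard peak-window
#'   size).
#' @param gc background GC content in (0, 1) (default 0.5).
#' @param concentration symmetric-Dirichlet concentration for the
#'   generating PFM's columns; smaller = sharper (default 0.1).
#' @param coupling NULL, or `list(pos = i, log_weights = 16-vector)`
#'   re-weighting the joint distribution of planted-site positions
#'   (i, i+1) by `exp(log_weights)` (first-base-major pair order).
#' @param seed integer seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(width = 8L, n_pos = 500L, n_neg = 500L,
                       seq_len = 100L, gc = 0.5, concentration = 0.1,
                       coupling = NULL, seed = 1L) {
  width <- check_count(width, "width")
  n_pos <- check_count(n_pos, "n_pos")
  n_neg <- check_count(n_neg, "n_neg")
  seq_len <- check_count(seq_len, "seq_len")
  if (seq_len < width) stop("'seq_len' must be >= 'width'")
  if (gc <= 0 || gc >= 1) stop("'gc' must be in (0, 1)")
  if (concentration <= 0) stop("'concentration' must be positive")
  if (!is.null(coupling)) {
    stopifnot(is.list(coupling), length(coupling$log_weights) == 16L)
    cp <- check_count(coupling$pos, "coupling$pos")
    if (cp >= width) stop("'coupling$pos' must be < width")
    coupling$pos <- cp
  }
  structure(list(width = width, n_pos = n_pos, n_neg = n_neg,
                 seq_len = seq_len, gc = gc,
                 concentration = concentration, coupling = coupling,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Sample a random PFM from a Dirichlet column prior
#'
#' Each column is drawn from a symmetric Dirichlet with the given
#' concentration; small concentrations give sharp (information-rich)
#' columns, large concentrations approach uniform columns.
#'
#' @param width motif width.
#' @param concentration positive Dirichlet concentration.
#' @param seed optional integer seed (NULL uses the current RNG stream).
#' @return a [pfm].
#' @export
sample_pfm <- function(width, concentration, seed = NULL) {
  width <- check_count(width, "width")
  if (!is.numeric(concentration) || length(concentration) != 1L ||
      concentration <= 0) {
    stop("'concentration' must be a positive number")
  }
  maybe_set_seed(seed)
  g <- matrix(stats::rgamma(4L * width, shape = concentration), 4L, width)
  # guard against all-zero columns at tiny concentrations (gamma underflow)
  zero <- colSums(g) == 0
  if (any(zero)) {
    g[cbind(sample.int(4L, sum(zero), replace = TRUE), which(zero))] <- 1
  }
  probs <- sweep(g, 2L, colSums(g), "/")
  pfm(probs, name = sprintf("dirichlet_w%d", width))
}

background_probs <- function(gc) {
  c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
}

sample_background <- function(n, len, gc) {
  p <- background_probs(gc)
  m <- matrix(sample(DNA_BASES, n * len, replace = TRUE, prob = p),
              nrow = n)
  apply(m, 1L, paste, collapse = "")
}

# Sample n sites from a PFM, optionally re-weighting one adjacent pair's
# joint distribution by exp(log_weights) then renormalizing. Positions
# outside the coupled pair stay independent, so the coupling perturbs only
# the targeted nearest-neighbour joint.
sample_sites <- function(pfm_obj, n, coupling = NULL) {
  w <- pfm_obj$width
  codes <- matrix(0L, n, w)
  skip <- integer(0)
  if (!is.null(coupling)) {
    i <- coupling$pos
    joint <- as.vector(outer(pfm_obj$probs[, i], pfm_obj$probs[, i + 1L],
                             function(a, b) a * b))
    # outer is column-major: element (x, y) sits at x + (y-1)*4; convert
    # to first-base-major pair order AA,AC,...,TT = (x-1)*4 + y
    first <- rep(seq_len(4L), times = 4L)
    second <- rep(seq_len(4L), each = 4L)
    pair_order <- (first - 1L) * 4L + second
    joint_fm <- numeric(16L)
    joint_fm[pair_order] <- joint
    joint_fm <- joint_fm * exp(coupling$log_weights)
    joint_fm <- joint_fm / sum(joint_fm)
    pair_draw <- sample.int(16L, n, replace = TRUE, prob = joint_fm)
    codes[, i] <- (pair_draw - 1L) %/% 4L + 1L
    codes[, i + 1L] <- (pair_draw - 1L) %% 4L + 1L
    skip <- c(i, i + 1L)
  }
  for (j in setdiff(seq_len(w), skip)) {
    codes[, j] <- sample.int(4L, n, replace = TRUE,
                             prob = pfm_obj$probs[, j])
  }
  apply(codes, 1L, function(r) paste(DNA_BASES[r], collapse = ""))
}

#' Generate a planted-motif positive/negative dataset
#'
#' Positives are background sequences with one PFM-sampled site planted
#' at a uniformly random offset; negatives are pure background. The truth
#' record retains everything needed to reconstruct each planted site.
#'
#' @param config a [sim_config].
#' @param generating_pfm optionally supply the generating [pfm] (drawn
#'   from [sample_pfm] with `config$concentration` otherwise).
#' @return list with `positive` and `negative` character vectors and
#'   `truth` (list: `pfm`, `offsets` 0-based, `planted_sites`, `config`).
#' @export
generate_dataset <- function(config, generating_pfm = NULL) {
  stopifnot(inherits(config, "sim_config"))
  maybe_set_seed(config$seed)
  if (is.null(generating_pfm)) {
    generating_pfm <- sample_pfm(config$width, config$concentration)
  }
  w <- config$width
  pos <- sample_background(config$n_pos, config$seq_len, config$gc)
  neg <- sample_background(config$n_neg, config$seq_len, config$gc)
  sites <- sample_sites(generating_pfm, config$n_pos, config$coupling)
  offsets <- sample.int(config$seq_len - w + 1L, config$n_pos,
                        replace = TRUE) - 1L
  pos <- vapply(seq_len(config$n_pos), function(i) {
    paste0(substr(pos[[i]], 1L, offsets[[i]]), sites[[i]],
           substr(pos[[i]], offsets[[i]] + w + 1L, config$seq_len))
  }, "")
  list(positive = pos, negative = neg,
       truth = list(pfm = generating_pfm, offsets = offsets,
                    planted_sites = sites, config = config))
}

#' Write a generated dataset to disk
#'
#' Emits `positive.fa`, `negative.fa` and `truth.json` (the truth record
#' with the PFM as a 4 x width probability array).
#'
#' @param dataset output of [generate_dataset].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pos <- Biostrings::DNAStringSet(dataset$positive)
  names(pos) <- sprintf("pos_%d", seq_along(pos))
  neg <- Biostrings::DNAStringSet(dataset$negative)
  names(neg) <- sprintf("neg_%d", seq_along(neg))
  Biostrings::writeXStringSet(pos, file.path(dir, "positive.fa"))
  Biostrings::writeXStringSet(neg, file.path(dir, "negative.fa"))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    truth <- dataset$truth
    jsonlite::write_json(
      list(pfm = truth$pfm$probs, offsets = truth$offsets,
           planted_sites = truth$planted_sites,
           config = unclass(truth$config)),
      file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA,
      null = "null")
  }
  invisible(dir)
}

#' Generate a toy genome with peak calls
#'
#' Random chromosomes plus narrowPeak-style peak records with summit
#' columns. Peaks are placed so that positive and negative windows fit
#' within the chromosome, except for `n_edge` deliberately placed
#' edge-case peaks whose positive window would run off the start.
#'
#' @param n_chroms number of chromosomes.
#' @param chrom_len chromosome length in bp.
#' @param n_peaks peaks per genome (interior, valid).
#' @param seed integer seed.
#' @param window,negative_offset the window geometry the peaks must
#'   accommodate (defaults 100/100).
#' @param n_edge number of additional off-the-start edge peaks
#'   (default 0).
#' @param gc background GC content.
#' @return list with `genome` (named `DNAStringSet`) and `peaks`
#'   (narrowPeak-style data.frame with 0-based `start`, `end`, `summit`
#'   offset).
#' @export
genome_fixture <- function(n_chroms = 2L, chrom_len = 10000L,
                           n_peaks = 20L, seed = 1L, window = 100L,
                           negative_offset = 100L, n_edge = 0L,
                           gc = 0.5) {
  n_chroms <- check_count(n_chroms, "n_chroms")
  chrom_len <- check_count(chrom_len, "chrom_len")
  n_peaks <- check_count(n_peaks, "n_peaks")
  n_edge <- check_count(n_edge, "n_edge", min = 0L)
  lo <- window                       # summit keeps positive start >= 0
  hi <- chrom_len - (2L * window + negative_offset)
  if (hi <= lo) stop("'chrom_len' too small for any valid peak")
  maybe_set_seed(seed)
  genome <- Biostrings::DNAStringSet(
    sample_background(n_chroms, chrom_len, gc))
  names(genome) <- paste0("chr", seq_len(n_chroms))

  summit_abs <- sample(lo:hi, n_peaks, replace = TRUE)
  chrom <- sample(names(genome), n_peaks, replace = TRUE)
  if (n_edge > 0L) {
    # positive window [summit - window/2, ...) starts below 0
    summit_abs <- c(summit_abs, rep(window %/% 2L - 1L, n_edge))
    chrom <- c(chrom, rep(names(genome)[[1L]], n_edge))
  }
  half <- 50L
  peaks <- data.frame(
    chrom = chrom,
    start = pmax(summit_abs - half, 0L),
    end = summit_abs + half,
    name = sprintf("peak_%d", seq_along(chrom)),
    score = 0L, strand = ".",
    signalValue = round(stats::runif(length(chrom), 1, 100), 2),
    pValue = -1, qValue = -1,
    summit = summit_abs - pmax(summit_abs - half, 0L),
    stringsAsFactors = FALSE
  )
  list(genome = genome, peaks = peaks)
}

#' Write a genome fixture to FASTA + narrowPeak
#'
#' @param fixture output of [genome_fixture].
#' @param dir output directory.
#' @return list of the two paths, invisibly.
#' @export
write_genome_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "genome.fa")
  bed <- file.path(dir, "peaks.narrowPeak")
  Biostrings::writeXStringSet(fixture$genome, fa)
  utils::write.table(fixture$peaks, bed, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(list(genome = fa, peaks = bed))
}

#' Fabricate DNA-shape tracks for sites
#'
#' Stands in for external shape predictions: each of the 8 features at
#' each position is a base-dependent mean plus Gaussian noise. Because
#' the values are a (noisy) deterministic function of the underlying
#' sequence, shape-only classifiers can discriminate planted sites from
#' background — the same sequence-within-structure redundancy real shape
#' predictions carry.
#'
#' @param sites character vector of equal-width A/C/G/T sites.
#' @param seed optional integer seed (NULL uses the current stream).
#' @param signal optional 8 x 4 numeric matrix of per-base feature means
#'   (columns A,C,G,T); a fixed arbitrary default is used otherwise.
#' @param noise_sd Gaussian noise standard deviation (default 0.3).
#' @return named list of [shape_track], keyed by site sequence.
#' @export
fabricate_shape_tracks <- function(sites, seed = NULL, signal = NULL,
                                   noise_sd = 0.3) {
  if (length(sites) == 0L) stop("empty site list")
  idx <- site_index_matrix(sites)
  maybe_set_seed(seed)
  if (is.null(signal)) {
    # fixed arbitrary per-base signature, loosely ordered like real
    # helix/groove parameter scales
    signal <- matrix(c(
      34.1, 35.8, 33.9, 36.2,   # HelT by A,C,G,T
      5.9, 4.6, 5.1, 5.5,       # MGW
      -7.2, -11.8, -9.4, -6.1,  # ProT
      2.1, -1.3, 0.4, 3.0,      # Roll
      0.5, -0.2, 0.1, 0.8,      # second-order variants
      -0.4, 0.3, 0.6, -0.1,
      1.1, -0.7, 0.2, 0.5,
      -0.9, 0.4, -0.3, 0.7), nrow = 8L, byrow = TRUE)
  }
  stopifnot(nrow(signal) == 8L, ncol(signal) == 4L)
  w <- nrow(idx)
  out <- lapply(seq_along(sites), function(i) {
    mu <- signal[, idx[, i], drop = FALSE]   # 8 x w
    shape_track(sites[[i]],
                mu + matrix(stats::rnorm(8L * w, sd = noise_sd), 8L, w))
  })
  stats::setNames(out, sites)
}
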