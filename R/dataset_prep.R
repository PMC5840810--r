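#' Read peak intervals from BED / narrowPeak
#'
#' Accepts BED3, BED6 or ENCODE narrowPeak. The point-source of each peak
#' is the summit (`start + peak` offset) when a narrowPeak 10th column
#' >= 0 is present, otherwise the interval midpoint (floored). Coordinates
#' are 0-based half-open throughout.
#'
#' @param path BED file path.
#' @return data.frame with columns `chrom`, `start`, `end`, `point_source`
#'   (all 0-based).
#' @export
read_peaks <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  ncols <- length(strsplit(first, "\t", fixed = TRUE)[[1L]])
  gr <- if (ncols >= 10L) {
    rtracklayer::import(path, format = "BED",
                        extraCols = c(signalValue = "numeric",
                                      pValue = "numeric",
                                      qValue = "numeric",
                                      peak = "integer"))
  } else {
    rtracklayer::import(path, format = "BED")
  }
  start0 <- GenomicRanges::start(gr) - 1L    # back to 0-based
  end0 <- GenomicRanges::end(gr)
  summit <- if (!is.null(gr$peak)) gr$peak else rep(-1L, length(gr))
  summit[is.na(summit)] <- -1L
  ps <- ifelse(summit >= 0L, start0 + summit, (start0 + end0) %/% 2L)
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = start0, end = end0, point_source = as.integer(ps),
    stringsAsFactors = FALSE
  )
}

#' Extract paired positive/negative windows around peak point-sources
#'
#' For each peak, the positive window is the `window` bp interval centered
#' on the point-source (for odd widths the extra base falls to the right),
#' and the paired negative window is the same-width interval
#' `negative_offset` bp downstream of the positive window's end
#' (`negative_offset = 5000` gives the distal-negative variant). Pairs
#' whose positive or negative window runs off the chromosome are dropped
#' together.
#'
#' @param peaks data.frame from [read_peaks], or any data.frame with
#'   `chrom` and `point_source` columns (0-based).
#' @param genome a named `Biostrings::DNAStringSet`, or a FASTA file path.
#' @param window window length in bp (default 100).
#' @param negative_offset gap in bp between positive end and negative
#'   start (default 100).
#' @return data.frame of class `genomic_windows`: columns `chrom`, `start`,
#'   `end` (0-based half-open), `label` (`"positive"`/`"negative"`),
#'   `pair_id`, `seq`.
#' @export
extract_windows <- function(peaks, genome, window = 100L,
                            negative_offset = 100L) {
  window <- check_count(window, "window")
  negative_offset <- check_count(negative_offset, "negative_offset", min = 0L)
  if (is.character(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
  }
  stopifnot(is.data.frame(peaks),
            all(c("chrom", "point_source") %in% names(peaks)))
  missing_chrom <- setdiff(unique(peaks$chrom), names(genome))
  if (length(missing_chrom)) {
    stop(sprintf("chromosome(s) not in genome: %s",
                 paste(missing_chrom, collapse = ", ")))
  }
  chrom_len <- stats::setNames(Biostrings::width(genome), names(genome))

  half <- window %/% 2L
  pos_start <- peaks$point_source - half
  pos_end <- pos_start + window
  neg_start <- pos_end + negative_offset
  neg_end <- neg_start + window
  keep <- pos_start >= 0L & neg_end <= chrom_len[peaks$chrom]
  if (!any(keep)) stop("no peak yields valid positive+negative windows")

  k <- which(keep)
  pair_id <- seq_along(k)
  out <- data.frame(
    chrom = rep(peaks$chrom[k], 2L),
    start = c(pos_start[k], neg_start[k]),
    end = c(pos_end[k], neg_end[k]),
    label = rep(c("positive", "negative"), each = length(k)),
    pair_id = rep(pair_id, 2L),
    stringsAsFactors = FALSE
  )
  out$seq <- as.character(Biostrings::subseq(
    genome[out$chrom], start = out$start + 1L, end = out$end))
  class(out) <- c("genomic_windows", class(out))
  out
}

#' Write extracted windows as FASTA
#'
#' Headers follow `chrom:start-end|label|pair_id`.
#'
#' @param windows output of [extract_windows].
#' @param path FASTA path.
#' @return `path`, invisibly.
#' @export
write_windows_fasta <- function(windows, path) {
  ss <- Biostrings::DNAStringSet(windows$seq)
  names(ss) <- sprintf("%s:%d-%d|%s|%d", windows$chrom, windows$start,
                       windows$end, windows$label, windows$pair_id)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Find the best-scoring binding site in a sequence
#'
#' Scans every width-length window of `sequence` (both strands by default)
#' with the model and returns the maximum-scoring site. Windows containing
#' ambiguous bases are skipped. Ties are broken toward the smaller offset,
#' then the forward strand, so results are reproducible.
#'
#' @param model a `pwm` or `pfm` (any model [score_sites] accepts).
#' @param sequence a single DNA string, length >= model width.
#' @param both_strands scan the reverse strand too (default TRUE).
#' @return one-row data.frame: `offset` (0-based start in `sequence`),
#'   `strand` (`"+"`/`"-"`), `site_seq` (reverse-complemented for `"-"`),
#'   `score`.
#' @examples
#' m <- pwm(matrix(c(5, 0, 0, 0), 4, 4))  # favors AAAA
#' best_site(m, "TTAAAATT")
#' @export
best_site <- function(model, sequence, both_strands = TRUE) {
  check_flag(both_strands, "both_strands")
  w <- motif_width(model)
  sequence <- toupper(as.character(sequence)[[1L]])
  n <- nchar(sequence)
  if (n < w) {
    stop(sprintf("sequence length %d is shorter than model width %d", n, w))
  }
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  codes <- match(chars, DNA_BASES)
  n_win <- n - w + 1L
  # window j (1-based) covers positions j .. j+w-1
  valid <- !vapply(seq_len(n_win),
                   function(j) anyNA(codes[j:(j + w - 1L)]), TRUE)
  if (!any(valid)) {
    stop(sprintf("no window of width %d free of ambiguous bases in '%s'",
                 w, if (n > 40L) paste0(substr(sequence, 1L, 40L), "...")
                     else sequence))
  }
  offs <- which(valid)
  wins <- vapply(offs, function(j) substr(sequence, j, j + w - 1L), "")
  fwd <- score_sites(model, wins)
  if (both_strands) {
    rc <- reverse_complement(wins)
    rev <- score_sites(model, rc)
  } else {
    rev <- rep(-Inf, length(wins))
  }
  # tie-break: smaller offset, then + strand
  cand_score <- c(fwd, rev)
  cand_off <- c(offs, offs)
  cand_strand <- rep(c("+", "-"), each = length(offs))
  ord <- order(-cand_score, cand_off, cand_strand)
  b <- ord[[1L]]
  site <- if (cand_strand[[b]] == "+") wins[[match(cand_off[[b]], offs)]]
          else rc[[match(cand_off[[b]], offs)]]
  data.frame(offset = cand_off[[b]] - 1L, strand = cand_strand[[b]],
             site_seq = site, score = cand_score[[b]],
             stringsAsFactors = FALSE)
}

#' Build a site dataset from paired windows with a seed model
#'
#' Implements the fixed preprocessing of the evaluation protocol: scan
#' every positive and negative window once with the seed matrix, keep only
#' each window's best site, and use those frozen sites for all downstream
#' training and testing. Pairs where either window has no scannable
#' site are dropped (with a warning naming how many).
#'
#' @param windows output of [extract_windows], or a list with character
#'   vectors `positive` and `negative` of equal length (paired by index).
#' @param seed_model the scanning model, typically the seed `pfm` or its
#'   log-odds `pwm`.
#' @param both_strands scan both strands (default TRUE).
#' @return a `site_dataset`: list with data.frames `positives` and
#'   `negatives` (columns `parent_id`, `offset`, `strand`, `site_seq`,
#'   `score`, `label`, `pair_id`; row i of each is a pair) and `fold`
#'   (NA until [make_folds]).
#' @export
build_site_dataset <- function(windows, seed_model, both_strands = TRUE) {
  if (inherits(windows, "genomic_windows")) {
    pos <- windows[windows$label == "positive", ]
    neg <- windows[windows$label == "negative", ]
    neg <- neg[match(pos$pair_id, neg$pair_id), ]
    pos_seq <- pos$seq
    neg_seq <- neg$seq
    ids <- sprintf("%s:%d-%d", pos$chrom, pos$start, pos$end)
    neg_ids <- sprintf("%s:%d-%d", neg$chrom, neg$start, neg$end)
  } else {
    pos_seq <- windows$positive
    neg_seq <- windows$negative
    stopifnot(length(pos_seq) == length(neg_seq))
    ids <- sprintf("pos_%d", seq_along(pos_seq))
    neg_ids <- sprintf("neg_%d", seq_along(neg_seq))
  }
  scan1 <- function(s) {
    tryCatch(best_site(seed_model, s, both_strands = both_strands),
             error = function(e) NULL)
  }
  bp <- lapply(pos_seq, scan1)
  bn <- lapply(neg_seq, scan1)
  ok <- !vapply(bp, is.null, TRUE) & !vapply(bn, is.null, TRUE)
  if (!any(ok)) stop("no pair has scannable sites in both windows")
  if (any(!ok)) {
    warning(sprintf("dropped %d pair(s) with no scannable site", sum(!ok)))
  }
  mk <- function(best, ids, label) {
    df <- do.call(rbind, best[ok])
    df$parent_id <- ids[ok]
    df$label <- label
    df$pair_id <- seq_len(sum(ok))
    df[, c("parent_id", "offset", "strand", "site_seq", "score",
           "label", "pair_id")]
  }
  structure(
    list(positives = mk(bp, ids, "positive"),
         negatives = mk(bn, neg_ids, "negative"),
         fold = rep(NA_integer_, sum(ok))),
    class = "site_dataset"
  )
}

#' @export
print.site_dataset <- function(x, ...) {
  k <- if (all(is.na(x$fold))) "none" else length(unique(x$fold))
  cat(sprintf("site_dataset: %d positive/negative pairs, folds: %s\n",
              nrow(x$positives), k))
  invisible(x)
}

n_pairs <- function(dataset) nrow(dataset$positives)

#' Assign cross-validation folds to a site dataset
#'
#' Pairs (a positive site and its paired negative) are shuffled with the
#' seeded generator and dealt round-robin into `k` folds, so fold sizes
#' differ by at most one pair and a positive never straddles folds from
#' its negative. With the default `k = 10`, each training split is 9 times
#' the size of its test fold.
#'
#' @param dataset a `site_dataset`.
#' @param k number of folds (default 10).
#' @param seed integer seed for the shuffle.
#' @return the dataset with `fold` filled in (values 1..k per pair).
#' @export
make_folds <- function(dataset, k = 10L, seed) {
  stopifnot(inherits(dataset, "site_dataset"))
  k <- check_count(k, "k", min = 2L)
  n <- n_pairs(dataset)
  if (n < k) stop(sprintf("need at least k = %d pairs, have %d", k, n))
  maybe_set_seed(seed)
  perm <- sample.int(n)
  fold <- integer(n)
  fold[perm] <- ((seq_len(n) - 1L) %% k) + 1L
  dataset$fold <- fold
  dataset
}

#' Subset a site dataset to a set of pairs
#'
#' @param dataset a `site_dataset`.
#' @param pairs integer indices of pairs to keep.
#' @return a `site_dataset` with those pairs (pair ids renumbered).
#' @export
subset_pairs <- function(dataset, pairs) {
  stopifnot(inherits(dataset, "site_dataset"))
  out <- dataset
  out$positives <- dataset$positives[pairs, ]
  out$negatives <- dataset$negatives[pairs, ]
  out$positives$pair_id <- seq_along(pairs)
  out$negatives$pair_id <- seq_along(pairs)
  out$fold <- dataset$fold[pairs]
  rownames(out$positives) <- rownames(out$negatives) <- NULL
  out
}

#' Reduced-size training variant
#'
#' Draws two disjoint random subsets of pairs, each of size
#' `floor(fraction * n_pairs)`, to emulate training on as little data as a
#' single test fold (default `fraction = 0.1`, matching the size of one
#' fold out of ten).
#'
#' @param dataset a `site_dataset`.
#' @param fraction fraction of pairs per subset, in (0, 0.5].
#' @param seed integer seed.
#' @return list with `site_dataset`s `train` and `test`.
#' @export
small_training_variant <- function(dataset, fraction = 0.1, seed) {
  stopifnot(inherits(dataset, "site_dataset"))
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 0.5) {
    stop("'fraction' must be in (0, 0.5]")
  }
  n <- n_pairs(dataset)
  m <- floor(fraction * n)
  if (m < 1L) stop("fraction too small: no pairs selected")
  maybe_set_seed(seed)
  perm <- sample.int(n)
  list(train = subset_pairs(dataset, perm[seq_len(m)]),
       test = subset_pairs(dataset, perm[m + seq_len(m)]))
}

#' Write a site dataset as tab-delimited text
#'
#' Columns: `parent_id`, `offset`, `strand`, `site_seq`, `score`, `label`,
#' `pair_id`, `fold`.
#'
#' @param dataset a `site_dataset`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_sites <- function(dataset, path) {
  stopifnot(inherits(dataset, "site_dataset"))
  df <- rbind(dataset$positives, dataset$negatives)
  df$fold <- rep(dataset$fold, 2L)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a site dataset written by [write_sites]
#'
#' @param path TSV path.
#' @return a `site_dataset`.
#' @export
read_sites <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  pos <- df[df$label == "positive", ]
  neg <- df[df$label == "negative", ]
  neg <- neg[match(pos$pair_id, neg$pair_id), ]
  fold <- if ("fold" %in% names(pos)) as.integer(pos$fold)
          else rep(NA_integer_, nrow(pos))
  cols <- c("parent_id", "offset", "strand", "site_seq", "score",
            "label", "pair_id")
  rownames(pos) <- rownames(neg) <- NULL
  structure(list(positives = pos[, cols], negatives = neg[, cols],
                 fold = fold),
            class = "site_dataset")
}
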