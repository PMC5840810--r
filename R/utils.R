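DNA_BASES <- c("A", "C", "G", "T")

# first-base-major: AA, AC, AG, AT, CA, ..., TT (pair (x, y) at
# row (x-1)*4 + y, matching pair_index_matrix codes)
DNA_PAIRS <- paste0(rep(DNA_BASES, each = 4L), rep(DNA_BASES, times = 4L))

#' Reverse complement of DNA strings
#'
#' Vectorized over a character vector of A/C/G/T (and IUPAC ambiguity codes)
#' strings.
#'
#' @param x character vector of DNA strings.
#' @return character vector of reverse complements.
#' @examples
#' reverse_complement(c("ACGT", "AAC"))
#' @export
reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Encode equal-length sites as a width x n integer matrix of base codes
# (A=1, C=2, G=3, T=4). Errors on ambiguous or non-ACGT characters.
site_index_matrix <- function(sites, width = NULL) {
  if (length(sites) == 0L) stop("no sites supplied")
  lens <- nchar(sites)
  if (length(unique(lens)) != 1L) stop("sites must all have the same length")
  w <- lens[[1L]]
  if (!is.null(width) && w != width) {
    stop(sprintf("site length %d does not match model width %d", w, width))
  }
  chars <- strsplit(toupper(sites), "", fixed = TRUE)
  idx <- matrix(match(unlist(chars), DNA_BASES), nrow = w)
  if (anyNA(idx)) {
    bad <- which(colSums(is.na(idx)) > 0L)[1L]
    stop(sprintf("unresolvable non-ACGT base in site '%s'", sites[[bad]]))
  }
  idx
}

# Adjacent-pair codes (1..16, first-base-major) from a base-code matrix.
pair_index_matrix <- function(idx) {
  w <- nrow(idx)
  if (w < 2L) stop("dinucleotide encoding needs width >= 2")
  (idx[-w, , drop = FALSE] - 1L) * 4L + idx[-1L, , drop = FALSE]
}

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("'%s' must be TRUE or FALSE", name))
  }
  x
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != as.integer(x) ||
      x < min) {
    stop(sprintf("'%s' must be an integer >= %d", name, min))
  }
  as.integer(x)
}

# Seed R's global RNG when a seed is supplied; NULL leaves the stream alone.
maybe_set_seed <- function(seed) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    set.seed(as.integer(seed))
  }
  invisible(seed)
}
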