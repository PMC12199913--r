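# Positional k-mer descriptors of a sequence, for k-mer orders 1, 2, 3.
#
# All k-mer counting is overlapping with step 1, so a 41-mer contributes 41
# mononucleotides, 40 dinucleotides and 39 trinucleotides.  K-mers are
# indexed lexicographically over A < C < G < U with the first character most
# significant (base-4 digits A=0, C=1, G=2, U=3).
#
# These functions accept any sequence of length >= k over {A,C,G,U(,T)}, not
# only 41-mers, so that small worked examples remain checkable by hand; the
# feature assembler enforces the 41-nt window contract.

#' All k-mers of a given order in canonical order
#'
#' @param k K-mer order, 1, 2 or 3.
#' @return Character vector of length `4^k`, ordered so that
#'   `nm_kmer_index(nm_kmers(k))` is `0:(4^k - 1)`.
#' @export
nm_kmers <- function(k) {
  k <- check_order(k)
  idx <- 0:(4^k - 1)
  chars <- matrix("", length(idx), k)
  for (j in seq_len(k)) {
    chars[, j] <- nm_alphabet()[(idx %/% 4^(k - j)) %% 4 + 1]
  }
  apply(chars, 1L, paste0, collapse = "")
}

check_order <- function(k) {
  if (!(length(k) == 1L && k %in% 1:3))
    stop_validation("k-mer order must be 1, 2 or 3")
  as.integer(k)
}

#' Canonical index of a k-mer
#'
#' Lexicographic rank over `A < C < G < U`, i.e. the base-4 value of the
#' k-mer with digits A=0, C=1, G=2, U=3 and the first character most
#' significant.  `"CG"` has index `1*4 + 2 = 6`.
#'
#' @param kmer Character vector of k-mers, all of one length in 1..3.
#' @return Integer vector of 0-based indices in `0:(4^k - 1)`.
#' @export
nm_kmer_index <- function(kmer) {
  if (!is.character(kmer) || length(kmer) == 0L)
    stop_validation("kmer must be a non-empty character vector")
  k <- unique(nchar(kmer))
  if (length(k) != 1L) stop_validation("k-mers must share one length")
  k <- check_order(k)
  vapply(kmer, function(s) {
    d <- match(strsplit(s, "")[[1L]], nm_alphabet()) - 1L
    if (anyNA(d)) stop_validation("invalid k-mer '%s'", s)
    sum(d * 4^((k - 1):0))
  }, numeric(1), USE.NAMES = FALSE)
}

## 0-based k-mer codes of every overlapping k-mer of `seq` (step 1).
seq_codes <- function(seq, k) {
  k <- check_order(k)
  d <- match(strsplit(seq, "")[[1L]], nm_alphabet()) - 1L
  if (anyNA(d))
    stop_validation("invalid residue at position %d", which(is.na(d))[[1L]])
  n <- length(d)
  if (n < k) stop_validation("sequence length %d < k-mer order %d", n, k)
  codes <- integer(n - k + 1L)
  for (j in seq_len(k)) codes <- codes + d[j:(n - k + j)] * 4L^(k - j)
  codes
}

reverse_seq <- function(seq) {
  paste(rev(strsplit(seq, "")[[1L]]), collapse = "")
}

as_residues <- function(x) {
  if (inherits(x, "nm_windows")) {
    if (nrow(x) != 1L)
      stop_validation("expected a single window, got %d", nrow(x))
    x$seq[[1L]]
  } else if (is.character(x) && length(x) == 1L) {
    normalize_residues(x)
  } else {
    stop_validation("expected a single sequence or one-row nm_windows")
  }
}

#' Overlapping k-mer frequency vector (FV)
#'
#' Counts every overlapping k-mer for k = 1, 2, 3 in the canonical layout
#' `[mono 4 | di 16 | tri 64]`.  For a 41-nt window the blocks sum to 41,
#' 40 and 39 respectively.
#'
#' @param x A single sequence (character) or one-row `nm_windows`.
#' @return Named integer vector of length 84.
#' @export
nm_freq_vector <- function(x) {
  s <- as_residues(x)
  out <- lapply(1:3, function(k)
    tabulate(seq_codes(s, k) + 1L, nbins = 4L^k))
  stats::setNames(as.integer(unlist(out)), unlist(lapply(1:3, nm_kmers)))
}

## Per-k-mer sum of 1-based start positions of all (overlapping) occurrences.
position_sums <- function(seq, k) {
  codes <- seq_codes(seq, k)
  v <- numeric(4^k)
  agg <- rowsum(seq_along(codes), codes)
  v[as.integer(rownames(agg)) + 1L] <- agg[, 1L]
  v
}

#' Accumulative absolute position incidence vector (AAPIV)
#'
#' For every k-mer (k = 1, 2, 3) the sum of the 1-based start positions of
#' all its overlapping occurrences, in the canonical `[mono|di|tri]` layout.
#' On any 41-nt window the mono, di and tri blocks total 861, 820 and 780
#' (each start position counted exactly once per order).
#'
#' @inheritParams nm_freq_vector
#' @return Named numeric vector of length 84.
#' @export
nm_aapiv <- function(x) {
  s <- as_residues(x)
  stats::setNames(unlist(lapply(1:3, function(k) position_sums(s, k))),
                  unlist(lapply(1:3, nm_kmers)))
}

#' Reverse accumulative absolute position incidence vector (RAAPIV)
#'
#' [nm_aapiv()] applied to the reversed sequence.
#'
#' @inheritParams nm_freq_vector
#' @return Named numeric vector of length 84.
#' @export
nm_raapiv <- function(x) {
  nm_aapiv(reverse_seq(as_residues(x)))
}

#' Position-relative incidence matrix (PRIM)
#'
#' Square matrix over the `4^k` k-mers whose entry `[i, j]` accumulates,
#' over every occurrence of k-mer `j` at start position `p`, the relative
#' offset `p - first(i)` where `first(i)` is the 1-based start of the first
#' occurrence of k-mer `i`.  Offsets may be negative; the whole row `i` is
#' zero when k-mer `i` does not occur.
#'
#' @inheritParams nm_freq_vector
#' @param k K-mer order, 1, 2 or 3.
#' @return Numeric `4^k` by `4^k` matrix with k-mer dimnames.
#' @export
nm_prim <- function(x, k = 1) {
  s <- as_residues(x)
  k <- check_order(k)
  codes <- seq_codes(s, k)
  nk <- 4L^k
  first <- match(0:(nk - 1L), codes)             # first occurrence position
  n_occ <- tabulate(codes + 1L, nbins = nk)      # occurrences per k-mer
  pos_sum <- position_sums(s, k)                 # sum of start positions
  M <- matrix(0, nk, nk, dimnames = list(nm_kmers(k), nm_kmers(k)))
  present <- which(!is.na(first))
  # row i over occurrences of j: sum_p (p - first_i) = pos_sum_j - n_j*first_i
  M[present, ] <- matrix(pos_sum, length(present), nk, byrow = TRUE) -
    outer(first[present], n_occ)
  M
}

#' Reverse position-relative incidence matrix (RPRIM)
#'
#' [nm_prim()] applied to the reversed sequence.
#'
#' @inheritParams nm_prim
#' @return Numeric `4^k` by `4^k` matrix.
#' @export
nm_rprim <- function(x, k = 1) {
  nm_prim(reverse_seq(as_residues(x)), k = k)
}

#' Near-square 2-D matrix of integer k-mer codes
#'
#' The k-mer code sequence (1-based codes, [nm_kmer_index()] + 1) is
#' reshaped row-major into an N-by-N matrix with
#' `N = ceiling(sqrt(length))`; trailing cells are zero-padded so padding
#' carries no intensity.  For 41-nt windows N = 7 for every k in 1..3.
#'
#' @inheritParams nm_prim
#' @return Integer N-by-N matrix.
#' @export
nm_matrix2d <- function(x, k = 1) {
  s <- as_residues(x)
  k <- check_order(k)
  codes <- as.integer(seq_codes(s, k)) + 1L
  N <- ceiling(sqrt(length(codes)))
  matrix(c(codes, integer(N * N - length(codes))), N, N, byrow = TRUE)
}
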