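# Synthetic nucleotide-specific Nm benchmark generator.
#
# Emulates the structure of the four nucleotide-specific 2'-O-methylation
# datasets: 41-nt windows with a fixed centre base, where positive windows
# carry an enrichment of one base (guanine by default) in the downstream
# half (positions 22-41) and negative windows are uniform background
# throughout.  Positions are drawn independently given the class — enough
# to exercise every encoder and classifier path, with no attempt to mimic
# inter-position dependence of real Nm motifs.

#' Generate a labeled synthetic Nm dataset
#'
#' Draws `n_pos` positive and `n_neg` negative 41-nt windows with the given
#' centre base at position 21.  In positive windows each position of
#' `region` carries `enrichment_base` with probability `p_enriched` (the
#' remaining mass spread over the other bases in proportion to
#' `background`); all other positions, and every position of negative
#' windows, are drawn from `background`.  Setting `p_enriched` equal to the
#' background probability of `enrichment_base` produces a signal-free
#' dataset (the U2OM-like "evenly distributed" case).
#'
#' @param center_base Centre nucleotide, one of A, C, G, U (default "A").
#' @param n_pos,n_neg Numbers of positive / negative windows (default 200
#'   each).
#' @param p_enriched Probability of `enrichment_base` at enriched positions
#'   of positive windows (default 0.9).
#' @param enrichment_base Enriched base (default "G").
#' @param region Enriched positions, 1-based (default 22:41, the downstream
#'   half); position 21 is always the centre base and is excluded if given.
#' @param background Per-base probabilities for non-enriched positions,
#'   named A/C/G/U and summing to 1 (default uniform).
#' @param seed Optional integer seed; equal seeds give identical datasets.
#' @return A labeled `nm_windows` data frame (`n_pos` rows labeled 1, then
#'   `n_neg` labeled 0).
#' @examples
#' w <- nm_simulate(center_base = "G", n_pos = 5, n_neg = 5, seed = 42)
#' table(w$label)
#' @export
nm_simulate <- function(center_base = "A", n_pos = 200L, n_neg = 200L,
                        p_enriched = 0.9, enrichment_base = "G",
                        region = 22:41,
                        background = c(A = 0.25, C = 0.25, G = 0.25, U = 0.25),
                        seed = NULL) {
  center_base <- match.arg(center_base, nm_alphabet())
  enrichment_base <- match.arg(enrichment_base, nm_alphabet())
  if (!is.numeric(p_enriched) || p_enriched < 0 || p_enriched > 1)
    stop_validation("p_enriched must lie in [0, 1]")
  if (is.null(names(background))) names(background) <- nm_alphabet()
  background <- background[nm_alphabet()]
  if (anyNA(background) || any(background < 0) ||
      abs(sum(background) - 1) > 1e-8)
    stop_validation("background must be per-base probabilities summing to 1")
  if (n_pos < 0L || n_neg < 0L) stop_validation("counts must be non-negative")
  region <- setdiff(as.integer(region), 21L)
  if (length(region) && (min(region) < 1L || max(region) > 41L))
    stop_validation("region positions must lie in 1..41")
  if (!is.null(seed)) set.seed(as.integer(seed))

  # class-conditional per-position base probabilities
  e <- match(enrichment_base, nm_alphabet())
  enriched <- background * (1 - p_enriched) / (sum(background[-e]))
  enriched[e] <- p_enriched
  draw <- function(n, pos_probs) {
    # pos_probs: 41 x 4 matrix of per-position probabilities
    if (n == 0L) return(character(0))
    do.call(paste0, lapply(1:41, function(p)
      sample(nm_alphabet(), n, replace = TRUE, prob = pos_probs[p, ])))
  }
  base_probs <- matrix(background, 41L, 4L, byrow = TRUE)
  base_probs[21L, ] <- 0; base_probs[21L, match(center_base, nm_alphabet())] <- 1
  pos_probs <- base_probs
  if (length(region)) pos_probs[region, ] <-
    matrix(enriched, length(region), 4L, byrow = TRUE)

  seqs <- c(draw(n_pos, pos_probs), draw(n_neg, base_probs))
  ids <- c(sprintf("pos_%d", seq_len(n_pos)), sprintf("neg_%d", seq_len(n_neg)))
  labels <- rep(c(1L, 0L), c(n_pos, n_neg))
  if (length(seqs) == 0L) return(nm_windows(character()))
  nm_windows(stats::setNames(seqs, ids), label = labels)
}

#' Write a labeled dataset as a positive/negative FASTA pair
#'
#' @param windows A labeled `nm_windows` data frame.
#' @param dir Output directory (created if missing).
#' @param prefix File name prefix (default the shared centre base plus
#'   `"2OM"`, e.g. `A2OM_pos.fasta` / `A2OM_neg.fasta`).
#' @return Named character vector with the two paths (`pos`, `neg`),
#'   invisibly.
#' @export
nm_write_dataset <- function(windows, dir, prefix = NULL) {
  stopifnot(inherits(windows, "nm_windows"))
  if (anyNA(windows$label)) stop_validation("all windows must be labeled")
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop_io("cannot create directory '%s'", dir)
  if (is.null(prefix)) {
    cb <- unique(windows$center)
    prefix <- if (length(cb) == 1L) paste0(cb, "2OM") else "dataset"
  }
  paths <- c(pos = file.path(dir, paste0(prefix, "_pos.fasta")),
             neg = file.path(dir, paste0(prefix, "_neg.fasta")))
  nm_write_fasta(windows[windows$label == 1L, , drop = FALSE], paths[["pos"]])
  nm_write_fasta(windows[windows$label == 0L, , drop = FALSE], paths[["neg"]])
  invisible(paths)
}

#' Read a positive/negative FASTA pair back into labeled windows
#'
#' Inverse of [nm_write_dataset()]: windows from `pos_path` are labeled 1
#' and windows from `neg_path` 0.
#'
#' @param pos_path,neg_path FASTA files of 41-nt windows.
#' @return A labeled `nm_windows` data frame (positives first).
#' @export
nm_read_dataset <- function(pos_path, neg_path) {
  pos <- nm_read_sequences(pos_path)
  neg <- nm_read_sequences(neg_path)
  rbind(nm_windows(pos, label = if (nrow(pos)) 1L else integer(0)),
        nm_windows(neg, label = if (nrow(neg)) 0L else integer(0)))
}
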