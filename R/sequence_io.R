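# Reading, validation and windowing of RNA sequences.
#
# All coordinates are 1-based and inclusive.  A prediction window is a
# 41-nucleotide sequence whose candidate 2'-O-methylation site sits at
# position 21; the 20 flanking residues on either side carry the sequence
# context the encoder quantifies.

#' Nucleotide alphabet used throughout the package
#'
#' RNA alphabet in the fixed order `A < C < G < U`.  This ordering defines
#' every k-mer index in the encoder (see [nm_kmer_index()]).
#' @return Character vector of length 4.
#' @export
nm_alphabet <- function() c("A", "C", "G", "U")

#' Window width and centre position
#'
#' Prediction windows are 41 nt wide with the candidate site at 1-based
#' position 21.
#' @return Named integer vector with elements `width` and `center`.
#' @export
nm_window_geometry <- function() c(width = 41L, center = 21L)

## Normalize one residue string: uppercase, DNA thymine -> uracil, and hard
## validation of the 4-letter alphabet.  `id` is used in error messages only.
normalize_residues <- function(seq, id = "<sequence>") {
  s <- chartr("T", "U", toupper(seq))
  bad <- regexpr("[^ACGU]", s)
  if (bad > 0L) {
    stop_validation("record '%s': invalid residue '%s' at position %d",
                    id, substr(s, bad, bad), as.integer(bad))
  }
  s
}

new_nm_seqs <- function(id, seq, offset = NA_integer_) {
  structure(
    data.frame(id = as.character(id), seq = as.character(seq),
               offset = rep_len(as.integer(offset), length(id)),
               stringsAsFactors = FALSE),
    class = c("nm_seqs", "data.frame")
  )
}

#' Read RNA/DNA sequences from FASTA or plain text
#'
#' Reads a multi-record FASTA file (wrapped or unwrapped) or a plain-text
#' file with one sequence per non-empty line.  Residues are upper-cased and
#' DNA `T` is converted to RNA `U`; any other character outside `ACGU` is a
#' validation error naming the record and offending position.
#'
#' @param path Path to the input file.
#' @param format `"auto"` (default) sniffs FASTA by a leading `>`;
#'   `"fasta"` or `"plain"` force a format.
#' @return An `nm_seqs` data frame with columns `id`, `seq` and `offset`
#'   (1-based position of residue 1 in a parent sequence, `NA` for
#'   free-standing records).  Record order follows the file.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1", "ACGT"), fa)
#' nm_read_sequences(fa)$seq  # "ACGU"
#' @export
nm_read_sequences <- function(path, format = c("auto", "fasta", "plain")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_io("cannot read '%s': no such file", path)
  if (format == "auto") {
    head_lines <- readLines(path, n = 50L, warn = FALSE)
    head_lines <- head_lines[nzchar(trimws(head_lines))]
    format <- if (length(head_lines) && startsWith(head_lines[[1L]], ">"))
      "fasta" else "plain"
  }
  if (format == "fasta") {
    set <- tryCatch(Biostrings::readBStringSet(path),
                    error = function(e) stop_io("cannot parse FASTA '%s': %s",
                                                path, conditionMessage(e)))
    ids <- names(set) %||% character()
    seqs <- as.character(set)
    if (length(seqs) == 0L) return(new_nm_seqs(character(), character()))
    ids[!nzchar(ids)] <- paste0("seq", which(!nzchar(ids)))
  } else {
    lines <- readLines(path, warn = FALSE)
    seqs <- trimws(lines)
    seqs <- seqs[nzchar(seqs)]
    if (length(seqs) == 0L) return(new_nm_seqs(character(), character()))
    ids <- paste0("seq", seq_along(seqs))
  }
  seqs <- vapply(seq_along(seqs),
                 function(i) normalize_residues(seqs[[i]], ids[[i]]),
                 character(1))
  new_nm_seqs(ids, seqs)
}

new_nm_windows <- function(id, seq, center_pos, label) {
  structure(
    data.frame(id = as.character(id), seq = as.character(seq),
               center = substr(seq, 21L, 21L),
               center_pos = as.integer(center_pos),
               label = as.integer(label), stringsAsFactors = FALSE),
    class = c("nm_windows", "data.frame")
  )
}

#' Build validated 41-nt prediction windows
#'
#' Turns 41-nt sequences into an `nm_windows` table.  Each window records
#' its centre base (the residue at position 21, the candidate Nm site) and
#' an optional binary label (1 = methylated site, 0 = non-site).
#'
#' @param x An `nm_seqs` data frame from [nm_read_sequences()] or a
#'   character vector of 41-nt sequences.
#' @param label Optional label(s), recycled to the number of windows;
#'   `NA` (default) means unlabeled.
#' @return An `nm_windows` data frame with columns `id`, `seq`, `center`,
#'   `center_pos` (coordinate of the centre in the parent sequence; 21 for
#'   free-standing windows) and `label`.
#' @export
nm_windows <- function(x, label = NA) {
  if (inherits(x, "nm_seqs")) {
    ids <- x$id; seqs <- x$seq
  } else if (is.character(x)) {
    ids <- names(x) %||% paste0("w", seq_along(x))
    seqs <- unname(vapply(seq_along(x),
                          function(i) normalize_residues(x[[i]], ids[[i]]),
                          character(1)))
  } else {
    stop_validation("x must be an 'nm_seqs' table or a character vector")
  }
  len <- nchar(seqs)
  if (any(len != 41L)) {
    i <- which(len != 41L)[[1L]]
    stop_validation("window '%s' has length %d, expected 41", ids[[i]], len[[i]])
  }
  if (length(seqs) == 0L)
    return(new_nm_windows(character(), character(), integer(), integer()))
  label <- rep_len(label, length(seqs))
  if (!all(is.na(label) | label %in% c(0, 1)))
    stop_validation("labels must be binary (0/1) or NA")
  new_nm_windows(ids, seqs, 21L, label)
}

#' Extract every 41-nt window from longer sequences
#'
#' Slides a 41-nt window with step 1 over each record; a length-L sequence
#' yields L - 40 windows.  Only fully contained windows are produced (no
#' padding at sequence ends).  Each window is annotated with the 1-based
#' coordinate of its centre in the parent sequence (start + 20).
#'
#' @param x An `nm_seqs` data frame or character vector of sequences, each
#'   of length >= 41.
#' @return An `nm_windows` data frame ordered by record then start position.
#' @export
nm_scan <- function(x) {
  if (is.character(x)) {
    ids <- names(x) %||% paste0("seq", seq_along(x))
    x <- new_nm_seqs(ids, vapply(seq_along(x), function(i)
      normalize_residues(x[[i]], ids[[i]]), character(1)))
  }
  if (!inherits(x, "nm_seqs"))
    stop_validation("x must be an 'nm_seqs' table or a character vector")
  out <- lapply(seq_len(nrow(x)), function(i) {
    s <- x$seq[[i]]; L <- nchar(s)
    if (L < 41L)
      stop_validation("record '%s' has length %d: too short to scan (need >= 41)",
                      x$id[[i]], L)
    starts <- seq_len(L - 40L)
    list(id = rep(x$id[[i]], length(starts)),
         seq = substring(s, starts, starts + 40L),
         center_pos = starts + 20L)
  })
  new_nm_windows(unlist(lapply(out, `[[`, "id")),
                 unlist(lapply(out, `[[`, "seq")),
                 unlist(lapply(out, `[[`, "center_pos")),
                 NA_integer_)
}

#' Filter windows by centre base
#'
#' Keeps the windows whose candidate site (position 21) is the given base.
#' Applied over all four bases this partitions any window list, matching
#' the four nucleotide-specific Nm datasets (A2OM/C2OM/G2OM/U2OM).
#'
#' @param windows An `nm_windows` data frame.
#' @param base One of `"A"`, `"C"`, `"G"`, `"U"`.
#' @return The matching subset, order preserved.
#' @export
nm_filter_center <- function(windows, base) {
  stopifnot(inherits(windows, "nm_windows"))
  base <- match.arg(base, nm_alphabet())
  out <- windows[windows$center == base, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write windows to FASTA
#'
#' Headers have the form `id|center=<pos>|base=<b>` with `|label=<l>`
#' appended for labeled windows.
#'
#' @param windows An `nm_windows` data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
nm_write_fasta <- function(windows, path) {
  stopifnot(inherits(windows, "nm_windows"))
  hdr <- sprintf("%s|center=%d|base=%s", windows$id, windows$center_pos,
                 windows$center)
  lab <- !is.na(windows$label)
  hdr[lab] <- sprintf("%s|label=%d", hdr[lab], windows$label[lab])
  set <- Biostrings::BStringSet(windows$seq)
  names(set) <- hdr
  ok <- try(Biostrings::writeXStringSet(set, filepath = path), silent = TRUE)
  if (inherits(ok, "try-error")) stop_io("cannot write '%s'", path)
  invisible(path)
}

#' @export
print.nm_windows <- function(x, ...) {
  cat(sprintf("<nm_windows> %d window(s), 41 nt, centre at position 21\n",
              nrow(x)))
  if (nrow(x)) {
    tab <- table(factor(x$center, levels = nm_alphabet()))
    cat("  centre bases:", paste(sprintf("%s=%d", names(tab), tab),
                                 collapse = " "), "\n")
    nlab <- sum(!is.na(x$label))
    if (nlab) cat(sprintf("  labeled: %d (positives %d)\n", nlab,
                          sum(x$label == 1L, na.rm = TRUE)))
    print(utils::head(as.data.frame(x), 5L))
    if (nrow(x) > 5L) cat("  ...", nrow(x) - 5L, "more\n")
  }
  invisible(x)
}
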