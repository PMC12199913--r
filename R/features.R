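# Assembly of the canonical 522-dimensional feature vector and dataset-level
# standard scaling.
#
# Fixed block layout (1-based column ranges):
#   PRIM moments    1..90    (k = 1, 2, 3; 30 moments each)
#   RPRIM moments  91..180
#   frequency     181..264   (mono 4 | di 16 | tri 64)
#   AAPIV         265..348
#   RAAPIV        349..432
#   2-D matrix    433..522   (k = 1, 2, 3; 30 moments each)

#' Canonical feature names
#'
#' The 522 block-qualified feature names, in the fixed layout documented in
#' [nm_features()] (e.g. `prim.k1.raw.m00`, `fv.AAA`, `aapiv.CG`).
#'
#' @return Character vector of length 522.
#' @export
nm_feature_names <- function() {
  mom <- function(prefix) unlist(lapply(1:3, function(k)
    paste(prefix, paste0("k", k),
          paste(rep(c("raw", "central", "hahn"), each = 10),
                rep(rownames(nm_moment_orders()), 3), sep = "."),
          sep = ".")))
  kn <- unlist(lapply(1:3, nm_kmers))
  c(mom("prim"), mom("rprim"),
    paste("fv", kn, sep = "."),
    paste("aapiv", kn, sep = "."),
    paste("raapiv", kn, sep = "."),
    mom("mat2d"))
}

#' Block boundaries of the feature layout
#'
#' @return Named integer vector giving the last (1-based) column of each
#'   block: `prim = 90, rprim = 180, fv = 264, aapiv = 348, raapiv = 432,
#'   mat2d = 522`.
#' @export
nm_feature_blocks <- function() {
  c(prim = 90L, rprim = 180L, fv = 264L, aapiv = 348L, raapiv = 432L,
    mat2d = 522L)
}

## Encode one 41-nt residue string into the 522-vector.
encode_one <- function(seq, u = 0, v = 0) {
  fwd <- unlist(lapply(1:3, function(k) nm_moment_block(nm_prim(seq, k), u, v)))
  rev_ <- unlist(lapply(1:3, function(k) nm_moment_block(nm_rprim(seq, k), u, v)))
  m2d <- unlist(lapply(1:3, function(k)
    nm_moment_block(nm_matrix2d(seq, k), u, v)))
  unname(c(fwd, rev_, nm_freq_vector(seq), nm_aapiv(seq), nm_raapiv(seq), m2d))
}

#' Encode windows into the 522-dimensional feature matrix
#'
#' Deterministically maps each 41-nt window to its 522 features: degree-3
#' raw/central/Hahn moment blocks of the PRIM and RPRIM matrices (k-mer
#' orders 1-3), overlapping k-mer frequencies, AAPIV and RAAPIV position
#' sums, and moment blocks of the row-major 2-D code matrix.  Identical
#' windows yield identical rows.
#'
#' @param x An `nm_windows` data frame (see [nm_windows()], [nm_scan()]) or
#'   a character vector of 41-nt sequences.
#' @param u,v Hahn shape parameters passed to [nm_hahn_moments()]
#'   (default 0).
#' @return Numeric matrix with one row per window and 522 named columns;
#'   row names are window ids.  If any window is labeled the matrix carries
#'   a `label` attribute (integer vector, `NA` where unlabeled).
#' @export
nm_features <- function(x, u = 0, v = 0) {
  if (!inherits(x, "nm_windows")) x <- nm_windows(x)
  X <- matrix(0, nrow(x), 522L,
              dimnames = list(x$id, nm_feature_names()))
  # PRIM offsets can cancel to zero total mass; the all-zero central-moment
  # convention then applies per window and is not worth a warning per row.
  for (i in seq_len(nrow(x)))
    X[i, ] <- withCallingHandlers(
      encode_one(x$seq[[i]], u, v),
      warning = function(w) {
        if (grepl("zero total mass", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
  if (any(!is.na(x$label))) attr(X, "label") <- x$label
  X
}

#' Assemble a labeled feature table
#'
#' [nm_features()] for fully labeled windows, returning the features and
#' the label column separately.  Row order preserves input order.
#'
#' @param x An `nm_windows` data frame in which every window is labeled.
#' @inheritParams nm_features
#' @return List with elements `features` (n x 522 matrix) and `label`
#'   (integer vector of 0/1).
#' @export
nm_feature_table <- function(x, u = 0, v = 0) {
  if (!inherits(x, "nm_windows")) stop_validation("x must be an nm_windows table")
  if (nrow(x) > 0L && anyNA(x$label))
    stop_validation("all windows must be labeled (found %d unlabeled)",
                    sum(is.na(x$label)))
  list(features = nm_features(x, u, v), label = x$label)
}

#' Fit a standard scaler
#'
#' Records per-column means and population standard deviations (divisor n)
#' of a training feature table.  Fit the scaler on the training partition
#' only; applying it to held-out data with [nm_apply_scaler()] keeps
#' evaluation leakage-free.
#'
#' @param X Numeric matrix with at least 2 rows.
#' @return An object of class `nm_scaler` with elements `mean`, `sd` and
#'   `fitted_on` (the training row count).
#' @export
nm_fit_scaler <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop_validation("scaler needs at least 2 rows")
  mu <- colMeans(X)
  sdev <- sqrt(colMeans(sweep(X, 2L, mu)^2))
  structure(list(mean = mu, sd = sdev, fitted_on = nrow(X)),
            class = "nm_scaler")
}

#' Apply a fitted standard scaler
#'
#' Maps each column to `(x - mean) / sd`; columns that were constant in the
#' training data (sd = 0) map to 0.
#'
#' @param X Numeric matrix whose columns match the scaler's.
#' @param scaler An `nm_scaler` from [nm_fit_scaler()].
#' @return Scaled matrix of the same shape.
#' @export
nm_apply_scaler <- function(X, scaler) {
  stopifnot(inherits(scaler, "nm_scaler"))
  X <- as.matrix(X)
  if (ncol(X) != length(scaler$mean))
    stop_validation("column count %d does not match scaler (%d)",
                    ncol(X), length(scaler$mean))
  Z <- sweep(X, 2L, scaler$mean)
  sdev <- scaler$sd
  sdev[sdev == 0] <- Inf   # constant columns -> 0 after division
  sweep(Z, 2L, sdev, "/")
}

#' @export
print.nm_scaler <- function(x, ...) {
  cat(sprintf("<nm_scaler> %d columns, fitted on %d rows (%d constant)\n",
              length(x$mean), x$fitted_on, sum(x$sd == 0)))
  invisible(x)
}
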