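# Brute-force reference implementations used as independent oracles.
# Deliberately naive (explicit loops over occurrences and grid cells) and
# kept independent of the package's closed-form code paths.

ALPHA <- c("A", "C", "G", "U")

random_window <- function(center = NULL) {
  s <- sample(ALPHA, 41, replace = TRUE)
  if (!is.null(center)) s[21] <- center
  paste(s, collapse = "")
}

random_sequence <- function(len) paste(sample(ALPHA, len, replace = TRUE),
                                       collapse = "")

## all overlapping k-mers of s as strings
o_kmer_tokens <- function(s, k) {
  n <- nchar(s)
  substring(s, 1:(n - k + 1), k:n)
}

## position list per k-mer string
o_positions <- function(s, k) {
  toks <- o_kmer_tokens(s, k)
  split(seq_along(toks), toks)
}

o_freq <- function(s, k) {
  counts <- stats::setNames(integer(4^k), nm_kmers(k))
  tab <- table(o_kmer_tokens(s, k))
  counts[names(tab)] <- as.integer(tab)
  counts
}

o_aapiv <- function(s, k) {
  sums <- stats::setNames(numeric(4^k), nm_kmers(k))
  pos <- o_positions(s, k)
  for (m in names(pos)) sums[m] <- sum(pos[[m]])
  sums
}

## nested-loop PRIM: offset of every occurrence of column k-mer from the
## first occurrence of the row k-mer
o_prim <- function(s, k) {
  kmers <- nm_kmers(k)
  pos <- o_positions(s, k)
  M <- matrix(0, 4^k, 4^k, dimnames = list(kmers, kmers))
  for (i in kmers) {
    if (is.null(pos[[i]])) next
    fi <- min(pos[[i]])
    for (j in kmers) {
      if (is.null(pos[[j]])) next
      acc <- 0
      for (p in pos[[j]]) acc <- acc + (p - fi)
      M[i, j] <- acc
    }
  }
  M
}

o_revseq <- function(s) paste(rev(strsplit(s, "")[[1]]), collapse = "")

o_raw_moments <- function(m) {
  ord <- nm_moment_orders()
  vals <- numeric(nrow(ord))
  for (t in seq_len(nrow(ord))) {
    acc <- 0
    for (a in seq_len(nrow(m))) for (b in seq_len(ncol(m)))
      acc <- acc + a^ord[t, 1] * b^ord[t, 2] * m[a, b]
    vals[t] <- acc
  }
  stats::setNames(vals, rownames(ord))
}

o_central_moments <- function(m) {
  L00 <- sum(m)
  xb <- 0; yb <- 0
  for (a in seq_len(nrow(m))) for (b in seq_len(ncol(m))) {
    xb <- xb + a * m[a, b]; yb <- yb + b * m[a, b]
  }
  xb <- xb / L00; yb <- yb / L00
  ord <- nm_moment_orders()
  vals <- numeric(nrow(ord))
  for (t in seq_len(nrow(ord))) {
    acc <- 0
    for (a in seq_len(nrow(m))) for (b in seq_len(ncol(m)))
      acc <- acc + (a - xb)^ord[t, 1] * (b - yb)^ord[t, 2] * m[a, b]
    vals[t] <- acc
  }
  stats::setNames(vals, rownames(ord))
}

## Mann-Whitney AUC over all (positive, negative) pairs; ties count 1/2
o_auc <- function(labels, scores) {
  ps <- scores[labels == 1]; ns <- scores[labels == 0]
  acc <- 0
  for (p in ps) for (q in ns)
    acc <- acc + if (p > q) 1 else if (p == q) 0.5 else 0
  acc / (length(ps) * length(ns))
}

## separable toy features for classifier sanity checks
separable_features <- function(n_per_class, p = 20, gap = 4, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per_class * p, -gap / 2), n_per_class, p),
             matrix(rnorm(n_per_class * p, gap / 2), n_per_class, p))
  colnames(X) <- paste0("f", seq_len(p))
  list(X = X, y = rep(c(0L, 1L), each = n_per_class))
}
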