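# Raw, central and orthonormal discrete Hahn moments of square matrices.
#
# Moments of degree <= 3 are the package's dimensionality-reduction device:
# each square descriptor matrix collapses to 10 numbers per moment family.
# Raw/central moments use 1-based grid indices (a, b = 1..N); Hahn
# polynomials are evaluated on the 0-based lattice r = 0..N-1.  The
# off-by-one is internal and invisible to callers.

#' The fixed set of moment orders
#'
#' The ten exponent pairs (u, v) with u + v <= 3, in the fixed order used by
#' every moment family and by the feature layout.
#'
#' @return A 10 x 2 integer matrix with columns `u` and `v`.
#' @export
nm_moment_orders <- function() {
  m <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1), c(0, 2),
             c(2, 0), c(1, 2), c(2, 1), c(0, 3), c(3, 0))
  dimnames(m) <- list(paste0("m", m[, 1], m[, 2]), c("u", "v"))
  m
}

check_square <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m) || nrow(m) < 1L)
    stop_validation("input must be a square matrix")
  if (!all(is.finite(m))) stop_validation("matrix entries must be finite")
  storage.mode(m) <- "double"
  m
}

#' Raw moments of a square matrix
#'
#' `L_uv = sum_a sum_b a^u * b^v * beta[a, b]` with 1-based row index `a`
#' and column index `b`, for the ten order pairs of [nm_moment_orders()].
#'
#' @param m Square numeric matrix.
#' @return Named numeric vector of length 10.
#' @export
nm_raw_moments <- function(m) {
  m <- check_square(m)
  idx <- seq_len(nrow(m))
  ord <- nm_moment_orders()
  vals <- vapply(seq_len(nrow(ord)), function(i)
    drop(idx^ord[i, 1] %*% m %*% idx^ord[i, 2]), numeric(1))
  stats::setNames(vals, rownames(ord))
}

#' Central moments of a square matrix
#'
#' Raw-moment analogue about the intensity centroid
#' `(xbar, ybar) = (L10/L00, L01/L00)`:
#' `n_ij = sum_a sum_b (a - xbar)^i * (b - ybar)^j * beta[a, b]`.
#' By construction `n10 = n01 = 0` and `n00 = L00`.  A matrix with zero
#' total mass has no centroid; all ten values are returned as 0 with a
#' warning.
#'
#' @param m Square numeric matrix.
#' @return Named numeric vector of length 10.
#' @export
nm_central_moments <- function(m) {
  m <- check_square(m)
  idx <- seq_len(nrow(m))
  L00 <- sum(m)
  ord <- nm_moment_orders()
  if (L00 == 0) {
    warning("zero total mass: centroid undefined, central moments set to 0")
    return(stats::setNames(numeric(10), rownames(ord)))
  }
  xbar <- drop(idx %*% rowSums(m)) / L00
  ybar <- drop(colSums(m) %*% idx) / L00
  vals <- vapply(seq_len(nrow(ord)), function(i)
    drop((idx - xbar)^ord[i, 1] %*% m %*% (idx - ybar)^ord[i, 2]), numeric(1))
  stats::setNames(vals, rownames(ord))
}

## Pochhammer (rising factorial) in log space with sign tracking, so that
## basis construction stays finite for large N and degree.
lpoch <- function(x, k) {
  if (k == 0L) return(c(lg = 0, sign = 1))
  terms <- x + 0:(k - 1L)
  if (any(terms == 0)) return(c(lg = -Inf, sign = 0))
  c(lg = sum(log(abs(terms))), sign = prod(sign(terms)))
}

poch <- function(x, k) {
  p <- lpoch(x, k)
  p[["sign"]] * exp(p[["lg"]])
}

#' Discrete Hahn polynomial
#'
#' The degree-`n` Hahn polynomial on the lattice `r = 0..N-1` with
#' non-negative shape parameters `u`, `v`:
#' `h_n(r) = (N+v-1)_n (N-1)_n * 3F2(-n, n+u+v+1, -r; u+1, -(N-1); 1)`
#' where `(x)_k` is the rising factorial.  The family is orthogonal on the
#' lattice under the weight `w(r) = C(u+r, r) * C(v+N-1-r, N-1-r)`.
#' At `u = v = 0` it reduces to the discrete Chebyshev polynomials
#' (uniform weight), with e.g. `h_1(r) = (N-1)^2 - 2*r*(N-1)`.
#'
#' @param n Degree, `0 <= n <= N-1`.
#' @param r Evaluation point(s), each in `0..N-1`.
#' @param N Lattice size, `N >= 2`.
#' @param u,v Non-negative shape parameters (default 0).
#' @return Numeric vector of polynomial values at `r`.
#' @export
nm_hahn_poly <- function(n, r, N, u = 0, v = 0) {
  check_hahn_args(n, r, N, u, v)
  pref <- poch(N + v - 1, n) * poch(N - 1, n)
  vapply(r, function(ri) {
    s <- 0
    for (k in 0:n) {
      s <- s + poch(-n, k) * poch(n + u + v + 1, k) * poch(-ri, k) /
        (poch(u + 1, k) * poch(-(N - 1), k) * factorial(k))
    }
    pref * s
  }, numeric(1))
}

check_hahn_args <- function(n, r, N, u, v) {
  if (!(length(N) == 1L && N >= 2)) stop_validation("N must be >= 2")
  if (!(length(n) == 1L && n >= 0 && n <= N - 1))
    stop_validation("degree n must satisfy 0 <= n <= N-1")
  if (any(r < 0 | r > N - 1))
    stop_validation("evaluation points must lie in 0..N-1")
  if (u < 0 || v < 0) stop_validation("u and v must be non-negative")
  invisible(TRUE)
}

hahn_weight <- function(r, N, u, v) {
  exp(lgamma(u + r + 1) - lgamma(r + 1) - lgamma(u + 1) +
      lgamma(v + N - r) - lgamma(N - r) - lgamma(v + 1))
}

## Cache of orthonormal bases keyed by (N, u, v, degrees).
.hahn_cache <- new.env(parent = emptyenv())

#' Orthonormal Hahn basis
#'
#' Rows are the weighted, norm-scaled polynomials
#' `h~_n(r) = h_n(r) * sqrt(w(r) / rho_n)` with `rho_n` the squared norm
#' `sum_r h_n(r)^2 w(r)`, so that the rows form an orthonormal set:
#' `B %*% t(B)` is the identity.
#'
#' @param N Lattice size.
#' @param u,v Shape parameters (default 0).
#' @param degrees Degrees to include (default `0:3`).
#' @return A `length(degrees)` x `N` matrix.
#' @export
nm_hahn_basis <- function(N, u = 0, v = 0, degrees = 0:3) {
  key <- paste(N, u, v, paste(degrees, collapse = ","), sep = "|")
  hit <- .hahn_cache[[key]]
  if (!is.null(hit)) return(hit)
  r <- 0:(N - 1)
  w <- hahn_weight(r, N, u, v)
  B <- t(vapply(degrees, function(n) {
    h <- nm_hahn_poly(n, r, N, u, v)
    h * sqrt(w / sum(h^2 * w))
  }, numeric(N)))
  rownames(B) <- paste0("h", degrees)
  .hahn_cache[[key]] <- B
  B
}

#' Orthonormal Hahn polynomial value
#'
#' Single value `h~_n(r)` of the orthonormalized Hahn polynomial (see
#' [nm_hahn_basis()]).
#'
#' @inheritParams nm_hahn_poly
#' @return Numeric vector of values at `r`.
#' @export
nm_hahn_orthonormal <- function(n, r, N, u = 0, v = 0) {
  check_hahn_args(n, r, N, u, v)
  nm_hahn_basis(N, u, v, degrees = 0:(N - 1))[n + 1L, r + 1L]
}

#' Hahn moments of a square matrix
#'
#' Projections onto the orthonormal Hahn basis:
#' `H_ij = sum_q sum_p beta[q+1, p+1] * h~_i(q) * h~_j(p)` for the ten
#' order pairs with `i + j <= 3`.  With the full set of orders (i, j up to
#' N-1) the transform is invertible; here it is truncated to degree 3.
#'
#' @param m Square numeric matrix of side N.
#' @param u,v Hahn shape parameters (default 0).
#' @return Named numeric vector of length 10.
#' @export
nm_hahn_moments <- function(m, u = 0, v = 0) {
  m <- check_square(m)
  N <- nrow(m)
  if (N < 2L) stop_validation("Hahn moments need matrix side >= 2")
  B <- nm_hahn_basis(N, u, v, degrees = 0:min(3L, N - 1L))
  H <- B %*% m %*% t(B)
  ord <- nm_moment_orders()
  vals <- vapply(seq_len(nrow(ord)), function(i) {
    a <- ord[i, 1] + 1L; b <- ord[i, 2] + 1L
    if (a > nrow(B) || b > nrow(B)) NA_real_ else H[a, b]
  }, numeric(1))
  stats::setNames(vals, rownames(ord))
}

#' Thirty-number moment block of a square matrix
#'
#' Concatenation `[raw(10) | central(10) | hahn(10)]` in the order of
#' [nm_moment_orders()] — the unit from which the 522-feature layout is
#' built.
#'
#' @inheritParams nm_hahn_moments
#' @return Named numeric vector of length 30 with names
#'   `raw.m00, ..., hahn.m30`.
#' @export
nm_moment_block <- function(m, u = 0, v = 0) {
  m <- check_square(m)
  vals <- c(nm_raw_moments(m), nm_central_moments(m), nm_hahn_moments(m, u, v))
  names(vals) <- paste(rep(c("raw", "central", "hahn"), each = 10),
                       rep(rownames(nm_moment_orders()), 3), sep = ".")
  vals
}
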