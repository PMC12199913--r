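test_that("the moment order set is the ten pairs with u + v <= 3", {
  ord <- nm_moment_orders()
  expect_identical(dim(ord), c(10L, 2L))
  expect_true(all(rowSums(ord) <= 3) && all(ord >= 0))
  expect_identical(nrow(unique(ord)), 10L)
})

test_that("raw moments match hand-computed and oracle values", {
  expect_true(all(nm_raw_moments(matrix(0, 3, 3)) == 0))
  m <- diag(2)
  L <- nm_raw_moments(m)
  expect_identical(unname(L[c("m00", "m10", "m01", "m11")]), c(2, 3, 3, 5))
  c1 <- matrix(4.5, 1, 1)
  expect_true(all(nm_raw_moments(c1) == 4.5))   # 1^u 1^v = 1 for all pairs
  expect_error(nm_raw_moments(matrix(1, 2, 3)), class = "nm_validation_error")
})

test_that("central moments vanish at first order and match direct evaluation", {
  ones <- matrix(1, 2, 2)
  n <- nm_central_moments(ones)
  expect_identical(unname(n[c("m00", "m10", "m01", "m11")]), c(4, 0, 0, 0))
  expect_identical(unname(n[c("m20", "m02")]), c(1, 1))
  expect_warning(z <- nm_central_moments(matrix(0, 3, 3)), "zero total mass")
  expect_true(all(z == 0))
})

test_that("raw and central moments agree with the double-loop oracle", {
  set.seed(21)
  for (i in 1:50) {
    N <- sample(2:9, 1)
    m <- matrix(rnorm(N * N), N, N)
    expect_equal(nm_raw_moments(m), o_raw_moments(m), tolerance = 1e-9)
    if (abs(sum(m)) > 1e-6)
      expect_equal(nm_central_moments(m), o_central_moments(m),
                   tolerance = 1e-9)
    n <- nm_central_moments(m + 2)   # guaranteed mass
    expect_equal(unname(n[c("m10", "m01")]), c(0, 0), tolerance = 1e-9)
    expect_equal(n[["m00"]], nm_raw_moments(m + 2)[["m00"]])
  }
})

test_that("Hahn polynomials satisfy their closed forms", {
  N <- 5
  expect_equal(nm_hahn_poly(0, 0:4, N), rep(1, 5))        # h_0 = 1
  expect_equal(nm_hahn_poly(1, 2, N), 0)                  # centre point
  expect_equal(nm_hahn_poly(1, 0, N), 16)                 # (N-1)^2 at r = 0
  r <- 0:(N - 1)
  expect_equal(nm_hahn_poly(1, r, N), (N - 1)^2 - 2 * r * (N - 1))
  expect_error(nm_hahn_poly(5, 0, N), class = "nm_validation_error")
  expect_error(nm_hahn_poly(1, 7, N), class = "nm_validation_error")
})

test_that("the orthonormal Hahn basis has identity Gram matrix", {
  for (N in 2:10) {
    B <- nm_hahn_basis(N, degrees = 0:min(3, N - 1))
    G <- B %*% t(B)
    expect_lt(max(abs(G - diag(nrow(B)))), 1e-8)
  }
  # shape parameters other than zero stay orthonormal
  B <- nm_hahn_basis(7, u = 1.5, v = 2)
  expect_lt(max(abs(B %*% t(B) - diag(4))), 1e-8)
  # normalization: sum_r h~_0(r)^2 = 1
  for (N in 2:10)
    expect_equal(sum(nm_hahn_basis(N, degrees = 0)[1, ]^2), 1)
})

test_that("full-order Hahn analysis/synthesis round-trips random matrices", {
  set.seed(22)
  for (i in 1:10) {
    m <- matrix(rnorm(49), 7, 7)
    B <- nm_hahn_basis(7, degrees = 0:6)     # full order: invertible
    H <- B %*% m %*% t(B)
    back <- t(B) %*% H %*% B
    expect_lt(max(abs(back - m)), 1e-6)
  }
})

test_that("degree-3 Hahn moments equal the double-sum over the basis", {
  expect_true(all(nm_hahn_moments(matrix(0, 7, 7)) == 0))
  set.seed(23)
  m <- matrix(rnorm(49), 7, 7)
  H <- nm_hahn_moments(m)
  ord <- nm_moment_orders()
  B <- nm_hahn_basis(7)
  for (t in seq_len(nrow(ord))) {
    acc <- 0
    for (q in 1:7) for (p in 1:7)
      acc <- acc + m[q, p] * B[ord[t, 1] + 1, q] * B[ord[t, 2] + 1, p]
    expect_equal(unname(H[t]), unname(acc), tolerance = 1e-9)
  }
  # constant matrix: odd-degree projections vanish by symmetry of the basis
  Hc <- nm_hahn_moments(matrix(3, 7, 7))
  odd <- rowSums(ord) %% 2 == 1
  expect_true(all(abs(Hc[odd]) < 1e-8))
})

test_that("the 30-number moment block is the three families concatenated", {
  set.seed(24)
  m <- matrix(rpois(16, 3), 4, 4)
  blk <- nm_moment_block(m)
  expect_length(blk, 30)
  expect_equal(unname(blk[1:10]), unname(nm_raw_moments(m)))
  expect_equal(unname(blk[11:20]), unname(nm_central_moments(m)))
  expect_equal(unname(blk[21:30]), unname(nm_hahn_moments(m)))
  expect_warning(zb <- nm_moment_block(matrix(0, 4, 4)), "zero total mass")
  expect_true(all(zb == 0) && length(zb) == 30)
})
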