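test_that("default subspace size is the square-root ceiling", {
  expect_identical(default_r(44928), 212L)
  expect_identical(default_r(22283), 150L)
  expect_identical(default_r(4), 2L)
  expect_identical(default_r(1), 1L)
  expect_identical(default_r(100), 10L)
})

test_that("subspace selection draws distinct indices and respects bounds", {
  set.seed(1)
  s <- select_subspace(1000, 31)
  expect_length(s, 31)
  expect_false(any(duplicated(s)))
  expect_true(all(s >= 1 & s <= 1000))

  set.seed(9); a <- select_subspace(50, 7)
  set.seed(9); b <- select_subspace(50, 7)
  expect_identical(a, b)

  set.seed(2)
  full <- select_subspace(5, 5, allow_full = TRUE)
  expect_setequal(full, 1:5)
  expect_error(select_subspace(5, 5), "subspace size")
  expect_error(select_subspace(5, 6, allow_full = TRUE), "subspace size")
})

test_that("variable partition gives k size-M subsets plus the leftovers", {
  set.seed(3)
  part <- partition_variables(1:7, 3)
  expect_length(part$subsets, 2)
  expect_true(all(lengths(part$subsets) == 3))
  expect_length(part$remainder, 1)
  expect_setequal(c(unlist(part$subsets), part$remainder), 1:7)

  part2 <- partition_variables(1:150, 2)
  expect_length(part2$subsets, 75)
  expect_length(part2$remainder, 0)

  expect_error(partition_variables(1:4, 5), "M must satisfy")
})

test_that("block loadings match a direct eigendecomposition of each block", {
  # r = 4, M = 2, hand-built 6-row bootstrap sample
  set.seed(21)
  X <- matrix(rnorm(6 * 4), 6, 4)
  colnames(X) <- paste0("x", 1:4)
  d <- tibble::tibble(time = c(1, 2, 3, 4, 5, 6), event = rep(1L, 6),
                      as.data.frame(X))
  spec <- structure(list(
    p = 4L, subspace = 1:4,
    subsets = list(c(1L, 3L), c(2L, 4L)), remainder = integer(0),
    bootstrap_indices = 1:6,
    block_loadings = NULL, center = NULL, rotation = NULL
  ), class = "rotation_spec")
  spec <- fit_block_rotation(d, spec)

  for (b in 1:2) {
    pos <- spec$subsets[[b]]
    Xc <- scale(X[, pos], center = TRUE, scale = FALSE)
    eig <- eigen(crossprod(Xc) / (nrow(Xc) - 1), symmetric = TRUE)
    V <- eig$vectors
    # align the oracle's arbitrary signs with the documented convention
    for (j in 1:2) if (V[which.max(abs(V[, j])), j] < 0) V[, j] <- -V[, j]
    expect_equal(spec$block_loadings[[b]], V, tolerance = 1e-10)
    expect_equal(unname(spec$rotation[pos, pos]), V, tolerance = 1e-10)
  }
  off <- spec$rotation[spec$subsets[[1]], spec$subsets[[2]]]
  expect_true(all(off == 0))
})

test_that("loadings are orthonormal and remainder rows/columns exactly zero", {
  set.seed(4)
  for (rep in 1:10) {
    n <- 40; p <- sample(20:60, 1)
    d <- simulate_survival_data(n = n, p = p, n_informative = 3,
                                seed = 100 + rep)
    r <- sample(5:(p - 1), 1)
    M <- sample(2:min(4, r), 1)
    set.seed(rep)
    spec <- rrotsf:::new_rotation_spec(p, n, r, M)
    spec <- fit_block_rotation(d, spec)
    for (L in spec$block_loadings) {
      expect_lt(max(abs(crossprod(L) - diag(ncol(L)))), 1e-8)
    }
    if (length(spec$remainder) > 0) {
      expect_true(all(spec$rotation[spec$remainder, ] == 0))
      expect_true(all(spec$rotation[, spec$remainder] == 0))
    }
  }
})

test_that("rotation preserves per-block variance on the fitting sample", {
  set.seed(5)
  n <- 50; p <- 30
  d <- simulate_survival_data(n = n, p = p, n_informative = 2, seed = 55)
  X <- as.matrix(d[, paste0("x", 1:p)])
  set.seed(6)
  spec <- rrotsf:::new_rotation_spec(p, n, r = 11, M = 3)
  spec <- fit_block_rotation(d, spec)
  Xb <- X[spec$bootstrap_indices, , drop = FALSE]
  Z <- apply_rotation(Xb, spec)
  Xc <- sweep(Xb[, spec$subspace], 2, spec$center)
  for (pos in spec$subsets) {
    vin <- sum(apply(Xc[, pos, drop = FALSE], 2, stats::var))
    vout <- sum(apply(Z[, pos, drop = FALSE], 2, stats::var))
    expect_equal(vout, vin, tolerance = 1e-6)
  }
  # remainder output columns are exactly zero
  if (length(spec$remainder) > 0) {
    expect_true(all(Z[, spec$remainder] == 0))
  }
})

test_that("a centered row maps to zero and schema mismatches error", {
  d <- simulate_survival_data(n = 30, p = 8, seed = 9)
  set.seed(7)
  spec <- rrotsf:::new_rotation_spec(8, 30, r = 4, M = 2)
  spec <- fit_block_rotation(d, spec)
  x <- numeric(8)
  x[spec$subspace] <- spec$center
  expect_equal(as.vector(apply_rotation(matrix(x, 1), spec)), rep(0, 4))
  expect_error(apply_rotation(matrix(0, 2, 5), spec), "mismatch")
})

test_that("degenerate full-subspace single-block mode is plain PCA", {
  set.seed(8)
  n <- 25; p <- 6
  d <- simulate_survival_data(n = n, p = p, n_informative = 1, seed = 77)
  X <- as.matrix(d[, paste0("x", 1:p)])
  set.seed(12)
  spec <- rrotsf:::new_rotation_spec(p, n, r = p, M = p, allow_full = TRUE)
  spec <- fit_block_rotation(d, spec)
  expect_length(spec$remainder, 0)
  expect_length(spec$subsets, 1)

  Xb <- X[spec$bootstrap_indices, , drop = FALSE]
  Z <- apply_rotation(Xb, spec)

  # independent full PCA oracle: scores of the block's columns in block order
  block_cols <- spec$subspace[spec$subsets[[1]]]
  B <- scale(Xb[, block_cols, drop = FALSE], center = TRUE, scale = FALSE)
  eig <- eigen(crossprod(B) / (nrow(B) - 1), symmetric = TRUE)
  V <- eig$vectors
  for (j in seq_len(p)) {
    if (V[which.max(abs(V[, j])), j] < 0) V[, j] <- -V[, j]
  }
  scores <- B %*% V
  expect_equal(unname(Z[, spec$subsets[[1]], drop = FALSE]), unname(scores),
               tolerance = 1e-8)
})

test_that("different member seeds give different subspaces or partitions", {
  set.seed(31); s1 <- rrotsf:::new_rotation_spec(40, 30, 6, 2)
  set.seed(32); s2 <- rrotsf:::new_rotation_spec(40, 30, 6, 2)
  expect_false(identical(s1$subspace, s2$subspace) &&
                 identical(s1$subsets, s2$subsets))
})

test_that("constant-covariate blocks fall back to identity loadings", {
  n <- 20
  d <- tibble::tibble(time = seq_len(n), event = rep(1L, n),
                      x1 = rep(2, n), x2 = rep(-1, n),
                      x3 = rnorm(n), x4 = rnorm(n))
  spec <- structure(list(
    p = 4L, subspace = 1:4,
    subsets = list(c(1L, 2L), c(3L, 4L)), remainder = integer(0),
    bootstrap_indices = seq_len(n),
    block_loadings = NULL, center = NULL, rotation = NULL
  ), class = "rotation_spec")
  spec <- fit_block_rotation(d, spec)
  expect_equal(spec$block_loadings[[1]], diag(2))
})
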