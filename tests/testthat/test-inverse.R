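rand_system <- function(d, n, seed) {
  set.seed(seed)
  M <- matrix(rnorm(d * n), d, n)
  src <- matrix(rnorm(n * 3), n, 3) * 10
  ori <- src / sqrt(rowSums(src^2))
  ch <- matrix(rnorm(d * 3), d, 3)
  ch <- ch / sqrt(rowSums(ch^2)) * (max(sqrt(rowSums(src^2))) + 50)
  leadfield(M, sprintf("C%02d", seq_len(d)), ch, src, ori)
}

test_that("wMNE matches the dense closed form on small random systems", {
  for (seed in 1:10) {
    lf <- rand_system(4, 6, seed)
    y <- matrix(rnorm(4 * 5), 4, 5)
    cfg <- solver_config("wmne", lambda_rule = "fixed", lambda_value = 0.1,
                         depth_exponent = 1)
    est <- wmne(y, lf, cfg)
    # oracle: explicit dense evaluation of W^-1 M' (M W^-1 M' + lambda I)^-1 y
    M <- lf$matrix
    W <- diag(colSums(M^2))
    Winv <- diag(1 / diag(W))
    xo <- Winv %*% t(M) %*% solve(M %*% Winv %*% t(M) + 0.1 * diag(4)) %*% y
    expect_equal(est$x_hat, xo, tolerance = 1e-8)
  }
})

test_that("wMNE limits behave: zero data, heavy regularization, no weighting", {
  lf <- rand_system(6, 12, 3)
  y <- matrix(rnorm(6 * 8), 6, 8)
  expect_equal(wmne(matrix(0, 6, 8), lf)$x_hat, matrix(0, 12, 8))
  # ||x_hat|| decreases monotonically in lambda and vanishes
  scale <- sum(diag(tcrossprod(lf$matrix)))
  norms <- vapply(c(0.1, 10, 1e3, 1e12 * scale), function(l) {
    cfg <- solver_config("wmne", lambda_rule = "fixed", lambda_value = l)
    sqrt(sum(wmne(y, lf, cfg)$x_hat^2))
  }, numeric(1))
  expect_true(all(diff(norms) < 0))
  expect_lt(norms[4], 1e-9)
  # depth_exponent 0 reduces to plain (unweighted) Tikhonov MNE
  cfg0 <- solver_config("wmne", lambda_rule = "fixed", lambda_value = 0.5,
                        depth_exponent = 0)
  M <- lf$matrix
  plain <- t(M) %*% solve(tcrossprod(M) + 0.5 * diag(6)) %*% y
  expect_equal(wmne(y, lf, cfg0)$x_hat, plain, tolerance = 1e-10)
})

test_that("sLORETA matches a per-source brute-force standardization", {
  for (seed in 1:10) {
    lf <- rand_system(5, 8, seed + 20)
    y <- matrix(rnorm(5 * 4), 5, 4)
    cfg <- solver_config("sloreta", lambda_rule = "fixed", lambda_value = 0.2)
    est <- sloreta(y, lf, cfg)
    M <- lf$matrix
    Kinv <- solve(tcrossprod(M) + 0.2 * diag(5))
    xo <- matrix(0, 8, 4)
    for (i in 1:8) {
      mi <- M[, i]
      xo[i, ] <- (mi %*% Kinv %*% y) / sqrt(drop(mi %*% Kinv %*% mi))
    }
    expect_equal(est$x_hat, xo, tolerance = 1e-8)
  }
})

test_that("sLORETA zeroes sources invisible to the montage with a warning", {
  lf <- rand_system(5, 8, 77)
  lf$matrix[, 3] <- 0
  y <- matrix(rnorm(5 * 2), 5, 2)
  expect_warning(est <- sloreta(y, lf), "invisible")
  expect_equal(est$x_hat[3, ], c(0, 0))
  expect_equal(sloreta(matrix(0, 5, 2), rand_system(5, 8, 78))$x_hat,
               matrix(0, 8, 2))
})

test_that("sLORETA recovers a noiseless single dipole at every vertex", {
  lf <- fix$lf16
  op <- make_inverse_operator(lf, solver_config("sloreta"))
  for (j in seq_len(ncol(lf$matrix))) {
    est <- apply_inverse(op, lf$matrix[, j, drop = FALSE])
    loc <- estimate_location(est$x_hat, lf$source_positions, toi(0, 1), fs = 1)
    expect_identical(loc$estimated_vertex, j)
  }
})

test_that("solvers are linear in the data at fixed lambda", {
  lf <- rand_system(6, 10, 5)
  y1 <- matrix(rnorm(6 * 7), 6, 7)
  y2 <- matrix(rnorm(6 * 7), 6, 7)
  for (m in c("wmne", "sloreta")) {
    cfg <- solver_config(m, lambda_rule = "fixed", lambda_value = 0.3)
    op <- make_inverse_operator(lf, cfg)
    lhs <- apply_inverse(op, 2 * y1 - 3 * y2)$x_hat
    rhs <- 2 * apply_inverse(op, y1)$x_hat - 3 * apply_inverse(op, y2)$x_hat
    expect_equal(lhs, rhs, tolerance = 1e-9)
  }
})

test_that("dispatcher routes, validates, and honors the weighting identity", {
  lf <- rand_system(6, 10, 6)
  y <- matrix(rnorm(6 * 4), 6, 4)
  cfg <- solver_config("wmne", lambda_rule = "fixed", lambda_value = 0.1)
  expect_equal(solve_inverse(y, lf, cfg)$x_hat, wmne(y, lf, cfg)$x_hat)
  expect_equal(solve_inverse(matrix(0, 6, 4), lf, cfg)$x_hat, matrix(0, 10, 4))
  # all-ones chromosome: weighted epoch identical to the raw epoch
  expect_equal(solve_inverse(weight_eeg(y, rep(1, 6)), lf, cfg)$x_hat,
               solve_inverse(y, lf, cfg)$x_hat)
  expect_error(solve_inverse(y, lf, solver_config("nosuch")), "unknown")
  expect_error(apply_inverse(make_inverse_operator(lf, cfg), matrix(0, 3, 4)),
               "channel count")
})

test_that("third-party solvers can be plugged into the dispatcher", {
  builder <- function(leadfield, config) {
    structure(list(K_op = t(leadfield$matrix), method = "transpose",
                   lambda = 0, fallback = FALSE, reference = "none"),
              class = "inverse_operator")
  }
  register_solver("transpose", builder)
  lf <- rand_system(4, 6, 8)
  y <- matrix(rnorm(8), 4, 2)
  est <- solve_inverse(y, lf, solver_config("transpose"))
  expect_equal(est$x_hat, t(lf$matrix) %*% y)
})
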