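# PRCC machinery against independent implementations and rank properties.

# independent small-scale PRCC: explicit normal-equation regressions on ranks
prcc_oracle <- function(X, y) {
  R <- apply(X, 2, rank)
  ry <- rank(y)
  vapply(seq_len(ncol(X)), function(j) {
    Z <- cbind(1, R[, -j, drop = FALSE])
    bx <- solve(t(Z) %*% Z, t(Z) %*% R[, j])
    by <- solve(t(Z) %*% Z, t(Z) %*% ry)
    ex <- R[, j] - Z %*% bx
    ey <- ry - Z %*% by
    sum(ex * ey) / sqrt(sum(ex^2) * sum(ey^2))
  }, numeric(1))
}

test_that("uniform sampling respects ranges and reproduces under a seed", {
  spec <- sensitivity_spec(c("a", "b"), base = list(a = 2, b = 10),
                           n = 1000, seed = 99)
  X <- sample_parameters(spec)
  expect_true(all(X[, "a"] >= 0.02 & X[, "a"] <= 100))
  expect_true(all(X[, "b"] >= 0.1 & X[, "b"] <= 500))
  expect_identical(X, sample_parameters(spec))
  # Kolmogorov-Smirnov uniformity of the marginals
  for (j in 1:2) {
    b <- c(2, 10)[j]
    u <- (X[, j] - 0.01 * b) / (50 * b - 0.01 * b)
    expect_gt(suppressWarnings(stats::ks.test(u, "punif")$p.value), 0.01)
  }
})

test_that("PRCC finds perfect positive and negative drivers", {
  set.seed(4)
  X <- cbind(x1 = stats::runif(60), x2 = stats::runif(60), x3 = stats::runif(60))
  r1 <- prcc(X, X[, "x1"])
  expect_gt(r1$prcc[r1$parameter == "x1"], 0.999)
  expect_lt(max(abs(r1$prcc[r1$parameter != "x1"])), 0.5)
  r2 <- prcc(X, -X[, "x1"]^3) # monotone decreasing transform
  expect_lt(r2$prcc[r2$parameter == "x1"], -0.999)
})

test_that("PRCC equals the explicit rank-regression oracle at n = 50", {
  set.seed(8)
  X <- matrix(stats::runif(50 * 4), 50, 4,
              dimnames = list(NULL, paste0("p", 1:4)))
  y <- 2 * X[, 1] - 3 * X[, 3] + stats::rnorm(50, 0, 0.3)
  got <- prcc(X, y)
  expect_equal(got$prcc, prcc_oracle(X, y), tolerance = 1e-10)
  expect_true(all(abs(got$prcc) <= 1))
})

test_that("PRCC is invariant under monotone transforms of inputs/outputs", {
  set.seed(12)
  X <- matrix(stats::runif(80 * 3), 80, 3,
              dimnames = list(NULL, paste0("p", 1:3)))
  y <- X[, 1] - 0.5 * X[, 2] + stats::rnorm(80, 0, 0.2)
  base <- prcc(X, y)$prcc
  Xt <- X; Xt[, 1] <- exp(X[, 1]); Xt[, 2] <- X[, 2]^3
  expect_equal(prcc(Xt, y + 100)$prcc, base, tolerance = 1e-10)
  expect_equal(prcc(X, exp(y))$prcc, base, tolerance = 1e-10)
})

test_that("a dummy parameter stays inside its null interval most of the time", {
  inside <- vapply(1:30, function(s) {
    set.seed(s)
    n <- 80
    X <- matrix(stats::runif(n * 3), n, 3,
                dimnames = list(NULL, c("real", "dummy1", "dummy2")))
    y <- X[, "real"] + stats::rnorm(n, 0, 0.2)
    r <- prcc(X, y)
    # null 95% band for a correlation on n - k - 1 dof
    crit <- stats::qt(0.975, n - 4) / sqrt(n - 4 + stats::qt(0.975, n - 4)^2)
    abs(r$prcc[r$parameter == "dummy1"]) < crit
  }, logical(1))
  expect_gte(mean(inside), 0.9)
})

test_that("constant outputs are flagged, not silently zeroed", {
  X <- matrix(stats::runif(30 * 2), 30, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(prcc(X, rep(1, 30)), "constant output")
})

test_that("rank report ordering is invariant to parameter order", {
  set.seed(21)
  X <- matrix(stats::runif(60 * 3), 60, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  y <- 3 * X[, "c"] - X[, "a"] + stats::rnorm(60, 0, 0.1)
  r1 <- rank_report(prcc(X, y))
  r2 <- rank_report(prcc(X[, c("c", "a", "b")], y))
  expect_identical(r1$parameter, r2$parameter)
  expect_equal(r1$prcc, r2$prcc, tolerance = 1e-10)
})
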