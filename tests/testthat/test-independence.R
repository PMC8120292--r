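test_that("partial correlation matches the closed form and the recursive
           oracle", {
  ## identity matrix: everything is zero
  R <- diag(4); dimnames(R) <- list(letters[1:4], letters[1:4])
  expect_equal(partialCorrelation(R, 1, 2, 3), 0)
  ## |S| = 1 closed form
  R <- matrix(c(1, 0.8, 0.5, 0.8, 1, 0.5, 0.5, 0.5, 1), 3, 3)
  expected <- (0.8 - 0.5 * 0.5) / sqrt((1 - 0.25) * (1 - 0.25))
  expect_equal(partialCorrelation(R, 1, 2, 3), expected, tolerance = 1e-12)
  ## inversion route equals recursive elimination for |S| <= 3
  set.seed(7)
  for (rep in 1:20) {
    R <- randomCorr(6)
    for (sz in 0:3) {
      S <- if (sz) 2 + seq_len(sz) else integer()
      expect_equal(partialCorrelation(R, 1, 2, S),
                   pcorRecursive(R, 1, 2, S), tolerance = 1e-10)
    }
  }
  expect_error(partialCorrelation(diag(3), 1, 2, c(1)), "exclude")
  ## singular submatrix flagged as collinearity
  Rs <- matrix(1, 3, 3)
  expect_error(partialCorrelation(Rs, 1, 2, 3), "singular|collinearity")
})

test_that("Fisher-z p-values follow the normal-CDF formula", {
  R <- diag(2)
  expect_equal(fisherZTest(R, 100, 1, 2)$p, 1)
  R[1, 2] <- R[2, 1] <- 0.5
  expected <- 2 * pnorm(sqrt(97) * atanh(0.5), lower.tail = FALSE)
  expect_equal(fisherZTest(R, 100, 1, 2)$p, expected, tolerance = 1e-12)
  ## p strictly decreases with n at fixed correlation
  ps <- vapply(c(10, 50, 100, 500), function(n) fisherZTest(R, n, 1, 2)$p, 1)
  expect_true(all(diff(ps) < 0))
  ## degenerate perfect correlation
  R[1, 2] <- R[2, 1] <- 1
  expect_warning(res <- fisherZTest(R, 100, 1, 2), "degenerate")
  expect_equal(res$p, 0)
  expect_error(fisherZTest(diag(3), 4, 1, 2, 3), "sample size")
})

test_that("Fisher-z test holds its type-I error on independent pairs", {
  set.seed(11)
  n <- 200; B <- 400
  rej <- vapply(seq_len(B), function(b) {
    d <- matrix(rnorm(n * 2), n, 2)
    fisherZTest(cor(d), n, 1, 2)$p <= 0.05
  }, logical(1))
  ## binomial 99% band around 0.05 with B = 400
  expect_gt(mean(rej), 0.05 - 2.58 * sqrt(0.05 * 0.95 / B))
  expect_lt(mean(rej), 0.05 + 2.58 * sqrt(0.05 * 0.95 / B))
})

test_that("G-squared statistic agrees with the log-linear oracle", {
  ## perfectly proportional table: statistic 0, p = 1
  d <- cbind(rep(0:1, each = 20), rep(0:1, times = 20))
  res <- gSquareTest(d, 1, 2)
  expect_equal(res$estimate, 0, tolerance = 1e-12)
  expect_equal(res$p, 1)
  ## random 2x2x2 tables vs the loglin likelihood-ratio route
  set.seed(5)
  for (rep in 1:10) {
    d <- cbind(rbinom(300, 1, 0.5), rbinom(300, 1, 0.4), rbinom(300, 1, 0.6))
    res <- gSquareTest(d, 1, 2, 3)
    tab <- table(d[, 1], d[, 2], d[, 3])
    ll <- suppressWarnings(
      stats::loglin(tab, margin = list(c(1, 3), c(2, 3)), print = FALSE))
    expect_equal(res$estimate, ll$lrt, tolerance = 1e-8)
    expect_equal(res$df, ll$df)
    expect_equal(res$p, pchisq(ll$lrt, ll$df, lower.tail = FALSE),
                 tolerance = 1e-8)
  }
  ## constant variable: df <= 0 path
  d <- cbind(rep(1, 50), rbinom(50, 1, 0.5))
  expect_warning(res <- gSquareTest(d, 1, 2), "degrees of freedom")
  expect_equal(res$p, 1)
})
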