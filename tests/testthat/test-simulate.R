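test_that("genotype draws follow Hardy-Weinberg proportions", {
  set.seed(71)
  expect_true(all(simulateGenotype(100, 0) == 0))
  expect_true(all(simulateGenotype(100, 1) == 2))
  v <- simulateGenotype(1e5, 0.45)
  freq <- tabulate(v + 1, 3) / 1e5
  expect_lt(max(abs(freq - c(0.3025, 0.495, 0.2025))), 0.01)
})

test_that("simulation is reproducible and matches first and second
           moments", {
  g <- basicModelGraph("M1")
  d1 <- simData(g, gamma = 1, n = 500, seed = 72)
  d2 <- simData(g, gamma = 1, n = 500, seed = 72)
  expect_identical(d1, d2)

  ## parentless phenotype moments: mean m, sd sigma within 4/sqrt(n)
  lone <- causalGraph(matrix(0L, 1, 1, dimnames = list("T1", "T1")))
  n <- 4000
  d <- simulateDagData(simulationSpec(lone, mean = 2, sigma = 1.5, n = n,
                                      seed = 73))
  expect_lt(abs(mean(d) - 2), 4 * 1.5 / sqrt(n))
  expect_lt(abs(sd(d) - 1.5), 4 / sqrt(n))
})

test_that("chain correlations match the covariance-algebra oracle", {
  ## for V1 -> T1 -> T2 with unit coefficients and noise:
  ##   var(V1) = 2q(1-q), var(T1) = var(V1) + 1, var(T2) = var(T1) + 1,
  ##   cov(V1, T2) = var(V1)  =>  cor closed form below
  q <- 0.45
  vV <- 2 * q * (1 - q)
  corExp <- vV / sqrt(vV * (vV + 2))
  g <- basicModelGraph("M1")
  set.seed(74)
  cors <- replicate(20, {
    d <- simData(g, gamma = 1, n = 2000)
    cor(d[, "V1"], d[, "T2"])
  })
  expect_lt(abs(mean(cors) - corExp), 0.02)
})

test_that("undirected phenotype edges behave as a per-sample mixture", {
  ## M4: T1 - T2 dependence survives conditioning on the shared parent
  g4 <- basicModelGraph("M4")
  d <- simData(g4, gamma = 1, n = 4000, seed = 75)
  pc <- partialCorrelation(cor(d), "T1", "T2", "V1")
  expect_gt(pc, 0.2)
  ## cyclic directed truth is rejected
  A <- matrix(0L, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  A["a", "b"] <- 1L
  g <- causalGraph(A)
  gBad <- g; gBad@adj["b", "a"] <- 1L; gBad@adj["a", "b"] <- 1L
  ## (a symmetric pair is an undirected edge, not a cycle: must simulate)
  expect_silent(simulateDagData(simulationSpec(gBad, n = 10, seed = 1)))
})

test_that("empty graphs give uncorrelated columns", {
  p <- 4
  A <- matrix(0L, p, p, dimnames = list(letters[1:p], letters[1:p]))
  d <- simulateDagData(simulationSpec(causalGraph(A), n = 1000, seed = 76))
  cm <- cor(d)
  expect_lt(max(abs(cm[upper.tri(cm)])), 3 / sqrt(1000) * 1.5)
})

test_that("outlier injection flags exactly k rows and perturbs only
           phenotypes", {
  g <- exampleOutlierGraph()
  d <- simData(g, gamma = 1, n = 1000, seed = 77)
  same <- injectOutliers(d, 0)
  expect_identical(same$data, d)
  set.seed(78)
  out <- injectOutliers(d, 10, magnitude = 10, kinds = kindsOf(g))
  expect_length(out$outliers, 10)
  expect_identical(out$data[, c("V1", "V2")], d[, c("V1", "V2")])
  changed <- which(rowSums(out$data != d) > 0)
  expect_identical(changed, out$outliers)
  expect_error(injectOutliers(d, 2000), "exceed")
})

test_that("quantile discretization balances categories and flags constant
           columns", {
  set.seed(79)
  x <- cbind(a = rnorm(1001), b = rnorm(1001))
  d2 <- discretizeData(x, 2)
  expect_identical(sort(unique(as.vector(d2))), c(0L, 1L))
  ## median split: counts differ by at most 1
  expect_lte(abs(diff(table(d2[, 1]))), 1)
  d5 <- discretizeData(x, 5)
  expect_lte(max(table(d5[, 1])) - min(table(d5[, 1])), 1)
  expect_warning(discretizeData(cbind(a = rep(1, 10)), 2), "constant")
  expect_error(discretizeData(x, 1), "levels")
})

test_that("discretized chain data recover the chain skeleton via the
           G-squared route", {
  g <- basicModelGraph("M1")
  spec <- simulationSpec(g, gamma = 1, n = 2000, seed = 80,
                         discretizeLevels = 3)
  d <- simulateDagData(spec)
  fit <- inferCausalGraph(d, kinds = kindsOf(g), dataKind = "discrete")
  sk <- fit@skeleton
  expect_true(sk["T1", "T2"] && sk["T1", "V1"])
  expect_false(sk["T2", "V1"])
})
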