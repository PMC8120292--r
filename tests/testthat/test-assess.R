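test_that("weighted recall/precision and aSHD handle the canonical cases", {
  g <- basicModelGraph("M1")
  expect_equal(unname(recallPrecision(g, g)), c(1, 1))
  expect_equal(ashd(g, g), 0)

  ## all-undirected chain: every edge half credit
  A <- adjacencyMatrix(g)
  und <- causalGraph((A + t(A) > 0) * 1L, kinds = nodeKinds(g))
  expect_equal(unname(recallPrecision(g, und)), c(0.5, 0.5))
  expect_equal(ashd(g, und), 1.0)

  ## empty inferred graph: recall 0, precision 0 by convention
  empty <- causalGraph(A * 0L, kinds = nodeKinds(g))
  expect_equal(unname(recallPrecision(g, empty)), c(0, 0))

  ## single reversed edge costs 0.5 in aSHD
  rev <- g
  rev@adj["V1", "T1"] <- 0L; rev@adj["T1", "V1"] <- 1L
  expect_equal(ashd(g, rev), 0.5)

  ## one extra plus one missing edge: distance 2
  mod <- g
  mod@adj["T1", "T2"] <- 0L           # remove T1->T2
  mod@adj["V1", "T2"] <- 1L           # add V1->T2
  expect_equal(ashd(g, mod), 2.0)

  expect_error(recallPrecision(g, exampleChainGraph()), "label")
})

test_that("metrics match the brute-force pair-by-pair oracle on random
           graph pairs", {
  set.seed(91)
  for (rep in 1:20) {
    a <- randomMixedGraph(6)
    b <- randomMixedGraph(6)
    bf <- bruteMetrics(a, b)
    rp <- recallPrecision(a, b)
    expect_equal(unname(rp["recall"]), bf$recall)
    expect_equal(unname(rp["precision"]), bf$precision)
    expect_equal(ashd(a, b), bf$ashd)
    ## ashd is symmetric and triangle-bounded on the state metric
    cg <- randomMixedGraph(6)
    expect_equal(ashd(a, b), ashd(b, a))
    expect_lte(ashd(a, cg), ashd(a, b) + ashd(b, cg) + 1e-12)
  }
})

test_that("variant-variant direction can be ignored when comparing against
           methods that orient those edges", {
  labs <- c("V1", "V2")
  kinds <- c("genotype", "genotype")
  A <- matrix(0L, 2, 2, dimnames = list(labs, labs))
  truth <- causalGraph({ a <- A; a["V1", "V2"] <- a["V2", "V1"] <- 1L; a },
                       kinds = kinds)
  directed <- causalGraph({ a <- A; a["V1", "V2"] <- 1L; a }, kinds = kinds)
  expect_equal(unname(recallPrecision(truth, directed)), c(0.5, 0.5))
  expect_equal(unname(recallPrecision(truth, directed,
                                      ignoreVVDirection = TRUE)), c(1, 1))
})

test_that("stability counting distinguishes order-independent inference", {
  ## single variable: trivially one graph
  d1 <- matrix(rnorm(50), 50, 1, dimnames = list(NULL, "A"))
  expect_identical(stabilityCount(d1, nPerm = 3, seed = 1), 1L)
  g <- exampleColliderChainGraph()
  d <- simData(g, gamma = 1, n = 800, seed = 92)
  expect_identical(
    stabilityCount(d, kinds = kindsOf(g), nPerm = 8, seed = 93), 1L)
})

test_that("module clustering follows graph distances and the minimum size
           rule", {
  g <- basicModelGraph("M1")
  cm <- clusterModules(g, minSize = 1)
  D <- cm$distances
  expect_equal(unname(D["V1", "T1"]), 1)
  expect_equal(unname(D["T1", "T2"]), 1)
  expect_equal(unname(D["V1", "T2"]), 2)
  ## minSize above the node count: everything unassigned
  cm0 <- clusterModules(g, minSize = 10)
  expect_identical(unname(cm0$modules), rep(0L, 3))
  expect_identical(cm0$nModules, 0L)
  ## four well-separated groups in the synthetic complex graph
  cm4 <- clusterModules(exampleComplexGraph(), minSize = 5)
  expect_identical(cm4$nModules, 4L)
  expect_true(all(table(cm4$modules[cm4$modules > 0]) >= 5))
})
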