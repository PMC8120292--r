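mkSkeleton <- function(labels, edges) {
  p <- length(labels)
  A <- matrix(FALSE, p, p, dimnames = list(labels, labels))
  for (e in edges) A[e[1], e[2]] <- A[e[2], e[1]] <- TRUE
  A
}

test_that("PMR orientation directs variant edges toward phenotypes only", {
  sk <- mkSkeleton(c("V1", "V2", "T1"),
                   list(c("V1", "T1"), c("V1", "V2")))
  g <- orientPMR(sk, kinds = c("genotype", "genotype", "phenotype"))
  A <- adjacencyMatrix(g)
  expect_identical(unname(A["V1", "T1"]), 1L)
  expect_identical(unname(A["T1", "V1"]), 0L)
  ## variant-variant edge stays symmetric
  expect_identical(unname(A["V1", "V2"] + A["V2", "V1"]), 2L)
  ## no genotypes: untouched
  g2 <- orientPMR(sk, kinds = rep("phenotype", 3))
  expect_identical(adjacencyMatrix(g2), (sk | t(sk)) * 1L)
})

test_that("v-structures are identified only via the conditional test,
           including on demand", {
  g2 <- basicModelGraph("M2")
  d <- simData(g2, gamma = 1, n = 1000, seed = 51)
  fit <- inferCausalGraph(d, kinds = kindsOf(g2))
  A <- adjacencyMatrix(fit)
  expect_identical(unname(A["T2", "T1"]), 1L)
  expect_identical(unname(A["T1", "T2"]), 0L)
  ## the decisive test was performed on demand: it conditions on T1 and was
  ## not part of the level-0/1 removal history of the pair (T2, V1)
  led <- ledgerData(testLedger(fit))
  onDemand <- led[led$i == "T2" & led$j == "V1" & led$S == "T1", ]
  expect_identical(nrow(onDemand), 1L)
  expect_true(onDemand$rejected)

  ## chain data: same triplet test does not reject, no collider, and the
  ## undirected tail is oriented as a chain by the iterative step
  g1 <- basicModelGraph("M1")
  d <- simData(g1, gamma = 1, n = 1000, seed = 52)
  fit <- inferCausalGraph(d, kinds = kindsOf(g1))
  A <- adjacencyMatrix(fit)
  expect_identical(unname(A["T1", "T2"]), 1L)
  expect_identical(unname(A["T2", "T1"]), 0L)
})

test_that("the fork with an undirected tail (Markov-ambiguous pair) stays
           undirected", {
  g4 <- basicModelGraph("M4")
  d <- simData(g4, gamma = 1, n = 1000, seed = 53)
  fit <- inferCausalGraph(d, kinds = kindsOf(g4))
  A <- adjacencyMatrix(fit)
  expect_identical(unname(A["T1", "T2"] + A["T2", "T1"]), 2L)
  expect_identical(unname(A["V1", "T1"]), 1L)
  expect_identical(unname(A["V1", "T2"]), 1L)
})

test_that("orientation is idempotent, preserves the edge set, and never
           points an edge at a genotype", {
  graphs <- list(basicModelGraph("M1"), basicModelGraph("M4"),
                 exampleComplexGraph())
  for (gi in seq_along(graphs)) {
    g <- graphs[[gi]]
    d <- simData(g, gamma = 1, n = 800, seed = 54 + gi)
    fit <- inferCausalGraph(d, kinds = kindsOf(g))
    A <- adjacencyMatrix(fit)
    ## same unordered adjacencies as the skeleton
    expect_identical((A + t(A) > 0), unname(fit@skeleton) | t(fit@skeleton),
                     ignore_attr = TRUE)
    ## PMR constraint in the output
    kinds <- nodeKinds(fit)
    for (a in names(kinds)) for (b in names(kinds)) {
      if (kinds[a] == "phenotype" && kinds[b] == "genotype")
        expect_false(A[a, b] == 1 && A[b, a] == 0)
    }
    ## running the iterative step again changes nothing
    g2 <- orientRemaining(fittedGraph(fit), fit@skeleton, testLedger(fit))
    expect_identical(adjacencyMatrix(g2), A)
  }
})

test_that("classic mode claims v-structures from sepset absence and applies
           Meek rules", {
  ## M1 strong signal: sepset(T2, V1) = {T1} -> no collider, all-undirected
  g1 <- basicModelGraph("M1")
  d <- simData(g1, gamma = 1, n = 1000, seed = 61)
  fit <- inferCausalGraph(d, kinds = kindsOf(g1), mode = "classic")
  A <- adjacencyMatrix(fit)
  expect_identical(unname(A["T1", "T2"] + A["T2", "T1"]), 2L)
  expect_identical(unname(A["T1", "V1"] + A["V1", "T1"]), 2L)
  rp <- recallPrecision(g1, fittedGraph(fit))
  expect_equal(unname(rp), c(0.5, 0.5))

  ## M2: empty sepset -> collider correctly claimed
  g2 <- basicModelGraph("M2")
  d <- simData(g2, gamma = 1, n = 1000, seed = 62)
  fit <- inferCausalGraph(d, kinds = kindsOf(g2), mode = "classic")
  A <- adjacencyMatrix(fit)
  expect_identical(unname(A["V1", "T1"]), 1L)
  expect_identical(unname(A["T1", "V1"]), 0L)
  expect_identical(unname(A["T2", "T1"]), 1L)
  expect_identical(unname(A["T1", "T2"]), 0L)

  ## Meek R1 on a constructed skeleton: claimed collider a->b<-c plus b-d
  ## propagates to b->d
  sk <- mkSkeleton(c("a", "b", "c", "d"),
                   list(c("a", "b"), c("c", "b"), c("b", "d")))
  sep <- list("a|c" = character(),  # Y=b absent -> collider claimed
              "a|d" = "b", "c|d" = "b")
  g <- orientClassicCpdag(sk, sep)
  A <- adjacencyMatrix(g)
  expect_identical(unname(A["b", "d"]), 1L)
  expect_identical(unname(A["d", "b"]), 0L)
})

test_that("end-to-end inference is invariant to input column order and
           empty on independent data", {
  g <- exampleComplexGraph()
  d <- simData(g, gamma = 1, n = 600, seed = 63)
  ref <- canonicalForm(fittedGraph(inferCausalGraph(d, kinds = kindsOf(g))))
  set.seed(64)
  for (rep in 1:3) {
    perm <- sample(ncol(d))
    fit <- inferCausalGraph(d[, perm], kinds = kindsOf(g))
    expect_identical(canonicalForm(fittedGraph(fit)), ref)
  }
  d2 <- matrix(rnorm(2000), 1000, 2, dimnames = list(NULL, c("A", "B")))
  fit <- inferCausalGraph(d2)
  expect_identical(sum(adjacencyMatrix(fit)), 0L)
})
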