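test_that("canonical form is invariant to node storage order", {
  g <- basicModelGraph("M1")
  for (seedling in 1:5) {
    set.seed(seedling)
    perm <- sample(3)
    A <- adjacencyMatrix(g)[perm, perm]
    gp <- causalGraph(A, kinds = nodeKinds(g)[rownames(A)])
    expect_identical(canonicalForm(gp), canonicalForm(g))
  }
  ## single node
  g1 <- causalGraph(matrix(0, 1, 1, dimnames = list("A", "A")))
  expect_type(canonicalForm(g1), "character")
})

test_that("canonical form separates all edge states and is injective on
           3-node mixed graphs", {
  labs <- c("T1", "V1")
  mk <- function(a, b) {
    A <- matrix(c(0L, b, a, 0L), 2, 2, byrow = TRUE,
                dimnames = list(labs, labs))
    causalGraph(A, kinds = c("phenotype", "genotype"))
  }
  keys2 <- vapply(list(mk(1, 0), mk(0, 1), mk(1, 1)), canonicalForm, "")
  expect_length(unique(keys2), 3)

  ## exhaustive: all 4^3 = 64 labeled mixed graphs on 3 nodes are distinct
  states <- expand.grid(e12 = 0:3, e13 = 0:3, e23 = 0:3)
  keys <- apply(states, 1, function(s) {
    A <- matrix(0L, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
    put <- function(i, j, st) {
      if (st == 1) A[i, j] <<- 1L
      if (st == 2) A[j, i] <<- 1L
      if (st == 3) A[i, j] <<- A[j, i] <<- 1L
    }
    put(1, 2, s[1]); put(1, 3, s[2]); put(2, 3, s[3])
    canonicalForm(causalGraph(A))
  })
  expect_length(unique(keys), 64)
})

test_that("graph construction rejects invalid objects", {
  A <- matrix(0, 2, 2, dimnames = list(c("a", "a"), c("a", "a")))
  expect_error(causalGraph(A), "unique")
  B <- matrix(c(0, 2, 0, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(causalGraph(B), "0 or 1")
  D <- diag(2); dimnames(D) <- list(c("a", "b"), c("a", "b"))
  expect_error(causalGraph(D), "diagonal")
})

test_that("adjacency TSV round trip reproduces the graph exactly", {
  set.seed(42)
  for (rep in 1:5) {
    g <- randomMixedGraph(5)
    f <- tempfile(fileext = ".tsv")
    writeGraph(g, f)
    g2 <- readGraph(f)
    expect_identical(adjacencyMatrix(g2), adjacencyMatrix(g))
    expect_identical(nodeKinds(g2), nodeKinds(g))
    unlink(f)
  }
})

test_that("DOT export encodes orientation and node kinds", {
  g <- exampleOutlierGraph()
  f <- tempfile(fileext = ".dot")
  writeGraph(g, f, format = "dot")
  txt <- readLines(f)
  expect_true(any(grepl('"V1" \\[shape=triangle', txt)))
  expect_true(any(grepl('"T1" \\[shape=circle', txt)))
  expect_true(any(grepl('"V1" -> "T1";', txt)))
  ## undirected variant-variant edge renders once with dir=none
  A <- adjacencyMatrix(g)
  A["V1", "V2"] <- A["V2", "V1"] <- 1L
  writeGraph(causalGraph(A, kinds = nodeKinds(g)), f, format = "dot")
  txt <- readLines(f)
  expect_identical(sum(grepl("dir=none", txt)), 1L)
  ## empty graph: nodes only
  E <- matrix(0L, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  writeGraph(causalGraph(E), f, format = "dot")
  txt <- readLines(f)
  expect_false(any(grepl("->", txt[!grepl("shape", txt)])))
  unlink(f)
})

test_that("data matrix reader assigns kinds positionally and catches bad
           input", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("V1\tT1\tT2", "0\t1.5\t-0.3", "2\t0.1\t0.8"), f)
  inp <- readDataMatrix(f, nGenotypes = 1)
  expect_identical(inp$kinds, c("genotype", "phenotype", "phenotype"))
  expect_identical(dim(inp$data), c(2L, 3L))
  expect_identical(readDataMatrix(f, nGenotypes = 0)$kinds,
                   rep("phenotype", 3))
  expect_error(readDataMatrix(f, nGenotypes = 5), "exceeds")
  writeLines(c("V1\tT1", "0\tabc"), f)
  expect_error(readDataMatrix(f, 1), "non-numeric")
  writeLines("V1\tT1", f)
  expect_error(readDataMatrix(f, 1), "no data rows")
  unlink(f)
})
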