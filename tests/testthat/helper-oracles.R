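## Independent oracles and fixture builders used across the test files.
## These deliberately re-derive quantities by a different route than the
## package implementation.

## random correlation matrix (positive definite, unit diagonal)
randomCorr <- function(p) {
  A <- matrix(rnorm(p * (p + 2)), p + 2, p)
  cov2cor(crossprod(A) / (p + 2) + diag(1e-3, p))
}

## textbook recursive elimination for partial correlation
pcorRecursive <- function(R, i, j, S) {
  if (length(S) == 0) return(R[i, j])
  k <- S[1]
  rest <- S[-1]
  rij <- pcorRecursive(R, i, j, rest)
  rik <- pcorRecursive(R, i, k, rest)
  rjk <- pcorRecursive(R, j, k, rest)
  (rij - rik * rjk) / sqrt((1 - rik^2) * (1 - rjk^2))
}

## random labeled mixed graph with given edge-state probabilities
randomMixedGraph <- function(p, labels = sprintf("N%02d", seq_len(p)),
                             probs = c(none = 0.4, fwd = 0.2, bwd = 0.2,
                                       undir = 0.2)) {
  A <- matrix(0L, p, p, dimnames = list(labels, labels))
  for (i in seq_len(p - 1)) for (j in seq(i + 1, p)) {
    st <- sample(0:3, 1, prob = probs)
    if (st == 1) A[i, j] <- 1L
    if (st == 2) A[j, i] <- 1L
    if (st == 3) A[i, j] <- A[j, i] <- 1L
  }
  causalGraph(A, kinds = "phenotype", labels = labels)
}

## brute-force pair-by-pair recomputation of the weighted metrics
bruteMetrics <- function(truth, inferred, weight = 0.5) {
  labs <- sort(nodeLabels(truth))
  At <- adjacencyMatrix(truth)[labs, labs]
  Ai <- adjacencyMatrix(inferred)[labs, labs]
  state <- function(A, a, b) {
    if (A[a, b] == 1 && A[b, a] == 1) "undir"
    else if (A[a, b] == 1) paste0(a, ">", b)
    else if (A[b, a] == 1) paste0(b, ">", a)
    else "none"
  }
  credit <- 0; nTrue <- 0; nInf <- 0; dist <- 0
  for (a in labs) for (b in labs) {
    if (a >= b) next
    st <- state(At, a, b); si <- state(Ai, a, b)
    if (st != "none") nTrue <- nTrue + 1
    if (si != "none") nInf <- nInf + 1
    if (st != "none" && si != "none")
      credit <- credit + if (st == si) 1 else weight
    if ((st == "none") != (si == "none")) dist <- dist + 1
    else if (st != "none" && st != si) dist <- dist + 0.5
  }
  list(recall = if (nTrue) credit / nTrue else 0,
       precision = if (nInf) credit / nInf else 0,
       ashd = dist)
}

## straightforward re-implementation of the level-wise stable skeleton with
## the same sequential thresholds, used to cross-check learnSkeleton
bruteSkeleton <- function(R, n, alpha = 0.05) {
  labs <- sort(colnames(R))
  R <- R[labs, labs]
  p <- length(labs)
  adj <- matrix(TRUE, p, p, dimnames = list(labs, labs))
  diag(adj) <- FALSE
  st <- londState(alpha)
  for (ell in 0:(p - 2)) {
    frozen <- adj
    tested <- FALSE
    for (i in seq_len(p - 1)) for (j in seq(i + 1, p)) {
      if (!frozen[i, j]) next
      nbrs <- setdiff(which(frozen[i, ]), j)
      if (length(nbrs) < ell) next
      tested <- TRUE
      if (!adj[i, j]) next
      Ss <- if (ell == 0) list(integer()) else
        unlist(lapply(list(nbrs), function(v)
          if (length(v) == ell) list(v) else combn(v, ell, simplify = FALSE)),
          recursive = FALSE)
      for (S in Ss) {
        nt <- nextThreshold(st); st <- nt$state
        pval <- fisherZTest(R, n, i, j, S)$p
        rr <- recordResult(st, pval, nt$threshold); st <- rr$state
        if (!rr$rejected) { adj[i, j] <- adj[j, i] <- FALSE; break }
      }
    }
    if (!tested && ell > 0) break
  }
  adj
}

kindsOf <- function(g) nodeKinds(g)

simData <- function(g, gamma, n = 1000, seed = NULL, ...) {
  simulateDagData(simulationSpec(g, gamma = gamma, n = n, seed = seed, ...))
}
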