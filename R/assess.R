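## orientation-state matrix over canonically ordered labels:
## 0 none, 1 lower->higher (by label), 2 higher->lower, 3 undirected
.stateMatrix <- function(g, labs) {
  idx <- match(labs, g@labels)
  A <- g@adj[idx, idx, drop = FALSE]
  p <- length(labs)
  st <- matrix(0L, p, p)
  if (p >= 2) for (i in seq_len(p - 1)) for (j in seq(i + 1L, p))
    st[i, j] <- .edgeState(A, i, j)
  st
}

.alignPair <- function(truth, inferred) {
  if (!setequal(truth@labels, inferred@labels))
    stop("graphs must share the same node label set")
  labs <- sort(truth@labels)
  list(labs = labs,
       st = .stateMatrix(truth, labs),
       si = .stateMatrix(inferred, labs),
       kinds = truth@kinds[match(labs, truth@labels)])
}

#' Direction-weighted recall and precision of an inferred graph
#'
#' Edges are compared as unordered adjacencies with an orientation state.
#' A true edge recovered with matching state (same direction, or undirected
#' in both graphs) earns credit 1; recovered with the wrong or missing
#' direction earns \code{weight} (default 0.5); absent earns 0. Recall is
#' the summed credit over the number of true edges (power), precision the
#' summed credit over the number of inferred edges (one minus the false
#' discovery proportion); an empty inferred graph has precision 0 by
#' convention.
#'
#' @param truth,inferred [CausalGraph-class] objects over the same labels.
#' @param weight credit for a recovered edge with mismatched orientation.
#' @param ignoreVVDirection compare variant-variant edges as undirected in
#'   both graphs (useful against methods that orient them arbitrarily).
#' @return named numeric vector \code{c(recall =, precision =)}.
#' @export
recallPrecision <- function(truth, inferred, weight = 0.5,
                            ignoreVVDirection = FALSE) {
  al <- .alignPair(truth, inferred)
  st <- al$st; si <- al$si
  if (ignoreVVDirection) {
    vv <- outer(al$kinds == "genotype", al$kinds == "genotype", "&")
    st[vv & st != 0L] <- 3L
    si[vv & si != 0L] <- 3L
  }
  credit <- ifelse(st != 0L & si != 0L, ifelse(st == si, 1, weight), 0)
  nTrue <- sum(st != 0L)
  nInf <- sum(si != 0L)
  c(recall = if (nTrue) sum(credit) / nTrue else 0,
    precision = if (nInf) sum(credit) / nInf else 0)
}

#' Adjusted structural Hamming distance
#'
#' Sum over unordered node pairs of: 1.0 when an edge is present in one
#' graph and absent in the other, 0.5 when both graphs have the edge but
#' with differing orientation state, 0 otherwise. Identical graphs are at
#' distance 0.
#'
#' @param truth,inferred [CausalGraph-class] objects over the same labels.
#' @return nonnegative numeric distance.
#' @export
ashd <- function(truth, inferred) {
  al <- .alignPair(truth, inferred)
  st <- al$st; si <- al$si
  sum(ifelse((st != 0L) != (si != 0L), 1,
             ifelse(st != 0L & st != si, 0.5, 0)))
}

#' Count uniquely inferred graphs under node permutation
#'
#' Runs inference on column-permuted copies of the same data and counts
#' distinct canonical graph keys. An order-independent learner returns 1
#' for any data set; order-sensitive learners can return many.
#'
#' @param data samples-by-variables matrix with column names.
#' @param kinds per-column kinds, named by column (or NULL for all
#'   phenotype).
#' @param nPerm number of random column permutations (>= 1).
#' @param mode,alpha,... passed to [inferCausalGraph()].
#' @param seed optional RNG seed for the permutations.
#' @return integer: the number of distinct inferred graphs.
#' @export
stabilityCount <- function(data, kinds = NULL, nPerm = 20,
                           mode = "mrpc", alpha = 0.05, seed = NULL, ...) {
  if (nPerm < 1) stop("nPerm must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  if (ncol(data) < 2) return(1L)
  keys <- character(nPerm)
  if (!is.null(kinds) && is.null(names(kinds)))
    names(kinds) <- colnames(data)
  for (r in seq_len(nPerm)) {
    perm <- sample.int(ncol(data))
    d <- data[, perm, drop = FALSE]
    fit <- inferCausalGraph(d, kinds = kinds, mode = mode, alpha = alpha, ...)
    keys[r] <- canonicalForm(fittedGraph(fit))
  }
  length(unique(keys))
}

#' Cluster graph nodes into modules from the node-distance dendrogram
#'
#' Pairwise node distance is the shortest-path edge count ignoring edge
#' orientation, with disconnected pairs set to the number of nodes (a
#' finite sentinel exceeding any realizable path length). Nodes are
#' clustered agglomeratively (average linkage by default) and the
#' dendrogram is cut at the number of clusters that maximizes how many
#' clusters reach \code{minSize} nodes (smallest such cut on ties);
#' qualifying clusters are reported as modules 1, 2, ... and all remaining
#' nodes are left unassigned in module 0.
#'
#' @param g a [CausalGraph-class].
#' @param minSize minimum number of nodes for a reported module (>= 1).
#' @param linkage agglomeration method passed to [stats::hclust()].
#' @return list with \code{modules} (named integer vector, 0 =
#'   unassigned), \code{nModules}, the \code{hclust} tree, and the
#'   \code{distances} matrix.
#' @export
clusterModules <- function(g, minSize, linkage = "average") {
  if (minSize < 1) stop("minSize must be >= 1")
  labs <- g@labels
  p <- length(labs)
  U <- (g@adj | t(g@adj))
  D <- matrix(p, p, p, dimnames = list(labs, labs))
  diag(D) <- 0
  for (s in seq_len(p)) {  # BFS from each node
    dist <- rep(NA_integer_, p)
    dist[s] <- 0L
    frontier <- s
    while (length(frontier)) {
      nxt <- integer()
      for (v in frontier) {
        nb <- which(U[v, ] & is.na(dist))
        dist[nb] <- dist[v] + 1L
        nxt <- c(nxt, nb)
      }
      frontier <- nxt
    }
    known <- !is.na(dist)
    D[s, known] <- dist[known]
  }
  if (p == 1) {
    modules <- setNames(if (minSize <= 1) 1L else 0L, labs)
    return(list(modules = modules, nModules = max(modules),
                hclust = NULL, distances = D))
  }
  hc <- hclust(as.dist(D), method = linkage)
  best <- c(k = 1L, count = 0L)
  for (k in seq_len(p)) {
    cl <- cutree(hc, k = k)
    cnt <- sum(table(cl) >= minSize)
    if (cnt > best["count"]) best <- c(k = k, count = cnt)
  }
  cl <- cutree(hc, k = best[["k"]])
  sizes <- table(cl)
  keep <- as.integer(names(sizes)[sizes >= minSize])
  modules <- setNames(rep(0L, p), labs)
  mid <- 0L
  for (kk in keep[order(match(keep, cl))]) {
    mid <- mid + 1L
    modules[cl == kk] <- mid
  }
  list(modules = modules, nModules = mid, hclust = hc, distances = D)
}

#' Accuracy sweep over simulated replicates
#'
#' Simulates independent data sets from a ground-truth graph over a grid of
#' signal strengths, runs inference on each, scores it against the truth
#' with direction-weighted recall/precision, and reports per-cell means and
#' standard deviations -- the layout of the standard benchmark tables for
#' this class of methods. Each replicate gets its own dataset seed derived
#' from the master seed, so cells and replicates are independently
#' reproducible.
#'
#' @param truth ground-truth [CausalGraph-class].
#' @param gammas signal strengths to sweep (default c(1.0, 0.5, 0.2)).
#' @param nReps replicates per cell.
#' @param n sample size per dataset.
#' @param alpha FDR target for inference.
#' @param mode \code{"mrpc"} or \code{"classic"}.
#' @param q allele frequency for genotype nodes.
#' @param seed master seed.
#' @param corMethod correlation estimator passed to [inferCausalGraph()].
#' @param nOutliers outliers injected per dataset (see [injectOutliers()]).
#' @param weight direction-miss weight for scoring.
#' @return data.frame with one row per gamma: recall, recallSD, precision,
#'   precisionSD, nReps.
#' @export
sweepAccuracy <- function(truth, gammas = c(1.0, 0.5, 0.2), nReps = 200,
                          n = 1000, alpha = 0.05, mode = "mrpc", q = 0.45,
                          seed = NULL, corMethod = "pearson",
                          nOutliers = 0, weight = 0.5) {
  if (!is.null(seed)) set.seed(seed)
  seeds <- matrix(sample.int(.Machine$integer.max - 1, length(gammas) * nReps),
                  nrow = nReps)
  kinds <- setNames(truth@kinds, truth@labels)
  out <- data.frame()
  for (gi in seq_along(gammas)) {
    rec <- prec <- numeric(nReps)
    for (r in seq_len(nReps)) {
      spec <- simulationSpec(truth, gamma = gammas[gi], q = q, n = n,
                             seed = seeds[r, gi], nOutliers = nOutliers)
      d <- simulateDagData(spec)
      fit <- inferCausalGraph(d, kinds = kinds, alpha = alpha, mode = mode,
                              corMethod = corMethod)
      rp <- recallPrecision(truth, fittedGraph(fit), weight = weight)
      rec[r] <- rp["recall"]; prec[r] <- rp["precision"]
    }
    out <- rbind(out, data.frame(gamma = gammas[gi],
                                 recall = mean(rec), recallSD = sd(rec),
                                 precision = mean(prec),
                                 precisionSD = sd(prec), nReps = nReps))
  }
  out
}
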