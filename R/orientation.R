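.isUndirected <- function(A, i, j) A[i, j] == 1 && A[j, i] == 1
.isDirected <- function(A, i, j) A[i, j] == 1 && A[j, i] == 0

## is there a directed path from `from` to `to`? (directed edges only)
.directedReachable <- function(A, from, to) {
  p <- nrow(A)
  seen <- logical(p)
  stack <- from
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    if (v == to) return(TRUE)
    if (seen[v]) next
    seen[v] <- TRUE
    nxt <- which(A[v, ] == 1 & A[, v] == 0)
    stack <- c(stack, nxt[!seen[nxt]])
  }
  FALSE
}

#' Orient edges touching genotype nodes by the PMR (Step II, part 1)
#'
#' Under the principle of Mendelian randomization genotypes are randomized
#' at meiosis, so an edge between a genotype and a phenotype can only point
#' to the phenotype, and an edge between two genotypes stays undirected
#' (causality between two variants is not meaningful). Phenotype-phenotype
#' edges are untouched. With no genotype nodes the graph is returned
#' unchanged and orientation effectively starts at the v-structure step.
#'
#' @param skeleton symmetric adjacency (logical or 0/1 matrix with label
#'   dimnames) from [learnSkeleton()], or a [CausalGraph-class].
#' @param kinds per-node kinds in the same order as the skeleton labels
#'   (ignored when a CausalGraph is supplied).
#' @return a partially oriented [CausalGraph-class].
#' @export
orientPMR <- function(skeleton, kinds = NULL) {
  if (is(skeleton, "CausalGraph")) {
    g <- skeleton
  } else {
    A <- skeleton * 1L
    g <- causalGraph(A, kinds = if (is.null(kinds)) "phenotype" else kinds)
  }
  A <- g@adj
  geno <- g@kinds == "genotype"
  for (v in which(geno)) for (t in which(!geno)) {
    if (A[v, t] == 1 && A[t, v] == 1) A[t, v] <- 0L
  }
  g@adj <- A
  g
}

#' Identify v-structures with on-demand conditional testing (Step II, part 2)
#'
#' For every candidate triplet X-Y-Z (X and Z non-adjacent, both adjacent to
#' Y, taken in canonical order) the decision rests on the test of X and Z
#' given exactly Y. If Step I already performed that test it is looked up
#' in the ledger; otherwise -- typically because the marginal test removed
#' X-Z before any conditional test was needed -- it is performed now,
#' consuming the next online-FDR threshold. Only a *rejected* test
#' (conditional dependence) supports the collider X -> Y <- Z; a
#' non-rejected test leaves the edges as they are. This on-demand test is
#' the correction over classic PC, which claims a v-structure from the mere
#' absence of Y in the separation set. Triplets whose edges already point
#' away from Y cannot form the collider and are skipped. If two triplets
#' demand opposite directions for the same edge, the edge is reset to
#' undirected with a warning.
#'
#' @param g partially oriented [CausalGraph-class] from [orientPMR()].
#' @param skeleton,ledger,stat as returned/used by [learnSkeleton()]; the
#'   stat must be in canonical (sorted-label) column order.
#' @param lond the [LondState-class] continuing Step I's stream.
#' @return list with the updated \code{graph}, the updated \code{lond}
#'   state, the \code{ledger} (extended in place), and \code{conflicted},
#'   the pairs reset to undirected by conflicting demands.
#' @export
identifyVStructures <- function(g, skeleton, ledger, stat, lond) {
  A <- g@adj
  labs <- g@labels
  p <- length(labs)
  orientedBy <- new.env(parent = emptyenv())  # "i|j" -> child label
  conflicted <- character()
  orient <- function(from, to) {
    key <- paste0(min(labs[from], labs[to]), "|", max(labs[from], labs[to]))
    if (key %in% conflicted) return()
    prev <- orientedBy[[key]]
    if (!is.null(prev) && prev != labs[to]) {
      warning("conflicting v-structure orientations for edge ", key,
              "; leaving it undirected")
      A[from, to] <<- A[to, from] <<- 1L
      conflicted <<- c(conflicted, key)
      return()
    }
    if (.isDirected(A, to, from)) return()  # would reverse a directed edge
    A[to, from] <<- 0L
    orientedBy[[key]] <- labs[to]
  }
  geno <- g@kinds == "genotype"
  if (p >= 3) {
    for (x in seq_len(p - 1)) for (z in seq(x + 1L, p)) {
      if (skeleton[x, z]) next
      ys <- which(skeleton[x, ] & skeleton[z, ])
      for (y in ys) {
        ## a genotype middle node cannot host a collider: its phenotype
        ## edges already point away and variant-variant edges stay
        ## undirected under the PMR
        if (geno[y]) next
        ## edges pointing away from y rule the collider out
        if (.isDirected(A, y, x) || .isDirected(A, y, z)) next
        idx <- .ledgerLookup(ledger, labs[x], labs[z], labs[y])
        if (is.na(idx)) {
          nt <- nextThreshold(lond)
          lond <- nt$state
          res <- tryCatch(.ciTest(stat, x, z, y), error = function(e)
            stop("on-demand test failed for triplet (", labs[x], ",",
                 labs[y], ",", labs[z], "): ", conditionMessage(e),
                 call. = FALSE))
          rr <- recordResult(lond, res$p, nt$threshold)
          lond <- rr$state
          idx <- .ledgerAdd(ledger, labs[x], labs[z], labs[y],
                            res$estimate, res$p, nt$threshold, rr$rejected)
        }
        if (ledger@env$rejected[idx]) {
          orient(x, y)
          orient(z, y)
        }
      }
    }
  }
  g@adj <- A
  list(graph = g, lond = lond, ledger = ledger, conflicted = conflicted)
}

#' Iterative orientation against the basic causal models (Step II, part 3)
#'
#' Sweeps candidate triplets with at least one directed edge and exactly one
#' undirected edge, in canonical order, until a full pass changes nothing.
#' For a triplet X -> Y - Z with X and Z non-adjacent, the ledger's test of
#' X and Z given Y decides: conditional independence is consistent only
#' with the chain X -> Y -> Z among the basic three-node models (orienting
#' Y <- Z would create the collider X -> Y <- Z that the test contradicts),
#' so the edge is oriented Y -> Z. An orientation is skipped when it would
#' create a new, untested v-structure at Z or close a directed cycle, and
#' when the mirror triplet supports the opposite direction (the ambiguity of
#' the Markov-equivalent models that share an undirected edge, e.g. a
#' genotype pointing to two phenotypes joined by an edge). Edges between
#' genotypes and edges flagged as conflicted stay undirected; the final
#' graph may contain both directed and undirected edges.
#'
#' @param g [CausalGraph-class] after [identifyVStructures()].
#' @param skeleton,ledger as in [identifyVStructures()].
#' @param conflicted pairs to leave untouched (from
#'   [identifyVStructures()]).
#' @return the final [CausalGraph-class].
#' @export
orientRemaining <- function(g, skeleton, ledger, conflicted = character()) {
  A <- g@adj
  labs <- g@labels
  p <- length(labs)
  geno <- g@kinds == "genotype"
  supports <- function(a, b) {
    ## some X -> a, X and b non-adjacent, with a non-rejected test
    ## X _||_ b | {a} in the ledger (chain evidence for a -> b)
    for (x in seq_len(p)) {
      if (x == b || !.isDirected(A, x, a)) next
      if (skeleton[x, b]) next
      idx <- .ledgerLookup(ledger, labs[x], labs[b], labs[a])
      if (!is.na(idx) && !ledger@env$rejected[idx]) return(TRUE)
    }
    FALSE
  }
  admissible <- function(a, b) {
    ## orienting a -> b must not create an untested v-structure at b ...
    for (w in seq_len(p)) {
      if (w == a || w == b) next
      if (.isDirected(A, w, b) && !skeleton[w, a]) return(FALSE)
    }
    ## ... nor a directed cycle
    !.directedReachable(A, b, a)
  }
  repeat {
    changed <- FALSE
    for (i in seq_len(p - 1)) for (j in seq(i + 1L, p)) {
      if (!.isUndirected(A, i, j)) next
      if (geno[i] && geno[j]) next
      key <- paste0(min(labs[i], labs[j]), "|", max(labs[i], labs[j]))
      if (key %in% conflicted) next
      fwd <- supports(i, j)
      bwd <- supports(j, i)
      if (fwd && !bwd && admissible(i, j)) {
        A[j, i] <- 0L
        changed <- TRUE
      } else if (bwd && !fwd && admissible(j, i)) {
        A[i, j] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  g@adj <- A
  g
}

#' Classic sepset-based CPDAG orientation
#'
#' Reproduces the v-structure logic of the original PC algorithm: for each
#' triplet X-Y-Z with X and Z non-adjacent, the collider X -> Y <- Z is
#' claimed whenever Y is absent from the recorded separation set of X and
#' Z. No conditional test is (re)consulted, so when the X-Z edge was
#' removed by a marginal test the absence of Y is mistaken for evidence of
#' conditional dependence -- the documented false-v-structure behaviour this
#' mode exists to reproduce. Orientation is completed by applying Meek's
#' rules R1-R4 to closure. Node kinds are ignored (no PMR constraint).
#'
#' @param skeleton symmetric adjacency with label dimnames from
#'   [learnSkeleton()].
#' @param sepsets named list ("a|b" -> separating labels) from
#'   [learnSkeleton()].
#' @param kinds optional per-node kinds carried through to the output graph.
#' @return a [CausalGraph-class] (a CPDAG, possibly with extra colliders).
#' @export
orientClassicCpdag <- function(skeleton, sepsets, kinds = NULL) {
  labs <- colnames(skeleton)
  p <- length(labs)
  A <- matrix(as.integer(skeleton), p, p, dimnames = dimnames(skeleton))
  orientedBy <- new.env(parent = emptyenv())
  conflicted <- character()
  orient <- function(from, to) {
    key <- paste0(min(labs[from], labs[to]), "|", max(labs[from], labs[to]))
    if (key %in% conflicted) return()
    prev <- orientedBy[[key]]
    if (!is.null(prev) && prev != labs[to]) {
      warning("conflicting v-structure orientations for edge ", key,
              "; leaving it undirected")
      A[from, to] <<- A[to, from] <<- 1L
      conflicted <<- c(conflicted, key)
      return()
    }
    A[to, from] <<- 0L
    orientedBy[[key]] <- labs[to]
  }
  if (p >= 3) {
    for (x in seq_len(p - 1)) for (z in seq(x + 1L, p)) {
      if (skeleton[x, z]) next
      ys <- which(skeleton[x, ] & skeleton[z, ])
      if (!length(ys)) next
      sep <- sepsets[[paste0(labs[x], "|", labs[z])]]
      if (is.null(sep)) next  # pair never separated by a test: no claim
      for (y in ys) {
        if (!labs[y] %in% sep) {
          orient(x, y)
          orient(z, y)
        }
      }
    }
  }
  A <- .meekClosure(A, skeleton)
  causalGraph(A, kinds = if (is.null(kinds)) "phenotype" else kinds)
}

## Meek's orientation rules R1-R4, applied to closure. Rules only turn
## undirected edges into directed ones, never the reverse.
.meekClosure <- function(A, skeleton) {
  p <- nrow(A)
  repeat {
    changed <- FALSE
    for (a in seq_len(p)) for (b in seq_len(p)) {
      if (a == b || !.isUndirected(A, a, b)) next
      doOrient <- FALSE
      ## R1: c -> a, c and b non-adjacent  =>  a -> b
      for (cc in seq_len(p)) {
        if (cc == a || cc == b) next
        if (.isDirected(A, cc, a) && !skeleton[cc, b]) { doOrient <- TRUE; break }
      }
      ## R2: a -> c -> b  =>  a -> b
      if (!doOrient) for (cc in seq_len(p)) {
        if (cc == a || cc == b) next
        if (.isDirected(A, a, cc) && .isDirected(A, cc, b)) { doOrient <- TRUE; break }
      }
      ## R3: a - c -> b and a - d -> b with c, d non-adjacent  =>  a -> b
      if (!doOrient) {
        cands <- which(vapply(seq_len(p), function(cc)
          cc != a && cc != b && .isUndirected(A, a, cc) &&
            .isDirected(A, cc, b), logical(1)))
        if (length(cands) >= 2) {
          for (u in seq_along(cands)) for (v in seq_along(cands)) {
            if (u < v && !skeleton[cands[u], cands[v]]) { doOrient <- TRUE; break }
          }
        }
      }
      ## R4: a - c, c -> d, d -> b, c and b non-adjacent  =>  a -> b
      if (!doOrient) for (cc in seq_len(p)) {
        if (doOrient) break
        if (cc == a || cc == b || !.isUndirected(A, a, cc)) next
        for (d in seq_len(p)) {
          if (d == a || d == b || d == cc) next
          if (.isDirected(A, cc, d) && .isDirected(A, d, b) &&
              !skeleton[cc, b]) { doOrient <- TRUE; break }
        }
      }
      if (doOrient) {
        A[b, a] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  A
}

#' Infer a causal graph from data or sufficient statistics
#'
#' End-to-end composition of the two inference steps: the order-independent
#' PC-stable skeleton search with LOND online-FDR thresholds (Step I),
#' followed by edge orientation (Step II) in one of two modes.
#' \code{"mrpc"} applies the Mendelian-randomization constraint, the
#' corrected v-structure identification with on-demand conditional tests,
#' and iterative orientation against the basic three-node models;
#' \code{"classic"} reproduces the original PC behaviour (sepset-claimed
#' v-structures plus Meek rules, no genotype constraints). The result is
#' deterministic given the data and settings, and invariant to the column
#' order of the input: all enumeration follows the lexicographic label
#' order, and the returned graph stores nodes in that canonical order.
#'
#' @param data samples-by-variables numeric matrix (header names become node
#'   labels); alternatively supply \code{stat}.
#' @param stat a [SufficientStat-class] (e.g. a correlation matrix + n).
#' @param kinds per-node kinds (\code{"genotype"}/\code{"phenotype"}) named
#'   by or ordered as the columns; alternatively give \code{nGenotypes}.
#' @param nGenotypes number of leading genotype columns.
#' @param alpha target overall FDR for the LOND stream (or the per-test
#'   level when \code{fdrControl = "fixed"}).
#' @param mode \code{"mrpc"} or \code{"classic"}.
#' @param corMethod \code{"pearson"} or \code{"robust"} (robust correlation
#'   of the phenotype block, for data suspected to contain outliers).
#' @param fdrControl \code{"lond"} (online FDR across the whole test
#'   stream) or \code{"fixed"} (classic per-test type-I level).
#' @param dataKind \code{"gaussian"} (Fisher-z tests) or \code{"discrete"}
#'   (G-squared tests on integer-coded data).
#' @param maxCondSize cap on conditioning-set size.
#' @return a [CausalFit-class].
#' @examples
#' spec <- simulationSpec(basicModelGraph("M1"), gamma = 1, n = 500, seed = 7)
#' d <- simulateDagData(spec)
#' fit <- inferCausalGraph(d, nGenotypes = 1)
#' fittedGraph(fit)
#' @export
inferCausalGraph <- function(data = NULL, stat = NULL, kinds = NULL,
                             nGenotypes = NULL, alpha = 0.05,
                             mode = c("mrpc", "classic"),
                             corMethod = c("pearson", "robust"),
                             fdrControl = c("lond", "fixed"),
                             dataKind = c("gaussian", "discrete"),
                             maxCondSize = Inf) {
  mode <- match.arg(mode)
  corMethod <- match.arg(corMethod)
  fdrControl <- match.arg(fdrControl)
  dataKind <- match.arg(dataKind)
  weights <- numeric()
  if (!is.null(data)) {
    data <- as.matrix(data)
    if (is.null(colnames(data)))
      colnames(data) <- paste0("N", seq_len(ncol(data)))
    labs <- colnames(data)
    kinds <- .resolveKinds(kinds, nGenotypes, labs)
    if (dataKind == "gaussian") {
      ci <- .correlationInput(data, kinds, corMethod)
      weights <- ci$weights
      stat <- sufficientStat(R = ci$R, n = nrow(data))
    } else {
      stat <- sufficientStat(data = data, kind = "discrete")
    }
  } else if (!is.null(stat)) {
    labs <- colnames(stat@R)
    kinds <- .resolveKinds(kinds, nGenotypes, labs)
  } else stop("supply 'data' or 'stat'")
  ## canonical column order throughout
  ord <- order(labs)
  stat@R <- stat@R[ord, ord, drop = FALSE]
  if (nrow(stat@data) > 0) stat@data <- stat@data[, ord, drop = FALSE]
  kinds <- kinds[ord]
  lond <- londState(alpha = alpha, fixed = fdrControl == "fixed")
  sk <- learnSkeleton(stat, lond, maxCondSize = maxCondSize)
  if (mode == "mrpc") {
    g <- orientPMR(sk$skeleton, kinds)
    vs <- identifyVStructures(g, sk$skeleton, sk$ledger, stat, sk$lond)
    g <- orientRemaining(vs$graph, sk$skeleton, sk$ledger, vs$conflicted)
  } else {
    g <- orientClassicCpdag(sk$skeleton, sk$sepsets, kinds)
  }
  new("CausalFit", graph = g, skeleton = sk$skeleton, sepsets = sk$sepsets,
      ledger = sk$ledger, alpha = alpha, mode = mode, weights = weights)
}

.resolveKinds <- function(kinds, nGenotypes, labs) {
  if (!is.null(kinds)) {
    if (!is.null(names(kinds))) kinds <- kinds[labs]
    rep_len(as.character(kinds), length(labs))
  } else if (!is.null(nGenotypes)) {
    k <- rep("phenotype", length(labs))
    if (nGenotypes > 0) k[seq_len(nGenotypes)] <- "genotype"
    k
  } else rep("phenotype", length(labs))
}
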