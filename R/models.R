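.graphFromEdges <- function(labels, kinds, directed = NULL, undirected = NULL) {
  p <- length(labels)
  A <- matrix(0L, p, p, dimnames = list(labels, labels))
  if (!is.null(directed)) for (e in directed) A[e[1], e[2]] <- 1L
  if (!is.null(undirected)) for (e in undirected)
    A[e[1], e[2]] <- A[e[2], e[1]] <- 1L
  causalGraph(A, kinds = kinds, labels = labels)
}

#' The five basic three-node causal models
#'
#' Each basic model has one genotype node V1 (the instrumental variable)
#' and two phenotype nodes T1, T2: M0 is V1 -> T1 with T2 isolated; M1 the
#' chain V1 -> T1 -> T2; M2 the v-structure V1 -> T1 <- T2; M3 the fork
#' V1 -> T1, V1 -> T2; and M4 adds the undirected edge T1 - T2 to the fork,
#' standing for the two Markov-equivalent fully directed models (T1 -> T2
#' or T2 -> T1) that the data cannot distinguish.
#'
#' @param model one of "M0", "M1", "M2", "M3", "M4".
#' @return a [CausalGraph-class] over (V1, T1, T2).
#' @seealso [basicModelCatalog()]
#' @export
basicModelGraph <- function(model = c("M1", "M2", "M0", "M3", "M4")) {
  model <- match.arg(model)
  labs <- c("V1", "T1", "T2")
  kinds <- c("genotype", "phenotype", "phenotype")
  switch(model,
    M0 = .graphFromEdges(labs, kinds, directed = list(c("V1", "T1"))),
    M1 = .graphFromEdges(labs, kinds,
                         directed = list(c("V1", "T1"), c("T1", "T2"))),
    M2 = .graphFromEdges(labs, kinds,
                         directed = list(c("V1", "T1"), c("T2", "T1"))),
    M3 = .graphFromEdges(labs, kinds,
                         directed = list(c("V1", "T1"), c("V1", "T2"))),
    M4 = .graphFromEdges(labs, kinds,
                         directed = list(c("V1", "T1"), c("V1", "T2")),
                         undirected = list(c("T1", "T2"))))
}

#' Catalog of the basic models and their independence signatures
#'
#' For each basic model, the marginal and conditional (in)dependence
#' pattern among the three node pairs that the independence tests probe.
#' These signatures are what Step II's orientation logic distinguishes:
#' they are mutually distinguishable under the PMR constraints except for
#' the internal ambiguity of M4, whose two fully directed versions are
#' Markov equivalent.
#'
#' @return list with \code{graphs} (named list of [CausalGraph-class]) and
#'   \code{signatures}, a data.frame with one row per model and logical
#'   columns: dep.V1T1, dep.V1T2, dep.T1T2 (marginal dependence) and
#'   dep.V1T2.T1, dep.T1T2.V1 (conditional dependence given the third
#'   node).
#' @export
basicModelCatalog <- function() {
  models <- c("M0", "M1", "M2", "M3", "M4")
  graphs <- lapply(models, basicModelGraph)
  names(graphs) <- models
  signatures <- data.frame(
    model = models,
    dep.V1T1 = c(TRUE, TRUE, TRUE, TRUE, TRUE),
    dep.V1T2 = c(FALSE, TRUE, FALSE, TRUE, TRUE),
    dep.T1T2 = c(FALSE, TRUE, TRUE, TRUE, TRUE),
    dep.V1T2.T1 = c(FALSE, FALSE, TRUE, TRUE, TRUE),
    dep.T1T2.V1 = c(FALSE, TRUE, TRUE, FALSE, TRUE),
    stringsAsFactors = FALSE)
  list(graphs = graphs, signatures = signatures)
}

#' Four-node chain graph
#'
#' V1 -> T1 -> T2 -> T3: the small all-chain benchmark used in the
#' node-ordering stability experiments.
#'
#' @return a [CausalGraph-class].
#' @export
exampleChainGraph <- function() {
  labs <- c("V1", "T1", "T2", "T3")
  .graphFromEdges(labs, c("genotype", rep("phenotype", 3)),
                  directed = list(c("V1", "T1"), c("T1", "T2"),
                                  c("T2", "T3")))
}

#' Four-node collider-plus-chain graph
#'
#' V1 -> T1 <- T2 -> T3: a v-structure feeding a chain, the second small
#' benchmark of the node-ordering stability experiments.
#'
#' @return a [CausalGraph-class].
#' @export
exampleColliderChainGraph <- function() {
  labs <- c("V1", "T1", "T2", "T3")
  .graphFromEdges(labs, c("genotype", rep("phenotype", 3)),
                  directed = list(c("V1", "T1"), c("T2", "T1"),
                                  c("T2", "T3")))
}

#' Synthetic 22-node benchmark graph
#'
#' A synthetic complex benchmark with 14 genetic-variant nodes and 8
#' phenotype nodes, built to exercise the full method: chains (M1-type
#' subgraphs), colliders (M2-type subgraphs), and undirected
#' variant-variant edges, arranged in four well-separated groups of at
#' least five nodes each so that distance-based module clustering with a
#' minimum module size of 5 recovers four modules. This graph is a
#' constructed stand-in, not taken from any published network.
#'
#' @return a [CausalGraph-class] with 22 nodes and 22 edges (12 directed,
#'   10 undirected).
#' @export
exampleComplexGraph <- function() {
  labs <- c(paste0("V", 1:14), paste0("T", 1:8))
  kinds <- c(rep("genotype", 14), rep("phenotype", 8))
  .graphFromEdges(labs, kinds,
    directed = list(
      c("V1", "T1"), c("T1", "T2"), c("V4", "T2"),     # group A
      c("V5", "T3"), c("V8", "T4"), c("T4", "T3"),     # group B
      c("V9", "T5"), c("T5", "T6"), c("V11", "T6"),    # group C
      c("V12", "T7"), c("T7", "T8"), c("V14", "T8")),  # group D
    undirected = list(
      c("V1", "V2"), c("V2", "V3"), c("V3", "V4"),
      c("V5", "V6"), c("V6", "V7"), c("V7", "V8"),
      c("V9", "V10"), c("V10", "V11"),
      c("V12", "V13"), c("V13", "V14")))
}

#' Synthetic truth graph for the outlier-robustness experiment
#'
#' A small eQTL-style graph -- a chain V1 -> T1 -> T2 plus an unrelated
#' pair V2 -> T3 -- under which contaminating a minority of samples with
#' gross outliers induces spurious phenotype-phenotype correlations (and
#' hence extra edges) when plain Pearson correlation is used, while robust
#' correlation downweights the contaminated samples and recovers the true
#' graph. A constructed stand-in for this kind of experiment, not a
#' published network.
#'
#' @return a [CausalGraph-class] with 5 nodes.
#' @export
exampleOutlierGraph <- function() {
  labs <- c("V1", "V2", "T1", "T2", "T3")
  kinds <- c("genotype", "genotype", rep("phenotype", 3))
  .graphFromEdges(labs, kinds,
                  directed = list(c("V1", "T1"), c("T1", "T2"),
                                  c("V2", "T3")))
}
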