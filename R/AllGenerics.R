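#' @rdname nodeLabels
#' @export
setGeneric("nodeLabels", function(x) standardGeneric("nodeLabels"))

#' @rdname nodeKinds
#' @export
setGeneric("nodeKinds", function(x) standardGeneric("nodeKinds"))

#' @rdname adjacencyMatrix
#' @export
setGeneric("adjacencyMatrix", function(x) standardGeneric("adjacencyMatrix"))

#' @rdname canonicalForm
#' @export
setGeneric("canonicalForm", function(x) standardGeneric("canonicalForm"))

#' @rdname fittedGraph
#' @export
setGeneric("fittedGraph", function(x) standardGeneric("fittedGraph"))

#' @rdname testLedger
#' @export
setGeneric("testLedger", function(x) standardGeneric("testLedger"))

#' @rdname sepSets
#' @export
setGeneric("sepSets", function(x) standardGeneric("sepSets"))

#' Node labels of a graph
#'
#' @param x a CausalGraph or CausalFit.
#' @return character vector of node names.
#' @rdname nodeLabels
#' @export
setMethod("nodeLabels", "CausalGraph", function(x) x@labels)

#' Node kinds (genotype/phenotype)
#'
#' @param x a CausalGraph or CausalFit.
#' @return character vector of per-node kinds.
#' @rdname nodeKinds
#' @export
setMethod("nodeKinds", "CausalGraph",
          function(x) setNames(x@kinds, x@labels))

#' Adjacency matrix of a graph
#'
#' Rows are parents and columns children; a symmetric pair of 1s is one
#' undirected edge.
#'
#' @param x a CausalGraph or CausalFit.
#' @return integer 0/1 matrix.
#' @rdname adjacencyMatrix
#' @export
setMethod("adjacencyMatrix", "CausalGraph", function(x) x@adj)

#' @rdname nodeLabels
#' @export
setMethod("nodeLabels", "CausalFit", function(x) nodeLabels(x@graph))

#' @rdname nodeKinds
#' @export
setMethod("nodeKinds", "CausalFit", function(x) nodeKinds(x@graph))

#' @rdname adjacencyMatrix
#' @export
setMethod("adjacencyMatrix", "CausalFit", function(x) adjacencyMatrix(x@graph))

#' Inferred graph of a fit
#' @param x a CausalFit.
#' @return the [CausalGraph-class].
#' @rdname fittedGraph
#' @export
setMethod("fittedGraph", "CausalFit", function(x) x@graph)

#' Test ledger of a fit
#' @param x a CausalFit.
#' @return the [TestLedger-class].
#' @rdname testLedger
#' @export
setMethod("testLedger", "CausalFit", function(x) x@ledger)

#' Separation sets of a fit
#' @param x a CausalFit.
#' @return named list: removed pair ("a|b") -> conditioning set labels.
#' @rdname sepSets
#' @export
setMethod("sepSets", "CausalFit", function(x) x@sepsets)

## edge-state helper: 0 none, 1 i->j, 2 j->i, 3 undirected (i, j indices)
.edgeState <- function(A, i, j) {
  a <- A[i, j]; b <- A[j, i]
  if (a == 1 && b == 1) 3L else if (a == 1) 1L else if (b == 1) 2L else 0L
}

#' Edge list of a graph
#'
#' @param g a [CausalGraph-class].
#' @return data.frame with columns from, to, state
#'   (\code{"directed"} or \code{"undirected"}); undirected edges appear once
#'   with \code{from < to} by label.
#' @export
graphEdges <- function(g) {
  A <- g@adj
  labs <- g@labels
  from <- character(); to <- character(); state <- character()
  p <- length(labs)
  if (p >= 2) {
    for (i in seq_len(p - 1)) for (j in seq(i + 1, p)) {
      st <- .edgeState(A, i, j)
      if (st == 0L) next
      if (st == 3L) {
        o <- order(c(labs[i], labs[j]))
        pr <- c(labs[i], labs[j])[o]
        from <- c(from, pr[1]); to <- c(to, pr[2])
        state <- c(state, "undirected")
      } else if (st == 1L) {
        from <- c(from, labs[i]); to <- c(to, labs[j])
        state <- c(state, "directed")
      } else {
        from <- c(from, labs[j]); to <- c(to, labs[i])
        state <- c(state, "directed")
      }
    }
  }
  data.frame(from = from, to = to, state = state, stringsAsFactors = FALSE)
}

setMethod("show", "CausalGraph", function(object) {
  ed <- graphEdges(object)
  cat("CausalGraph with", length(object@labels), "nodes (",
      sum(object@kinds == "genotype"), "genotype,",
      sum(object@kinds == "phenotype"), "phenotype ) and",
      nrow(ed), "edges (", sum(ed$state == "directed"), "directed,",
      sum(ed$state == "undirected"), "undirected )\n")
  if (nrow(ed)) {
    shown <- head(ed, 10)
    arrows <- ifelse(shown$state == "directed", "->", "--")
    cat(paste0("  ", shown$from, " ", arrows, " ", shown$to), sep = "\n")
    if (nrow(ed) > 10) cat("  ...", nrow(ed) - 10, "more\n")
  }
  invisible(object)
})

setMethod("show", "SufficientStat", function(object) {
  cat("SufficientStat:", object@kind, "kind,", ncol(object@R),
      "variables, n =", object@n, "\n")
  invisible(object)
})

setMethod("show", "LondState", function(object) {
  if (object@fixed)
    cat("Fixed per-test threshold alpha =", object@alpha,
        "(", object@t, "tests )\n")
  else
    cat("LondState: alpha =", object@alpha, ",", object@t, "tests,",
        object@nDiscoveries, "discoveries\n")
  invisible(object)
})

setMethod("show", "TestLedger", function(object) {
  cat("TestLedger with", object@env$n, "tests (",
      sum(object@env$rejected[seq_len(object@env$n)]), "rejections )\n")
  invisible(object)
})

setMethod("show", "CausalFit", function(object) {
  cat("CausalFit (mode =", object@mode, ", alpha =", object@alpha, ")\n")
  show(object@graph)
  cat("Tests performed:", object@ledger@env$n, "\n")
  invisible(object)
})
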