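#' @import methods
#' @importFrom stats cor pnorm pchisq qchisq quantile rnorm rbinom runif
#'   mahalanobis median mad hclust as.dist cutree sd setNames
#' @importFrom utils combn read.table write.table head
NULL

## Mixed-graph adjacency convention used throughout:
##   A[i, j] = 1 means an edge from node i (parent, row) to node j (child,
##   column); A[i, j] = A[j, i] = 1 encodes an undirected (equivalently
##   bidirected) edge.  The diagonal is zero.

#' CausalGraph: a labeled mixed graph over genotype and phenotype nodes
#'
#' A square binary adjacency matrix together with node labels and per-node
#' kinds. Rows are parents, columns are children; a symmetric pair of 1s is a
#' single undirected edge. Genotype nodes represent genetic variants that act
#' as instrumental variables under the principle of Mendelian randomization
#' (PMR): an edge between a genotype and a phenotype may only point to the
#' phenotype, and edges between two genotypes are always undirected.
#'
#' @slot labels character vector of unique node names.
#' @slot kinds character vector, one of \code{"genotype"} or
#'   \code{"phenotype"} per node.
#' @slot adj integer 0/1 matrix with \code{labels} as dimnames.
#'
#' @seealso [causalGraph()], [canonicalForm()], [adjacencyMatrix()]
#' @export
setClass("CausalGraph",
         representation(labels = "character",
                        kinds = "character",
                        adj = "matrix"))

setValidity("CausalGraph", function(object) {
  msg <- character()
  p <- length(object@labels)
  if (anyDuplicated(object@labels))
    msg <- c(msg, "node labels must be unique")
  if (length(object@kinds) != p)
    msg <- c(msg, "kinds must have one entry per node")
  if (!all(object@kinds %in% c("genotype", "phenotype")))
    msg <- c(msg, "kinds must be 'genotype' or 'phenotype'")
  A <- object@adj
  if (!is.numeric(A) || nrow(A) != p || ncol(A) != p)
    msg <- c(msg, "adjacency must be a numeric p x p matrix")
  else {
    if (!all(A %in% c(0, 1)))
      msg <- c(msg, "adjacency entries must be 0 or 1")
    if (any(diag(A) != 0))
      msg <- c(msg, "adjacency diagonal must be zero")
    if (!identical(rownames(A), object@labels) ||
        !identical(colnames(A), object@labels))
      msg <- c(msg, "adjacency dimnames must equal the labels")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a CausalGraph
#'
#' @param adjacency square 0/1 matrix, rows = parents, columns = children;
#'   symmetric 1s encode an undirected edge. Dimnames, if present, are used
#'   as labels.
#' @param kinds per-node kind, \code{"genotype"} or \code{"phenotype"};
#'   recycled from a single value. Default: all phenotype.
#' @param labels node names; defaults to the adjacency dimnames or
#'   \code{N1, N2, ...}.
#' @return a [CausalGraph-class] object.
#' @examples
#' A <- matrix(0, 3, 3, dimnames = list(c("V1","T1","T2"), c("V1","T1","T2")))
#' A["V1","T1"] <- A["T1","T2"] <- 1
#' g <- causalGraph(A, kinds = c("genotype","phenotype","phenotype"))
#' g
#' @export
causalGraph <- function(adjacency, kinds = "phenotype", labels = NULL) {
  adjacency <- as.matrix(adjacency)
  p <- nrow(adjacency)
  if (is.null(labels))
    labels <- if (!is.null(rownames(adjacency))) rownames(adjacency)
              else paste0("N", seq_len(p))
  storage.mode(adjacency) <- "integer"
  dimnames(adjacency) <- list(labels, labels)
  kinds <- rep_len(kinds, p)
  new("CausalGraph", labels = as.character(labels),
      kinds = as.character(kinds), adj = adjacency)
}

#' SufficientStat: sufficient statistics for the independence tests
#'
#' For continuous (Gaussian) data all tests are computed from the correlation
#' matrix and the sample size; for discrete data the raw data matrix is
#' retained for the G-squared test.
#'
#' @slot R symmetric correlation matrix with unit diagonal.
#' @slot n sample size.
#' @slot kind \code{"gaussian"} or \code{"discrete"}.
#' @slot data raw data matrix (kept when \code{kind = "discrete"}, otherwise
#'   may be a 0-row matrix).
#' @seealso [sufficientStat()]
#' @export
setClass("SufficientStat",
         representation(R = "matrix", n = "numeric",
                        kind = "character", data = "matrix"))

setValidity("SufficientStat", function(object) {
  msg <- character()
  R <- object@R
  if (nrow(R) != ncol(R)) msg <- c(msg, "R must be square")
  if (max(abs(R - t(R))) > 1e-8) msg <- c(msg, "R must be symmetric")
  if (any(abs(R) > 1 + 1e-8)) msg <- c(msg, "|R| entries must be <= 1")
  if (!object@kind %in% c("gaussian", "discrete"))
    msg <- c(msg, "kind must be 'gaussian' or 'discrete'")
  if (object@n < 1) msg <- c(msg, "n must be positive")
  if (length(msg)) msg else TRUE
})

#' Build sufficient statistics from data or from a correlation matrix
#'
#' Mirrors the two input routes of PC-style learners: a samples-by-variables
#' data matrix, or a precomputed correlation matrix plus the sample size.
#'
#' @param data numeric matrix, samples in rows, variables in columns.
#' @param R correlation matrix (used when \code{data} is NULL).
#' @param n sample size (required with \code{R}).
#' @param kind \code{"gaussian"} for Fisher-z tests on (partial) correlations,
#'   \code{"discrete"} for G-squared tests on the raw data.
#' @return a [SufficientStat-class] object.
#' @export
sufficientStat <- function(data = NULL, R = NULL, n = NULL,
                           kind = c("gaussian", "discrete")) {
  kind <- match.arg(kind)
  if (!is.null(data)) {
    data <- as.matrix(data)
    if (is.null(colnames(data)))
      colnames(data) <- paste0("N", seq_len(ncol(data)))
    n <- nrow(data)
    R <- if (kind == "gaussian") cor(data) else diag(ncol(data))
    dimnames(R) <- list(colnames(data), colnames(data))
    if (kind == "gaussian") data <- data[0, , drop = FALSE]
  } else {
    if (is.null(R) || is.null(n))
      stop("supply either 'data' or both 'R' and 'n'")
    R <- as.matrix(R)
    if (is.null(colnames(R)))
      dimnames(R) <- list(paste0("N", seq_len(ncol(R))),
                          paste0("N", seq_len(ncol(R))))
    if (kind == "discrete")
      stop("discrete sufficient statistics require the raw data matrix")
    data <- matrix(numeric(), 0, ncol(R),
                   dimnames = list(NULL, colnames(R)))
  }
  new("SufficientStat", R = R, n = as.numeric(n), kind = kind, data = data)
}

#' LondState: sequential significance thresholds with overall FDR control
#'
#' State of the LOND rule (significance Levels based On the Number of
#' Discoveries): at test t the threshold is \eqn{\alpha_t = \beta_t (D_{t-1}
#' + 1)} where \eqn{D_{t-1}} is the number of rejections among the first
#' t-1 tests and \eqn{\{\beta_t\}} is a nonnegative sequence summing to the
#' target level \eqn{\alpha}. Thresholds are largest at the start of the
#' stream and shrink as testing proceeds, growing again with each discovery.
#'
#' @slot alpha target overall FDR level.
#' @slot t number of thresholds consumed so far.
#' @slot nDiscoveries rejections recorded so far.
#' @slot normConst normalizing constant of the default beta sequence.
#' @slot tMax horizon over which the beta sequence is normalized.
#' @slot fixed if TRUE the threshold is always \code{alpha} (per-test type-I
#'   control, as in classic PC implementations) and no FDR bookkeeping
#'   applies.
#' @seealso [londState()], [nextThreshold()], [recordResult()]
#' @export
setClass("LondState",
         representation(alpha = "numeric", t = "numeric",
                        nDiscoveries = "numeric", normConst = "numeric",
                        tMax = "numeric", fixed = "logical"))

setValidity("LondState", function(object) {
  msg <- character()
  if (object@alpha <= 0 || object@alpha >= 1)
    msg <- c(msg, "alpha must be in (0, 1)")
  if (object@nDiscoveries > object@t)
    msg <- c(msg, "discoveries cannot exceed tests")
  if (length(msg)) msg else TRUE
})

.londCache <- new.env(parent = emptyenv())

.londNormConst <- function(tMax) {
  key <- format(tMax)
  if (!is.null(.londCache[[key]])) return(.londCache[[key]])
  tt <- seq_len(tMax)
  s <- sum(1 / (tt * log(pmax(tt, 2))^2))
  .londCache[[key]] <- 1 / s
  1 / s
}

#' Create a fresh LOND state
#'
#' The default beta sequence is \eqn{\beta_t = \alpha C / (t \ln(\max(t,
#' 2))^2)} with C chosen so the sequence sums to \eqn{\alpha} over
#' \code{tMax} tests, a standard summable choice.
#'
#' @param alpha target overall FDR (default 0.05).
#' @param tMax horizon used to normalize the beta sequence (default 1e6).
#' @param fixed use a fixed per-test threshold \code{alpha} instead of LOND.
#' @return a [LondState-class] object.
#' @export
londState <- function(alpha = 0.05, tMax = 1e6, fixed = FALSE) {
  new("LondState", alpha = alpha, t = 0, nDiscoveries = 0,
      normConst = .londNormConst(tMax), tMax = tMax, fixed = fixed)
}

#' TestLedger: the ordered record of every independence test
#'
#' Environment-backed accumulator recording, for each test in the order it
#' was performed: the node pair, the conditioning set, the estimate (partial
#' correlation or G-squared statistic), the p-value, the significance
#' threshold in force, and the decision. The ledger is the source of truth
#' for edge orientation: v-structure and iterative orientation consult it
#' rather than re-testing.
#'
#' @slot env environment holding the growing record vectors and the
#'   (pair, conditioning set) lookup index.
#' @seealso [ledgerData()], [writeLedger()]
#' @export
setClass("TestLedger", representation(env = "environment"))

newTestLedger <- function() {
  e <- new.env(parent = emptyenv())
  e$n <- 0L
  e$cap <- 256L
  e$i <- character(256L); e$j <- character(256L); e$S <- character(256L)
  e$estimate <- numeric(256L); e$p <- numeric(256L)
  e$threshold <- numeric(256L); e$rejected <- logical(256L)
  e$index <- new.env(parent = emptyenv())
  new("TestLedger", env = e)
}

.ledgerKey <- function(i, j, S) {
  ij <- sort(c(i, j))
  paste0(ij[1L], "|", ij[2L], "|", paste(sort(S), collapse = ","))
}

.ledgerAdd <- function(ledger, i, j, S, estimate, p, threshold, rejected) {
  e <- ledger@env
  n <- e$n + 1L
  if (n > e$cap) {
    newcap <- e$cap * 2L
    for (f in c("i", "j", "S", "estimate", "p", "threshold", "rejected"))
      length(e[[f]]) <- newcap
    e$cap <- newcap
  }
  e$i[n] <- i; e$j[n] <- j
  e$S[n] <- paste(sort(S), collapse = ",")
  e$estimate[n] <- estimate; e$p[n] <- p
  e$threshold[n] <- threshold; e$rejected[n] <- rejected
  e$n <- n
  key <- .ledgerKey(i, j, S)
  if (!is.null(e$index[[key]]))
    stop("duplicate ledger entry for ", key)
  e$index[[key]] <- n
  invisible(n)
}

.ledgerLookup <- function(ledger, i, j, S) {
  idx <- ledger@env$index[[.ledgerKey(i, j, S)]]
  if (is.null(idx)) NA_integer_ else idx
}

#' Extract the test ledger as a data.frame
#'
#' One row per test, in execution order: node pair, conditioning set size and
#' members, estimate, p-value, LOND threshold, and decision.
#'
#' @param ledger a [TestLedger-class].
#' @return data.frame with columns i, j, sizeS, S, estimate, p, threshold,
#'   rejected.
#' @export
ledgerData <- function(ledger) {
  e <- ledger@env
  idx <- seq_len(e$n)
  S <- e$S[idx]
  data.frame(i = e$i[idx], j = e$j[idx],
             sizeS = ifelse(nzchar(S), lengths(strsplit(S, ",", fixed = TRUE)), 0L),
             S = S, estimate = e$estimate[idx], p = e$p[idx],
             threshold = e$threshold[idx], rejected = e$rejected[idx],
             stringsAsFactors = FALSE)
}

#' Write a test ledger to a TSV file for audit
#'
#' @param ledger a [TestLedger-class].
#' @param path output file path.
#' @export
writeLedger <- function(ledger, path) {
  write.table(ledgerData(ledger), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' CausalFit: result of a full inference run
#'
#' @slot graph the inferred [CausalGraph-class].
#' @slot skeleton the undirected skeleton adjacency (logical matrix).
#' @slot sepsets named list mapping removed pairs ("a|b", labels sorted) to
#'   the conditioning set of the test that removed the edge.
#' @slot ledger the [TestLedger-class] of every test performed.
#' @slot alpha target FDR level used.
#' @slot mode \code{"mrpc"} or \code{"classic"}.
#' @slot weights per-sample robust-correlation weights (length 0 unless
#'   robust correlation was used).
#' @export
setClass("CausalFit",
         representation(graph = "CausalGraph", skeleton = "matrix",
                        sepsets = "list", ledger = "TestLedger",
                        alpha = "numeric", mode = "character",
                        weights = "numeric"))
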