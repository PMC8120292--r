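#' Learn the undirected skeleton (Step I)
#'
#' Order-independent, level-wise conditional-independence search. Starting
#' from the complete graph over the canonically (lexicographically) ordered
#' nodes, level \eqn{\ell = 0, 1, 2, \dots} tests each adjacent pair (i, j)
#' (i the smaller label) against every size-\eqn{\ell} subset of the
#' neighbours of i excluding j, with adjacency sets frozen at the start of
#' the level (the stable variant). Every test consumes one online-FDR
#' threshold from the LOND stream; a non-rejected test removes the edge,
#' records the conditioning set as the pair's separation set, and the edge
#' is never tested again. The canonical test order makes the threshold
#' stream -- and therefore all decisions -- invariant to the column order of
#' the input data.
#'
#' @param stat a [SufficientStat-class].
#' @param lond a [LondState-class] (default \code{londState()}).
#' @param maxCondSize cap on the conditioning-set size (default unlimited).
#' @return list with \code{skeleton} (symmetric logical adjacency over the
#'   canonically ordered labels), \code{sepsets} (named list: "a|b" ->
#'   separating labels), \code{ledger} (the [TestLedger-class]), and the
#'   final \code{lond} state.
#' @export
learnSkeleton <- function(stat, lond = londState(), maxCondSize = Inf) {
  labsIn <- colnames(stat@R)
  if (length(labsIn) < 2) stop("skeleton search needs at least 2 nodes")
  ord <- order(labsIn)
  labs <- labsIn[ord]
  stat@R <- stat@R[ord, ord, drop = FALSE]
  if (nrow(stat@data) > 0)
    stat@data <- stat@data[, ord, drop = FALSE]
  p <- length(labs)
  adj <- matrix(TRUE, p, p)
  diag(adj) <- FALSE
  sepsets <- list()
  ledger <- newTestLedger()
  ell <- -1L
  repeat {
    ell <- ell + 1L
    if (ell > maxCondSize) break
    adjFrozen <- adj
    anyTestable <- FALSE
    for (i in seq_len(p - 1)) {
      for (j in seq(i + 1L, p)) {
        if (!adjFrozen[i, j]) next
        nbrs <- which(adjFrozen[i, ])
        nbrs <- nbrs[nbrs != j]
        if (length(nbrs) < ell) next
        anyTestable <- TRUE
        if (!adj[i, j]) next  # already removed at this level
        subsets <- if (ell == 0L) list(integer())
                   else if (length(nbrs) == ell) list(nbrs)
                   else combn(nbrs, ell, simplify = FALSE)
        for (S in subsets) {
          nt <- nextThreshold(lond)
          lond <- nt$state
          res <- tryCatch(.ciTest(stat, i, j, S), error = function(e)
            stop("independence test failed for pair (", labs[i], ",",
                 labs[j], ") given {", paste(labs[S], collapse = ","),
                 "}: ", conditionMessage(e), call. = FALSE))
          rr <- recordResult(lond, res$p, nt$threshold)
          lond <- rr$state
          .ledgerAdd(ledger, labs[i], labs[j], labs[S],
                     res$estimate, res$p, nt$threshold, rr$rejected)
          if (!rr$rejected) {
            adj[i, j] <- adj[j, i] <- FALSE
            sepsets[[paste0(labs[i], "|", labs[j])]] <- labs[S]
            break
          }
        }
      }
    }
    if (!anyTestable && ell > 0L) break
  }
  dimnames(adj) <- list(labs, labs)
  list(skeleton = adj, sepsets = sepsets, ledger = ledger, lond = lond)
}
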