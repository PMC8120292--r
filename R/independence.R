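#' Partial correlation from a correlation matrix
#'
#' Computes the correlation of variables \code{i} and \code{j} given the
#' conditioning set \code{S} by inverting the correlation submatrix on
#' \code{{i, j} union S} and normalizing the corresponding precision-matrix
#' entry; with an empty \code{S} this is simply \code{R[i, j]}.
#'
#' @param R correlation matrix.
#' @param i,j variable indices (or names matching dimnames of \code{R}).
#' @param S conditioning set (indices or names), excluding i and j.
#' @return partial correlation in [-1, 1].
#' @export
partialCorrelation <- function(R, i, j, S = integer()) {
  if (is.character(i)) i <- match(i, colnames(R))
  if (is.character(j)) j <- match(j, colnames(R))
  if (is.character(S)) S <- match(S, colnames(R))
  if (i %in% S || j %in% S) stop("conditioning set must exclude i and j")
  if (length(S) == 0) return(R[i, j])
  idx <- c(i, j, S)
  sub <- R[idx, idx, drop = FALSE]
  P <- tryCatch(solve(sub), error = function(e)
    stop("singular correlation submatrix (collinearity) for pair (",
         i, ",", j, ") given ", paste(S, collapse = ","), call. = FALSE))
  r <- -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
  max(-1, min(1, r))
}

#' Fisher-z test of (conditional) independence for Gaussian data
#'
#' Tests whether variables i and j are independent given S by applying
#' Fisher's z transformation to the estimated (partial) correlation: with
#' \eqn{z = \mathrm{atanh}(\hat\rho)} the statistic
#' \eqn{\sqrt{n - |S| - 3}\,|z|} is compared to a standard normal, two
#' sided. A degenerate \eqn{|\hat\rho| = 1} yields p = 0 with a warning.
#'
#' @param R correlation matrix.
#' @param n sample size; must satisfy \code{n - length(S) - 3 >= 1}.
#' @param i,j,S as in [partialCorrelation()].
#' @return list with \code{estimate} (the partial correlation) and \code{p}.
#' @export
fisherZTest <- function(R, n, i, j, S = integer()) {
  if (n - length(S) - 3 < 1)
    stop("sample size too small: need n - |S| - 3 >= 1")
  r <- partialCorrelation(R, i, j, S)
  if (abs(r) >= 1) {
    warning("degenerate (partial) correlation of magnitude 1; p set to 0")
    return(list(estimate = r, p = 0))
  }
  z <- atanh(r)
  stat <- sqrt(n - length(S) - 3) * abs(z)
  list(estimate = r, p = 2 * pnorm(-stat))
}

#' G-squared test of (conditional) independence for discrete data
#'
#' Likelihood-ratio test of independence of columns i and j within each
#' stratum formed by the joint levels of the conditioning columns S:
#' \eqn{G^2 = 2 \sum O \ln(O/E)} summed over strata, with zero-count cells
#' contributing 0 and strata with zero total skipped. Degrees of freedom are
#' \eqn{(L_i - 1)(L_j - 1)\prod_k L_k}; a nonpositive df yields p = 1 with a
#' warning.
#'
#' @param data matrix or data.frame of categorical (integer-coded) columns.
#' @param i,j column indices or names.
#' @param S conditioning columns (indices or names).
#' @return list with \code{estimate} (the G-squared statistic), \code{df},
#'   and \code{p}.
#' @export
gSquareTest <- function(data, i, j, S = integer()) {
  data <- as.matrix(data)
  if (is.character(i)) i <- match(i, colnames(data))
  if (is.character(j)) j <- match(j, colnames(data))
  if (is.character(S)) S <- match(S, colnames(data))
  xi <- factor(data[, i])
  xj <- factor(data[, j])
  Li <- nlevels(xi); Lj <- nlevels(xj)
  Lk <- if (length(S)) vapply(S, function(k) length(unique(data[, k])), 1L)
        else integer()
  df <- (Li - 1) * (Lj - 1) * prod(Lk)
  if (df <= 0) {
    warning("nonpositive degrees of freedom in G-squared test; p = 1")
    return(list(estimate = 0, df = 0, p = 1))
  }
  strata <- if (length(S)) interaction(as.data.frame(data[, S, drop = FALSE]),
                                       drop = TRUE)
            else factor(rep(1L, nrow(data)))
  G2 <- 0
  for (lev in levels(strata)) {
    sel <- strata == lev
    if (!any(sel)) next
    tab <- table(xi[sel], xj[sel])
    tot <- sum(tab)
    if (tot == 0) next
    E <- outer(rowSums(tab), colSums(tab)) / tot
    O <- as.numeric(tab)
    Ev <- as.numeric(E)
    nz <- O > 0
    G2 <- G2 + 2 * sum(O[nz] * log(O[nz] / Ev[nz]))
  }
  list(estimate = G2, df = df, p = pchisq(G2, df, lower.tail = FALSE))
}

## unified conditional-independence test against a SufficientStat
## (indices are relative to stat@R columns)
.ciTest <- function(stat, i, j, S) {
  if (stat@kind == "gaussian") {
    res <- withCallingHandlers(
      fisherZTest(stat@R, stat@n, i, j, S),
      warning = function(w) invokeRestart("muffleWarning"))
    list(estimate = res$estimate, p = res$p)
  } else {
    res <- withCallingHandlers(
      gSquareTest(stat@data, i, j, S),
      warning = function(w) invokeRestart("muffleWarning"))
    list(estimate = res$estimate, p = res$p)
  }
}
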