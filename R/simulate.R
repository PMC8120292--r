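#' SimulationSpec: ground truth and parameters for data generation
#'
#' Describes a linear-Gaussian structural-equation simulation from a known
#' causal graph: per-edge coefficients, per-node intercepts, means and noise
#' standard deviations for phenotypes, Hardy-Weinberg allele frequencies for
#' genotype nodes, sample size, seed, and optional outlier-injection and
#' discretization policies.
#'
#' @slot truth the ground-truth [CausalGraph-class] (may contain undirected
#'   edges; its directed part must be acyclic and no phenotype may parent a
#'   genotype).
#' @slot coef p x p matrix; \code{coef[i, j]} is the structural coefficient
#'   for edge i -> j.
#' @slot gamma0 per-node intercept.
#' @slot mean per-node marginal mean for parentless phenotypes.
#' @slot sigma per-node noise standard deviation.
#' @slot q per-node alternative-allele frequency (used for genotype nodes).
#' @slot n sample size.
#' @slot seed RNG seed (NA for none).
#' @slot nOutliers,outlierMagnitude outlier-injection policy.
#' @slot discretizeLevels 0 for continuous output, otherwise the number of
#'   quantile-bin categories.
#' @seealso [simulationSpec()], [simulateDagData()]
#' @export
setClass("SimulationSpec",
         representation(truth = "CausalGraph", coef = "matrix",
                        gamma0 = "numeric", mean = "numeric",
                        sigma = "numeric", q = "numeric", n = "numeric",
                        seed = "numeric", nOutliers = "numeric",
                        outlierMagnitude = "numeric",
                        discretizeLevels = "numeric"))

setValidity("SimulationSpec", function(object) {
  msg <- character()
  if (object@n < 1) msg <- c(msg, "n must be >= 1")
  if (any(object@q < 0 | object@q > 1)) msg <- c(msg, "q must be in [0, 1]")
  if (any(object@sigma <= 0)) msg <- c(msg, "sigma must be positive")
  A <- object@truth@adj
  kinds <- object@truth@kinds
  dirA <- A * (1 - t(A))  # strictly directed part
  if (.hasDirectedCycle(dirA)) msg <- c(msg, "directed part must be acyclic")
  if (any(dirA[kinds == "phenotype", kinds == "genotype"] == 1))
    msg <- c(msg, "a phenotype cannot be a parent of a genotype")
  if (length(msg)) msg else TRUE
})

.hasDirectedCycle <- function(dirA) {
  p <- nrow(dirA)
  indeg <- colSums(dirA)
  active <- rep(TRUE, p)
  for (k in seq_len(p)) {
    v <- which(active & indeg == 0)
    if (!length(v)) return(any(active))
    v <- v[1]
    active[v] <- FALSE
    indeg <- indeg - dirA[v, ]
  }
  any(active)
}

#' Create a simulation specification
#'
#' Defaults follow the standard study conditions for this class of
#' simulation: allele frequency \code{q = 0.45}, zero intercepts and means,
#' unit noise standard deviation, sample size \code{n = 1000}, and a common
#' signal strength \code{gamma} on every edge (the usual sweep values being
#' 1.0, 0.5 and 0.2 for strong, moderate and weak signal).
#'
#' @param truth ground-truth [CausalGraph-class].
#' @param gamma scalar edge coefficient applied to every edge, or a full
#'   p x p coefficient matrix.
#' @param gamma0,mean,sigma,q per-node values, recycled from scalars.
#' @param n sample size.
#' @param seed RNG seed (NULL for none).
#' @param nOutliers,outlierMagnitude outlier policy applied after
#'   generation (see [injectOutliers()]).
#' @param discretizeLevels 0 to keep data continuous, else the number of
#'   categories for [discretizeData()].
#' @return a [SimulationSpec-class].
#' @export
simulationSpec <- function(truth, gamma = 1, gamma0 = 0, mean = 0,
                           sigma = 1, q = 0.45, n = 1000, seed = NULL,
                           nOutliers = 0, outlierMagnitude = 10,
                           discretizeLevels = 0) {
  p <- length(truth@labels)
  coef <- if (is.matrix(gamma)) gamma else gamma * (truth@adj != 0)
  new("SimulationSpec", truth = truth, coef = coef,
      gamma0 = rep_len(gamma0, p), mean = rep_len(mean, p),
      sigma = rep_len(sigma, p), q = rep_len(q, p), n = n,
      seed = if (is.null(seed)) NA_real_ else as.numeric(seed),
      nOutliers = nOutliers, outlierMagnitude = outlierMagnitude,
      discretizeLevels = discretizeLevels)
}

#' Simulate genotypes under Hardy-Weinberg equilibrium
#'
#' Draws of 0/1/2 (copies of the alternative allele) from the multinomial
#' with probabilities \eqn{(1-q)^2, 2q(1-q), q^2}.
#'
#' @param n number of samples.
#' @param q alternative-allele frequency in [0, 1].
#' @return integer vector in {0, 1, 2}.
#' @export
simulateGenotype <- function(n, q) {
  sample(0:2, n, replace = TRUE,
         prob = c((1 - q)^2, 2 * q * (1 - q), q^2))
}

#' Simulate data from a ground-truth graph
#'
#' Nodes are generated in topological order. Parentless genotype nodes are
#' drawn from the Hardy-Weinberg multinomial; any node with parents --
#' including a variant with variant parents -- follows the conditional
#' normal below, so the strength of variant-variant edges scales with the
#' same coefficient as every other edge. Parentless phenotypes are
#' N(mean, sigma^2); a phenotype with parents is N(gamma0 + sum of
#' coefficient-weighted parent values, sigma^2). An undirected
#' genotype-genotype edge is given a random direction (one draw per edge
#' per dataset); an undirected phenotype-phenotype edge is treated as a
#' per-sample 50:50 mixture of the two directions: data are generated under
#' both orientations and, independently for each sample, one orientation's
#' values are kept. Optional outlier injection and discretization are
#' applied afterwards when the spec requests them.
#'
#' @param spec a [SimulationSpec-class].
#' @return numeric matrix n x p with columns named and ordered as the truth
#'   graph's labels. When outliers were injected the row indices are
#'   attached as \code{attr(, "outliers")}.
#' @export
simulateDagData <- function(spec) {
  if (!is.na(spec@seed)) set.seed(spec@seed)
  g <- spec@truth
  A <- g@adj
  labs <- g@labels
  kinds <- g@kinds
  p <- length(labs)
  n <- spec@n
  geno <- kinds == "genotype"

  ## undirected edges by endpoint kinds
  undirVV <- list(); undirTT <- list()
  if (p >= 2) for (i in seq_len(p - 1)) for (j in seq(i + 1L, p)) {
    if (A[i, j] == 1 && A[j, i] == 1) {
      if (geno[i] && geno[j]) undirVV[[length(undirVV) + 1L]] <- c(i, j)
      else if (!geno[i] && !geno[j]) undirTT[[length(undirTT) + 1L]] <- c(i, j)
      else if (geno[i]) A[j, i] <- 0L  # PMR: direct toward the phenotype
      else A[i, j] <- 0L
    }
  }
  ## random direction per variant-variant edge
  for (e in undirVV) {
    if (runif(1) < 0.5) A[e[1], e[2]] <- 0L else A[e[2], e[1]] <- 0L
  }
  if (length(undirTT) > 12)
    stop("too many undirected phenotype-phenotype edges for mixture ",
         "simulation (max 12)")

  data <- matrix(NA_real_, n, p, dimnames = list(NULL, labs))

  ## genotype block first: genotypes never descend from phenotypes
  genoIdx <- which(geno)
  dirA <- A * (1 - t(A))
  for (v in .topoOrder(dirA, genoIdx)) {
    par <- which(dirA[, v] == 1)
    if (!length(par)) {
      data[, v] <- simulateGenotype(n, spec@q[v])
    } else {
      ## a variant with variant parents follows the conditional normal,
      ## like any other node with parents
      data[, v] <- spec@gamma0[v] +
        as.vector(data[, par, drop = FALSE] %*% spec@coef[par, v]) +
        rnorm(n, 0, spec@sigma[v])
    }
  }

  ## per-sample mixture over orientations of undirected phenotype edges
  k <- length(undirTT)
  combo <- if (k) {
    flips <- matrix(runif(n * k) < 0.5, n, k)
    as.integer(flips %*% 2^(seq_len(k) - 1))
  } else rep(0L, n)
  phenIdx <- which(!geno)
  for (cmb in sort(unique(combo))) {
    rows <- which(combo == cmb)
    Ac <- A
    if (k) for (e in seq_len(k)) {
      ij <- undirTT[[e]]
      if (bitwAnd(cmb, bitwShiftL(1L, e - 1L)) > 0)
        Ac[ij[2], ij[1]] <- 0L  # i -> j
      else
        Ac[ij[1], ij[2]] <- 0L  # j -> i
    }
    dirAc <- Ac * (1 - t(Ac))
    for (v in .topoOrder(dirAc, phenIdx)) {
      par <- which(dirAc[, v] == 1)
      if (!length(par)) {
        data[rows, v] <- rnorm(length(rows), spec@mean[v], spec@sigma[v])
      } else {
        data[rows, v] <- spec@gamma0[v] +
          as.vector(data[rows, par, drop = FALSE] %*% spec@coef[par, v]) +
          rnorm(length(rows), 0, spec@sigma[v])
      }
    }
  }

  if (spec@nOutliers > 0) {
    out <- injectOutliers(data, spec@nOutliers, spec@outlierMagnitude,
                          kinds = kinds)
    data <- out$data
    attr(data, "outliers") <- out$outliers
  }
  if (spec@discretizeLevels >= 2)
    data <- discretizeData(data, spec@discretizeLevels)
  data
}

## topological order of `subset` under the directed adjacency dirA,
## breaking ties by canonical index order
.topoOrder <- function(dirA, subset) {
  sub <- dirA[subset, subset, drop = FALSE]
  if (.hasDirectedCycle(sub)) stop("directed part of the truth is cyclic")
  ord <- integer()
  indeg <- colSums(sub)
  active <- rep(TRUE, length(subset))
  while (any(active)) {
    v <- which(active & indeg == 0)[1]
    ord <- c(ord, subset[v])
    active[v] <- FALSE
    indeg <- indeg - sub[v, ]
  }
  ord
}

#' Inject gross outliers into the phenotype columns
#'
#' Picks \code{k} distinct samples uniformly at random and replaces their
#' phenotype values by draws centred \code{magnitude} column standard
#' deviations above the column mean (one fresh draw per cell, sd equal to
#' the column sd). Genotype columns are untouched.
#'
#' @param data numeric matrix (samples x variables).
#' @param k number of outlying samples (\code{k <= nrow(data)}).
#' @param magnitude shift in units of the column standard deviation
#'   (default 10).
#' @param kinds per-column kinds; columns with kind \code{"genotype"} are
#'   left alone (default: all phenotype).
#' @return list with the contaminated \code{data} and the sorted
#'   \code{outliers} row indices.
#' @export
injectOutliers <- function(data, k, magnitude = 10, kinds = NULL) {
  n <- nrow(data)
  if (k > n) stop("k must not exceed the number of samples")
  if (k == 0) return(list(data = data, outliers = integer()))
  if (is.null(kinds)) kinds <- rep("phenotype", ncol(data))
  rows <- sort(sample.int(n, k))
  for (cc in which(kinds == "phenotype")) {
    s <- sd(data[, cc])
    data[rows, cc] <- rnorm(k, mean(data[, cc]) + magnitude * s, s)
  }
  list(data = data, outliers = rows)
}

#' Discretize continuous columns into quantile bins
#'
#' Per-column quantile binning into \code{levels} categories coded
#' 0..levels-1; with distinct values the category counts differ by at most
#' one. A constant column collapses to a single category with a warning.
#'
#' @param data numeric matrix.
#' @param levels number of categories (>= 2).
#' @return integer matrix of category codes.
#' @export
discretizeData <- function(data, levels) {
  if (levels < 2) stop("levels must be >= 2")
  out <- matrix(0L, nrow(data), ncol(data), dimnames = dimnames(data))
  for (cc in seq_len(ncol(data))) {
    x <- data[, cc]
    if (length(unique(x)) == 1) {
      warning("constant column ", cc, " collapses to a single category")
      next
    }
    br <- unique(quantile(x, probs = seq(0, 1, length.out = levels + 1)))
    out[, cc] <- cut(x, breaks = br, include.lowest = TRUE,
                     labels = FALSE) - 1L
  }
  out
}
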