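.londBeta <- function(state, t) {
  state@alpha * state@normConst / (t * log(max(t, 2))^2)
}

#' Next significance threshold in the online stream
#'
#' Consumes one position of the LOND sequence and returns the threshold for
#' the upcoming test, \eqn{\alpha_t = \beta_t (D_{t-1} + 1)}: the per-test
#' level scales with one plus the number of discoveries made so far, so
#' thresholds shrink along a null stream but recover with each rejection.
#' With a fixed-level state the threshold is always \code{alpha}.
#'
#' @param state a [LondState-class].
#' @return list with \code{threshold} and the updated \code{state}.
#' @seealso [recordResult()]
#' @export
nextThreshold <- function(state) {
  t <- state@t + 1
  state@t <- t
  thr <- if (state@fixed) state@alpha
         else .londBeta(state, t) * (state@nDiscoveries + 1)
  list(threshold = thr, state = state)
}

#' Record a test outcome in the online stream
#'
#' A p-value at or below the threshold is a rejection (a discovery), which
#' increments the discovery count used by later thresholds.
#'
#' @param state a [LondState-class] (as updated by [nextThreshold()]).
#' @param p observed p-value.
#' @param threshold the threshold returned by [nextThreshold()] for this
#'   test.
#' @return list with logical \code{rejected} and the updated \code{state}.
#' @export
recordResult <- function(state, p, threshold) {
  rejected <- p <= threshold
  if (rejected && !state@fixed)
    state@nDiscoveries <- state@nDiscoveries + 1
  list(rejected = rejected, state = state)
}
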