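# Initial-state construction: ideal states (dye miss not yet applied), the
# initial joint with the first observation, and the greedy top-N_B search.

#' Ideal initial states
#'
#' One ideal state per distinct dye count vector among the database's dye
#' sequences; its probability is the summed dye-sequence prior.  Ideal states
#' have `K = N` and an empty removed prefix.
#'
#' @param db A [build_database()] result.
#' @return A data.frame with a list column `N` (count vectors) and `prob`;
#'   probabilities sum to 1.
#' @export
ideal_states <- function(db) {
  r <- pb_ideal_states(db_ptr(db))
  data.frame(N = I(lapply(r$N, as.integer)), prob = exp(r$logp))
}

#' Log joint probability of an initial state
#'
#' `log[P_DyeMiss(K | N) * P(S_0^I.N = N)]`: the ideal-state probability of
#' the count vector `N` times the binomial dye-miss probability of `K`.
#'
#' @param db A [build_database()] result.
#' @param s A [pb_state()] with empty `R`.
#' @param params A [probeam_params()].
#' @return Log probability (`-Inf` when `N` matches no dye sequence).
#' @export
initial_joint_logprob <- function(db, s, params) {
  stopifnot(s$R == "")
  ideal <- ideal_states(db)
  hit <- vapply(ideal$N, identical, logical(1), y = as.integer(s$N))
  if (!any(hit)) return(-Inf)
  log(ideal$prob[hit]) + log(dye_miss_prob(s$K, s$N, params))
}

#' Initial-state scores for the greedy search
#'
#' `p_alpha` is the full log score of an initial state under the first
#' observation: ideal-state probability + dye-miss probability + observation
#' log-likelihood.  `p_upper` drops the dye-miss term and hence upper-bounds
#' `p_alpha`; it is the bound that lets the search skip dominated nodes.
#'
#' @inheritParams initial_joint_logprob
#' @param x_0 First observation vector.
#' @return Log score.
#' @export
p_alpha <- function(db, s, x_0, params) {
  stopifnot(s$R == "")
  ideal <- ideal_states(db)
  hit <- vapply(ideal$N, identical, logical(1), y = as.integer(s$N))
  if (!any(hit)) return(-Inf)
  # same summation order as the compiled search
  (log(ideal$prob[hit]) + obs_logprob(x_0, s$K, params)) +
    log(dye_miss_prob(s$K, s$N, params))
}

#' @rdname p_alpha
#' @export
p_upper <- function(db, s, x_0, params) {
  stopifnot(s$R == "")
  ideal <- ideal_states(db)
  hit <- vapply(ideal$N, identical, logical(1), y = as.integer(s$N))
  if (!any(hit)) return(-Inf)
  log(ideal$prob[hit]) + obs_logprob(x_0, s$K, params)
}

#' Greedy search for the most likely initial states
#'
#' Returns exactly the `n_beam` initial states maximizing `p_alpha` under the
#' first observation.  Ideal states are ordered by the Euclidean distance
#' `||x_0 / mu - N||`; for each, a breadth-first search over deviations from
#' the bounded optimal count `K^opt` evaluates candidates, skipping a node
#' (and the deviations beyond it) only when the `p_upper` bound proves it
#' cannot enter the current top list -- so the result is identical to
#' exhaustive enumeration.  Ties at the cutoff keep the canonically smallest
#' state keys.
#'
#' @param db A [build_database()] result.
#' @param x_0 First observation vector.
#' @param params A [probeam_params()]; `n_beam` may be `Inf` to keep all.
#' @return A `pb_beam`: list of `states`, normalized `logw`, and the raw
#'   `log_palpha` scores.
#' @export
greedy_initial_beam <- function(db, x_0, params) {
  stopifnot(length(x_0) == params$n_colors)
  r <- pb_greedy_initial(db_ptr(db), as.numeric(x_0), unclass(params))
  structure(list(states = lapply(r$states, function(s) {
    class(s) <- "pb_state"
    s
  }), logw = r$logw, log_palpha = r$log_palpha, t = 0L),
  class = "pb_beam")
}

#' @export
print.pb_beam <- function(x, ...) {
  cat(sprintf("beam of %d state(s) at cycle %d\n", length(x$states), x$t))
  n <- min(5L, length(x$states))
  for (i in seq_len(n))
    cat(sprintf("  %-30s w=%.4g\n", state_key(x$states[[i]]), exp(x$logw[i])))
  if (length(x$states) > n) cat("  ...\n")
  invisible(x)
}
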