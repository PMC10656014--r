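# One-cycle transition model, factored into three independent phenomena:
# detachment -> dye loss -> Edman degradation.  States with K = 0 (detached
# or fully dark) are absorbing: they transition to themselves with
# probability 1 through every phase.

as_transitions <- function(x) {
  keep <- which(as.numeric(x$prob) > 0)
  structure(list(states = lapply(x$states[keep], function(s) {
    class(s) <- "pb_state"
    s
  }), prob = as.numeric(x$prob)[keep], pruned = isTRUE(x$pruned)),
  class = "pb_transitions")
}

#' @export
print.pb_transitions <- function(x, ...) {
  cat(sprintf("%d successor state(s), total mass %.6f%s\n",
              length(x$states), sum(x$prob),
              if (x$pruned) " (pruned)" else ""))
  invisible(x)
}

#' Detachment phase
#'
#' A state with attached fluorophores detaches with probability `p_d`
#' (zeroing `K`) and survives otherwise; `K = 0` states are absorbing.
#'
#' @param s A [pb_state()].
#' @param params A [probeam_params()].
#' @return A transition list: `states` (list of successors) and `prob`
#'   (matching probabilities, summing to 1).
#' @export
detach_step <- function(s, params) {
  if (all(s$K == 0L)) {
    out <- list(states = list(s), prob = 1)
  } else {
    out <- list(states = list(detach(s), s),
                prob = c(params$p_d, 1 - params$p_d))
  }
  as_transitions(out)
}

#' Dye-miss probability
#'
#' Probability that `K` fluorophores attached out of the ideal `N`, each
#' missing independently with rate `m`: a per-color binomial product.
#'
#' @param K,N Integer count vectors, `K <= N` componentwise.
#' @param params A [probeam_params()].
#' @return A probability.
#' @export
dye_miss_prob <- function(K, N, params) {
  if (any(K > N) || any(K < 0)) stop("dye_miss_prob requires 0 <= K <= N")
  prod(dbinom(K, N, 1 - params$m))
}

#' Dye-loss phase
#'
#' Successors over all `K' <= K`, each with the per-color binomial loss
#' probability (per-fluorophore loss rate `l`).  When an observation `x_t`
#' is supplied, successors failing [prune_pass()] are dropped and their mass
#' is discarded (not renormalized), matching a pruned forward pass;
#' renormalization happens only at the beam level.
#'
#' @param s A [pb_state()].
#' @param x_t Optional intensity vector enabling pruning; `NULL` disables it.
#' @param params A [probeam_params()].
#' @return A transition list (`pruned` records whether any mass was dropped).
#' @export
dye_loss_step <- function(s, x_t = NULL, params) {
  x <- if (is.null(x_t)) NULL else as.numeric(x_t)
  as_transitions(pb_dye_loss_step(unclass(s), x, unclass(params)))
}

#' Probability that the front residue of color i carries its fluorophore
#'
#' With `K_i` dyes over `N_i` exchangeable labelable residues, the chance
#' the next-removed residue of color `i` still carries a dye is `K_i / N_i`.
#'
#' @param s A [pb_state()].
#' @param i 0-based color index with `N_i >= 1`.
#' @return A probability.
#' @export
p_dye_attached <- function(s, i) {
  j <- i + 1L
  if (j < 1L || j > length(s$N) || s$N[j] < 1L)
    stop("p_dye_attached requires N_i >= 1")
  s$K[j] / s$N[j]
}

#' Marginal removal probability of the next symbol
#'
#' Given the state's consistency set `eta(N, R)`, the probability that the
#' next removed symbol is `a`, with the dye-sequence prior renormalized over
#' the set.  Sums to 1 over `"."` and the colors.
#'
#' @param db A [build_database()] result.
#' @param s A [pb_state()].
#' @param a Optional symbol (`"."` or a color digit); when `NULL` the full
#'   named vector is returned.
#' @return A probability, or a named vector over symbols.
#' @export
p_removal <- function(db, s, a = NULL) {
  pr <- pb_removal_probs(db_ptr(db), as.integer(s$N), s$R)
  names(pr) <- c(".", as.character(seq_len(db$n_colors) - 1L))
  if (is.null(a)) return(pr)
  stopifnot(a %in% names(pr))
  pr[[a]]
}

#' Edman degradation phase
#'
#' With probability `e` the cycle fails and the state is unchanged.
#' Otherwise the next symbol `a` is removed with probability
#' `p_removal(db, s, a)`: a `"."` only lengthens `R`; a color `i` decrements
#' `N_i` and, with probability `K_i / N_i`, also removes the attached dye
#' (decrementing `K_i`).
#'
#' @inheritParams p_removal
#' @param params A [probeam_params()].
#' @return A transition list; probabilities sum to 1.
#' @export
edman_step <- function(db, s, params) {
  as_transitions(pb_edman_step(db_ptr(db), unclass(s), unclass(params)))
}

#' Full one-cycle transition
#'
#' Composition detachment -> dye loss -> Edman degradation, merging duplicate
#' successors by summing probabilities.  Without pruning (`x_t = NULL`) the
#' total mass is 1.
#'
#' @inheritParams dye_loss_step
#' @param db A [build_database()] result.
#' @return A transition list.
#' @export
one_cycle_transitions <- function(db, s, x_t = NULL, params) {
  x <- if (is.null(x_t)) NULL else as.numeric(x_t)
  as_transitions(pb_one_cycle(db_ptr(db), unclass(s), x, unclass(params)))
}
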