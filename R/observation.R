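#' Effective intensity standard deviation
#'
#' With `K_i` independent fluorophores attached plus background noise the
#' variances add: `sqrt(K_i * sigma^2 + sigma_b^2)`.
#'
#' @param K_i Attached fluorophore count(s); vectorized.
#' @param params A [probeam_params()].
#' @return Standard deviation(s), intensity units.
#' @export
sigma_eff <- function(K_i, params) {
  stopifnot(all(K_i >= 0))
  sqrt(K_i * params$sigma^2 + params$sigma_b^2)
}

#' Observation log-probability of one intensity vector
#'
#' Per-color independent Gaussian emissions: color `i` is
#' `Normal(K_i * mu, sigma_eff(K_i))`.  Depends on the state only through `K`.
#'
#' @param x_t Intensity vector, length `n_colors`.
#' @param K Attached fluorophore counts, length `n_colors`.
#' @param params A [probeam_params()].
#' @return Log density (sum over colors).
#' @export
obs_logprob <- function(x_t, K, params) {
  stopifnot(length(x_t) == params$n_colors, length(K) == params$n_colors)
  pb_obs_logprob(as.numeric(x_t), as.integer(K), unclass(params))
}

#' Bounded integer optimum of the per-color emission density
#'
#' For each color, the integer `K_i` in `[0, N_bound_i]` maximizing the
#' Gaussian emission density of `x_i`; found by local search around
#' `round(x_i / mu)`, which is exact because the density is unimodal in
#' `K_i`.  Ties break toward the smaller count.
#'
#' @param x_t Intensity vector.
#' @param N_bound Per-color upper bounds (the state's `N`).
#' @param params A [probeam_params()].
#' @return Integer vector `K^opt`, componentwise in `[0, N_bound]`.
#' @export
k_opt <- function(x_t, N_bound, params) {
  stopifnot(length(x_t) == length(N_bound), all(N_bound >= 0))
  pb_kopt(as.numeric(x_t), as.integer(N_bound), unclass(params))
}

#' Dye-loss pruning test
#'
#' Passes when, for every color, the observation deviates from `K_i * mu` by
#' at most `h` effective standard deviations (boundary inclusive).  Used to
#' discard dye-loss successor counts far from the observation.
#'
#' @param x_t Intensity vector.
#' @param K Candidate attached counts.
#' @param params A [probeam_params()]; `h = Inf` always passes.
#' @return `TRUE`/`FALSE`.
#' @export
prune_pass <- function(x_t, K, params) {
  pb_prune_pass(as.numeric(x_t), as.integer(K), unclass(params))
}
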