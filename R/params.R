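#' Model parameters for the fluorosequencing process
#'
#' Bundles the seven process rates / noise levels together with the
#' experiment geometry (number of colors and Edman cycles) and the decoder
#' tuning knobs (beam width, pruning threshold).
#'
#' @param n_colors Number of fluorophore colors `N_D` (>= 1).
#' @param n_cycles Number of Edman degradation cycles `N_C` (>= 0); a read has
#'   `n_cycles + 1` observations (one before the first cycle).
#' @param e Edman degradation failure rate.
#' @param l Per-cycle dye loss rate (same for every color).
#' @param m Missing-fluorophore (dye miss) rate at attachment.
#' @param p_d Per-cycle whole-peptide detach probability.
#' @param mu Mean fluorophore intensity (intensity units).
#' @param sigma Standard deviation of a single fluorophore's intensity.
#' @param sigma_b Standard deviation of the background noise.
#' @param h Pruning threshold for the dye-loss successor test, in units of the
#'   effective standard deviation; `Inf` disables pruning.
#' @param n_beam Beam width `N_B`: number of highest-weight states kept per
#'   cycle; `Inf` keeps every reachable state.
#'
#' @return An object of class `pb_params` (a validated list).
#' @examples
#' p <- probeam_params(n_colors = 3, n_cycles = 10)
#' p$sigma_b
#' @export
probeam_params <- function(n_colors, n_cycles,
                           e = 0.06, l = 0.05, m = 0.07, p_d = 0.05,
                           mu = 1, sigma = 0.16, sigma_b = 0.0067,
                           h = 5, n_beam = 60) {
  n_colors <- as.integer(n_colors)
  n_cycles <- as.integer(n_cycles)
  stopifnot(length(n_colors) == 1L, n_colors >= 1L,
            length(n_cycles) == 1L, n_cycles >= 0L)
  for (r in list(e = e, l = l, m = m, p_d = p_d)) {
    if (!is.numeric(r) || length(r) != 1L || r < 0 || r > 1)
      stop("rates e, l, m, p_d must be single values in [0, 1]")
  }
  stopifnot(mu > 0, sigma >= 0, sigma_b > 0, h > 0, n_beam >= 1)
  structure(list(e = e, l = l, m = m, p_d = p_d,
                 mu = mu, sigma = sigma, sigma_b = sigma_b,
                 h = h, n_colors = n_colors, n_cycles = n_cycles,
                 n_beam = n_beam),
            class = "pb_params")
}

#' @export
print.pb_params <- function(x, ...) {
  cat("fluorosequencing model parameters\n")
  cat(sprintf("  colors N_D = %d, cycles N_C = %d, beam width N_B = %s\n",
              x$n_colors, x$n_cycles, format(x$n_beam)))
  cat(sprintf("  e = %g, l = %g, m = %g, p_d = %g\n", x$e, x$l, x$m, x$p_d))
  cat(sprintf("  mu = %g, sigma = %g, sigma_b = %g, h = %s\n",
              x$mu, x$sigma, x$sigma_b, format(x$h)))
  invisible(x)
}
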