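#' Sample random physically consistent catalytic cycles
#'
#' Draws rate constants log-uniformly, then rescales one reverse constant
#' so that the cycle's thermodynamic force X/RT lands exactly on a target
#' drawn uniformly from `force_window`. Every sampled scheme therefore has
#' J > 0, satisfies detailed-balance consistency (Haldane check) by
#' construction, and carries concentrations consistent with its
#' second-order binding constants. Defaults emulate the observed
#' compilation: forces X/RT between 1 and 23, rate constants spanning
#' 1e-2..1e6 s^-1, substrate 1e-6..1e-2 M with product at \[S\]/10.
#'
#' @param n number of schemes.
#' @param n_states 2, 3 or 4.
#' @param seed integer seed; the sampler is bit-reproducible for a fixed
#'   seed and leaves the caller's RNG state untouched.
#' @param log10_rate_range length-2 log10 range of the rate constants
#'   (s^-1).
#' @param force_window length-2 positive window for X/RT.
#' @param log10_conc_range length-2 log10 range for \[S\] (mol/L).
#' @param product_ratio \[P\]/\[S\]; default 1/10.
#' @param max_retries retry budget per scheme before failing: a draw is
#'   rejected when the force-fixing rescale pushes the adjusted constant
#'   outside 1e-12..1e12 s^-1.
#' @return for `sample_schemes`, a list of [reaction_scheme()]; for
#'   `sample_scheme`, a single one.
#' @export
sample_schemes <- function(n, n_states = 3, seed,
                           log10_rate_range = c(-2, 6),
                           force_window = c(1, 23),
                           log10_conc_range = c(-6, -2),
                           product_ratio = 0.1,
                           max_retries = 100) {
  stopifnot(n >= 1, n_states %in% 2:4,
            length(force_window) == 2, all(force_window > 0),
            force_window[2] > force_window[1],
            diff(log10_rate_range) > 0, diff(log10_conc_range) > 0)
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      for (try in seq_len(max_retries)) {
        k <- 10^stats::runif(2L * n_states, log10_rate_range[1],
                             log10_rate_range[2])
        target <- stats::runif(1, force_window[1], force_window[2])
        # rescale the last reverse constant so ln(prod odd / prod even) = target
        last_even <- 2L * n_states
        odd <- k[seq(1L, last_even, 2L)]
        even <- k[seq(2L, last_even, 2L)]
        k[last_even] <- k[last_even] *
          (prod(odd) / prod(even)) / exp(target)
        if (k[last_even] < 1e-12 || k[last_even] > 1e12) next
        s_conc <- 10^stats::runif(1, log10_conc_range[1], log10_conc_range[2])
        p_conc <- s_conc * product_ratio
        return(reaction_scheme(
          k, substrate_conc = s_conc, product_conc = p_conc,
          k1_second_order = k[1] / s_conc,
          k_rev_bind_second_order = k[last_even] / p_conc,
          label = sprintf("synthetic_%dstate_%03d", n_states, i)))
      }
      stop("could not sample a scheme inside the force window after ",
           max_retries, " retries; widen the rate range or the window")
    })
  })
}

#' @rdname sample_schemes
#' @export
sample_scheme <- function(n_states = 3, seed, ...) {
  sample_schemes(1, n_states = n_states, seed = seed, ...)[[1]]
}

#' Generate a power-law ensemble with log-normal noise
#'
#' Draws pairs following `y = alpha * x^beta * exp(e)`, `e ~ N(0, sd^2)`,
#' with x log-uniform over `log10_x_range`. With `sd = 0` the pairs lie
#' exactly on the power law; downstream log-log regression then recovers
#' `(alpha, beta)` to machine precision. Used for parameter-recovery and
#' coverage experiments on the scaling-law fit.
#'
#' @param n number of points (>= 3); ignored when `x` is supplied.
#' @param alpha,beta power-law parameters.
#' @param sd standard deviation of the log-scale (natural log) noise.
#' @param log10_x_range length-2 log10 range of x.
#' @param seed integer seed.
#' @param x optional explicit positive x values instead of log-uniform
#'   draws.
#' @return data.frame with columns `x`, `y`.
#' @export
generate_power_law_ensemble <- function(n, alpha, beta, sd = 0,
                                        log10_x_range = c(-4, 9), seed,
                                        x = NULL) {
  stopifnot(sd >= 0, alpha > 0, diff(log10_x_range) > 0)
  if (!is.null(x)) {
    stopifnot(all(x > 0))
    n <- length(x)
  }
  stopifnot(n >= 3)
  with_seed(seed, {
    if (is.null(x))
      x <- 10^stats::runif(n, log10_x_range[1], log10_x_range[2])
    y <- alpha * x^beta * exp(stats::rnorm(n, 0, sd))
    data.frame(x = x, y = y)
  })
}
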