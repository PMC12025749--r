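#' Shifted Box-Muller noise multiplier
#'
#' The noise protocols multiply rate constants by
#' `g = sqrt(-2 ln s1) * cos(2 pi s2) + 1` with s1, s2 uniform on (0, 1):
#' a standard-normal deviate shifted by +1, so that g - 1 ~ N(0, 1) and
#' positive multipliers predominate. Only positive g values are consumed
#' by the simulations; a non-positive draw repeats the previous accepted
#' step (see [run_forward_variations()]).
#'
#' `box_muller_shift()` is the deterministic transform; `draw_noise()`
#' draws the uniforms from the current RNG stream and returns the sample.
#'
#' @param s1,s2 uniforms on (0, 1).
#' @return `box_muller_shift`: numeric g. `draw_noise`: list with `s1`,
#'   `s2`, `g`.
#' @examples
#' box_muller_shift(exp(-2), 0)    # 3
#' box_muller_shift(0.37, 0.25)    # 1: cos(pi/2) = 0
#' @export
box_muller_shift <- function(s1, s2) {
  stopifnot(all(s1 > 0), all(s1 < 1), all(s2 >= 0), all(s2 < 1))
  sqrt(-2 * log(s1)) * cos(2 * pi * s2) + 1
}

#' @rdname box_muller_shift
#' @export
draw_noise <- function() {
  s1 <- stats::runif(1)
  s2 <- stats::runif(1)
  list(s1 = s1, s2 = s2, g = box_muller_shift(s1, s2))
}

# Draw until a positive multiplier appears; used for the first step of a
# trace, where the "repeat the previous row" rule has no previous row.
draw_positive_g <- function() {
  repeat {
    g <- draw_noise()$g
    if (g > 0) return(g)
  }
}

#' Forward-variation transform: uniform rescaling of the whole cycle
#'
#' Applies the same noise multiplier to every forward rate constant while
#' keeping every step equilibrium constant K_i = k(2i-1)/k(2i) fixed - the
#' two requirements jointly force multiplying every forward AND reverse
#' constant by g. Consequently K_m, all K_i, the force X/RT, the state
#' probabilities and their entropy are invariant, while k_cat, k_cat/K_m,
#' J and phi/RT scale by exactly g.
#'
#' @param scheme a [reaction_scheme()].
#' @param g positive multiplier.
#' @return the transformed [reaction_scheme()].
#' @export
forward_variation_step <- function(scheme, g) {
  stop_unless_scheme(scheme)
  if (!is.finite(g) || g <= 0) stop("'g' must be positive, got ", g)
  out <- scheme
  out$k <- scheme$k * g
  if (!is.na(out$k1_second_order))
    out$k1_second_order <- out$k1_second_order * g
  if (!is.na(out$k_rev_bind_second_order))
    out$k_rev_bind_second_order <- out$k_rev_bind_second_order * g
  out
}

#' Run the forward-variation noise protocol
#'
#' Simulates `n_steps` jumps among steady states: at each step one shifted
#' Box-Muller multiplier g is drawn and applied to all rate constants via
#' [forward_variation_step()]; steps whose draw is non-positive repeat the
#' previous accepted step (the first step redraws until positive). Along
#' the trace the Michaelis constant, step equilibrium constants, force,
#' probabilities and entropy stay fixed, so efficiency is exactly
#' proportional to dissipation (regression R^2 = 1 up to rounding) and the
#' maxima of k_cat, k_cat/K_m and phi/RT all land on the max-g step.
#'
#' @param scheme a [reaction_scheme()].
#' @param n_steps number of steps (conventionally 1000..30000).
#' @param seed integer seed.
#' @return object of class `simulation_trace`: data.frame with columns
#'   `step`, `g`, `kcat`, `efficiency`, `km`, `flux`, `force_rt`,
#'   `dissipation_rt`, `shannon_entropy`; attributes `protocol`, `seed`,
#'   `argmax` (step index of the maximal dissipation), `probabilities`
#'   (the invariant state distribution) and `base` (step-0 summary of the
#'   unperturbed scheme).
#' @export
run_forward_variations <- function(scheme, n_steps = 1000, seed) {
  stop_unless_scheme(scheme)
  stopifnot(n_steps >= 1)
  base_ss <- steady_state(scheme)
  base_pp <- performance_params(scheme)
  g <- with_seed(seed, {
    raw <- numeric(n_steps)
    raw[1] <- draw_positive_g()
    for (i in seq_len(n_steps)[-1]) {
      gi <- draw_noise()$g
      raw[i] <- if (gi > 0) gi else raw[i - 1]  # repeat previous row
    }
    raw
  })
  # every quantity recorded is homogeneous of degree 1 (or 0) in the rates
  trace <- data.frame(
    step = seq_len(n_steps), g = g,
    kcat = base_pp$kcat * g,
    efficiency = base_pp$efficiency * g,
    km = rep(base_pp$km, n_steps),
    flux = base_ss$flux * g,
    force_rt = rep(base_ss$force_rt, n_steps),
    dissipation_rt = base_ss$dissipation_rt * g,
    shannon_entropy = rep(base_ss$shannon_entropy, n_steps))
  structure(trace,
            protocol = "forward", seed = seed,
            argmax = which.max(trace$dissipation_rt),
            probabilities = base_ss$probabilities,
            base = list(performance = base_pp, steady_state = base_ss),
            class = c("simulation_trace", "data.frame"))
}

#' Trade-off transform: compensatory noise at fixed total force
#'
#' Perturbs the enzyme-substrate association step and the last
#' (product-dissociation) step compensatorily: K_1 -> g*K_1 and
#' K_last -> K_last/g, leaving every other step equilibrium constant and
#' hence the total force X/RT unchanged. In the default mode `"rates"` the
#' noise enters the forward rates (k1 -> g*k1, last odd constant divided
#' by g); mode `"reverse"` adjusts the corresponding reverse constants
#' instead (k2 -> k2/g, last even constant times g), a sensitivity-analysis
#' alternative with different dynamics but the same equilibrium shift.
#'
#' @param scheme a [reaction_scheme()].
#' @param g positive multiplier.
#' @param mode `"rates"` (default) or `"reverse"`.
#' @return the transformed [reaction_scheme()].
#' @export
tradeoff_transform <- function(scheme, g, mode = c("rates", "reverse")) {
  stop_unless_scheme(scheme)
  mode <- match.arg(mode)
  if (!is.finite(g) || g <= 0) stop("'g' must be positive, got ", g)
  k <- scheme$k
  n2 <- 2L * scheme$n_states
  if (mode == "rates") {
    k[1] <- k[1] * g
    k[n2 - 1L] <- k[n2 - 1L] / g
  } else {
    k[2] <- k[2] / g
    k[n2] <- k[n2] * g
  }
  out <- scheme
  out$k <- k
  if (mode == "rates" && !is.na(out$k1_second_order))
    out$k1_second_order <- out$k1_second_order * g
  if (mode == "reverse" && !is.na(out$k_rev_bind_second_order))
    out$k_rev_bind_second_order <- out$k_rev_bind_second_order * g
  out
}

# Per-step summaries of the trade-off transform over a vector of g values,
# evaluated elementwise (the transform only touches the first and last
# steps, so every quantity has a closed form in g). phi's numerator and the
# force are g-invariant; only the cycle denominator and the performance
# parameters move.
tradeoff_profile <- function(scheme, g, mode = c("rates", "reverse")) {
  mode <- match.arg(mode)
  n <- scheme$n_states
  net <- prod(fwd_k(scheme)) - prod(rev_k(scheme))
  force_rt <- log(prod(fwd_k(scheme)) / prod(rev_k(scheme)))
  s <- scheme$substrate_conc
  one <- rep(1, length(g))
  # perturbed constants as vectors over g; the rest stay scalar
  k <- as.list(scheme$k)
  if (mode == "rates") {
    k[[1]] <- scheme$k[1] * g
    k[[2L * n - 1L]] <- scheme$k[2L * n - 1L] / g
  } else {
    k[[2]] <- scheme$k[2] / g
    k[[2L * n]] <- scheme$k[2L * n] * g
  }
  if (n == 2L) {
    kcat <- k[[3]] * one
    eff <- k[[1]] * k[[3]] / (s * (k[[2]] + k[[3]]))
    d <- k[[1]] + k[[2]] + k[[3]] + k[[4]] * one
  } else if (n == 3L) {
    kcat <- k[[3]] * k[[5]] / (k[[3]] + k[[4]] + k[[5]])
    eff <- k[[1]] * k[[3]] * k[[5]] /
      (s * (k[[2]] * k[[4]] + k[[2]] * k[[5]] + k[[3]] * k[[5]]))
    d <- k[[1]] * (k[[3]] + k[[4]] + k[[5]]) +
      k[[2]] * k[[4]] + k[[2]] * k[[5]] + k[[3]] * k[[5]] +
      k[[6]] * (k[[2]] + k[[3]] + k[[4]])
  } else {
    kcat <- k[[3]] * k[[5]] * k[[7]] /
      (k[[3]] * k[[5]] + k[[3]] * k[[6]] + k[[3]] * k[[7]] +
       k[[4]] * k[[6]] + k[[4]] * k[[7]] + k[[5]] * k[[7]])
    eff <- k[[1]] * k[[3]] * k[[5]] * k[[7]] /
      (s * (k[[2]] * k[[4]] * k[[6]] + k[[2]] * k[[4]] * k[[7]] +
            k[[2]] * k[[5]] * k[[7]] + k[[3]] * k[[5]] * k[[7]]))
    d <- (k[[2]] * k[[4]] * k[[6]] + k[[2]] * k[[4]] * k[[7]] +
          k[[2]] * k[[5]] * k[[7]] + k[[3]] * k[[5]] * k[[7]]) +
         (k[[1]] * k[[5]] * k[[7]] + k[[4]] * k[[6]] * k[[8]] +
          k[[1]] * k[[4]] * k[[6]] + k[[1]] * k[[4]] * k[[7]]) +
         (k[[1]] * k[[3]] * k[[7]] + k[[2]] * k[[6]] * k[[8]] +
          k[[3]] * k[[6]] * k[[8]] + k[[1]] * k[[3]] * k[[6]]) +
         (k[[2]] * k[[4]] * k[[8]] + k[[1]] * k[[3]] * k[[5]] +
          k[[3]] * k[[5]] * k[[8]] + k[[2]] * k[[5]] * k[[8]])
  }
  flux <- net / d
  data.frame(g = g, kcat = kcat * one, efficiency = eff * one,
             flux = flux * one, force_rt = force_rt,
             dissipation_rt = flux * force_rt * one)
}

#' Locate the maximum-dissipation steady state under trade-off variations
#'
#' Searches over the trade-off multiplier g for the steady state with
#' maximal dissipation phi/RT at fixed total force. Two methods share the
#' contract that `phi_max >= phi(g = 1)` (the observed state is always a
#' candidate):
#' * `"stochastic"` draws `budget` shifted Box-Muller multipliers
#'   (positive draws only) and keeps the best - the protocol used to
#'   generate the packaged trade-off optima;
#' * `"grid"` is the deterministic oracle: a log-spaced scan of g over
#'   1e-3..1e3 refined by golden-section search ([stats::optimize()]) to
#'   relative tolerance 1e-6.
#'
#' A maximum sitting on the grid boundary is flagged (`boundary = TRUE`)
#' rather than silently returned; the conventional remedy is to raise the
#' substrate concentration and re-run.
#'
#' @param scheme a [reaction_scheme()].
#' @param mode trade-off mode, see [tradeoff_transform()].
#' @param method `"grid"` (default) or `"stochastic"`.
#' @param budget number of stochastic draws.
#' @param seed integer seed (stochastic method only).
#' @return list with `g_opt`, `phi_max` (s^-1), `optimal_scheme`,
#'   `optimal` (performance + flux at the optimum), `observed` (the same
#'   at g = 1), `boundary` flag, `method`, and for the stochastic method
#'   the candidate `trace` (class `simulation_trace`).
#' @export
find_max_dissipation <- function(scheme, mode = c("rates", "reverse"),
                                 method = c("grid", "stochastic"),
                                 budget = 30000, seed = NULL) {
  stop_unless_scheme(scheme)
  mode <- match.arg(mode)
  method <- match.arg(method)
  observed <- tradeoff_profile(scheme, 1, mode)
  trace <- NULL
  boundary <- FALSE
  if (method == "grid") {
    grid_g <- sort(unique(c(1, 10^seq(-3, 3, length.out = 121))))
    prof <- tradeoff_profile(scheme, grid_g, mode)
    best <- which.max(prof$dissipation_rt)
    lo <- grid_g[max(1L, best - 1L)]
    hi <- grid_g[min(length(grid_g), best + 1L)]
    opt <- stats::optimize(
      function(lg) tradeoff_profile(scheme, 10^lg, mode)$dissipation_rt,
      lower = log10(lo), upper = log10(hi), maximum = TRUE,
      tol = 1e-8)
    g_opt <- 10^opt$maximum
    phi_max <- opt$objective
    # keep g = 1 in the candidate set explicitly
    if (observed$dissipation_rt >= phi_max) {
      g_opt <- 1
      phi_max <- observed$dissipation_rt
    }
    boundary <- best == 1L || best == length(grid_g)
  } else {
    if (is.null(seed)) stop("the stochastic method requires a seed")
    g <- with_seed(seed, {
      raw <- numeric(budget)
      raw[1] <- draw_positive_g()
      for (i in seq_len(budget)[-1]) {
        gi <- draw_noise()$g
        raw[i] <- if (gi > 0) gi else raw[i - 1]
      }
      raw
    })
    prof <- tradeoff_profile(scheme, g, mode)
    prof <- cbind(step = seq_len(budget), prof)
    best <- which.max(prof$dissipation_rt)
    if (prof$dissipation_rt[best] >= observed$dissipation_rt) {
      g_opt <- g[best]
      phi_max <- prof$dissipation_rt[best]
    } else {
      g_opt <- 1
      phi_max <- observed$dissipation_rt
    }
    trace <- structure(prof, protocol = "tradeoff", seed = seed,
                       argmax = best,
                       class = c("simulation_trace", "data.frame"))
  }
  optimal_scheme <- tradeoff_transform(scheme, g_opt, mode)
  list(g_opt = g_opt, phi_max = phi_max,
       optimal_scheme = optimal_scheme,
       optimal = tradeoff_profile(scheme, g_opt, mode),
       observed = observed,
       boundary = boundary, method = method, mode = mode, trace = trace)
}

#' Classify a reaction as Eff- or Tur-type
#'
#' Compares the maximum-dissipation optimum with the observed state:
#' `"Eff"` when the optimal catalytic efficiency strictly exceeds the
#' observed one (trade-off variations can improve k_cat/K_m), `"Tur"`
#' otherwise (they can improve the turnover number instead). The two
#' classes are expected to be complementary in k_cat: an Eff reaction
#' should have optimal k_cat below the observed value and vice versa; a
#' violation of that implication triggers a warning, not an error.
#'
#' @param observed,optimal lists (or one-row data.frames) with
#'   `efficiency` and `kcat`.
#' @return `"Eff"` or `"Tur"`.
#' @export
classify_reaction <- function(observed, optimal) {
  label <- if (optimal$efficiency > observed$efficiency) "Eff" else "Tur"
  kcat_up <- optimal$kcat > observed$kcat
  if ((label == "Eff" && kcat_up) || (label == "Tur" && !kcat_up))
    warning("Eff/Tur efficiency and k_cat implications disagree: ",
            "optimal efficiency fold = ",
            signif(optimal$efficiency / observed$efficiency, 3),
            ", optimal k_cat fold = ",
            signif(optimal$kcat / observed$kcat, 3))
  label
}
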