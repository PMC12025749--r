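# Cycle denominator (sum of King-Altman directed-tree terms) shared by the
# net and one-way flux expressions.
cycle_denominator <- function(n_states, k) {
  switch(as.character(n_states),
    "2" = k[1] + k[2] + k[3] + k[4],
    "3" = k[1] * (k[3] + k[4] + k[5]) +
          k[2] * k[4] + k[2] * k[5] + k[3] * k[5] +
          k[6] * (k[2] + k[3] + k[4]),
    "4" = {
      # Directed-tree sums for each root state of the 4-cycle. The third
      # and fourth terms of s4 carry k8 (the product-rebinding constant):
      # the trees toward state 4 that keep the 1-4 edge route through k8.
      s1 <- k[2] * k[4] * k[6] + k[2] * k[4] * k[7] +
            k[2] * k[5] * k[7] + k[3] * k[5] * k[7]
      s2 <- k[1] * k[5] * k[7] + k[4] * k[6] * k[8] +
            k[1] * k[4] * k[6] + k[1] * k[4] * k[7]
      s3 <- k[1] * k[3] * k[7] + k[2] * k[6] * k[8] +
            k[3] * k[6] * k[8] + k[1] * k[3] * k[6]
      s4 <- k[2] * k[4] * k[8] + k[1] * k[3] * k[5] +
            k[3] * k[5] * k[8] + k[2] * k[5] * k[8]
      s1 + s2 + s3 + s4
    },
    stop("unsupported n_states = ", n_states))
}

#' Transition-rate matrix of a catalytic cycle
#'
#' Returns the n x n generator matrix Q of the cycle's master equation,
#' with Q\[j, i\] the rate of the i -> j transition and columns summing to
#' zero, so that dp/dt = Q p. Forward (counterclockwise) steps are the odd
#' rate constants, reverse steps the even ones; for the two-state cycle the
#' binding and release channels act in parallel between the same pair of
#' states.
#'
#' @param scheme a [reaction_scheme()].
#' @return numeric matrix n_states x n_states.
#' @export
rate_matrix <- function(scheme) {
  stop_unless_scheme(scheme)
  n <- scheme$n_states
  k <- scheme$k
  q <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    q[j, i] <- q[j, i] + k[2L * i - 1L]  # forward i -> i+1
    q[i, j] <- q[i, j] + k[2L * i]       # reverse i+1 -> i
  }
  diag(q) <- diag(q) - colSums(q)
  q
}

#' Stationary state probabilities of a catalytic cycle
#'
#' Solves the stationary master equation Q p = 0, sum(p) = 1 as a linear
#' system (the null space of the generator is one-dimensional for a single
#' connected cycle with positive rates).
#'
#' @param scheme a [reaction_scheme()].
#' @return probability vector over the n states.
#' @export
stationary_probabilities <- function(scheme) {
  q <- rate_matrix(scheme)
  n <- nrow(q)
  a <- rbind(q[-n, , drop = FALSE], rep(1, n))
  p <- solve(a, c(rep(0, n - 1L), 1))
  p / sum(p)
}

#' Steady-state flux, force and dissipation of a catalytic cycle
#'
#' Computes the non-equilibrium steady state of a reversible 2-, 3- or
#' 4-state cycle under chemiostatic conditions (substrate and product
#' clamped, so their concentrations stay folded into the binding
#' constants):
#' * net cycle flux `J = (prod forward k - prod reverse k) / D` with `D`
#'   the sum of the cycle's directed-tree terms, and the one-way fluxes
#'   `J+ = prod(odd k)/D`, `J- = prod(even k)/D`, so `J = J+ - J-`;
#' * thermodynamic force `X/RT = ln K` with
#'   `K = prod(odd k)/prod(even k)` the cycle equilibrium constant;
#' * dissipation function `phi/RT = J * X/RT` (s^-1). phi equals T times
#'   the entropy production, so all thermodynamic outputs here are reduced
#'   by RT; multiply by R*T for absolute phi in J mol^-1 s^-1;
#' * stationary state probabilities from the master equation and their
#'   Shannon entropy `-sum(p log p)` in nats.
#'
#' The second law guarantees `phi/RT >= 0`, with equality exactly at
#' detailed balance (`prod odd k == prod even k`).
#'
#' @param scheme a [reaction_scheme()].
#' @return object of class `steady_state_solution`: list with `flux`,
#'   `flux_forward`, `flux_backward` (s^-1), `force_rt` (dimensionless),
#'   `dissipation_rt` (s^-1), `equilibrium_constant`, `probabilities`,
#'   `shannon_entropy` (nats).
#' @examples
#' ss <- steady_state(reaction_scheme(c(2, 1, 1, 1), substrate_conc = 1e-3))
#' c(ss$flux, ss$force_rt, ss$dissipation_rt)
#' @export
steady_state <- function(scheme) {
  stop_unless_scheme(scheme)
  k <- scheme$k
  fwd <- prod(fwd_k(scheme))
  rev <- prod(rev_k(scheme))
  d <- cycle_denominator(scheme$n_states, k)
  flux_forward <- fwd / d
  flux_backward <- rev / d
  flux <- flux_forward - flux_backward
  keq <- fwd / rev
  force_rt <- log(keq)
  p <- stationary_probabilities(scheme)
  structure(
    list(flux = flux, flux_forward = flux_forward,
         flux_backward = flux_backward, force_rt = force_rt,
         dissipation_rt = flux * force_rt, equilibrium_constant = keq,
         probabilities = p,
         shannon_entropy = -sum(p * log(p))),
    class = "steady_state_solution")
}

#' @export
print.steady_state_solution <- function(x, ...) {
  cat("<steady_state_solution>\n")
  cat(sprintf("  J = %.6g s^-1 (J+ = %.6g, J- = %.6g)\n",
              x$flux, x$flux_forward, x$flux_backward))
  cat(sprintf("  X/RT = %.6g, phi/RT = %.6g s^-1, K = %.6g\n",
              x$force_rt, x$dissipation_rt, x$equilibrium_constant))
  cat("  p =", format(x$probabilities, digits = 4),
      sprintf(" (entropy %.4g nats)\n", x$shannon_entropy))
  invisible(x)
}

#' Consistency of the kinetic and thermodynamic equilibrium constants
#'
#' The cycle equilibrium constant can be obtained two ways: directly as the
#' ratio of the forward and reverse rate-constant products, or as the
#' scaling of the product-rebinding step at which the net flux J vanishes
#' (the Haldane / detailed-balance condition, located here by a numeric
#' root search over the product concentration scaling). For any
#' mass-action-consistent scheme the two agree; the returned relative error
#' should be below 1e-9.
#'
#' @param scheme a [reaction_scheme()].
#' @return dimensionless relative error between the two determinations.
#' @export
haldane_check <- function(scheme) {
  stop_unless_scheme(scheme)
  k_products <- prod(fwd_k(scheme)) / prod(rev_k(scheme))
  last_even <- 2L * scheme$n_states
  # Scale [P] (hence the last even constant) by c = exp(logc) and evaluate
  # the full steady-state flux; J crosses zero at the equilibrium product
  # concentration. The flux is strictly decreasing in c.
  f <- function(logc) {
    k <- scheme$k
    k[last_even] <- k[last_even] * exp(logc)
    odd <- k[seq(1L, last_even, 2L)]
    even <- k[seq(2L, last_even, 2L)]
    (prod(odd) - prod(even)) / cycle_denominator(scheme$n_states, k)
  }
  if (f(0) == 0) return(abs(k_products - 1) / k_products)
  lo <- 0
  hi <- 0
  while (f(lo) < 0 && lo > -700) lo <- lo - 25
  while (f(hi) > 0 && hi < 700) hi <- hi + 25
  if (f(lo) < 0 || f(hi) > 0)
    stop("could not bracket the J = 0 root; scheme is numerically degenerate")
  root <- stats::uniroot(f, c(lo, hi), tol = 1e-13)$root
  k_from_root <- exp(root)
  abs(k_products - k_from_root) / k_products
}
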