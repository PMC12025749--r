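#' Turnover number of the forward reaction
#'
#' Computes k_cat, the maximal product-release rate per enzyme at saturating
#' substrate, from the first-order rate constants of a 2-, 3- or 4-state
#' reversible cycle. For two states k_cat = k3; for three states
#' k_cat = k3*k5 / (k3 + k4 + k5); for four states
#' k_cat = k3*k5*k7 / (k3*k5 + k3*k6 + k3*k7 + k4*k6 + k4*k7 + k5*k7),
#' i.e. the saturating-substrate limit of the stationary cycle flux.
#'
#' @param scheme a [reaction_scheme()].
#' @return k_cat in s^-1.
#' @export
catalytic_constant <- function(scheme) {
  stop_unless_scheme(scheme)
  k <- scheme$k
  switch(as.character(scheme$n_states),
    "2" = k[3],
    "3" = k[3] * k[5] / (k[3] + k[4] + k[5]),
    "4" = k[3] * k[5] * k[7] /
      (k[3] * k[5] + k[3] * k[6] + k[3] * k[7] +
       k[4] * k[6] + k[4] * k[7] + k[5] * k[7]),
    stop("unsupported n_states = ", scheme$n_states,
         "; only 2-, 3- and 4-state cycles are implemented"))
}

#' Catalytic efficiency (specificity constant) of the forward reaction
#'
#' Computes k_cat/K_m in M^-1 s^-1. Because the binding constant k1 carries
#' the substrate concentration folded in, \[S\] reappears explicitly here:
#' for two states k_cat/K_m = k1*k3 / (\[S\]*(k2 + k3)), for three states
#' k1*k3*k5 / (\[S\]*(k2*k4 + k2*k5 + k3*k5)), and for four states
#' k1*k3*k5*k7 / (\[S\]*(k2*k4*k6 + k2*k4*k7 + k2*k5*k7 + k3*k5*k7)).
#'
#' @param scheme a [reaction_scheme()] with positive `substrate_conc`.
#' @return k_cat/K_m in M^-1 s^-1.
#' @export
catalytic_efficiency <- function(scheme) {
  stop_unless_scheme(scheme)
  s <- scheme$substrate_conc
  if (is.na(s) || s <= 0)
    stop("catalytic efficiency requires a positive substrate concentration")
  k <- scheme$k
  switch(as.character(scheme$n_states),
    "2" = k[1] * k[3] / (s * (k[2] + k[3])),
    "3" = k[1] * k[3] * k[5] /
      (s * (k[2] * k[4] + k[2] * k[5] + k[3] * k[5])),
    "4" = k[1] * k[3] * k[5] * k[7] /
      (s * (k[2] * k[4] * k[6] + k[2] * k[4] * k[7] +
            k[2] * k[5] * k[7] + k[3] * k[5] * k[7])),
    stop("unsupported n_states = ", scheme$n_states))
}

#' Michaelis constant of the forward reaction
#'
#' K_m = k_cat / (k_cat/K_m), in mol/L. K_m is invariant under a uniform
#' rescaling of all rate constants (both k_cat and k_cat/K_m are homogeneous
#' of degree one in the rate constants).
#'
#' @inheritParams catalytic_efficiency
#' @return K_m in M.
#' @export
michaelis_constant <- function(scheme) {
  catalytic_constant(scheme) / catalytic_efficiency(scheme)
}

#' Forward performance parameters of a scheme
#'
#' Convenience bundle of [catalytic_constant()], [michaelis_constant()] and
#' [catalytic_efficiency()].
#'
#' @inheritParams catalytic_efficiency
#' @return list with elements `kcat` (s^-1), `km` (M), `efficiency`
#'   (M^-1 s^-1).
#' @export
performance_params <- function(scheme) {
  kcat <- catalytic_constant(scheme)
  eff <- catalytic_efficiency(scheme)
  list(kcat = kcat, km = kcat / eff, efficiency = eff)
}
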