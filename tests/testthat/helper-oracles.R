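# Independent oracles used across the test files. These deliberately take
# different computational routes from the package internals: probabilities
# by directed-spanning-tree enumeration (all-positive products, no linear
# solve), fluxes read off the stationary distribution edge by edge, the
# trade-off optimum from the analytic structure of the cycle denominator,
# and the rank-sum p-value by exhaustive enumeration.

# Stationary distribution from directed spanning trees of the cycle graph.
# The two-state cycle is a two-edge multigraph and is handled explicitly.
oracle_tree_probabilities <- function(k) {
  n <- length(k) / 2L
  if (n == 2L) {
    s <- c(k[2] + k[3], k[1] + k[4])
    return(s / sum(s))
  }
  rate <- function(a, b) if (b == (a %% n) + 1L) k[2L * a - 1L] else k[2L * b]
  sums <- vapply(seq_len(n), function(root) {
    total <- 0
    for (rm in seq_len(n)) {          # remove the edge between rm and rm+1
      prodv <- 1
      for (v in setdiff(seq_len(n), root)) {
        # walk v -> v+1 -> ...; if the removed edge comes before the root,
        # v must route the other way around
        w <- v
        crossed <- FALSE
        repeat {
          if (w == rm) { crossed <- TRUE; break }
          w <- (w %% n) + 1L
          if (w == root) break
        }
        nxt <- if (!crossed) (v %% n) + 1L else (if (v == 1L) n else v - 1L)
        prodv <- prodv * rate(v, nxt)
      }
      total <- total + prodv
    }
    total
  }, numeric(1))
  sums / sum(sums)
}

# Net cycle flux from the stationary distribution: every edge of a single
# cycle carries the same net flux; read it off the edge with the smallest
# one-way flux to minimize cancellation.
oracle_master_equation_flux <- function(k, p = oracle_tree_probabilities(k)) {
  n <- length(k) / 2L
  fluxes <- vapply(seq_len(n), function(i) {
    j <- (i %% n) + 1L
    p[i] * k[2L * i - 1L] - p[j] * k[2L * i]
  }, numeric(1))
  oneway <- vapply(seq_len(n), function(i) p[i] * k[2L * i - 1L], numeric(1))
  fluxes[which.min(oneway)]
}

# Random scheme on a moderate rate range where double-precision comparison
# of the two flux routes is meaningful (see the methods vignette).
oracle_random_scheme <- function(n_states, log10_range = c(-1, 3)) {
  k <- 10^stats::runif(2L * n_states, log10_range[1], log10_range[2])
  reaction_scheme(k, substrate_conc = 10^stats::runif(1, -6, -2))
}

# Analytic trade-off optimum: the cycle denominator under the trade-off
# transform is D(g) = A*g + B/g + C, so phi = const/D(g) is maximized at
# g* = sqrt(B/A). A and B are recovered from three evaluations of D.
oracle_tradeoff_gopt <- function(scheme, mode = "rates") {
  phi <- function(g) dissipath:::tradeoff_profile(scheme, g, mode)$dissipation_rt
  net_over_phi <- function(g) 1 / phi(g)   # proportional to D(g)
  d1 <- net_over_phi(1); d2 <- net_over_phi(2); dh <- net_over_phi(0.5)
  a <- (2 * (d2 - d1) + (dh - d1)) * 2 / 3
  b <- (2 * (dh - d1) + (d2 - d1)) * 2 / 3
  if (a <= 0 || b <= 0) return(NA_real_)   # numerically flat in g
  sqrt(b / a)
}

# Exact Mann-Whitney p by exhaustive enumeration of group assignments.
oracle_mw_exact_p <- function(a, b, alternative = "two.sided") {
  pooled <- c(a, b)
  n <- length(pooled)
  na <- length(a)
  u_stat <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - na * (na + 1) / 2
  }
  obs <- u_stat(seq_len(na))
  splits <- utils::combn(n, na)
  us <- apply(splits, 2, u_stat)
  mu <- na * (n - na) / 2
  switch(alternative,
    two.sided = mean(abs(us - mu) >= abs(obs - mu)),
    less = mean(us <= obs),
    greater = mean(us >= obs),
    stop("bad alternative"))
}

# Compact scheme builders for readable test cases.
sch2 <- function(k, S = 1e-3, P = 1e-4) reaction_scheme(k, S, P)
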