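test_that("the shifted Box-Muller transform matches hand evaluations", {
  expect_equal(box_muller_shift(exp(-2), 0), 3)
  expect_equal(box_muller_shift(exp(-2), 0.5), -1)
  expect_equal(box_muller_shift(0.37, 0.25), 1)
  expect_equal(box_muller_shift(0.91, 0.25), 1)
  expect_error(box_muller_shift(0, 0.5))
  set.seed(6)
  s <- draw_noise()
  expect_equal(s$g, box_muller_shift(s$s1, s$s2))
})

test_that("g - 1 is standard normal", {
  set.seed(60)
  g <- replicate(1e5, draw_noise()$g)
  ks <- stats::ks.test(g - 1, "pnorm")
  expect_gt(ks$p.value, 0.01)
})

test_that("non-positive multipliers repeat the previous accepted step", {
  sc <- sch2(c(2, 1, 1, 1))
  tr <- run_forward_variations(sc, n_steps = 3000, seed = 17)
  expect_true(all(tr$g > 0))
  # re-derive the multiplier sequence independently from the same stream
  set.seed(17)
  g <- numeric(3000)
  repeat { g[1] <- box_muller_shift(runif(1), runif(1)); if (g[1] > 0) break }
  for (i in 2:3000) {
    gi <- box_muller_shift(runif(1), runif(1))
    g[i] <- if (gi > 0) gi else g[i - 1]
  }
  expect_equal(tr$g, g)
  expect_gt(sum(duplicated(tr$g)), 0)  # the rule did fire at this length
  dup <- which(tr$g[-1] == tr$g[-3000]) + 1
  expect_equal(tr$dissipation_rt[dup], tr$dissipation_rt[dup - 1])
})

test_that("forward variations rescale the cycle and preserve its thermodynamics", {
  sc <- sch2(c(2, 1, 1, 1))
  expect_equal(forward_variation_step(sc, 1)$k, sc$k)
  doubled <- forward_variation_step(sc, 2)
  ss <- steady_state(doubled)
  expect_equal(ss$flux, 0.4)
  expect_equal(ss$force_rt, log(2))
  expect_equal(ss$dissipation_rt, 0.4 * log(2))
  expect_error(forward_variation_step(sc, 0), "positive")
  expect_error(forward_variation_step(sc, -1), "positive")
})

test_that("forward-variation traces have exact invariants and unit-R2 scaling", {
  for (n_states in 2:4) {
    sc <- sample_scheme(n_states = n_states, seed = 70 + n_states)
    tr <- run_forward_variations(sc, n_steps = 2000, seed = 7)
    base <- attr(tr, "base")
    # invariant columns
    expect_equal(diff(range(tr$km)), 0)
    expect_equal(diff(range(tr$force_rt)), 0)
    expect_equal(diff(range(tr$shannon_entropy)), 0)
    # all maxima coincide on the max-g step
    expect_equal(which.max(tr$kcat), which.max(tr$g))
    expect_equal(which.max(tr$efficiency), which.max(tr$g))
    expect_equal(which.max(tr$dissipation_rt), which.max(tr$g))
    expect_equal(attr(tr, "argmax"), which.max(tr$g))
    expect_equal(max(tr$dissipation_rt) / base$steady_state$dissipation_rt,
                 max(tr$g))
    # efficiency rises exactly linearly with dissipation
    fit <- stats::lm(efficiency ~ dissipation_rt, data = tr)
    expect_gt(suppressWarnings(summary(fit))$r.squared, 1 - 1e-12)
    expect_equal(unname(stats::coef(fit)[2]),
                 base$performance$efficiency /
                   base$steady_state$dissipation_rt)
    # dual route: recompute sampled rows through the scheme transform
    for (i in c(1, 500, 2000)) {
      tsc <- forward_variation_step(sc, tr$g[i])
      ss <- steady_state(tsc)
      pp <- performance_params(tsc)
      expect_equal(tr$kcat[i], pp$kcat)
      expect_equal(tr$efficiency[i], pp$efficiency)
      expect_equal(tr$km[i], pp$km)
      expect_equal(tr$flux[i], ss$flux)
      expect_equal(tr$dissipation_rt[i], ss$dissipation_rt)
      expect_equal(tr$shannon_entropy[i], ss$shannon_entropy)
      expect_equal(attr(tr, "probabilities"), ss$probabilities)
      # step equilibrium constants unchanged
      n2 <- 2 * sc$n_states
      expect_equal(tsc$k[seq(1, n2, 2)] / tsc$k[seq(2, n2, 2)],
                   sc$k[seq(1, n2, 2)] / sc$k[seq(2, n2, 2)])
    }
  }
})

test_that("traces are reproducible under a fixed seed", {
  sc <- sch2(c(5, 1, 2, 0.5))
  expect_identical(run_forward_variations(sc, 500, seed = 3),
                   run_forward_variations(sc, 500, seed = 3))
})

test_that("the trade-off transform moves only the end-step equilibria at fixed force", {
  sc3 <- reaction_scheme(c(2, 1, 1, 1, 1, 1), 1e-3)
  expect_equal(tradeoff_transform(sc3, 1)$k, sc3$k)
  t2 <- tradeoff_transform(sc3, 2, mode = "rates")
  expect_equal(t2$k, c(4, 1, 1, 1, 0.5, 1))
  ss <- steady_state(t2)
  expect_equal(ss$force_rt, log(2), tolerance = 1e-12)
  expect_equal(ss$flux,
               oracle_master_equation_flux(t2$k), tolerance = 1e-10)
  expect_lt(haldane_check(t2), 1e-9)

  tr <- tradeoff_transform(sc3, 2, mode = "reverse")
  expect_equal(tr$k, c(2, 0.5, 1, 1, 1, 2))
  expect_equal(steady_state(tr)$force_rt, log(2), tolerance = 1e-12)

  set.seed(81)
  for (n_states in 2:4) {
    sc <- sample_scheme(n_states = n_states, seed = 500 + n_states)
    x0 <- steady_state(sc)$force_rt
    for (g in c(0.03, 0.8, 12)) for (mode in c("rates", "reverse")) {
      tt <- tradeoff_transform(sc, g, mode)
      expect_equal(steady_state(tt)$force_rt, x0, tolerance = 1e-12)
      # middle-step equilibrium constants untouched
      n2 <- 2 * sc$n_states
      ki <- function(s) s$k[seq(1, n2, 2)] / s$k[seq(2, n2, 2)]
      expect_equal(ki(tt)[-c(1, sc$n_states)], ki(sc)[-c(1, sc$n_states)])
      expect_equal(ki(tt)[1], g * ki(sc)[1])
      expect_equal(ki(tt)[sc$n_states], ki(sc)[sc$n_states] / g)
    }
  }
  expect_error(tradeoff_transform(sc3, -2), "positive")
})

test_that("the grid search lands on the analytic dissipation maximum", {
  # 2-state closed form: D(g) = g k1 + k2 + k3/g + k4, optimum sqrt(k3/k1)
  sc <- sch2(c(2, 1, 1, 1))
  res <- find_max_dissipation(sc, method = "grid")
  expect_equal(res$g_opt, sqrt(1 / 2), tolerance = 1e-5)
  expect_gte(res$phi_max, res$observed$dissipation_rt)
  expect_false(res$boundary)

  for (n_states in 2:4) {
    for (sc in sample_schemes(10, n_states = n_states, seed = 90 + n_states)) {
      res <- find_max_dissipation(sc, method = "grid")
      gstar <- oracle_tradeoff_gopt(sc)
      if (!res$boundary && is.finite(gstar) &&
          gstar > 1.2e-3 && gstar < 8e2) {
        phi_star <- dissipath:::tradeoff_profile(sc, gstar)$dissipation_rt
        expect_equal(res$phi_max, phi_star, tolerance = 1e-6)
      }
      expect_gte(res$phi_max, res$observed$dissipation_rt)
      # the dissipation profile declines at both extremes of g
      prof <- dissipath:::tradeoff_profile(sc, c(1e-6, res$g_opt, 1e6))
      expect_gt(prof$dissipation_rt[2], prof$dissipation_rt[1])
      expect_gt(prof$dissipation_rt[2], prof$dissipation_rt[3])
    }
  }
})

test_that("the stochastic search respects its contract against the grid oracle", {
  sc <- sch2(c(8, 3, 2, 0.4))
  grid <- find_max_dissipation(sc, method = "grid")
  sto <- find_max_dissipation(sc, method = "stochastic", budget = 10000,
                              seed = 42)
  # never better than the refined deterministic optimum (interior case)
  expect_lte(sto$phi_max, grid$phi_max * (1 + 1e-12))
  expect_gte(sto$phi_max, sto$observed$dissipation_rt)
  # the reported maximum dominates every sampled candidate
  expect_gte(sto$phi_max, max(sto$trace$dissipation_rt))
  expect_true(all(sto$trace$g > 0))
  expect_error(find_max_dissipation(sc, method = "stochastic"),
               "seed")
})

test_that("Eff/Tur classification follows the efficiency fold with kcat complementarity", {
  expect_equal(classify_reaction(list(efficiency = 100, kcat = 10),
                                 list(efficiency = 186, kcat = 9.5)),
               "Eff")
  expect_equal(classify_reaction(list(efficiency = 100, kcat = 10),
                                 list(efficiency = 64, kcat = 12.3)),
               "Tur")
  # the boundary fold of exactly 1 is Tur by convention
  expect_warning(
    lbl <- classify_reaction(list(efficiency = 100, kcat = 10),
                             list(efficiency = 100, kcat = 10)))
  expect_equal(lbl, "Tur")
  expect_warning(classify_reaction(list(efficiency = 100, kcat = 10),
                                   list(efficiency = 150, kcat = 11)),
                 "disagree")
})
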