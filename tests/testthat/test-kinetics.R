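test_that("mass-action derivatives match hand evaluation and an independent implementation", {
  r1 <- rate_constants(1, 1, 1, 1, 1, 1, 1, 1)
  d <- binding_derivatives(system_state(1, 0, 0, 0, l = 1), r1)
  expect_equal(unname(d), c(-2, 1, 1, 0, -2))

  withr::with_seed(421, {
    for (i in 1:20) {
      r <- random_closed_rates()
      y <- runif(5, 0, 5)
      got <- binding_derivatives(setNames(y, c("m00", "m10", "m01", "m11", "l")), r)
      want <- oracle_derivs(y[1], y[2], y[3], y[4], y[5],
                            r[["k1"]], r[["k2"]], r[["k1_given_2"]],
                            r[["k2_given_1"]], r[["km1"]], r[["km2"]],
                            r[["km1_given_2"]], r[["km2_given_1"]])
      expect_equal(unname(got), want, tolerance = 1e-12)
      # macromolecule states sum to zero; ligand combination conserved
      expect_lt(abs(sum(got[c("m00", "m10", "m01", "m11")])),
                1e-12 * max(abs(got), 1))
      expect_lt(abs(got[["l"]] + got[["m10"]] + got[["m01"]] +
                      2 * got[["m11"]]), 1e-12 * max(abs(got), 1))
    }
  })
})

test_that("closed-form equilibria are fixed points of the rate equations", {
  withr::with_seed(77, {
    for (i in 1:10) {
      r <- random_closed_rates()
      l <- exp(runif(1, log(0.05), log(20)))
      sp <- oracle_equilibrium_species(r, m_total = 1, l = l)
      d <- binding_derivatives(c(sp, l = l), r)
      expect_lt(max(abs(d)), 1e-10)
    }
  })
})

test_that("RK4 integration preserves both conservation laws at every recorded step", {
  withr::with_seed(90, {
    for (i in 1:5) {
      r <- random_closed_rates()
      tc <- integrate_binding(r, m_total = 1, l_total = exp(runif(1, 0, log(50))))
      expect_true(tc$converged)
      expect_lt(max_conservation_error(tc), 1e-9)
    }
  })
})

test_that("simulated equilibrium matches the closed-form isotherm", {
  # identical and independent sites, Ko = 1: <n> = 2L/(1+L)
  tc <- integrate_binding(rate_constants(1, 1, 1, 1, 1, 1, 1, 1), 1, 10)
  l_eq <- tc$equilibrium_state[["l"]]
  n_eq <- binding_density(tc$equilibrium_state, 1)
  n_cf <- model_binding_density(identical_independent_model(1), l_eq)
  expect_equal(n_eq, n_cf, tolerance = 1e-4)
})

test_that("without ligand the system stays constant at zero occupancy", {
  tc <- integrate_binding(cooperative_rates(1, 10), 1, 0)
  expect_true(tc$converged)
  expect_equal(max(abs(binding_density(tc))), 0)
  expect_equal(unique(tc$states$m00), 1)
})

test_that("equilibrium is independent of step size and of initial ligand partitioning", {
  r <- cooperative_rates(1, 10)
  cfg1 <- sim_config(step_size = 1e-4)
  cfg2 <- sim_config(step_size = 5e-5)
  eq1 <- integrate_binding(r, 1, 10, cfg1)$equilibrium_state
  eq2 <- integrate_binding(r, 1, 10, cfg2)$equilibrium_state
  rel <- abs(eq1[-1] - eq2[-1]) / pmax(abs(eq2[-1]), 1e-12)
  expect_lt(max(rel), 1e-6)

  # start with part of the ligand pre-bound instead of all free
  init <- system_state(m00 = 0.5, m10 = 0.2, m01 = 0.2, m11 = 0.1,
                       l = 10 - 0.2 - 0.2 - 2 * 0.1)
  eq3 <- integrate_binding(r, 1, 10, initial = init)$equilibrium_state
  rel3 <- abs(eq3[-1] - eq1[-1]) / pmax(abs(eq1[-1]), 1e-12)
  expect_lt(max(rel3), 1e-4)
})

test_that("integration agrees with an independent stiff ODE solver", {
  skip_if_not_installed("deSolve")
  r <- cooperative_rates(0.55, 0.33058)
  m0 <- 1; l0 <- 25
  times <- c(0.1, 0.5, 1, 2, 5)
  ref <- deSolve::lsoda(
    y = c(m00 = m0, m10 = 0, m01 = 0, m11 = 0, l = l0),
    times = c(0, times),
    func = function(t, y, p)
      list(oracle_derivs(y[1], y[2], y[3], y[4], y[5],
                         p[["k1"]], p[["k2"]], p[["k1_given_2"]],
                         p[["k2_given_1"]], p[["km1"]], p[["km2"]],
                         p[["km1_given_2"]], p[["km2_given_1"]])),
    parms = unclass(r), rtol = 1e-10, atol = 1e-12)
  ours <- coopbind:::.sim_course(r, m0, l0, times)
  expect_equal(unname(ours), unname(as.matrix(ref[-1, -1])),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("equilibrium detection returns a genuinely stationary state", {
  tc0 <- integrate_binding(cooperative_rates(1, 10), 1, 0)
  eq0 <- detect_equilibrium(tc0)
  expect_equal(eq0[["t"]], 0)  # constant trace: first state qualifies

  cfg <- sim_config(convergence_threshold = 1e-6)
  tc <- integrate_binding(cooperative_rates(1, 10), 1, 10, cfg)
  eq <- detect_equilibrium(tc)
  d <- binding_derivatives(eq, tc$rates)
  expect_lt(max(abs(d)), 1e-6)

  expect_error(detect_equilibrium(tc, threshold = 0), "never met")
})

test_that("non-convergence is flagged, not silent", {
  cfg <- sim_config(max_time = 0.01)
  tc <- integrate_binding(cooperative_rates(1, 10), 1, 10, cfg)
  expect_false(tc$converged)
  expect_null(tc$equilibrium_state)
})

test_that("binding density identities hold", {
  expect_equal(binding_density(system_state(0, 0, 0, 1, 0), 1), 2)
  expect_equal(binding_density(system_state(0, 0.5, 0.5, 0, 0), 1), 1)
  expect_error(binding_density(system_state(1, 0, 0, 0, 0), 0), "positive")

  tc <- integrate_binding(cooperative_rates(1, 0.33058, 1), 1, 5)
  s <- tc$states
  n1 <- binding_density(tc)
  n2 <- (tc$l_total - s$l) / tc$m_total
  expect_equal(n1, n2, tolerance = 1e-9)
})

test_that("detailed-balance violations are rejected unless explicitly permitted", {
  expect_error(rate_constants(1, 1, 10, 1, 1, 1, 1, 1), "cycle closure")
  r <- rate_constants(1, 1, 10, 1, 1, 1, 1, 1, allow_cycle_violation = TRUE)
  expect_false(attr(r, "cycle_closed"))
  expect_error(rate_constants(1, 1, 1, 1, 1, 1, 1, -1), "positive")
})

test_that("time-course CSV round-trips", {
  tc <- integrate_binding(cooperative_rates(1, 2), 1, 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_timecourse_csv(tc, path)
  back <- read_timecourse_csv(path)
  expect_equal(back$m11_uM, tc$states$m11, tolerance = 1e-12)
  expect_equal(back$n_avg, binding_density(tc), tolerance = 1e-12)
})
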