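test_that("a degenerate matched pair (omega = 1) shows zero discrepancy", {
  tr <- paired_timecourses(1, 1, l_totals = c(2, 20))
  for (t in tr) expect_lt(max(abs(t$delta_n)), 1e-12)
})

test_that("matched models coincide at equilibrium but differ before it", {
  p <- load_preset("matched_pair_kinetics")
  tr <- paired_timecourses(p$ko, p$omega, p$l_totals, p$m_total, p$off_rate)
  delta_end <- vapply(tr, function(t) abs(t$delta_n[nrow(t)]), 0)
  expect_true(all(delta_end < 1e-4))       # indistinguishable at equilibrium
  delta_max <- vapply(tr, function(t) max(abs(t$delta_n)), 0)
  expect_gt(max(delta_max), 0.01)          # but not on the way there
  # each trace starts at zero and peaks at an interior time
  for (t in tr) {
    expect_equal(t$delta_n[1], 0)
    i <- which.max(abs(t$delta_n))
    expect_gt(i, 1)
    expect_lt(i, nrow(t))
  }
  # peak times shift with ligand concentration
  t_max <- vapply(tr, attr, 0, "t_max")
  expect_gt(diff(range(t_max)) / min(t_max), 0.5)
})

test_that("matched-pair equilibrium isotherms from full simulations agree", {
  p <- load_preset("matched_pair")
  l0s <- 10^seq(-2, log10(300), by = 0.25)  # thinned grid of the preset
  iso_c <- simulate_isotherm(p$rates_cooperative, p$m_total, l0s)
  iso_t <- simulate_isotherm(p$rates_two_classes, p$m_total, l0s)
  expect_lt(max(abs(iso_c$n_avg - iso_t$n_avg)), 1e-3)
})

test_that("noiseless isotherm fits recover their generating parameters", {
  iso <- model_isotherm(single_site_model(2.5))
  fit <- fit_isotherm(iso, "single_site")
  expect_true(fit$converged)
  expect_equal(fit$estimates[["K"]], 2.5, tolerance = 1e-6)
  expect_lt(fit$rss, 1e-12)

  full <- model_isotherm(cooperative_model(1, 0.02))
  fit_c <- fit_isotherm(full, "cooperative")
  expect_equal(fit_c$estimates[["ko"]], 1, tolerance = 0.01)
  expect_equal(fit_c$estimates[["omega"]], 0.02, tolerance = 0.02 * 0.05)
})

test_that("the hidden-site isotherm looks like one site of doubled affinity", {
  hidden <- model_isotherm(cooperative_model(1, 0.02),
                           l = seq(0.06, 6, by = 0.06))
  fit <- fit_isotherm(hidden, "hyperbola")
  expect_true(fit$converged)
  expect_equal(fit$estimates[["Nmax"]], 1.055, tolerance = 0.01)
  expect_equal(fit$estimates[["K"]], 1.78, tolerance = 0.03)
  # apparent affinity bounded by the statistical factor: Ko < K < 2 Ko
  expect_gt(fit$estimates[["K"]], 1)
  expect_lt(fit$estimates[["K"]], 2)
})

test_that("omega is recovered within 15% from noisy isotherms", {
  withr::with_seed(303, {
    frac_ok <- vapply(c(0.1, 0.33, 3, 10), function(omega) {
      ok <- vapply(1:20, function(i) {
        iso <- add_noise(model_isotherm(cooperative_model(1, omega)), 0.02)
        fit <- fit_isotherm(iso, "cooperative")
        fit$converged && abs(fit$estimates[["omega"]] - omega) < 0.15 * omega
      }, TRUE)
      mean(ok)
    }, 0)
    expect_gte(mean(frac_ok), 0.95)
  })
})

test_that("constrained kinetic self-fits recover the generating off-rate", {
  ktrue <- two_site_class_rates(1, 0.1, off_rate = 1)
  times <- 10^seq(-2, 1, length.out = 30)
  data <- do.call(rbind, lapply(c(5, 25, 100), function(l0) {
    st <- coopbind:::.sim_course(ktrue, 1, l0, times)
    data.frame(time = times, n_avg = binding_density(as.data.frame(st), 1),
               l_total = l0)
  }))
  K1 <- 1.1; K2 <- 0.1 / 1.1  # macroscopic constants of the true model
  fit <- fit_kinetics(data, "two_site_classes", list(K1 = K1, K2 = K2),
                      m_total = 1)
  expect_true(fit$converged)
  expect_equal(unname(fit$estimates), c(1, 1), tolerance = 0.01)
})

test_that("the generating kinetic model wins the constrained comparison", {
  ktrue <- two_site_class_rates(1, 0.1, off_rate = 1)
  times <- 10^seq(-2, 1, length.out = 30)
  clean <- do.call(rbind, lapply(c(5, 25, 100), function(l0) {
    st <- coopbind:::.sim_course(ktrue, 1, l0, times)
    data.frame(time = times, n_avg = binding_density(as.data.frame(st), 1),
               l_total = l0)
  }))
  K1 <- 1.1; K2 <- 0.1 / 1.1
  noisy <- clean
  noisy$n_avg <- add_noise(clean$n_avg, 0.01, seed = 99)
  f_two <- fit_kinetics(noisy, "two_site_classes",
                        list(K1 = K1, K2 = K2), m_total = 1)
  f_coop <- fit_kinetics(noisy, "cooperative",
                         list(K1 = K1, K2 = K2), m_total = 1)
  expect_true(f_two$converged && f_coop$converged)
  expect_lt(f_two$aicc, f_coop$aicc)
})

test_that("a single low-concentration trace cannot discriminate the models", {
  ktrue <- two_site_class_rates(1, 0.1, off_rate = 1)
  times <- 10^seq(-2, 1, length.out = 30)
  st <- coopbind:::.sim_course(ktrue, 1, 2, times)
  noisy <- data.frame(time = times,
                      n_avg = add_noise(binding_density(as.data.frame(st), 1),
                                        0.01, seed = 7),
                      l_total = 2)
  K1 <- 1.1; K2 <- 0.1 / 1.1
  f_two <- fit_kinetics(noisy, "two_site_classes",
                        list(K1 = K1, K2 = K2), m_total = 1)
  f_coop <- fit_kinetics(noisy, "cooperative",
                         list(K1 = K1, K2 = K2), m_total = 1)
  expect_lt(abs(f_two$aicc - f_coop$aicc), 2)
})

test_that("infeasible macroscopic constraints are rejected for two site classes", {
  dummy <- data.frame(time = 1:10, n_avg = seq(0.1, 1, 0.1), l_total = 5)
  expect_error(fit_kinetics(dummy, "two_site_classes",
                            list(K1 = 1, K2 = 0.5), m_total = 1),
               "infeasible")
})

test_that("phase counting: exact mono-exponential traces report one phase", {
  t <- seq(0, 10, by = 0.05)
  n <- 0.8 * (1 - exp(-1.3 * t))
  expect_equal(as.integer(classify_kinetics(t, n)), 1L)
  expect_error(classify_kinetics(t, rev(n)), "non-monotone")
})

test_that("the hidden site is kinetically invisible at low ligand and exposed at high", {
  r <- cooperative_rates(1, 0.02)
  times <- 10^seq(-3, 1.3, length.out = 60)
  # pseudo-first-order, low ligand: mono-exponential
  low <- binding_density(as.data.frame(coopbind:::.sim_course(r, 0.05, 2,
                                                              times)), 0.05)
  expect_equal(as.integer(classify_kinetics(times, low)), 1L)
  # very high ligand: the slow second phase appears
  times_hi <- 10^seq(-5, 1, length.out = 60)
  hi <- binding_density(as.data.frame(coopbind:::.sim_course(r, 1, 1e4,
                                                             times_hi)), 1)
  expect_equal(as.integer(classify_kinetics(times_hi, hi)), 2L)
})
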