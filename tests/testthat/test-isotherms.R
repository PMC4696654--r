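test_that("closed-form models reduce to each other where they should", {
  l <- 10^seq(-3, 3, by = 0.1)
  # omega = 1 removes the interaction
  expect_equal(model_binding_density(cooperative_model(1, 1), l),
               model_binding_density(identical_independent_model(1), l),
               tolerance = 1e-12)
  expect_equal(model_binding_density(identical_independent_model(1), l),
               2 * l / (1 + l), tolerance = 1e-12)
  # half saturation of the Hill model at L = K^(-1/nH)
  expect_equal(model_binding_density(hill_model(1, 1), 1), 0.5)
  # matched negative-cooperativity / two-site-class pair
  expect_equal(model_binding_density(cooperative_model(0.55, 0.33058), l),
               model_binding_density(two_site_class_model(1, 0.1), l),
               tolerance = 1e-6)
  expect_error(model_binding_density(single_site_model(1), -1), "nonnegative")
})

test_that("every model variant is monotone non-decreasing and saturates at N", {
  l <- 10^seq(-4, 6, by = 0.05)
  models <- list(single_site_model(2), identical_independent_model(0.5),
                 cooperative_model(1, 25), cooperative_model(1, 0.04),
                 two_site_class_model(3, 0.02), hill_model(1, 1.7, 2))
  for (m in models) {
    n <- model_binding_density(m, l)
    expect_true(all(diff(n) >= -1e-12))
    expect_true(all(n >= 0 & n <= m$n_sites + 1e-9))
    expect_equal(model_binding_density(m, 1e12), m$n_sites, tolerance = 1e-3)
  }
})

test_that("equivalence mapping gives pointwise identical isotherms for omega < 1", {
  l <- 10^seq(-3, 4, by = 0.1)
  withr::with_seed(11, {
    for (i in 1:25) {
      ko <- exp(runif(1, log(0.05), log(20)))
      omega <- runif(1, 0.01, 0.999)
      ks <- equivalent_two_sites(ko, omega)
      expect_equal(
        model_binding_density(cooperative_model(ko, omega), l),
        model_binding_density(two_site_class_model(ks[["ko1"]],
                                                   ks[["ko2"]]), l),
        tolerance = 1e-9)
    }
  })
})

test_that("the omega -> 0 limit is a single site with doubled affinity", {
  l <- 10^seq(-3, 1, by = 0.05)  # bounded range below the hidden transition
  n_coop <- model_binding_density(cooperative_model(1, 1e-8), l)
  n_single <- model_binding_density(single_site_model(2), l)
  expect_equal(n_coop, n_single, tolerance = 1e-6)
})

test_that("free-ligand span is 81 for one class of sites and shrinks with cooperativity", {
  sp <- free_ligand_span(single_site_model(1))
  expect_equal(sp$ratio, 81, tolerance = 1e-6)
  expect_equal(sp$log10_ratio, 1.908, tolerance = 1e-3)
  expect_equal(free_ligand_span(identical_independent_model(3))$ratio, 81,
               tolerance = 1e-6)
  # Hill closed form: span = 81^(1/nH)
  expect_equal(free_ligand_span(hill_model(1, 2))$ratio, 9, tolerance = 1e-6)
  expect_gt(free_ligand_span(cooperative_model(1, 0.02))$ratio, 81)
  expect_lt(free_ligand_span(cooperative_model(1, 10))$ratio, 81)
})

test_that("isotherm span by monotone interpolation matches the generating model", {
  m <- cooperative_model(1, 10)
  iso <- model_isotherm(m)
  sp_iso <- free_ligand_span(iso, n_sites = 2)
  sp_mod <- free_ligand_span(m)
  expect_equal(sp_iso$ratio, sp_mod$ratio, tolerance = 1e-3)
  # truncated isotherm cannot span theta 0.1..0.9
  short <- isotherm(iso$free_l[iso$n_avg < 1], iso$n_avg[iso$n_avg < 1])
  expect_error(free_ligand_span(short, n_sites = 2), "extend")
})

test_that("isotherms assembled from time courses overlay the closed form", {
  l0s <- 10^seq(-2, 2, by = 0.25)
  iso <- simulate_isotherm(cooperative_rates(1, 10), 1, l0s)
  n_cf <- model_binding_density(cooperative_model(1, 10), iso$free_l)
  expect_lt(max(abs(iso$n_avg - n_cf)), 1e-3)
  expect_true(all(diff(iso$free_l) > 0))
})

test_that("a single ligand-free time course gives the origin point", {
  tc <- integrate_binding(cooperative_rates(1, 10), 1, 0)
  iso <- isotherm_from_timecourses(list(tc))
  expect_equal(iso$free_l, 0)
  expect_equal(iso$n_avg, 0)
})

test_that("non-converged time courses are refused by name", {
  ok <- integrate_binding(cooperative_rates(1, 2), 1, 1)
  bad <- integrate_binding(cooperative_rates(1, 2), 1, 7,
                           sim_config(max_time = 0.01))
  expect_error(isotherm_from_timecourses(list(ok, bad)), "7")
})

test_that("isotherm constructor enforces its invariants", {
  expect_error(isotherm(c(1, 1), c(0.1, 0.2)), "increasing")
  expect_error(isotherm(c(1, 2), c(0.5, 0.1)), "non-decreasing")
  expect_error(isotherm(c(1, 2), c(0.5, 2.5)), "0, 2")
  expect_s3_class(isotherm(c(1, 2), c(0.5, 0.1), validate = FALSE),
                  "binding_isotherm")
})

test_that("isotherm CSV round-trips", {
  iso <- model_isotherm(cooperative_model(1, 4), l = 10^seq(-2, 2, 0.5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_isotherm_csv(iso, path)
  back <- read_isotherm_csv(path)
  expect_equal(back$free_l, iso$free_l, tolerance = 1e-12)
  expect_equal(back$n_avg, iso$n_avg, tolerance = 1e-12)
})
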