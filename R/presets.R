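#' Built-in simulation scenarios
#'
#' Parameter sets for the package's reference scenarios, each describing
#' a complete study condition (rate coefficients, totals, ligand grid and
#' simulation settings):
#'
#' * `"positive_coop"` — two identical sites, `Ko = 1` uM^-1,
#'   `omega = 10`, total macromolecule 1 uM, total ligand 0.01 to 100 uM
#'   (log grid): the positive-cooperativity showcase whose isotherm gives
#'   a Hill coefficient near 1.5.
#' * `"omega_sweep"` — `Ko = 1` uM^-1 with `omega` from 0.01 to 100
#'   (nine log-spaced values): the Hill-coefficient versus
#'   interaction-energy relationship.
#' * `"affinity_sweep"` — `omega = 8` with `Ko` from 0.01 to 100 uM^-1
#'   (nine log-spaced values): independence of the Hill coefficient from
#'   the intrinsic affinity.
#' * `"matched_pair"` — negative cooperativity `Ko = 0.55` uM^-1,
#'   `omega = 0.33058` versus its equilibrium-equivalent two-site-class
#'   model `Ko1 = 1`, `Ko2 = 0.1` uM^-1, all off-rates 1 s^-1, total
#'   ligand 0.01 to 300 uM: indistinguishable at equilibrium.
#' * `"matched_pair_kinetics"` — the same pair at total ligand
#'   5, 10, 25, 50, 100 and 300 uM for pre-equilibrium comparison.
#' * `"hidden_site"` — strong negative cooperativity `Ko = 1` uM^-1,
#'   `omega = 0.02`, total ligand up to 6 uM in regular (linear) steps:
#'   the second site is invisible and a hyperbola fit reports a single
#'   apparent site of roughly doubled affinity.
#' * `"hidden_site_unmasked"` — the same macromolecule probed up to
#'   3e5 uM (300 mM), where the second site emerges.
#'
#' @param id preset identifier (see above).
#' @return A list of class `scenario_preset` with elements `id`,
#'   `description`, `m_total`, `l_totals`, `config` and either `rates`
#'   (with `ko`, `omega`) or both members of a matched pair, or a sweep
#'   specification.
#' @export
#' @examples
#' load_preset("hidden_site")
load_preset <- function(id) {
  ids <- c("positive_coop", "omega_sweep", "affinity_sweep", "matched_pair",
           "matched_pair_kinetics", "hidden_site", "hidden_site_unmasked")
  if (!is.character(id) || length(id) != 1 || !(id %in% ids))
    stop("unknown preset id; valid ids: ", paste(ids, collapse = ", "))
  log_grid <- function(lo, hi, per_decade = 25) {
    n <- max(2, round(log10(hi / lo) * per_decade) + 1)
    10^seq(log10(lo), log10(hi), length.out = n)
  }
  base <- list(id = id, m_total = 1, config = sim_config())
  p <- switch(id,
    positive_coop = c(base, list(
      description = "two identical sites with omega = 10, Ko = 1 uM^-1",
      ko = 1, omega = 10, off_rate = 1,
      rates = cooperative_rates(1, 10, 1),
      l_totals = log_grid(0.01, 100))),
    omega_sweep = c(base, list(
      description = "Ko = 1 uM^-1, omega from 0.01 to 100",
      ko = 1, omegas = 10^seq(-2, 2, by = 0.5), off_rate = 1)),
    affinity_sweep = c(base, list(
      description = "omega = 8, Ko from 0.01 to 100 uM^-1",
      omega = 8, kos = 10^seq(-2, 2, by = 0.5), off_rate = 1)),
    matched_pair = c(base, list(
      description = paste("negative cooperativity (Ko = 0.55, omega =",
                          "0.33058) vs two site classes (1, 0.1 uM^-1)"),
      ko = 0.55, omega = 0.33058, ko1 = 1, ko2 = 0.1, off_rate = 1,
      rates_cooperative = cooperative_rates(0.55, 0.33058, 1),
      rates_two_classes = two_site_class_rates(1, 0.1, 1),
      l_totals = log_grid(0.01, 300))),
    matched_pair_kinetics = c(base, list(
      description = "matched pair probed before equilibrium",
      ko = 0.55, omega = 0.33058, ko1 = 1, ko2 = 0.1, off_rate = 1,
      rates_cooperative = cooperative_rates(0.55, 0.33058, 1),
      rates_two_classes = two_site_class_rates(1, 0.1, 1),
      l_totals = c(5, 10, 25, 50, 100, 300))),
    hidden_site = c(base, list(
      description = "omega = 0.02, Ko = 1 uM^-1, ligand up to 6 uM",
      ko = 1, omega = 0.02, off_rate = 1,
      rates = cooperative_rates(1, 0.02, 1),
      l_totals = seq(0.06, 6, by = 0.06))),
    hidden_site_unmasked = c(base, list(
      description = "omega = 0.02, Ko = 1 uM^-1, ligand up to 300 mM",
      ko = 1, omega = 0.02, off_rate = 1,
      rates = cooperative_rates(1, 0.02, 1),
      l_totals = log_grid(0.01, 3e5, 10))))
  class(p) <- "scenario_preset"
  p
}

#' @export
print.scenario_preset <- function(x, ...) {
  cat("Scenario preset '", x$id, "': ", x$description, "\n", sep = "")
  cat("  [M]o =", x$m_total, "uM;",
      if (!is.null(x$l_totals))
        paste(length(x$l_totals), "ligand concentrations in [",
              format(min(x$l_totals)), ",", format(max(x$l_totals)), "] uM"),
      "\n")
  invisible(x)
}

#' Run a scenario preset end to end
#'
#' Simulates the preset's condition(s) and applies the analysis the
#' scenario was designed for: isotherm plus Hill analysis for the
#' single-condition presets, per-parameter Hill sweeps, matched-pair
#' equilibrium comparison or pre-equilibrium discrepancy traces, and for
#' the hidden-site preset the apparent-hyperbola fit.
#'
#' @param id preset identifier, see [load_preset()].
#' @param config optional [sim_config()] override.
#' @return A list whose structure depends on the preset (always includes
#'   the preset under `$preset`).
#' @export
run_preset <- function(id, config = NULL) {
  p <- load_preset(id)
  if (!is.null(config)) p$config <- config
  switch(p$id,
    positive_coop = ,
    hidden_site_unmasked = {
      iso <- simulate_isotherm(p$rates, p$m_total, p$l_totals, p$config)
      list(preset = p, isotherm = iso, hill = hill_analysis(iso))
    },
    hidden_site = {
      iso <- simulate_isotherm(p$rates, p$m_total, p$l_totals, p$config)
      list(preset = p, isotherm = iso,
           hyperbola_fit = fit_isotherm(iso, "hyperbola"),
           hill = hill_analysis(iso))
    },
    omega_sweep = {
      rows <- lapply(p$omegas, function(w) {
        iso <- simulate_isotherm(cooperative_rates(p$ko, w, p$off_rate),
                                 p$m_total,
                                 default_ligand_grid(ko = p$ko, omega = w),
                                 p$config)
        data.frame(omega = w, n_h = hill_analysis(iso)$n_h,
                   dg_int = interaction_free_energy(w))
      })
      list(preset = p, sweep = do.call(rbind, rows))
    },
    affinity_sweep = {
      rows <- lapply(p$kos, function(ko) {
        iso <- simulate_isotherm(cooperative_rates(ko, p$omega, p$off_rate),
                                 p$m_total,
                                 default_ligand_grid(ko = ko,
                                                     omega = p$omega),
                                 p$config)
        data.frame(ko = ko, n_h = hill_analysis(iso)$n_h,
                   dg_assoc = assoc_free_energy(ko * p$off_rate,
                                                p$off_rate))
      })
      list(preset = p, sweep = do.call(rbind, rows))
    },
    matched_pair = {
      iso_c <- simulate_isotherm(p$rates_cooperative, p$m_total,
                                 p$l_totals, p$config)
      iso_t <- simulate_isotherm(p$rates_two_classes, p$m_total,
                                 p$l_totals, p$config)
      list(preset = p, isotherm_cooperative = iso_c,
           isotherm_two_classes = iso_t,
           max_abs_difference = max(abs(iso_c$n_avg - iso_t$n_avg)))
    },
    matched_pair_kinetics = {
      tr <- paired_timecourses(p$ko, p$omega, p$l_totals, p$m_total,
                               p$off_rate)
      list(preset = p, traces = tr,
           summary = data.frame(
             l_total = vapply(tr, attr, 0, "l_total"),
             t_max = vapply(tr, attr, 0, "t_max"),
             delta_max = vapply(tr, attr, 0, "delta_max")))
    })
}

#' Add seeded Gaussian noise to an isotherm or trace
#'
#' Additive, homoscedastic noise on the binding-density values, used to
#' emulate experimental scatter in fitting and recovery studies.  With a
#' `seed` the draw is reproducible and the caller's random-number state
#' is left untouched.  `sigma = 0` returns the input unchanged.
#'
#' @param x a [isotherm()] or a numeric vector of binding densities.
#' @param sigma noise standard deviation (binding-density units), >= 0.
#' @param seed optional integer seed.
#' @return Same shape as `x`; isotherms are returned without monotonicity
#'   validation and with the noise recorded in their provenance.
#' @export
add_noise <- function(x, sigma, seed = NULL) {
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma < 0)
    stop("'sigma' must be a single nonnegative number")
  n_vals <- if (inherits(x, "binding_isotherm")) x$n_avg else x
  if (sigma == 0) return(x)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
            else assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  noisy <- n_vals + rnorm(length(n_vals), sd = sigma)
  if (inherits(x, "binding_isotherm")) {
    prov <- attr(x, "provenance")
    prov$noise <- list(sigma = sigma, seed = seed)
    isotherm(x$free_l, noisy, provenance = prov, validate = FALSE)
  } else noisy
}
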