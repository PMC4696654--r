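#' Closed-form equilibrium binding models
#'
#' Constructors for the binding-polynomial (partition-function) models of
#' ligand binding at equilibrium:
#'
#' * `single_site_model(ko)`: one site, `<n> = Ko L / (1 + Ko L)`.
#' * `identical_independent_model(ko, n_sites)`: `N` identical sites
#'   without interaction, `<n> = N Ko L / (1 + Ko L)`.
#' * `cooperative_model(ko, omega)`: two identical interacting sites with
#'   binding polynomial `Z = 1 + 2 Ko L + omega Ko^2 L^2` and
#'   `<n> = (2 Ko L + 2 omega Ko^2 L^2) / Z`.
#' * `two_site_class_model(ko1, ko2)`: two different independent sites,
#'   `Z = 1 + (Ko1 + Ko2) L + Ko1 Ko2 L^2`.
#' * `hill_model(k, n_h, n_sites)`: the phenomenological Hill equation,
#'   fractional saturation `theta = K L^nH / (1 + K L^nH)`, reported as
#'   `<n> = N theta`.
#'
#' @param ko,ko1,ko2 intrinsic association constants (uM^-1), > 0.
#' @param omega cooperativity factor, > 0.
#' @param n_sites number of sites (1 or 2).
#' @param k Hill-equation constant (uM^-nH), > 0.
#' @param n_h Hill coefficient, > 0.
#' @return An object of class `binding_model` with a variant subclass.
#' @name binding_models
NULL

new_binding_model <- function(variant, params, n_sites) {
  structure(c(params, list(n_sites = n_sites)),
            class = c(variant, "binding_model"))
}

#' @rdname binding_models
#' @export
single_site_model <- function(ko) {
  stopifnot(ko > 0)
  new_binding_model("single_site", list(ko = ko), 1)
}

#' @rdname binding_models
#' @export
identical_independent_model <- function(ko, n_sites = 2) {
  stopifnot(ko > 0, n_sites %in% c(1, 2))
  new_binding_model("identical_independent", list(ko = ko), n_sites)
}

#' @rdname binding_models
#' @export
cooperative_model <- function(ko, omega) {
  stopifnot(ko > 0, omega > 0)
  new_binding_model("cooperative_two_site", list(ko = ko, omega = omega), 2)
}

#' @rdname binding_models
#' @export
two_site_class_model <- function(ko1, ko2) {
  stopifnot(ko1 > 0, ko2 > 0)
  new_binding_model("two_site_classes", list(ko1 = ko1, ko2 = ko2), 2)
}

#' @rdname binding_models
#' @export
hill_model <- function(k, n_h, n_sites = 1) {
  stopifnot(k > 0, n_h > 0, n_sites %in% c(1, 2))
  new_binding_model("hill", list(k = k, n_h = n_h), n_sites)
}

#' @export
print.binding_model <- function(x, ...) {
  cat("Binding model:", class(x)[1], "\n  parameters:",
      paste(names(x)[names(x) != "n_sites"],
            vapply(x[names(x) != "n_sites"], format, ""),
            sep = " = ", collapse = ", "),
      "\n  sites:", x$n_sites, "\n")
  invisible(x)
}

#' Equilibrium binding density of a closed-form model
#'
#' @param model a [binding_models] object.
#' @param l free ligand concentration(s) (uM), >= 0.
#' @return Binding density `<n>` at each `l` (dimensionless, in
#'   `[0, n_sites]`).
#' @export
#' @examples
#' model_binding_density(cooperative_model(1, 10), c(0.1, 1, 10))
model_binding_density <- function(model, l) {
  stopifnot(inherits(model, "binding_model"))
  if (any(!is.finite(l)) || any(l < 0))
    stop("free ligand concentrations must be finite and nonnegative")
  UseMethod("model_binding_density")
}

#' @export
model_binding_density.single_site <- function(model, l) {
  model$ko * l / (1 + model$ko * l)
}

#' @export
model_binding_density.identical_independent <- function(model, l) {
  model$n_sites * model$ko * l / (1 + model$ko * l)
}

#' @export
model_binding_density.cooperative_two_site <- function(model, l) {
  kl <- model$ko * l
  (2 * kl + 2 * model$omega * kl^2) / (1 + 2 * kl + model$omega * kl^2)
}

#' @export
model_binding_density.two_site_classes <- function(model, l) {
  (model$ko1 * l + model$ko2 * l + 2 * model$ko1 * model$ko2 * l^2) /
    (1 + (model$ko1 + model$ko2) * l + model$ko1 * model$ko2 * l^2)
}

#' @export
model_binding_density.hill <- function(model, l) {
  kl <- model$k * l^model$n_h
  model$n_sites * kl / (1 + kl)
}

#' Equilibrium binding isotherm
#'
#' An ordered set of (free ligand, binding density) points.  With
#' `validate = TRUE` (the default) the free-ligand grid must be strictly
#' increasing and the binding density non-decreasing within `[0, 2]`;
#' noisy synthetic isotherms may disable validation.
#'
#' @param free_l free ligand concentrations (uM), strictly increasing.
#' @param n_avg binding densities.
#' @param provenance free-form metadata (model parameters or preset id).
#' @param validate enforce the monotonicity invariants.
#' @return A data frame of class `binding_isotherm` with columns
#'   `free_l` and `n_avg`.
#' @export
isotherm <- function(free_l, n_avg, provenance = NULL, validate = TRUE) {
  stopifnot(length(free_l) == length(n_avg), length(free_l) >= 1)
  if (validate) {
    if (any(diff(free_l) <= 0))
      stop("free_l must be strictly increasing")
    if (any(n_avg < -1e-9) || any(n_avg > 2 + 1e-9))
      stop("n_avg must lie in [0, 2]")
    if (any(diff(n_avg) < -1e-9 * max(n_avg, 1)))
      stop("n_avg must be non-decreasing in free_l")
  }
  structure(data.frame(free_l = free_l, n_avg = n_avg),
            class = c("binding_isotherm", "data.frame"),
            provenance = provenance)
}

#' @export
print.binding_isotherm <- function(x, ...) {
  cat("Binding isotherm:", nrow(x), "points, free [L] in [",
      format(min(x$free_l)), ",", format(max(x$free_l)), "] uM, <n> up to",
      format(max(x$n_avg)), "\n")
  if (!is.null(attr(x, "provenance")))
    cat("  provenance:", paste(deparse(attr(x, "provenance")), collapse = ""),
        "\n")
  invisible(x)
}

#' Sample a closed-form model on a ligand grid
#'
#' @param model a [binding_models] object.
#' @param l free-ligand grid (uM); default [default_ligand_grid()] for
#'   the model.
#' @return A [isotherm()].
#' @export
model_isotherm <- function(model, l = default_ligand_grid(model)) {
  isotherm(l, model_binding_density(model, l),
           provenance = list(model = class(model)[1],
                             params = unclass(model)))
}

#' Logarithmic ligand grid spanning a binding transition
#'
#' Twenty-five points per decade from two orders of magnitude below the
#' dissociation constant of the strongest binding step to two orders of
#' magnitude above that of the weakest step, so the full transition is
#' sampled even under strong negative cooperativity.
#'
#' @param model a [binding_models] object, or `NULL` to use `ko`/`omega`.
#' @param ko,omega parameters used when no model is given.
#' @param points_per_decade grid density.
#' @return Increasing numeric vector of free-ligand concentrations (uM).
#' @export
default_ligand_grid <- function(model = NULL, ko = 1, omega = 1,
                                points_per_decade = 25) {
  if (!is.null(model)) {
    ks <- switch(class(model)[1],
                 single_site = model$ko,
                 identical_independent = model$ko,
                 cooperative_two_site = c(model$ko, model$ko * model$omega),
                 two_site_classes = c(model$ko1, model$ko2),
                 hill = model$k^(1 / model$n_h))
  } else {
    stopifnot(ko > 0, omega > 0)
    ks <- c(ko, ko * omega)
  }
  lo <- 0.01 / max(ks)
  hi <- 100 / min(ks)
  10^seq(log10(lo), log10(hi), by = 1 / points_per_decade)
}

#' Assemble an isotherm from converged time courses
#'
#' Extracts one `(free [L], <n>)` point from the equilibrium state of
#' each time course and orders the points by free ligand concentration.
#' All time courses must share the same rate coefficients and total
#' macromolecule concentration and must have converged.
#'
#' @param tcs list of `binding_timecourse` objects.
#' @return A [isotherm()].
#' @export
isotherm_from_timecourses <- function(tcs) {
  if (inherits(tcs, "binding_timecourse")) tcs <- list(tcs)
  stopifnot(length(tcs) >= 1,
            all(vapply(tcs, inherits, TRUE, "binding_timecourse")))
  bad <- !vapply(tcs, `[[`, TRUE, "converged")
  if (any(bad))
    stop("non-converged time course(s) at [L]o = ",
         paste(vapply(tcs[bad], `[[`, 0, "l_total"), collapse = ", "),
         " uM")
  m_total <- tcs[[1]]$m_total
  r0 <- unclass(tcs[[1]]$rates)
  for (tc in tcs[-1]) {
    if (abs(tc$m_total - m_total) > 1e-12 ||
        max(abs(unclass(tc$rates) - r0)) > 1e-12)
      stop("time courses must share rate coefficients and m_total")
  }
  l <- vapply(tcs, function(tc) tc$equilibrium_state[["l"]], 0)
  n <- vapply(tcs, function(tc) binding_density(tc$equilibrium_state,
                                                tc$m_total), 0)
  o <- order(l)
  isotherm(l[o], n[o],
           provenance = list(source = "simulation", rates = r0,
                             m_total = m_total,
                             l_total = vapply(tcs, `[[`, 0, "l_total")[o]))
}

#' Simulate an equilibrium isotherm over a grid of total ligand
#' concentrations
#'
#' Runs one kinetic simulation per total ligand concentration and
#' collects the equilibrium points.
#'
#' @param rates a [rate_constants()] object.
#' @param m_total total macromolecule concentration (uM).
#' @param l_totals vector of total ligand concentrations (uM).
#' @param config a [sim_config()].
#' @return A [isotherm()].
#' @export
#' @examples
#' iso <- simulate_isotherm(cooperative_rates(1, 10), 1, c(0.1, 1, 10, 100))
simulate_isotherm <- function(rates, m_total, l_totals,
                              config = sim_config()) {
  tcs <- lapply(l_totals, function(l0)
    integrate_binding(rates, m_total, l0, config))
  isotherm_from_timecourses(tcs)
}

#' Characteristic free-ligand span of a binding transition
#'
#' The ratio of the free-ligand concentrations at fractional saturations
#' 0.9 and 0.1.  For a single class of independent sites the span is 81
#' (1.908 log10 units); positive cooperativity compresses it and negative
#' cooperativity (or site heterogeneity) stretches it.
#'
#' @param x a [binding_models] object or a [isotherm()].
#' @param n_sites site number used to convert `<n>` to fractional
#'   saturation for an isotherm; default [estimate_site_number()].
#' @return List with elements `ratio`, `log10_ratio`, `l_low` (uM at
#'   theta = 0.1) and `l_high` (uM at theta = 0.9).
#' @export
#' @examples
#' free_ligand_span(single_site_model(1))$ratio        # 81
#' free_ligand_span(hill_model(1, n_h = 2))$ratio      # 9
free_ligand_span <- function(x, n_sites = NULL) UseMethod("free_ligand_span")

span_result <- function(l_low, l_high) {
  list(ratio = l_high / l_low, log10_ratio = log10(l_high / l_low),
       l_low = l_low, l_high = l_high)
}

#' @export
free_ligand_span.binding_model <- function(x, n_sites = NULL) {
  n <- x$n_sites
  theta_at <- function(l) model_binding_density(x, l) / n
  solve_theta <- function(target) {
    f <- function(u) theta_at(10^u) - target
    lo <- -12; hi <- 12
    while (f(hi) < 0 && hi < 40) hi <- hi + 4
    while (f(lo) > 0 && lo > -40) lo <- lo - 4
    10^uniroot(f, c(lo, hi), tol = 1e-12)$root
  }
  span_result(solve_theta(0.1), solve_theta(0.9))
}

#' @export
free_ligand_span.binding_isotherm <- function(x, n_sites = NULL) {
  if (is.null(n_sites)) n_sites <- estimate_site_number(x)
  keep <- x$free_l > 0
  lx <- log(x$free_l[keep])
  theta <- x$n_avg[keep] / n_sites
  if (min(theta) > 0.1 || max(theta) < 0.9)
    stop("isotherm does not span fractional saturations 0.1 to 0.9; ",
         "extend the ligand range")
  # monotone piecewise-cubic interpolation of theta on log free ligand
  f <- splinefun(lx, theta, method = "hyman")
  solve_theta <- function(target)
    exp(uniroot(function(u) f(u) - target, range(lx), tol = 1e-12)$root)
  span_result(solve_theta(0.1), solve_theta(0.9))
}
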