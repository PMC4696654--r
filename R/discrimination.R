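.auto_step <- function(rates, m_total, l_total) {
  0.01 / (max(rates[1:4]) * max(l_total, m_total) + max(rates[5:8]))
}

# Fixed-step RK4 sampled at explicit output times, with automatic step
# halving on negative-concentration excursions.
.sim_course <- function(rates, m_total, l_total, times, h = NULL) {
  rates <- as_rate_constants(rates)
  if (is.null(h)) h <- .auto_step(rates, m_total, l_total)
  y0 <- c(m_total, 0, 0, 0, l_total)
  for (attempt in 1:8) {
    st <- .rk4_course_cpp(y0, unclass(rates), h, times, 1e-9)
    if (!isTRUE(attr(st, "negative"))) break
    h <- h / 2
  }
  if (isTRUE(attr(st, "negative")))
    stop("negative concentration excursion persisted after 8 step halvings")
  colnames(st) <- c("m00", "m10", "m01", "m11", "l")
  st
}

#' Pre-equilibrium discrepancy between matched binding models
#'
#' Builds the two-site-class model that is equilibrium-equivalent to a
#' negatively cooperative model (see [equivalent_two_sites()]), simulates
#' both on identical time grids and steps at each total ligand
#' concentration, and returns the occupancy difference
#' `delta_n(t) = <n>_coop(t) - <n>_two_classes(t)`.  Although the two
#' models share every equilibrium isotherm point, their approach to
#' equilibrium differs: each trace grows from zero, peaks at an interior
#' time and decays back below simulation precision — the kinetic
#' signature that discriminates the models.
#'
#' All dissociation coefficients are set to `off_rate` in both models.
#'
#' @param ko intrinsic association constant of the cooperative model
#'   (uM^-1).
#' @param omega cooperativity factor, must be < 1 for a non-degenerate
#'   pair (omega = 1 gives identical models and a zero trace).
#' @param l_totals total ligand concentrations (uM).
#' @param m_total total macromolecule concentration (uM).
#' @param off_rate common dissociation rate coefficient (s^-1).
#' @param times output time grid (s); the default covers the approach to
#'   equilibrium (15 dissociation time constants, log-spaced).
#' @return List of class `discrepancy_traces`; one data frame per
#'   `l_totals` entry with columns `time`, `n_coop`, `n_two_classes`,
#'   `delta_n`, and attributes `l_total`, `t_max`, `delta_max`.
#' @export
#' @examples
#' tr <- paired_timecourses(0.55, 0.33058, l_totals = c(10, 100))
#' sapply(tr, attr, "delta_max")
paired_timecourses <- function(ko, omega, l_totals, m_total = 1,
                               off_rate = 1, times = NULL) {
  map <- equivalent_two_sites(ko, omega)  # errors for omega > 1
  rc <- cooperative_rates(ko, omega, off_rate)
  rt <- two_site_class_rates(map[["ko1"]], map[["ko2"]], off_rate)
  if (is.null(times)) {
    t_end <- 15 / off_rate
    times <- unique(c(0, 10^seq(log10(t_end) - 5, log10(t_end),
                                length.out = 250)))
  }
  out <- lapply(l_totals, function(l0) {
    h <- min(.auto_step(rc, m_total, l0), .auto_step(rt, m_total, l0))
    nc <- binding_density(as.data.frame(.sim_course(rc, m_total, l0,
                                                    times, h)), m_total)
    nt <- binding_density(as.data.frame(.sim_course(rt, m_total, l0,
                                                    times, h)), m_total)
    delta <- nc - nt
    i <- which.max(abs(delta))
    structure(data.frame(time = times, n_coop = nc, n_two_classes = nt,
                         delta_n = delta),
              class = c("discrepancy_trace", "data.frame"),
              l_total = l0, t_max = times[i], delta_max = delta[i])
  })
  structure(out, class = "discrepancy_traces",
            ko = ko, omega = omega, m_total = m_total,
            off_rate = off_rate)
}

#' @export
print.discrepancy_traces <- function(x, ...) {
  cat("Matched-model discrepancy traces (ko =", attr(x, "ko"),
      ", omega =", attr(x, "omega"), ")\n")
  for (tr in x)
    cat(sprintf("  [L]o = %8.3g uM: max |delta n| = %.4g at t = %.4g s\n",
                attr(tr, "l_total"), abs(attr(tr, "delta_max")),
                attr(tr, "t_max")))
  invisible(x)
}

aicc <- function(rss, n_obs, n_par) {
  k <- n_par + 1  # residual variance counts as a parameter
  if (n_obs - k - 1 <= 0) return(Inf)
  n_obs * log(rss / n_obs) + 2 * k + 2 * k * (k + 1) / (n_obs - k - 1)
}

new_binding_fit <- function(model, estimates, se, rss, n_obs, n_par,
                            converged, details = NULL) {
  structure(list(model = model, estimates = estimates, se = se,
                 rss = rss, sigma = sqrt(rss / max(n_obs - n_par, 1)),
                 aicc = if (converged) aicc(rss, n_obs, n_par) else NA_real_,
                 n_obs = n_obs, n_par = n_par, converged = converged,
                 details = details),
            class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  cat("Nonlinear least-squares fit:", x$model,
      if (!x$converged) "(NOT converged)", "\n")
  est <- format(x$estimates, digits = 4)
  se <- format(x$se, digits = 2)
  for (i in seq_along(est))
    cat("  ", names(x$estimates)[i], "=", est[i], "+/-", se[i], "\n")
  cat("  RSS =", format(x$rss, digits = 4), " AICc =",
      format(x$aicc, digits = 4), " n =", x$n_obs, "\n")
  invisible(x)
}

#' Fit a closed-form binding model to an isotherm
#'
#' Least-squares fit by the Levenberg-Marquardt algorithm with positivity
#' bounds.  Available model families:
#' `"hyperbola"` (`<n> = Nmax K L / (1 + K L)`, the form an experimenter
#' fits to an apparently simple saturation curve), `"single_site"`
#' (hyperbola with unit plateau), `"cooperative"` (two identical
#' interacting sites; parameters `ko`, `omega`), `"two_site_classes"`
#' (parameters `ko1`, `ko2`) and `"hill"` (`Nmax`, `K`, `n_h`).
#'
#' @param iso a [isotherm()] (possibly noisy).
#' @param model model family tag.
#' @param start optional named list of start values.
#' @return A `binding_fit`: parameter estimates with standard errors from
#'   the Jacobian, residual sum of squares, AICc and convergence flag.
#' @export
#' @examples
#' iso <- model_isotherm(cooperative_model(1, 0.02),
#'                       l = seq(0.06, 6, by = 0.06))
#' fit_isotherm(iso, "hyperbola")$estimates
fit_isotherm <- function(iso, model = c("hyperbola", "single_site",
                                        "cooperative", "two_site_classes",
                                        "hill"),
                         start = NULL) {
  stopifnot(inherits(iso, "binding_isotherm"))
  model <- match.arg(model)
  l <- iso$free_l
  n <- iso$n_avg
  khalf <- 1 / max(l[which.min(abs(n - max(n) / 2))], 1e-12)
  spec <- switch(model,
    hyperbola = list(formula = n ~ Nmax * K * l / (1 + K * l),
                     start = list(Nmax = max(n), K = khalf)),
    single_site = list(formula = n ~ K * l / (1 + K * l),
                       start = list(K = khalf)),
    cooperative = list(
      formula = n ~ (2 * ko * l + 2 * omega * ko^2 * l^2) /
                    (1 + 2 * ko * l + omega * ko^2 * l^2),
      start = list(ko = khalf, omega = 1)),
    two_site_classes = list(
      formula = n ~ ((ko1 + ko2) * l + 2 * ko1 * ko2 * l^2) /
                    (1 + (ko1 + ko2) * l + ko1 * ko2 * l^2),
      start = list(ko1 = 2 * khalf, ko2 = khalf / 2)),
    hill = list(formula = n ~ Nmax * K * l^n_h / (1 + K * l^n_h),
                start = list(Nmax = max(n), K = khalf, n_h = 1)))
  if (!is.null(start)) spec$start[names(start)] <- start
  if (nrow(iso) < 2 * length(spec$start))
    stop("need at least ", 2 * length(spec$start),
         " points to fit ", length(spec$start), " parameters")
  fit <- tryCatch(
    minpack.lm::nlsLM(spec$formula, data = data.frame(l = l, n = n),
                      start = spec$start,
                      lower = rep(1e-12, length(spec$start)),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error"))
    return(new_binding_fit(model, setNames(rep(NA_real_,
                                               length(spec$start)),
                                           names(spec$start)),
                           NA_real_, NA_real_, nrow(iso),
                           length(spec$start), FALSE,
                           details = conditionMessage(fit)))
  sm <- summary(fit)
  new_binding_fit(model, coef(fit), sm$coefficients[, "Std. Error"],
                  sum(residuals(fit)^2), nrow(iso), length(spec$start),
                  fit$convInfo$isConv, details = fit)
}

# rate set implied by constrained macroscopic constants and free off-rates
.constrained_rates <- function(model, K1, K2, koff) {
  koff <- unname(koff)
  if (model == "cooperative") {
    ko <- K1 / 2
    omega <- 4 * K2 / K1
    cooperative_rates(ko, omega, koff[1])
  } else {
    disc <- K1^2 - 4 * K1 * K2
    if (disc < 0)
      stop("constraint-infeasible: macroscopic constants require K1 >= 4 K2 ",
           "for a two-site-class model")
    ko1 <- (K1 + sqrt(disc)) / 2
    ko2 <- (K1 - sqrt(disc)) / 2
    rate_constants(k1 = ko1 * koff[1], k2 = ko2 * koff[2],
                   k1_given_2 = ko1 * koff[1], k2_given_1 = ko2 * koff[2],
                   km1 = koff[1], km2 = koff[2],
                   km1_given_2 = koff[1], km2_given_1 = koff[2])
  }
}

#' Constrained kinetic fit of binding time courses
#'
#' Fits a binding model to observed occupancy time courses at several
#' total ligand concentrations, holding the macroscopic equilibrium
#' constants fixed at values determined beforehand from the equilibrium
#' isotherm (stage one of the discrimination strategy).  The constraints
#' are imposed by reparameterization, not penalties: for the cooperative
#' model `Ko = K1/2` and `omega = 4 K2 / K1` are fixed and the single
#' free parameter is the common dissociation coefficient; for the
#' two-site-class model the intrinsic constants are the roots of
#' `x^2 - K1 x + K1 K2 = 0` (requiring `K1 >= 4 K2`) and the free
#' parameters are the two dissociation coefficients.  Optimization is on
#' the log scale; model selection between the two constrained fits uses
#' AICc.
#'
#' @param data data frame with columns `time` (s), `n_avg` and `l_total`
#'   (uM); one group of rows per time course.
#' @param model `"cooperative"` or `"two_site_classes"`.
#' @param constraints named list or vector with the macroscopic stepwise
#'   association constants `K1` and `K2` (uM^-1).
#' @param m_total total macromolecule concentration (uM).
#' @param koff_start optional start value(s) for the dissociation
#'   coefficient(s) (s^-1).
#' @return A `binding_fit`; `estimates` holds the fitted dissociation
#'   coefficient(s) and the derived rate coefficients are in
#'   `details$rates`.
#' @export
fit_kinetics <- function(data, model = c("cooperative", "two_site_classes"),
                         constraints, m_total, koff_start = NULL) {
  model <- match.arg(model)
  stopifnot(is.data.frame(data),
            all(c("time", "n_avg", "l_total") %in% names(data)),
            m_total > 0)
  K1 <- constraints[["K1"]]
  K2 <- constraints[["K2"]]
  stopifnot(K1 > 0, K2 > 0)
  .constrained_rates(model, K1, K2, c(1, 1))  # fail fast if infeasible
  groups <- split(data, data$l_total)
  n_par <- if (model == "cooperative") 1L else 2L
  if (is.null(koff_start)) {
    # observed relaxation rate is roughly koff * (1 + Ko_eff * L) under the
    # equilibrium constraint, so divide the half-rise rate by that factor
    ko_eff <- K1 / 2
    ks <- vapply(groups, function(g) {
      g <- g[order(g$time), ]
      i <- which(g$n_avg >= max(g$n_avg) / 2)[1]
      th <- max(g$time[i], min(g$time[g$time > 0]))
      (log(2) / th) / (1 + ko_eff * g$l_total[1])
    }, 0)
    koff_start <- rep(stats::median(ks), n_par)
  } else koff_start <- rep(koff_start, length.out = n_par)

  objective <- function(logk) {
    rates <- .constrained_rates(model, K1, K2, exp(logk))
    rss <- 0
    for (g in groups) {
      l0 <- g$l_total[1]
      o <- order(g$time)
      st <- .sim_course(rates, m_total, l0, g$time[o])
      pred <- binding_density(as.data.frame(st), m_total)
      rss <- rss + sum((g$n_avg[o] - pred)^2)
    }
    rss
  }
  # coarse log-grid scan guards against local minima before the
  # gradient-based refinement
  offsets <- log(c(0.1, 1 / 3, 1, 3, 10))
  grid <- as.matrix(do.call(expand.grid, rep(list(offsets), n_par)))
  scan <- apply(grid, 1, function(o) objective(log(koff_start) + o))
  start <- log(koff_start) + grid[which.min(scan), ]
  opt <- optim(start, objective, method = "L-BFGS-B",
               lower = start - log(100), upper = start + log(100),
               hessian = TRUE)
  koff <- exp(opt$par)
  nobs <- nrow(data)
  s2 <- opt$value / max(nobs - n_par, 1)
  se_log <- tryCatch(sqrt(2 * s2 * diag(solve(opt$hessian))),
                     error = function(e) rep(NA_real_, n_par))
  nm <- if (n_par == 1) "koff" else c("koff1", "koff2")
  new_binding_fit(model, setNames(koff, nm), setNames(se_log * koff, nm),
                  opt$value, nobs, n_par, opt$convergence == 0,
                  details = list(rates = .constrained_rates(model, K1, K2,
                                                            koff),
                                 constraints = c(K1 = K1, K2 = K2),
                                 optim = opt[c("convergence", "message")]))
}

#' Count resolvable kinetic phases in a binding time course
#'
#' Fits mono- and bi-exponential approach-to-equilibrium models to an
#' occupancy trace and reports 2 phases only when the bi-exponential fit
#' is favored by the extra-sum-of-squares F-test at level `alpha` *and*
#' the minor phase is experimentally meaningful: its amplitude is at
#' least `min_amplitude` of the total and the two rates are separated by
#' at least a factor `min_rate_ratio`.  Under pseudo-first-order
#' conditions (ligand in large excess) binding to a single site gives a
#' mono-exponential trace, so this classification probes the number of
#' kinetically visible sites.
#'
#' @param time,n_avg the observed trace; `n_avg` must be non-decreasing
#'   (within `monotone_tol` of its amplitude).  A `binding_timecourse`
#'   may be given as `time`.
#' @param alpha F-test level.
#' @param min_amplitude minimum minor-phase amplitude fraction.
#' @param min_rate_ratio minimum fast/slow rate separation.
#' @param monotone_tol tolerated non-monotonicity, as a fraction of the
#'   trace amplitude.
#' @return 1 or 2, with attributes `p_value`, `fits` (the two nls fits)
#'   and `amplitude_fraction`.
#' @export
classify_kinetics <- function(time, n_avg = NULL, alpha = 0.01,
                              min_amplitude = 0.02, min_rate_ratio = 3,
                              monotone_tol = 1e-3) {
  if (inherits(time, "binding_timecourse")) {
    tc <- time
    n_avg <- binding_density(tc)
    time <- tc$states$t
  }
  stopifnot(length(time) == length(n_avg), length(time) >= 8)
  o <- order(time)
  time <- time[o]; n_avg <- n_avg[o]
  amp <- max(n_avg) - min(n_avg)
  if (amp <= 0) stop("flat trace: no binding progress to classify")
  if (any(diff(n_avg) < -monotone_tol * amp))
    stop("non-monotone trace: classification supports monotone ",
         "approach-to-equilibrium traces only")
  t_half <- time[which(n_avg >= min(n_avg) + amp / 2)[1]]
  k0 <- log(2) / max(t_half, min(time[time > 0]))
  df1 <- data.frame(t = time, n = n_avg)
  f1 <- tryCatch(minpack.lm::nlsLM(n ~ A * (1 - exp(-k * t)), data = df1,
                                   start = list(A = max(n_avg), k = k0),
                                   lower = c(1e-12, 1e-12)),
                 error = function(e) NULL)
  if (is.null(f1)) stop("mono-exponential fit failed")
  rss1 <- sum(residuals(f1)^2)
  tss <- sum((n_avg - mean(n_avg))^2)
  if (rss1 <= 1e-16 * tss)   # numerically exact mono-exponential
    return(structure(1L, p_value = 1, amplitude_fraction = 0,
                     fits = list(mono = f1, bi = NULL)))
  A0 <- coef(f1)[["A"]]; kf <- coef(f1)[["k"]]
  f2 <- tryCatch(minpack.lm::nlsLM(
    n ~ A1 * (1 - exp(-k1 * t)) + A2 * (1 - exp(-k2 * t)), data = df1,
    start = list(A1 = 0.7 * A0, A2 = 0.3 * A0, k1 = 3 * kf, k2 = kf / 3),
    lower = rep(1e-12, 4),
    control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(f2))
    return(structure(1L, p_value = 1, amplitude_fraction = 0,
                     fits = list(mono = f1, bi = NULL)))
  rss2 <- sum(residuals(f2)^2)
  df_den <- length(time) - 4
  Fstat <- ((rss1 - rss2) / 2) / (rss2 / df_den)
  p <- pf(Fstat, 2, df_den, lower.tail = FALSE)
  cf <- coef(f2)
  amp_frac <- min(cf[["A1"]], cf[["A2"]]) / (cf[["A1"]] + cf[["A2"]])
  ratio <- max(cf[["k1"]], cf[["k2"]]) / min(cf[["k1"]], cf[["k2"]])
  phases <- if (!is.na(p) && p < alpha && amp_frac >= min_amplitude &&
                ratio >= min_rate_ratio) 2L else 1L
  structure(phases, p_value = p, amplitude_fraction = amp_frac,
            fits = list(mono = f1, bi = f2))
}
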