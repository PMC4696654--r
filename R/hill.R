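#' Estimate the number of binding sites from an isotherm plateau
#'
#' The site number `N` is taken as the asymptotic value of the binding
#' density, estimated blind from the data: if a rectangular hyperbola
#' `<n> = Nmax K L / (1 + K L)` describes the isotherm to within
#' `hyperbola_tol` (root-mean-square residual relative to the plateau),
#' `N` is the fitted asymptote `Nmax` — this is what an experimenter
#' reads off an apparently simple saturation curve.  Otherwise (sigmoid
#' or biphasic isotherms) `N` is the intercept of a linear regression of
#' the last `tail_points` binding densities on `1/L`, the model-free
#' plateau extrapolation.
#'
#' The estimate is returned as a continuous value, not rounded to an
#' integer.  An isotherm whose largest binding density is below 90
#' percent of the estimated plateau is rejected: the plateau is not
#' characterised and the ligand range must be extended.
#'
#' @param iso a [isotherm()].
#' @param tail_points number of top points used in the `1/L`
#'   extrapolation.
#' @param hyperbola_tol relative RMS residual below which the hyperbola
#'   asymptote is used.
#' @return Estimated site number (dimensionless, continuous).
#' @export
#' @examples
#' iso <- model_isotherm(cooperative_model(1, 10))
#' estimate_site_number(iso)  # close to 2
estimate_site_number <- function(iso, tail_points = 5,
                                 hyperbola_tol = 0.01) {
  stopifnot(inherits(iso, "binding_isotherm"))
  keep <- iso$free_l > 0 & iso$n_avg > 0
  l <- iso$free_l[keep]
  n <- iso$n_avg[keep]
  if (length(l) < max(3, tail_points))
    stop("too few isotherm points to estimate the site number")

  est <- NULL
  hy <- tryCatch(
    minpack.lm::nlsLM(n ~ Nmax * K * l / (1 + K * l),
                      start = list(Nmax = max(n),
                                   K = 1 / l[which.min(abs(n - max(n) / 2))]),
                      lower = c(1e-12, 1e-12)),
    error = function(e) NULL)
  if (!is.null(hy)) {
    Nmax <- coef(hy)[["Nmax"]]
    if (sqrt(mean(residuals(hy)^2)) < hyperbola_tol * Nmax) est <- Nmax
  }
  if (is.null(est)) {
    i <- tail(seq_along(l), tail_points)
    est <- unname(coef(lm(n[i] ~ I(1 / l[i])))[1])
  }
  if (!is.finite(est) || est <= 0)
    stop("site-number estimate is not positive; isotherm may be degenerate")
  if (max(n) < 0.9 * est)
    stop("isotherm has not approached its plateau (max <n> = ",
         format(max(n)), " < 90% of the estimated asymptote ", format(est),
         "); extend the ligand range")
  est
}

#' Wyman Hill plot of a binding isotherm
#'
#' Transforms an isotherm to Hill-plot coordinates
#' `x = ln [L]`, `y = ln(<n> / (N - <n>))`.  Points with `<n>` outside
#' `(0, N)` cannot be transformed and are dropped with a message.  The
#' transition region — the central part of the saturation transition used
#' for slope analysis — is marked where the fractional saturation
#' `<n>/N` lies within `transition`.
#'
#' @param iso a [isotherm()].
#' @param n_sites site number `N`; default [estimate_site_number()].
#' @param transition fractional-saturation bounds of the transition
#'   region.
#' @return A data frame of class `hill_plot` with columns `x`, `y`,
#'   `transition` and attributes `n_sites` and `transition_bounds`.
#' @export
wyman_hill_plot <- function(iso, n_sites = NULL,
                            transition = c(0.25, 0.75)) {
  stopifnot(inherits(iso, "binding_isotherm"),
            length(transition) == 2, transition[1] < transition[2],
            transition[1] > 0, transition[2] < 1)
  if (is.null(n_sites)) n_sites <- estimate_site_number(iso)
  stopifnot(n_sites > 0)
  drop <- iso$n_avg <= 0 | iso$n_avg >= n_sites | iso$free_l <= 0
  if (any(iso$n_avg >= n_sites))
    message(sum(iso$n_avg >= n_sites),
            " point(s) with <n> >= N dropped from the Hill plot")
  l <- iso$free_l[!drop]
  n <- iso$n_avg[!drop]
  theta <- n / n_sites
  hp <- data.frame(x = log(l), y = log(n / (n_sites - n)),
                   transition = theta >= transition[1] &
                                theta <= transition[2])
  if (sum(hp$transition) < 5)
    stop("fewer than 5 points in the transition region; ",
         "sample the transition more densely")
  structure(hp, class = c("hill_plot", "data.frame"),
            n_sites = n_sites, transition_bounds = transition)
}

#' Hill coefficient from the transition region of a Hill plot
#'
#' Fits a third-order polynomial `y = a0 + a1 x + a2 x^2 + a3 x^3` to the
#' transition-region points by least squares and reports the Hill
#' coefficient as the extremal slope: the stationary extremum of the
#' fitted derivative when it falls inside the transition-region
#' x-interval, otherwise the boundary value deviating most from 1
#' (extrapolating the cubic beyond the fitted range would be
#' meaningless).  The slope maximum corresponds to positive and the
#' minimum to negative cooperativity; when the extremal slope is 1 within
#' 1e-6 the sites are reported as non-interacting (`operator = "none"`).
#'
#' @param hp a [wyman_hill_plot()] result.
#' @return An object of class `hill_result`: list with `n_h`, the cubic
#'   coefficients `a0`..`a3`, `x_extremum` (ln uM), `operator`
#'   (`"max"`, `"min"` or `"none"`) and `n_points_fit`.
#' @export
#' @examples
#' iso <- model_isotherm(cooperative_model(1, 10))
#' hill_coefficient(wyman_hill_plot(iso))$n_h  # about 1.52
hill_coefficient <- function(hp) {
  stopifnot(inherits(hp, "hill_plot"))
  tr <- hp[hp$transition, ]
  if (nrow(tr) < 5) stop("fewer than 5 transition-region points")
  if (diff(range(tr$x)) < 1e-8) stop("degenerate fit: collinear x values")
  fit <- lm(y ~ x + I(x^2) + I(x^3), data = tr)
  a <- unname(coef(fit))
  if (any(!is.finite(a))) stop("degenerate cubic fit")
  dslope <- function(x) a[2] + 2 * a[3] * x + 3 * a[4] * x^2
  xr <- range(tr$x)
  vertex <- if (abs(a[4]) > 0) -a[3] / (3 * a[4]) else NA_real_
  if (is.finite(vertex) && vertex >= xr[1] && vertex <= xr[2]) {
    x_ext <- vertex
  } else {
    db <- dslope(xr)
    x_ext <- xr[which.max(abs(db - 1))]
  }
  n_h <- dslope(x_ext)
  if (n_h <= 0)
    warning("non-positive extremal slope; the cubic fit is unreliable here")
  operator <- if (abs(n_h - 1) < 1e-6) "none" else if (n_h > 1) "max" else "min"
  if (operator == "none") n_h <- 1
  structure(list(n_h = n_h, a0 = a[1], a1 = a[2], a2 = a[3], a3 = a[4],
                 x_extremum = x_ext, operator = operator,
                 n_points_fit = nrow(tr),
                 n_sites = attr(hp, "n_sites")),
            class = "hill_result")
}

#' @export
print.hill_result <- function(x, ...) {
  cat("Hill analysis: n_H =", format(x$n_h, digits = 4),
      "(operator", x$operator, "at ln[L] =", format(x$x_extremum, digits = 4),
      ")\n  cubic: a0 =", format(x$a0, digits = 4),
      " a1 =", format(x$a1, digits = 4),
      " a2 =", format(x$a2, digits = 4),
      " a3 =", format(x$a3, digits = 4),
      "\n  fitted to", x$n_points_fit, "transition points, N =",
      format(x$n_sites, digits = 4), "\n")
  invisible(x)
}

#' One-call Hill analysis of an isotherm
#'
#' Convenience wrapper: estimate the site number (unless given), build
#' the Wyman Hill plot and extract the Hill coefficient.
#'
#' @inheritParams wyman_hill_plot
#' @return A `hill_result` (see [hill_coefficient()]).
#' @export
hill_analysis <- function(iso, n_sites = NULL,
                          transition = c(0.25, 0.75)) {
  hill_coefficient(wyman_hill_plot(iso, n_sites, transition))
}
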