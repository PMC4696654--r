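#' Microscopic rate coefficients of the two-site binding scheme
#'
#' Bundles the eight kinetic coefficients connecting the four microscopic
#' states of a macromolecule with two ligand-binding sites: the empty
#' state, the two singly bound states (ligand on site 1 or site 2) and
#' the doubly bound state.  `k1` and `k2` are the association rate
#' coefficients for binding to an empty macromolecule, `k1_given_2` and
#' `k2_given_1` those for binding to a site while the other one is
#' occupied; `km*` are the corresponding dissociation coefficients.
#'
#' The scheme is a closed reaction cycle, so at equilibrium the two paths
#' from the empty to the doubly bound state must give the same overall
#' constant (detailed balance):
#' `(k1/km1) * (k2_given_1/km2_given_1) == (k2/km2) * (k1_given_2/km1_given_2)`.
#' Violations beyond a relative tolerance of 1e-6 are an error unless
#' `allow_cycle_violation = TRUE`, which permits exploring non-equilibrium
#' steady states (closed-form equilibrium isotherms then no longer apply).
#'
#' @param k1,k2,k1_given_2,k2_given_1 association rate coefficients
#'   (uM^-1 s^-1), all strictly positive.
#' @param km1,km2,km1_given_2,km2_given_1 dissociation rate coefficients
#'   (s^-1), all strictly positive.
#' @param allow_cycle_violation logical; skip the detailed-balance check.
#' @return An object of class `rate_constants` (named numeric vector of
#'   length 8).
#' @seealso [cooperative_rates()], [two_site_class_rates()]
#' @export
#' @examples
#' rate_constants(1, 1, 10, 10, 1, 1, 1, 1)  # positive cooperativity
rate_constants <- function(k1, k2, k1_given_2, k2_given_1,
                           km1, km2, km1_given_2, km2_given_1,
                           allow_cycle_violation = FALSE) {
  k <- c(k1 = k1, k2 = k2, k1_given_2 = k1_given_2, k2_given_1 = k2_given_1,
         km1 = km1, km2 = km2, km1_given_2 = km1_given_2,
         km2_given_1 = km2_given_1)
  if (!all(is.finite(k)) || any(k <= 0))
    stop("all eight rate coefficients must be finite and strictly positive")
  path1 <- (k[["k1"]] / k[["km1"]]) * (k[["k2_given_1"]] / k[["km2_given_1"]])
  path2 <- (k[["k2"]] / k[["km2"]]) * (k[["k1_given_2"]] / k[["km1_given_2"]])
  closed <- abs(path1 - path2) <= 1e-6 * max(path1, path2)
  if (!closed && !allow_cycle_violation)
    stop("thermodynamic cycle closure violated: the two binding paths give ",
         "overall constants ", format(path1), " and ", format(path2),
         "; use allow_cycle_violation = TRUE for non-equilibrium schemes")
  structure(k, class = "rate_constants", cycle_closed = closed)
}

#' Rate coefficients for two identical, possibly interacting sites
#'
#' All dissociation coefficients equal `off_rate`; association to an empty
#' macromolecule proceeds with intrinsic constant `ko`, and association of
#' the second ligand is scaled by the cooperativity factor `omega`
#' (`omega > 1` positive, `omega < 1` negative cooperativity, `omega = 1`
#' independent sites).
#'
#' @param ko intrinsic association constant of the empty sites (uM^-1).
#' @param omega dimensionless cooperativity factor, > 0.
#' @param off_rate common dissociation rate coefficient (s^-1).
#' @return A [rate_constants()] object.
#' @export
cooperative_rates <- function(ko, omega, off_rate = 1) {
  stopifnot(ko > 0, omega > 0, off_rate > 0)
  rate_constants(k1 = ko * off_rate, k2 = ko * off_rate,
                 k1_given_2 = omega * ko * off_rate,
                 k2_given_1 = omega * ko * off_rate,
                 km1 = off_rate, km2 = off_rate,
                 km1_given_2 = off_rate, km2_given_1 = off_rate)
}

#' Rate coefficients for two different, non-interacting site classes
#'
#' Site 1 binds with intrinsic constant `ko1`, site 2 with `ko2`, and the
#' occupancy of one site does not affect the other
#' (`k1_given_2 = k1`, `k2_given_1 = k2`).
#'
#' @param ko1,ko2 intrinsic association constants (uM^-1).
#' @param off_rate common dissociation rate coefficient (s^-1).
#' @return A [rate_constants()] object.
#' @export
two_site_class_rates <- function(ko1, ko2, off_rate = 1) {
  stopifnot(ko1 > 0, ko2 > 0, off_rate > 0)
  rate_constants(k1 = ko1 * off_rate, k2 = ko2 * off_rate,
                 k1_given_2 = ko1 * off_rate, k2_given_1 = ko2 * off_rate,
                 km1 = off_rate, km2 = off_rate,
                 km1_given_2 = off_rate, km2_given_1 = off_rate)
}

#' @export
print.rate_constants <- function(x, ...) {
  cat("Two-site binding scheme rate coefficients\n")
  cat("  association (uM^-1 s^-1): k1 =", x[["k1"]], " k2 =", x[["k2"]],
      " k1(2) =", x[["k1_given_2"]], " k2(1) =", x[["k2_given_1"]], "\n")
  cat("  dissociation (s^-1):      k-1 =", x[["km1"]], " k-2 =", x[["km2"]],
      " k-1(2) =", x[["km1_given_2"]], " k-2(1) =", x[["km2_given_1"]], "\n")
  invisible(x)
}

as_rate_constants <- function(x) {
  if (inherits(x, "rate_constants")) return(x)
  nm <- c("k1", "k2", "k1_given_2", "k2_given_1",
          "km1", "km2", "km1_given_2", "km2_given_1")
  if (is.numeric(x) && length(x) == 8) {
    if (!is.null(names(x)) && all(nm %in% names(x))) x <- x[nm]
    return(do.call(rate_constants, as.list(unname(x))))
  }
  stop("cannot interpret 'rates'; supply a rate_constants object or 8 numbers")
}
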