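#' Thermodynamic context for free-energy calculations
#'
#' Binding constants expressed in uM^-1 are made dimensionless inside
#' logarithms by the 1 uM standard concentration, so numeric constants in
#' the package's units enter the free energies directly.
#'
#' @param temperature absolute temperature (K).
#' @param gas_constant gas constant (kJ mol^-1 K^-1).
#' @param standard_conc standard concentration (uM).
#' @return An object of class `thermo_context`.
#' @export
thermo_context <- function(temperature = 298.15,
                           gas_constant = 8.314e-3,
                           standard_conc = 1) {
  stopifnot(temperature > 0, gas_constant > 0, standard_conc > 0)
  structure(list(temperature = temperature, gas_constant = gas_constant,
                 standard_conc = standard_conc), class = "thermo_context")
}

#' Standard association free energy from kinetic coefficients
#'
#' `dG_assoc = -R T ln((k_on / k_off) * c_std)`, the free energy of
#' binding for the step with association coefficient `k_on` and
#' dissociation coefficient `k_off`.  With the 1 uM standard state an
#' association constant of 1 uM^-1 corresponds to 0 kJ/mol.
#'
#' @param k_on association rate coefficient (uM^-1 s^-1), > 0.
#' @param k_off dissociation rate coefficient (s^-1), > 0.
#' @param ctx a [thermo_context()].
#' @return Free energy (kJ/mol).
#' @export
#' @examples
#' assoc_free_energy(100, 1)  # -11.41 kJ/mol at 298.15 K
assoc_free_energy <- function(k_on, k_off, ctx = thermo_context()) {
  stopifnot(inherits(ctx, "thermo_context"))
  if (any(k_on <= 0) || any(k_off <= 0))
    stop("rate coefficients must be strictly positive")
  -ctx$gas_constant * ctx$temperature *
    log((k_on / k_off) * ctx$standard_conc)
}

#' Free energy of interaction between binding sites
#'
#' `dG_int = -R T ln(omega)`: zero for independent sites, negative for
#' positive cooperativity (`omega > 1`), positive for negative
#' cooperativity (`omega < 1`).  Independent of the intrinsic affinity.
#'
#' @param omega cooperativity factor, > 0.
#' @param ctx a [thermo_context()].
#' @return Free energy (kJ/mol).
#' @export
interaction_free_energy <- function(omega, ctx = thermo_context()) {
  stopifnot(inherits(ctx, "thermo_context"))
  if (any(omega <= 0)) stop("'omega' must be strictly positive")
  -ctx$gas_constant * ctx$temperature * log(omega)
}

#' Two-different-sites model equivalent to a negatively cooperative one
#'
#' At equilibrium a macromolecule with two identical sites and
#' cooperativity factor `omega <= 1` is indistinguishable from one with
#' two independent sites of intrinsic constants
#' `Ko1 = Ko (1 + sqrt(1 - omega))` and `Ko2 = Ko (1 - sqrt(1 - omega))`:
#' the two binding polynomials are identical.  For `omega > 1` the roots
#' are complex and no physically meaningful two-site-class counterpart
#' exists, which is why a positively cooperative isotherm can never be
#' mistaken for site heterogeneity.
#'
#' @param ko intrinsic association constant of the cooperative model
#'   (uM^-1).
#' @param omega cooperativity factor, `0 < omega <= 1`.
#' @return Named vector `c(ko1, ko2)` (uM^-1).
#' @seealso [equivalent_cooperative()] for the inverse mapping.
#' @export
#' @examples
#' equivalent_two_sites(0.55, 0.33058)  # close to (1, 0.1)
equivalent_two_sites <- function(ko, omega) {
  stopifnot(ko > 0)
  if (omega <= 0) stop("'omega' must be strictly positive")
  if (omega > 1)
    stop("no physical two-site-class equivalent for omega > 1: ",
         "both roots are complex")
  s <- sqrt(1 - omega)
  c(ko1 = ko * (1 + s), ko2 = ko * (1 - s))
}

#' Cooperative model equivalent to two different site classes
#'
#' Inverse of [equivalent_two_sites()]: `Ko = (Ko1 + Ko2) / 2` and
#' `omega = Ko1 Ko2 / Ko^2`.  By the arithmetic-geometric mean inequality
#' `omega <= 1` always, i.e. heterogeneous independent sites masquerade
#' as negative cooperativity, never positive.
#'
#' @param ko1,ko2 intrinsic association constants (uM^-1), > 0.
#' @return Named vector `c(ko, omega)`.
#' @export
#' @examples
#' equivalent_cooperative(1, 0.1)  # ko = 0.55, omega = 0.33058
equivalent_cooperative <- function(ko1, ko2) {
  if (ko1 <= 0 || ko2 <= 0)
    stop("association constants must be strictly positive")
  ko <- (ko1 + ko2) / 2
  c(ko = ko, omega = ko1 * ko2 / ko^2)
}
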