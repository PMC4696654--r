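# Independent oracles, written directly from the mass-action scheme and the
# binding polynomial, deliberately not sharing code with the package.

# Term-by-term right-hand sides of the five rate equations.
oracle_derivs <- function(m00, m10, m01, m11, l,
                          k1, k2, k12, k21, km1, km2, km12, km21) {
  d_m00 <- km1 * m10 + km2 * m01 - (k1 + k2) * l * m00
  d_m10 <- k1 * l * m00 + km21 * m11 - (km1 + k21 * l) * m10
  d_m01 <- k2 * l * m00 + km12 * m11 - (km2 + k12 * l) * m01
  d_m11 <- (k12 * m01 + k21 * m10) * l - (km12 + km21) * m11
  d_l <- km1 * m10 + km2 * m01 + (km21 + km12) * m11 -
    ((k1 + k2) * m00 + k21 * m10 + k12 * m01) * l
  c(d_m00, d_m10, d_m01, d_m11, d_l)
}

# Random rate set satisfying detailed balance around the cycle.
random_closed_rates <- function() {
  k <- exp(runif(7, log(0.1), log(10)))  # k1 k2 k12 km1 km2 km12 km21
  k21 <- k[7] * (k[2] * k[3] * k[4]) / (k[5] * k[6] * k[1])
  rate_constants(k1 = k[1], k2 = k[2], k1_given_2 = k[3], k2_given_1 = k21,
                 km1 = k[4], km2 = k[5], km1_given_2 = k[6], km2_given_1 = k[7])
}

# Microstate concentrations at equilibrium for given FREE ligand l, from the
# Boltzmann weights of the four states.
oracle_equilibrium_species <- function(rates, m_total, l) {
  ko1 <- rates[["k1"]] / rates[["km1"]]
  ko2 <- rates[["k2"]] / rates[["km2"]]
  w11 <- ko1 * (rates[["k2_given_1"]] / rates[["km2_given_1"]])  # both sites
  z <- 1 + ko1 * l + ko2 * l + w11 * l^2
  m_total * c(m00 = 1, m10 = ko1 * l, m01 = ko2 * l, m11 = w11 * l^2) / z
}

# Binding density of the symmetric cooperative model, straight from the
# binding polynomial Z = 1 + 2KL + wK^2L^2.
oracle_coop_n <- function(l, ko, omega) {
  (2 * ko * l + 2 * omega * ko^2 * l^2) / (1 + 2 * ko * l + omega * ko^2 * l^2)
}

# Free ligand at equilibrium for totals (l0, m0) of the cooperative model,
# by solving the conservation relation l + m0 * n(l) = l0.
oracle_coop_free_l <- function(l0, m0, ko, omega) {
  if (l0 == 0) return(0)
  uniroot(function(l) l + m0 * oracle_coop_n(l, ko, omega) - l0,
          c(0, l0), tol = 1e-13)$root
}

max_conservation_error <- function(tc) {
  s <- tc$states
  err_m <- abs(s$m00 + s$m10 + s$m01 + s$m11 - tc$m_total) / tc$m_total
  err_l <- if (tc$l_total > 0)
    abs(s$l + s$m10 + s$m01 + 2 * s$m11 - tc$l_total) / tc$l_total
  else abs(s$l + s$m10 + s$m01 + 2 * s$m11)
  max(err_m, err_l)
}
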