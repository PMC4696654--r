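#' Microscopic state of the two-site binding system
#'
#' Concentrations (uM) of the five chemical species at time `t`:
#' empty macromolecule (`m00`), ligand bound at site 1 only (`m10`), at
#' site 2 only (`m01`), both sites occupied (`m11`), and free ligand
#' (`l`).
#'
#' @param m00,m10,m01,m11,l species concentrations (uM), all >= 0.
#' @param t time (s).
#' @return An object of class `system_state` (named numeric vector).
#' @export
system_state <- function(m00, m10, m01, m11, l, t = 0) {
  s <- c(t = unname(t), m00 = unname(m00), m10 = unname(m10),
         m01 = unname(m01), m11 = unname(m11), l = unname(l))
  if (!all(is.finite(s))) stop("state components must be finite")
  if (any(s[-1] < 0)) stop("concentrations must be nonnegative")
  structure(s, class = "system_state")
}

state_species <- function(state) {
  if (inherits(state, "system_state") ||
      (is.numeric(state) && all(c("m00", "m10", "m01", "m11", "l") %in%
                                names(state))))
    return(unname(state[c("m00", "m10", "m01", "m11", "l")]))
  if (is.numeric(state) && length(state) == 5) return(unname(state))
  stop("cannot interpret 'state'")
}

#' Mass-action derivatives of the two-site scheme
#'
#' Evaluates the right-hand sides of the five coupled ordinary
#' differential equations governing the microscopic scheme.  The returned
#' rates satisfy the two linear conservation laws identically:
#' the macromolecule derivatives sum to zero, and
#' `dl + dm10 + dm01 + 2*dm11 = 0`.
#'
#' @param state a [system_state()] (or named numeric vector with elements
#'   `m00`, `m10`, `m01`, `m11`, `l`).
#' @param rates a [rate_constants()] object.
#' @return Named numeric vector of the five time derivatives (uM/s), in
#'   the order `m00`, `m10`, `m01`, `m11`, `l`.
#' @export
#' @examples
#' r <- rate_constants(1, 1, 1, 1, 1, 1, 1, 1)
#' binding_derivatives(system_state(1, 0, 0, 0, l = 1), r)
binding_derivatives <- function(state, rates) {
  y <- state_species(state)
  if (!all(is.finite(y)) || any(y < 0))
    stop("state concentrations must be finite and nonnegative")
  rates <- as_rate_constants(rates)
  setNames(.binding_derivs_cpp(y, unclass(rates)),
           c("m00", "m10", "m01", "m11", "l"))
}

#' Simulation settings for the fixed-step RK4 integrator
#'
#' @param step_size RK4 time step (s), or `"auto"` (the default):
#'   `0.01 / (max association coefficient * max(total ligand, total
#'   macromolecule) + max dissociation coefficient)`, i.e. one hundredth
#'   of the fastest process time scale.
#' @param convergence_threshold maximum relative concentration change per
#'   recorded step below which the system is considered equilibrated.
#'   The default `1e-5` is a relative change of 10^-3 percent.
#' @param max_time simulated-time cap (s), or `"auto"`
#'   (`60 / min dissociation coefficient`).
#' @param record_every output decimation: keep one state every this many
#'   RK4 steps; `"auto"` targets a recording interval of about 2 percent
#'   of the slowest dissociation time scale.
#' @param convergence_window number of consecutive recorded steps that
#'   must satisfy the convergence threshold (guards against declaring
#'   convergence on a slow transient).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(step_size = "auto", convergence_threshold = 1e-5,
                       max_time = "auto", record_every = "auto",
                       convergence_window = 10) {
  if (!identical(step_size, "auto")) {
    stopifnot(is.numeric(step_size), step_size > 0)
  }
  stopifnot(is.numeric(convergence_threshold),
            convergence_threshold > 0, convergence_threshold < 1)
  if (!identical(max_time, "auto")) stopifnot(is.numeric(max_time), max_time > 0)
  if (!identical(record_every, "auto"))
    stopifnot(is.numeric(record_every), record_every >= 1)
  structure(list(step_size = step_size,
                 convergence_threshold = convergence_threshold,
                 max_time = max_time, record_every = record_every,
                 convergence_window = as.integer(convergence_window)),
            class = "sim_config")
}

#' Integrate the binding scheme to equilibrium
#'
#' Solves the mass-action equations with a classic fixed-step 4th-order
#' Runge-Kutta scheme, starting (by default) from all macromolecule empty
#' and all ligand free, and stops once the relative concentration change
#' of every species per recorded step has stayed below the convergence
#' threshold for a trailing window of recorded steps.  A negative
#' concentration excursion beyond -1e-9 of the total concentration scale
#' triggers an automatic retry with a halved step.
#'
#' @param rates a [rate_constants()] object.
#' @param m_total total macromolecule concentration (uM).
#' @param l_total total ligand concentration (uM).
#' @param config a [sim_config()].
#' @param initial optional [system_state()] start point; must satisfy the
#'   conservation laws for `m_total` and `l_total`.  Defaults to
#'   `m00 = m_total`, `l = l_total`, other species zero.
#' @return An object of class `binding_timecourse`: a list with elements
#'   `states` (data frame `t`, `m00`, `m10`, `m01`, `m11`, `l`),
#'   `rates`, `m_total`, `l_total`, `converged`, `equilibrium_state`
#'   (a [system_state()], `NULL` if not converged) and `step_size`.
#' @export
#' @examples
#' r <- cooperative_rates(ko = 1, omega = 10)
#' tc <- integrate_binding(r, m_total = 1, l_total = 10)
#' tc$converged
#' binding_density(tc$equilibrium_state, m_total = 1)
integrate_binding <- function(rates, m_total, l_total,
                              config = sim_config(), initial = NULL) {
  rates <- as_rate_constants(rates)
  stopifnot(inherits(config, "sim_config"), m_total > 0, l_total >= 0)
  kon_max <- max(rates[1:4])
  koff_max <- max(rates[5:8])
  koff_min <- min(rates[5:8])

  if (is.null(initial)) {
    y0 <- c(m_total, 0, 0, 0, l_total)
  } else {
    y0 <- state_species(initial)
    if (abs(sum(y0[1:4]) - m_total) > 1e-9 * m_total ||
        abs(y0[5] + y0[2] + y0[3] + 2 * y0[4] - l_total) >
          1e-9 * max(l_total, m_total))
      stop("initial state does not satisfy conservation for the stated totals")
  }

  h <- if (identical(config$step_size, "auto"))
    0.01 / (kon_max * max(l_total, m_total) + koff_max) else config$step_size
  t_relax <- 1 / koff_min
  max_time <- if (identical(config$max_time, "auto")) 60 * t_relax
              else config$max_time
  stride <- if (identical(config$record_every, "auto"))
    max(1L, as.integer(round(0.02 * t_relax / h))) else
    as.integer(config$record_every)

  for (attempt in 1:8) {
    max_records <- ceiling(max_time / (stride * h)) + 1
    res <- .rk4_equilibrate_cpp(y0, unclass(rates), h, stride,
                                config$convergence_threshold,
                                config$convergence_window,
                                max_records, 1e-9)
    if (!res$negative) break
    h <- h / 2  # step too coarse: retry, preserving the recording interval
    stride <- stride * 2L
  }
  if (res$negative)
    stop("negative concentration excursion persisted after 8 step halvings; ",
         "supply a smaller 'step_size'")

  states <- data.frame(t = c(0, res$time),
                       m00 = c(y0[1], res$states[, 1]),
                       m10 = c(y0[2], res$states[, 2]),
                       m01 = c(y0[3], res$states[, 3]),
                       m11 = c(y0[4], res$states[, 4]),
                       l = c(y0[5], res$states[, 5]))
  eq <- NULL
  if (res$converged) {
    last <- states[nrow(states), ]
    eq <- system_state(max(last$m00, 0), max(last$m10, 0), max(last$m01, 0),
                       max(last$m11, 0), max(last$l, 0), t = last$t)
  }
  structure(list(rates = rates, m_total = m_total, l_total = l_total,
                 states = states, converged = res$converged,
                 equilibrium_state = eq, step_size = h,
                 config = config, n_steps = res$n_steps),
            class = "binding_timecourse")
}

#' @export
print.binding_timecourse <- function(x, ...) {
  cat("Binding time course: [M]o =", x$m_total, "uM, [L]o =", x$l_total,
      "uM\n  ", nrow(x$states), "recorded states, step", format(x$step_size),
      "s,", if (x$converged) "converged" else "NOT converged", "\n")
  if (x$converged)
    cat("  equilibrium <n> =",
        format(binding_density(x$equilibrium_state, x$m_total)),
        " free [L] =", format(x$equilibrium_state[["l"]]), "uM\n")
  invisible(x)
}

#' Locate the equilibrium state in a recorded time course
#'
#' Returns the first recorded state after which the per-step relative
#' change of every species stays below `threshold` for the remainder of
#' the trace.
#'
#' @param tc a `binding_timecourse`.
#' @param threshold strictly positive relative-change criterion; defaults
#'   to the threshold the time course was run with.
#' @return A [system_state()].
#' @export
detect_equilibrium <- function(tc, threshold = NULL) {
  stopifnot(inherits(tc, "binding_timecourse"))
  if (is.null(threshold)) threshold <- tc$config$convergence_threshold
  s <- as.matrix(tc$states[, c("m00", "m10", "m01", "m11", "l")])
  n <- nrow(s)
  if (n < 2) {
    if (n == 1 && threshold > 0)
      return(system_state(s[1, 1], s[1, 2], s[1, 3], s[1, 4], s[1, 5],
                          t = tc$states$t[1]))
    stop("time course too short to assess equilibrium")
  }
  floor_c <- 1e-12 * (tc$m_total + tc$l_total)
  rel <- abs(s[-1, , drop = FALSE] - s[-n, , drop = FALSE]) /
    pmax(abs(s[-1, , drop = FALSE]), floor_c)
  ok <- apply(rel, 1, max) < threshold   # strict: threshold 0 never attained
  # first index i such that all subsequent per-step changes are below threshold
  run <- rev(cumprod(rev(ok)))
  idx <- which(run == 1)[1]
  if (is.na(idx))
    stop("equilibrium criterion never met within the recorded time course")
  i <- idx  # state preceding the first compliant step
  system_state(s[i, 1], s[i, 2], s[i, 3], s[i, 4], s[i, 5],
               t = tc$states$t[i])
}

#' Binding density (average occupied sites per macromolecule)
#'
#' `<n> = ([L1M] + 2 [L2M]) / [M]o`, the mean number of ligand molecules
#' bound per macromolecule.  When the conservation laws hold this equals
#' `([L]o - [L]) / [M]o`.
#'
#' @param state a [system_state()], a `binding_timecourse` (vectorized
#'   over its recorded states) or a data frame of states.
#' @param m_total total macromolecule concentration (uM), > 0; taken from
#'   the time course when one is supplied.
#' @return Numeric vector of binding densities (dimensionless, in
#'   `[0, 2]`).
#' @export
binding_density <- function(state, m_total = NULL) {
  if (inherits(state, "binding_timecourse")) {
    if (is.null(m_total)) m_total <- state$m_total
    state <- state$states
  }
  if (is.data.frame(state)) {
    if (is.null(m_total) || m_total <= 0) stop("'m_total' must be positive")
    return((state$m10 + state$m01 + 2 * state$m11) / m_total)
  }
  y <- state_species(state)
  if (is.null(m_total) || m_total <= 0) stop("'m_total' must be positive")
  (y[2] + y[3] + 2 * y[4]) / m_total
}
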