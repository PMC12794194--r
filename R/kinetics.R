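## Becker-Doring / Aniansson-Wall stepwise association kinetics.
##
## Aggregates grow and shrink one monomer at a time,
##     A_1 + A_n  <->  A_{n+1}     (forward k_n^+, backward k_n^-)
## with diffusion-limited forward rates and backward rates fixed by detailed
## balance against a supplied equilibrium distribution. The resulting mass-
## action rate equations are stiff (the monomer couples to every step) and
## are integrated with an implicit solver and the analytic Jacobian.

#' Stepwise association rate constants
#'
#' Builds the forward and backward rate constants of the stepwise
#' (monomer-exchange) association model from an equilibrium size
#' distribution. Forward rates are diffusion-limited
#' (Smoluchowski encounter rate of a monomer with a sphere of radius
#' \eqn{\propto n^{1/3}}):
#' \deqn{k_n^+ = (1 + n^{1/3})(1 + n^{-1/3}) / 16,}
#' normalised so the dimer formation rate is \eqn{k_1^+ = 1/4}, which fixes
#' the unit of time. Backward rates follow from detailed balance,
#' \eqn{k_n^+ / k_n^- = c_{n+1}^{eq} / (c_n^{eq} c_1^{eq})}, so every
#' stepwise flux vanishes identically at `eq_dist`.
#'
#' @param eq_dist A strictly positive [equilibrium_distribution()] (or any
#'   `size_distribution`) over sizes `1..n_max`.
#' @return An object of class `rate_constants`: a tibble with columns `n`,
#'   `k_plus`, `k_minus` for the steps `n -> n+1` (`n = 1..n_max-1`),
#'   carrying `eq_dist` as an attribute. There is no flux beyond `n_max`
#'   (reflecting boundary).
#' @export
#' @examples
#' p <- calibrate_to_peak()
#' r <- build_rates(equilibrium_distribution(p, 0.01, 60))
#' r$k_plus[1]  # 0.25
build_rates <- function(eq_dist) {
  c_eq <- eq_dist$c
  n_max <- length(c_eq)
  if (n_max < 2) abort("need at least two sizes to build rates.")
  bad <- which(c_eq <= 0)
  if (length(bad) > 0)
    abort(sprintf("detailed balance undefined: equilibrium concentration is zero at n = %s.",
                  paste(utils::head(bad, 3), collapse = ", ")))
  n <- seq_len(n_max - 1)
  k_plus <- (1 + n^(1 / 3)) * (1 + n^(-1 / 3)) / 16
  k_minus <- k_plus * c_eq[1] * c_eq[n] / c_eq[n + 1]
  out <- tibble(n = as.integer(n), k_plus = k_plus, k_minus = k_minus)
  attr(out, "eq_dist") <- eq_dist
  attr(out, "n_max") <- n_max
  class(out) <- c("rate_constants", class(out))
  out
}

rate_nmax <- function(rates) attr(rates, "n_max")

#' Equilibrium distribution a set of rate constants was built from
#' @param rates A `rate_constants` object.
#' @return The `size_distribution` supplied to [build_rates()].
#' @export
equilibrium_of <- function(rates) attr(rates, "eq_dist")

#' Net stepwise association flux
#'
#' The net chemical flux from size `n` to `n + 1`,
#' \eqn{j_n = k_n^+ c_1 c_n - k_n^- c_{n+1}}, which vanishes for every `n`
#' at equilibrium.
#'
#' @param state Numeric vector of concentrations `c_1..c_n_max`.
#' @param rates A [build_rates()] object.
#' @param n Step index (or vector of indices) in `1..n_max-1`; `NULL`
#'   (default) returns all fluxes.
#' @return Numeric vector of fluxes.
#' @export
net_flux <- function(state, rates, n = NULL) {
  n_max <- rate_nmax(rates)
  stopifnot(length(state) == n_max)
  idx <- n %||% seq_len(n_max - 1)
  if (any(idx < 1 | idx > n_max - 1)) abort("`n` must lie in 1..n_max-1.")
  rates$k_plus[idx] * state[1] * state[idx] - rates$k_minus[idx] * state[idx + 1]
}

#' Time derivatives of the stepwise association rate equations
#'
#' Mass-action right-hand side of the kinetic system:
#' \deqn{\dot c_1 = -2 j_1 - \sum_{n \ge 2} j_n, \qquad
#'       \dot c_n = j_{n-1} - j_n \;(n \ge 2),}
#' with \eqn{j_{n_{max}} = 0} (reflecting boundary), so the total monomer
#' mass \eqn{\sum_n n c_n} is conserved identically.
#'
#' @inheritParams net_flux
#' @return Numeric vector `dc/dt` of length `n_max`.
#' @export
kinetic_rhs <- function(state, rates) {
  n_max <- rate_nmax(rates)
  stopifnot(length(state) == n_max)
  j <- rates$k_plus * state[1] * state[seq_len(n_max - 1)] -
    rates$k_minus * state[2:n_max]
  dc <- numeric(n_max)
  dc[1] <- -2 * j[1] - sum(j[-1])
  dc[2:n_max] <- j - c(j[-1], 0)
  dc
}

#' Analytic Jacobian of the kinetic right-hand side
#'
#' The instantaneous Jacobian \eqn{M_{ij} = \partial \dot c_i / \partial c_j}
#' of [kinetic_rhs()]: tridiagonal from the stepwise reactions plus a dense
#' first row and column from the monomer's participation in every step. The
#' mass-conservation law appears as the exact left null vector
#' `(1, 2, ..., n_max)`.
#'
#' @inheritParams net_flux
#' @return An `n_max` by `n_max` numeric matrix.
#' @export
kinetic_jacobian <- function(state, rates) {
  n_max <- rate_nmax(rates)
  stopifnot(length(state) == n_max)
  kp <- rates$k_plus
  km <- rates$k_minus
  ns <- seq_len(n_max - 1)
  # derivatives of j_n = kp_n c1 c_n - km_n c_{n+1}
  dj_d1 <- kp * state[ns]          # d j_n / d c_1 (n >= 2); n = 1 handled below
  dj_d1[1] <- 2 * kp[1] * state[1] # j_1 = kp_1 c_1^2 - km_1 c_2
  dj_dn <- kp * state[1]           # d j_n / d c_n (n >= 2)
  dj_dn1 <- -km                    # d j_n / d c_{n+1}
  M <- matrix(0, n_max, n_max)
  # row 1: dc1/dt = -2 j_1 - sum_{n=2}^{n_max-1} j_n
  M[1, 1] <- -2 * dj_d1[1] - sum(dj_d1[-1])
  M[1, 2] <- -2 * dj_dn1[1]
  if (n_max > 2) {
    for (m in 2:(n_max - 1)) {
      M[1, m] <- M[1, m] - dj_dn[m]
      M[1, m + 1] <- M[1, m + 1] - dj_dn1[m]
    }
  }
  # rows 2..n_max: dc_i/dt = j_{i-1} - j_i  (j_{n_max} = 0)
  for (i in 2:n_max) {
    M[i, 1] <- dj_d1[i - 1] - (if (i <= n_max - 1) dj_d1[i] else 0)
    if (i - 1 >= 2) M[i, i - 1] <- M[i, i - 1] + dj_dn[i - 1]
    M[i, i] <- M[i, i] + dj_dn1[i - 1]
    if (i <= n_max - 1) {
      M[i, i] <- M[i, i] - dj_dn[i]
      M[i, i + 1] <- M[i, i + 1] - dj_dn1[i]
    }
  }
  M
}

#' Integrate the stepwise association kinetics
#'
#' Solves the stiff rate equations with `deSolve::lsoda` using the analytic
#' Jacobian. The default initial condition is a pure monomer solution
#' carrying the same total mass as the equilibrium distribution behind
#' `rates`, which reproduces the canonical numerical experiment: micelles
#' nucleate, the free-monomer fraction decays toward its plateau, and the
#' state converges to the equilibrium distribution.
#'
#' @param rates A [build_rates()] object.
#' @param times Monotone output time grid (reduced time units).
#' @param c0 Initial concentrations (length `n_max`), or `NULL` for the
#'   pure-monomer state at total mass `C_tot`.
#' @param C_tot Total surfactant mass for the pure-monomer start; defaults
#'   to the total mass of the equilibrium distribution.
#' @param rtol,atol_factor Relative tolerance and absolute tolerance as a
#'   fraction of `C_tot` (defaults 1e-8 and 1e-12).
#' @return An object of class `kinetic_trajectory`: list with `times`,
#'   `states` (matrix, one row per time), `C_tot`, `rates` and the maximum
#'   relative mass-conservation error `mass_error`.
#' @export
#' @examples
#' p <- calibrate_to_peak()
#' r <- build_rates(equilibrium_distribution(p, 0.01, 60))
#' traj <- integrate_kinetics(r, times = seq(0, 2000, by = 20))
integrate_kinetics <- function(rates, times, c0 = NULL, C_tot = NULL,
                               rtol = 1e-8, atol_factor = 1e-12) {
  n_max <- rate_nmax(rates)
  if (is.unsorted(times, strictly = TRUE)) abort("`times` must be strictly increasing.")
  if (is.null(c0)) {
    C_tot <- C_tot %||% total_concentration(equilibrium_of(rates))
    c0 <- c(C_tot, rep(0, n_max - 1))
  } else {
    stopifnot(length(c0) == n_max)
    if (any(c0 < 0)) abort("initial concentrations must be >= 0.")
    C_tot <- sum(seq_len(n_max) * c0)
  }
  kp <- rates$k_plus
  km <- rates$k_minus
  rhs_ode <- function(t, y, parms) {
    j <- kp * y[1] * y[seq_len(n_max - 1)] - km * y[2:n_max]
    dy <- numeric(n_max)
    dy[1] <- -2 * j[1] - sum(j[-1])
    dy[2:n_max] <- j - c(j[-1], 0)
    list(dy)
  }
  jac_ode <- function(t, y, parms) kinetic_jacobian(y, rates)
  sol <- deSolve::lsoda(c0, times, rhs_ode, parms = NULL,
                        jacfunc = jac_ode, jactype = "fullusr",
                        rtol = rtol, atol = atol_factor * C_tot)
  istate <- attr(sol, "istate")[1]
  if (!is.null(istate) && istate < 0) {
    got <- nrow(sol)
    abort(sprintf("integrator failed at t = %.6g (istate = %d); last valid state attached.",
                  sol[got, 1], istate),
          class = "micellekin_integration_error",
          last_time = sol[got, 1], last_state = sol[got, -1])
  }
  states <- unname(sol[, -1, drop = FALSE])
  mass <- as.numeric(states %*% seq_len(n_max))
  structure(
    list(times = as.numeric(times), states = states, C_tot = C_tot,
         rates = rates, mass_error = max(abs(mass - C_tot)) / C_tot),
    class = "kinetic_trajectory"
  )
}

#' @export
print.kinetic_trajectory <- function(x, ...) {
  cat(sprintf("<kinetic_trajectory>  n_max = %d, %d frames over t = [%g, %g]\n",
              ncol(x$states), length(x$times), min(x$times), max(x$times)))
  cat(sprintf("  C_tot = %.6g (max relative mass error %.2e)\n", x$C_tot, x$mass_error))
  invisible(x)
}

#' @export
tidy.kinetic_trajectory <- function(x, ...) {
  n_max <- ncol(x$states)
  tibble(
    time = rep(x$times, each = n_max),
    n = rep(seq_len(n_max), times = length(x$times)),
    c = as.numeric(t(x$states))
  )
}

#' @export
glance.kinetic_trajectory <- function(x, ...) {
  eq <- equilibrium_of(x$rates)
  final <- x$states[nrow(x$states), ]
  tibble(
    n_max = ncol(x$states),
    n_frames = length(x$times),
    t_end = max(x$times),
    C_tot = x$C_tot,
    mass_error = x$mass_error,
    eq_distance = max(abs(final - eq$c)) / max(eq$c)
  )
}

#' Free fraction, micelle count and mean micelle size along a trajectory
#'
#' Per output time computes the observables used by the CMC protocol:
#' `p_free` (mass fraction of surfactant in aggregates of size
#' `<= n_star`), `n_mic_mean` (number-averaged micelle aggregation number;
#' 0 when no micelles are present) and `N_mic` (micelle number density).
#'
#' @param traj A [integrate_kinetics()] trajectory.
#' @param n_star Submicellar cutoff (default 6).
#' @return A tibble with columns `time`, `p_free`, `n_mic_mean`, `N_mic`.
#' @export
summarize_kinetics <- function(traj, n_star = 6) {
  n_max <- ncol(traj$states)
  n <- seq_len(n_max)
  free <- n <= n_star
  mass <- as.numeric(traj$states %*% n)
  free_mass <- as.numeric(traj$states[, free, drop = FALSE] %*% n[free])
  mic_mass <- mass - free_mass
  mic_num <- as.numeric(traj$states[, !free, drop = FALSE] %*% rep(1, sum(!free)))
  tibble(
    time = traj$times,
    p_free = free_mass / mass,
    n_mic_mean = ifelse(mic_num > 0, mic_mass / mic_num, 0),
    N_mic = mic_num
  )
}
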