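test_that("forward rates follow the diffusion-limited form with k1+ = 1/4", {
  r <- std_rates()
  expect_identical(r$k_plus[1], 0.25)
  expect_equal(r$k_plus[8], (1 + 2) * (1 + 0.5) / 16)  # 0.28125
})

test_that("detailed balance makes every flux vanish at equilibrium", {
  eq <- std_eq()
  r <- std_rates()
  j <- net_flux(eq$c, r)
  scale <- max(r$k_plus * eq$c[1] * eq$c[-length(eq$c)])
  expect_lt(max(abs(j)), 1e-12 * scale)
})

test_that("rates refuse a distribution with zeros, naming the offender", {
  d <- as_size_distribution(tibble::tibble(n = 1:5, c = c(1, 0.1, 0, 0.01, 0.001)))
  expect_error(build_rates(d), "n = 3")
})

test_that("fluxes match the mass-action expression state by state", {
  r <- std_rates()
  set.seed(2)
  state <- runif(60, 0, 0.02)
  j <- net_flux(state, r)
  # independent evaluation straight from the rate table
  for (n in c(1, 7, 30, 59)) {
    expect_equal(j[n], r$k_plus[n] * state[1] * state[n] - r$k_minus[n] * state[n + 1])
  }
  # pure monomer: only dimerization is live
  mono <- c(0.1, rep(0, 59))
  j0 <- net_flux(mono, r)
  expect_equal(j0[1], r$k_plus[1] * 0.1^2)
  expect_true(all(j0[-1] == 0))
})

test_that("the right-hand side conserves mass and fixes the equilibrium", {
  r <- std_rates()
  eq <- std_eq()
  n <- 1:60
  set.seed(3)
  for (i in 1:10) {
    state <- runif(60, 0, 0.02)
    expect_lt(abs(sum(n * kinetic_rhs(state, r))), 1e-16 * sum(state) * 60)
  }
  expect_lt(max(abs(kinetic_rhs(eq$c, r))), 1e-18)
  # pure monomer start: dimers grow, monomers deplete at twice the dimer flux
  mono <- c(0.1, rep(0, 59))
  dc <- kinetic_rhs(mono, r)
  j1 <- net_flux(mono, r, 1)
  expect_equal(dc[2], j1)
  expect_equal(dc[1], -2 * j1)
  expect_gt(dc[2], 0)
})

test_that("analytic Jacobian matches central finite differences", {
  r <- std_rates()
  set.seed(4)
  state <- runif(60, 1e-4, 0.02)
  M <- kinetic_jacobian(state, r)
  eps <- 1e-7
  Mnum <- matrix(0, 60, 60)
  for (j in 1:60) {
    up <- state; up[j] <- up[j] + eps
    dn <- state; dn[j] <- dn[j] - eps
    Mnum[, j] <- (kinetic_rhs(up, r) - kinetic_rhs(dn, r)) / (2 * eps)
  }
  expect_lt(max(abs(M - Mnum)) / max(abs(Mnum)), 1e-6)
})

test_that("mass conservation is the exact left null vector of the Jacobian", {
  r <- std_rates()
  set.seed(6)
  for (i in 1:5) {
    state <- runif(60, 0, 0.05)
    M <- kinetic_jacobian(state, r)
    lhs <- as.numeric((1:60) %*% M)
    expect_lt(max(abs(lhs)), 1e-13 * max(abs(M)))
  }
})

test_that("integration from equilibrium stays put", {
  r <- std_rates()
  eq <- std_eq()
  traj <- integrate_kinetics(r, times = seq(0, 5000, 500), c0 = eq$c)
  drift <- apply(traj$states, 1, function(s) max(abs(s - eq$c)))
  expect_lt(max(drift), 1e-8 * max(eq$c))
})

test_that("pure-monomer start decays monotonically to a finite plateau and reaches equilibrium", {
  traj <- std_traj()
  expect_lt(traj$mass_error, 1e-8)
  summ <- summarize_kinetics(traj)
  expect_equal(summ$p_free[1], 1)
  # monotone after the initial dimerization transient
  late <- summ$p_free[summ$time >= 200]
  expect_true(all(diff(late) <= 1e-10))
  expect_gt(dplyr::last(summ$p_free), 0.05)
  # long integration converges to the equilibrium distribution
  long <- integrate_kinetics(std_rates(), times = seq(0, 1.5e5, 3000))
  final <- long$states[nrow(long$states), ]
  expect_lt(max(abs(final - std_eq()$c)) / max(std_eq()$c), 1e-3)
})

test_that("a perturbation along one eigenmode decays as a single exponential", {
  r <- std_rates()
  eq <- std_eq()
  sp <- relaxation_spectrum(r)
  k <- sp$slow_mode_index
  v <- sp$vectors[, k]
  lam <- abs(Re(sp$values[k]))
  # keep the state positive
  eps <- 0.1 * min(eq$c / pmax(abs(v), 1e-300))
  c0 <- eq$c + eps * v
  expect_true(all(c0 > 0))
  times <- seq(0, 0.5 / lam, length.out = 40)
  traj <- integrate_kinetics(r, times = times, c0 = c0,
                             rtol = 1e-11, atol_factor = 1e-15)
  coefs <- apply(traj$states, 1, function(s) sum((s - eq$c) * v) / sum(v * v))
  fit <- lm(log(coefs) ~ times)
  expect_gt(summary(fit)$r.squared, 0.999)
  expect_equal(unname(-coef(fit)[2]), lam, tolerance = 0.01)
})

test_that("trajectory observables match hand-built distributions", {
  r <- std_rates()
  state <- rep(0, 60)
  state[1] <- 8
  state[10] <- 3
  traj <- structure(list(times = c(0, 1), states = rbind(state, state),
                         C_tot = 38, rates = r, mass_error = 0),
                    class = "kinetic_trajectory")
  summ <- summarize_kinetics(traj, n_star = 6)
  expect_equal(summ$p_free, c(8, 8) / 38)
  expect_equal(summ$n_mic_mean, c(10, 10))
  expect_equal(summ$N_mic, c(3, 3))
  # stationary values over appended equilibrium times
  eqtraj <- integrate_kinetics(r, times = c(0, 10, 20), c0 = std_eq()$c)
  s2 <- summarize_kinetics(eqtraj)
  expect_equal(diff(s2$p_free), c(0, 0), tolerance = 1e-10)
})

test_that("integration inputs are validated", {
  r <- std_rates()
  expect_error(integrate_kinetics(r, times = c(0, 10, 5)), "increasing")
  expect_error(integrate_kinetics(r, times = c(0, 10), c0 = c(-1, rep(0, 59))), ">= 0")
  expect_error(net_flux(std_eq()$c, r, n = 60), "1..n_max-1", fixed = TRUE)
})
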