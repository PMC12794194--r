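test_that("charge-phase inversion round-trips through the defining relation", {
  set.seed(11)
  for (i in 1:200) {
    beta <- runif(1)
    phi <- runif(1, 0, 0.3)
    C_tot <- 10^runif(1, -1, 2)
    C_free <- C_tot * runif(1, 0.01, 1)
    cmc <- cmc_ionic(C_free, C_tot, beta, phi)
    lhs <- log(C_free) + beta * log(beta * C_free + (1 - beta) * C_tot / (1 - phi))
    expect_equal(lhs, (1 + beta) * log(cmc), tolerance = 1e-10)
  }
})

test_that("limits of the charge-phase model are exact", {
  expect_identical(cmc_ionic(1.2, 30, beta = 0), 1.2)
  expect_equal(cmc_ionic(2.5, 40, beta = 1, phi = 0), 2.5)  # (C_free^2)^(1/2)
  # continuity at the endpoints
  expect_equal(cmc_ionic(2, 30, beta = 1e-9), cmc_ionic(2, 30, beta = 0),
               tolerance = 1e-6)
  expect_equal(cmc_ionic(2, 30, beta = 1 - 1e-9), cmc_ionic(2, 30, beta = 1),
               tolerance = 1e-6)
})

test_that("the closed form matches a bisection oracle", {
  expect_equal(cmc_ionic(2, 30, beta = 0.7, phi = 0.01),
               oracle_cmc_ionic(2, 30, 0.7, 0.01), tolerance = 1e-10)
})

test_that("more added salt depresses the apparent CMC monotonically", {
  ctots <- seq(10, 100, by = 10)
  cmcs <- cmc_ionic(2, ctots, beta = 0.6)
  expect_true(all(diff(cmcs) > 0))  # CMC estimate grows with C_tot at fixed C_free
  # equivalently: at fixed CMC, C_free falls with C_tot — invert numerically
  cfree_at <- vapply(ctots, function(ct)
    uniroot(function(cf) cmc_ionic(cf, ct, beta = 0.6) - 3, c(1e-6, 50))$root, 1)
  expect_true(all(diff(cfree_at) < 0))
})

test_that("nonionic conversion and crowding correction behave", {
  expect_identical(cmc_nonionic(1.2), 1.2)
  expect_identical(cmc_nonionic(1.2, phi = 0, crowding = TRUE), 1.2)
  expect_equal(cmc_nonionic(1.2, phi = 0.01, crowding = TRUE), 1.2 / 0.99)
  expect_error(cmc_nonionic(1.2, phi = 1), "\\[0, 1\\)")
})

test_that("plateau converts to C_free with propagated uncertainty", {
  expect_equal(pfree_to_cfree(0, 100)$C_free, 0)
  expect_equal(pfree_to_cfree(1, 100)$C_free, 100)
  out <- pfree_to_cfree(0.5, 40, sigma_A = 0.01)
  expect_equal(out$sigma_Cfree, 0.4)
  expect_warning(pfree_to_cfree(-0.1, 100), "outside")

  # worked example: hexaethylene glycol monodecyl ether at 1.5 wt percent
  # (C22H46O7, 422.6 g/mol): dimensional analysis gives C_tot, then C_free
  molar_mass <- 22 * 12.011 + 46 * 1.008 + 7 * 15.999
  ctot <- 1e4 * 1.5 * 1 / molar_mass
  got <- pfree_to_cfree(0.0482, wtpercent_to_mM(1.5, molar_mass))
  expect_equal(got$C_free, 0.0482 * ctot, tolerance = 1e-12)
  expect_equal(got$C_free, 1.71, tolerance = 0.005)
})

test_that("unit helpers agree with dimensional analysis", {
  expect_equal(wtpercent_to_mM(1, 100), 100)
  expect_equal(wtpercent_to_mM(0, 250), 0)
  # 1 wt% of a 288.4 g/mol surfactant in water:
  # 10 g / L / (288.4 g/mol) = 0.03467 mol/L = 34.67 mM
  expect_equal(wtpercent_to_mM(1, 288.4), 10 / 288.4 * 1000, tolerance = 1e-12)
  expect_equal(molar_volume(288.4), 0.2884)
  expect_equal(molar_volume(288.4) * wtpercent_to_mM(1, 288.4) / 1000,
               0.01, tolerance = 1e-12)  # 1 wt% at unit density is phi = 1%
})

test_that("homologous-series ratios extrapolate geometrically", {
  sk <- stauff_klevens(data.frame(tail_length = c(5, 6), cmc = c(1.19, 0.11)))
  expect_equal(sk$ratio, 0.11 / 1.19)
  expect_equal(predict(sk, 6), 0.11, tolerance = 1e-12)
  expect_equal(predict(sk, 8), 1.19 * (0.11 / 1.19)^3, tolerance = 1e-12)

  flat <- stauff_klevens(data.frame(tail_length = c(4, 7), cmc = c(2, 2)))
  expect_equal(flat$ratio, 1)
  expect_equal(predict(flat, 12), 2)

  # >= 3 points: geometric regression equals lm on the log scale
  d3 <- data.frame(tail_length = c(5, 6, 8), cmc = c(1.2, 0.4, 0.05))
  sk3 <- stauff_klevens(d3)
  expect_equal(log(sk3$ratio),
               coef(lm(log(cmc) ~ tail_length, d3))[["tail_length"]])
})

test_that("per-concentration CMCs combine as unweighted mean and sd", {
  out <- combine_cmc(c(1.0, 1.2, 1.4, NA))
  expect_equal(out$cmc_mean, 1.2)
  expect_equal(out$cmc_sd, sd(c(1.0, 1.2, 1.4)))
  expect_identical(out$n, 3L)
})
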