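make_exact_series <- function(m = 3, A = 0.05, B = 1, tau = 4000,
                              times = seq(0, 2e4, by = 20)) {
  truth <- A + (B - A) * exp(-times / tau)
  dplyr::bind_rows(lapply(seq_len(m), function(r)
    tibble::tibble(run = sprintf("r%d", r), time = times, p_free = truth)))
}

test_that("a noiseless exponential is recovered to high precision", {
  series <- make_exact_series()
  fit <- fit_plateau(series, window = c(0, 2e4))
  expect_true(fit$ok)
  expect_equal(fit$A, 0.05, tolerance = 1e-6)
  expect_equal(fit$B, 1, tolerance = 1e-6)
  expect_equal(fit$tau, 4000, tolerance = 1e-6)
})

test_that("tau is invariant under the window origin; B refers to the window start", {
  series <- make_exact_series()
  fit <- fit_plateau(series, window = c(4000, 16000))
  expect_equal(fit$tau, 4000, tolerance = 1e-6)
  expect_equal(fit$B, 0.05 + 0.95 * exp(-1), tolerance = 1e-6)
  expect_equal(fit$A, 0.05, tolerance = 1e-5)
})

test_that("degenerate inputs are flagged, not thrown", {
  const <- tibble::tibble(run = "r1", time = seq(0, 1000, 20), p_free = 0.3)
  fit <- fit_plateau(const, window = c(0, 1000))
  expect_true(fit$ok)
  expect_equal(fit$A, 0.3)
  expect_equal(fit$B, 0.3)
  expect_true(is.na(fit$tau))
  expect_match(fit$flag, "unidentifiable")

  tiny <- fit_plateau(make_exact_series(), window = c(0, 100))
  expect_false(tiny$ok)
  expect_match(tiny$flag, "fewer than 10 frames")
})

test_that("fits on noisy generator repeats recover the finite-box plateau", {
  fit <- jackknife_plateau(std_series(), window = c(5000, 15000))
  truth <- expected_box_pfree(std_eq(), n_molecules = 300)
  expect_true(fit$ok)
  expect_lt(abs(fit$A - truth), 3 * fit$sigma_A)
})

test_that("jackknife enumerates the right subsets and vanishes on identical repeats", {
  series <- make_exact_series(m = 10)
  fit <- jackknife_plateau(series, window = c(0, 2e4), j_ratio = 0.9)
  expect_identical(nrow(fit$subsets), 10L)
  subsets <- micellekin:::jackknife_subsets(10, 0.9)
  expect_identical(length(subsets), 10L)
  expect_true(all(vapply(subsets, length, 1L) == 9L))
  expect_equal(fit$sigma_A, 0, tolerance = 1e-10)

  # smaller j_ratio enumerates all subsets exhaustively
  subsets7 <- micellekin:::jackknife_subsets(10, 0.7)
  expect_equal(length(subsets7), choose(10, 7))

  expect_error(jackknife_plateau(series, c(0, 2e4), j_ratio = 0.85), "multiple of 1/m")
})

test_that("sigma_A matches the jackknife variance formula on outlier data", {
  times <- seq(0, 2e4, by = 40)
  truth <- 0.1 + 0.8 * exp(-times / 3000)
  series <- dplyr::bind_rows(lapply(1:10, function(r) {
    shift <- if (r == 10) 0.02 else 0  # one outlier run
    tibble::tibble(run = sprintf("r%02d", r), time = times, p_free = truth + shift)
  }))
  fit <- jackknife_plateau(series, window = c(2000, 18000), j_ratio = 0.9)
  # independent oracle: refit each leave-one-out subset with stats::nls
  A_i <- vapply(1:10, function(drop) {
    keep <- setdiff(1:10, drop)
    p <- Reduce(`+`, lapply(keep, function(r) truth + (r == 10) * 0.02)) / 9
    sel <- times >= 2000 & times <= 18000
    df <- data.frame(t = times[sel] - 2000, y = p[sel])
    # scaleOffset handles the zero-residual (noise-free) case
    coef(stats::nls(y ~ A + (B - A) * exp(-t / tau), data = df,
                    start = list(A = 0.1, B = 0.5, tau = 3000),
                    control = stats::nls.control(maxiter = 200, scaleOffset = 1)))[["A"]]
  }, 1)
  sigma_oracle <- sqrt((10 - 1) / 10 * sum((A_i - mean(A_i))^2))
  expect_equal(fit$sigma_A, sigma_oracle, tolerance = 1e-5)
})

test_that("window scans flag bad windows and early-transient bias", {
  # model-consistent data: every valid window recovers A almost exactly
  series <- make_exact_series(m = 2, A = 0.2, B = 1, tau = 2500)
  scan <- window_scan(series, starts = c(0, 2500, 5000),
                      durations = c(5000, 10000), A_ref = 0.2, j_ratio = NULL)
  expect_identical(nrow(scan), 6L)
  expect_true(all(scan$ok))
  expect_true(all(scan$sq_error < 1e-10))

  # two-time-scale decay: windows inside the fast transient overshoot the
  # plateau; late windows see the slow tail only
  times <- seq(0, 4e4, by = 40)
  p2 <- 0.1 + 0.5 * exp(-times / 400) + 0.3 * exp(-times / 6000)
  s2 <- tibble::tibble(run = "r1", time = times, p_free = p2)
  early <- fit_plateau(s2, c(0, 2000))
  late <- fit_plateau(s2, c(12000, 36000))
  expect_gt(abs(early$A - 0.1), abs(late$A - 0.1))
  expect_lt(abs(late$A - 0.1), 0.01)
})

test_that("high-sigma_A regions co-localize with high-error regions", {
  truth <- expected_box_pfree(std_eq(), n_molecules = 300)
  scan <- window_scan(std_series(),
                      starts = c(0, 500, 1000, 2000, 4000, 7000, 10000),
                      durations = c(2000, 5000, 9000, 13000),
                      A_ref = truth, j_ratio = 0.9)
  # failed ("nonsensical") cells rank as very-high in both surfaces
  sa <- scan$sigma_A
  se <- scan$sq_error
  bad <- !scan$ok | !is.finite(se) | !is.finite(sa)
  expect_gt(sum(!bad), 20)
  sa[bad] <- max(sa[!bad]) * 10
  se[bad] <- max(se[!bad]) * 10
  expect_gt(cor(sa, se, method = "spearman"), 0)
})

test_that("auto window starts near one decay time and respects the floor", {
  times <- seq(0, 4e4, by = 20)
  tau <- 5000
  series <- tibble::tibble(run = "r1", time = times,
                           p_free = 0.1 + 0.9 * exp(-times / tau))
  w <- auto_window(series, min_duration = 1e4)
  expect_lt(abs(w[1] - tau), 300)
  expect_gte(w[2] - w[1], 1e4)

  fast <- tibble::tibble(run = "r1", time = times,
                         p_free = 0.1 + 0.9 * exp(-times / 300))
  wf <- auto_window(fast, min_duration = 1e4)
  expect_gte(wf[2] - wf[1], 1e4)  # floored despite the small tau

  flat <- tibble::tibble(run = "r1", time = seq(0, 1000, 20),
                         p_free = 1 - 1e-4 * seq(0, 1000, 20) / 1000)
  expect_error(auto_window(flat), class = "micellekin_insufficient_data")
})

test_that("the auto window lands in the low-uncertainty region of the scan", {
  w <- auto_window(std_series())
  scan <- window_scan(std_series(),
                      starts = c(0, 200, w[1], 5000),
                      durations = c(w[2] - w[1]),
                      j_ratio = 0.9)
  here <- scan$sigma_A[scan$t_start == w[1]]
  expect_true(is.finite(here))
  expect_lte(here, stats::median(scan$sigma_A[scan$ok], na.rm = TRUE) * 1.5)
})
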