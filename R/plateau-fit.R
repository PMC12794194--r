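## Exponential plateau fitting of p_free(t) with jackknife uncertainty.
##
## The long-time kinetics predicts exponential decay of the free-surfactant
## fraction toward its equilibrium plateau,
##     p_free(t) = A + (B - A) exp(-t / tau),
## so the plateau A = p_free(infinity) — and with it C_free and the CMC —
## can be estimated from runs much shorter than full equilibration. Repeats
## are averaged before fitting; the jackknife over repeats provides sigma_A.

#' Validate and normalise a repeat series of p_free(t)
#'
#' A repeat series is a long-format table with one row per run per frame:
#' columns `run` (label), `time` and `p_free`. All runs must share the same
#' time grid and `p_free` must lie in `[0, 1]`.
#'
#' @param df Data frame with columns `run`, `time`, `p_free`.
#' @return A tibble sorted by run and time, classed `repeat_series`.
#' @export
as_repeat_series <- function(df) {
  df <- as_tibble(df)
  need <- c("run", "time", "p_free")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    abort(sprintf("repeat series is missing column(s): %s.", paste(miss, collapse = ", ")))
  if (any(df$p_free < -1e-12 | df$p_free > 1 + 1e-12))
    abort("`p_free` must lie in [0, 1].")
  df <- arrange(df, .data$run, .data$time)
  grids <- split(df$time, df$run)
  if (length(unique(vapply(grids, length, 1L))) != 1 ||
      !all(vapply(grids, function(g) isTRUE(all.equal(g, grids[[1]])), TRUE)))
    abort("all repeats must share the same time grid.")
  if (!inherits(df, "repeat_series")) class(df) <- c("repeat_series", class(df))
  df
}

series_matrix <- function(series) {
  series <- as_repeat_series(series)
  runs <- unique(series$run)
  times <- sort(unique(series$time))
  m <- matrix(series$p_free, nrow = length(runs), byrow = TRUE,
              dimnames = list(as.character(runs), NULL))
  list(times = times, pfree = m, runs = runs)
}

#' Repeat-mean p_free curve
#'
#' @param series A repeat series (see [as_repeat_series()]).
#' @return Tibble with columns `time`, `p_free` (mean over runs) and `m`
#'   (number of runs averaged).
#' @export
mean_series <- function(series) {
  sm <- series_matrix(series)
  tibble(time = sm$times, p_free = colMeans(sm$pfree), m = nrow(sm$pfree))
}

fit_window <- function(times, window) {
  if (length(window) != 2 || window[1] >= window[2])
    abort("`window` must be c(t_start, t_end) with t_start < t_end.")
  which(times >= window[1] & times <= window[2])
}

## core single-curve fit; returns a plateau_fit (ok = FALSE on failure
## rather than an error, so window scans can treat failures as data)
fit_plateau_curve <- function(times, p, window) {
  sel <- fit_window(times, window)
  t0 <- times[sel] - window[1]
  y <- p[sel]
  out <- list(A = NA_real_, B = NA_real_, tau = NA_real_,
              window = as.numeric(window), sigma_A = NA_real_,
              j_ratio = NA_real_, n_frames = length(sel),
              converged = FALSE, ok = FALSE, flag = NULL,
              residual_norm = NA_real_, fit = NULL)
  class(out) <- "plateau_fit"
  if (length(sel) < 10) {
    out$flag <- "window contains fewer than 10 frames"
    return(out)
  }
  rng <- diff(range(y))
  if (rng < .Machine$double.eps * 100) {
    # constant series: plateau trivially identified, tau unidentifiable
    out$A <- out$B <- mean(y)
    out$tau <- NA_real_
    out$converged <- TRUE
    out$ok <- TRUE
    out$flag <- "constant series: tau unidentifiable"
    out$residual_norm <- sqrt(sum((y - mean(y))^2))
    return(out)
  }
  # start values: decile-averaged end points (robust to frame noise), tau
  # at a third of the window
  nq <- max(2L, ceiling(length(y) / 10))
  A0 <- mean(tail(y, nq))
  B0 <- mean(head(y, nq))
  if (abs(B0 - A0) < 1e-3 * rng) B0 <- A0 + rng
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ A + (B - A) * exp(-t0 / tau),
      data = data.frame(t0 = t0, y = y),
      start = list(A = A0, B = B0, tau = diff(range(t0)) / 3),
      lower = c(-Inf, -Inf, .Machine$double.eps),
      control = minpack.lm::nls.lm.control(maxiter = 500)
    ),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    out$flag <- paste("fit failed:", conditionMessage(fit))
    return(out)
  }
  cf <- coef(fit)
  out$A <- unname(cf["A"])
  out$B <- unname(cf["B"])
  # tau was fitted with the window origin at t_start; it is invariant under
  # the shift, only B refers to t = t_start
  out$tau <- unname(cf["tau"])
  out$converged <- fit$convInfo$isConv %||% TRUE
  out$residual_norm <- sqrt(sum(resid(fit)^2))
  out$fit <- fit
  if (!is.finite(out$A) || out$A < 0) {
    out$flag <- "nonsensical plateau: A < 0"
  } else if (out$A > 1) {
    out$flag <- "plateau above 1"
  } else if (out$tau <= 0 || !is.finite(out$tau)) {
    out$flag <- "nonpositive decay time"
  } else if (out$tau > 50 * diff(as.numeric(window))) {
    out$flag <- "decay time far exceeds window: plateau unconstrained"
  } else {
    out$ok <- TRUE
  }
  out
}

#' Fit the exponential plateau model to a repeat series
#'
#' Fits \eqn{p_{free}(t) = A + (B - A)\,e^{-t/\tau}} by nonlinear least
#' squares to the repeat-averaged series restricted to `window`. Failed or
#' nonsensical fits (non-convergence, `A < 0`, `tau <= 0`) are returned as
#' flagged results with `ok = FALSE`, not as errors, so window scans can
#' map the bad-fit regions.
#'
#' @param series A repeat series (long tibble `run`, `time`, `p_free`).
#' @param window `c(t_start, t_end)` in recorded-frame time units; frames
#'   are never interpolated. Must contain at least 10 frames.
#' @return An object of class `plateau_fit` with elements `A` (plateau =
#'   `p_free(Inf)`), `B` (value at the window start), `tau` (decay time),
#'   `window`, `converged`, `ok`, `flag`, `residual_norm` and `n_frames`.
#'   Use [jackknife_plateau()] to attach `sigma_A`.
#' @seealso [auto_window()], [window_scan()], [pfree_to_cfree()]
#' @export
fit_plateau <- function(series, window) {
  sm <- series_matrix(series)
  fit <- fit_plateau_curve(sm$times, colMeans(sm$pfree), window)
  fit$m_repeats <- nrow(sm$pfree)
  fit
}

#' @export
print.plateau_fit <- function(x, ...) {
  cat("<plateau_fit>\n")
  cat(sprintf("  window   [%g, %g]  (%d frames)\n", x$window[1], x$window[2], x$n_frames))
  cat(sprintf("  A    = %.6g", x$A))
  if (!is.na(x$sigma_A)) cat(sprintf(" +/- %.3g (jackknife, j_ratio = %.2g)", x$sigma_A, x$j_ratio))
  cat("\n")
  cat(sprintf("  B    = %.6g\n  tau  = %.6g\n", x$B, x$tau))
  if (!x$ok) cat(sprintf("  ** flagged: %s\n", x$flag %||% "failed"))
  invisible(x)
}

#' @export
tidy.plateau_fit <- function(x, ...) {
  tibble(term = c("A", "B", "tau"),
         estimate = c(x$A, x$B, x$tau),
         std.error = c(x$sigma_A, NA_real_, NA_real_))
}

#' @export
glance.plateau_fit <- function(x, ...) {
  tibble(A = x$A, B = x$B, tau = x$tau, sigma_A = x$sigma_A,
         t_start = x$window[1], t_end = x$window[2],
         n_frames = x$n_frames, converged = x$converged, ok = x$ok,
         flag = x$flag %||% NA_character_)
}

jackknife_subsets <- function(m, j_ratio) {
  k <- round(j_ratio * m)
  if (k < 1 || k >= m)
    abort(sprintf("`j_ratio` = %.3g keeps %d of %d runs; need 1 <= kept < m.", j_ratio, k, m))
  if (abs(j_ratio * m - k) > 1e-8)
    abort(sprintf("`j_ratio` must be a multiple of 1/m; got %.4g with m = %d.", j_ratio, m))
  if (k == m - 1) {
    lapply(seq_len(m), function(i) setdiff(seq_len(m), i))
  } else {
    # exhaustive enumeration (computationally more demanding, as for
    # j_ratio 0.7 or 0.8)
    asplit(utils::combn(m, k), 2)
  }
}

#' Jackknife uncertainty of the fitted plateau
#'
#' Refits the plateau model on resampled subsets of the repeats and returns
#' the jackknife mean and standard deviation of `A`. With
#' `j_ratio = (m-1)/m` this is the leave-one-out jackknife (`m` subsets of
#' `m - 1` runs, each averaged before fitting) using the classic variance
#' inflation \eqn{\sigma_A^2 = \frac{m-1}{m}\sum_i (A_i - \bar A)^2}. For
#' smaller `j_ratio` all `choose(m, k)` subsets are enumerated and the
#' delete-d jackknife variance \eqn{\frac{k}{(m-k)\,N_s}\sum_s (A_s - \bar
#' A)^2} is used.
#'
#' @param series A repeat series with `m >= 2` runs.
#' @param window Fit window `c(t_start, t_end)`.
#' @param j_ratio Fraction of runs retained per subset; must be a multiple
#'   of `1/m` (default 0.9, the leave-one-out strategy for 10 repeats).
#' @return A `plateau_fit` for the full series with `sigma_A`, `j_ratio`,
#'   `A_jack` (jackknife mean) and a `subsets` tibble (`subset`, `A`, `ok`)
#'   attached. Failed subset fits are excluded from the variance and
#'   counted in `n_failed`; an error is raised only if every subset fails.
#' @export
jackknife_plateau <- function(series, window, j_ratio = 0.9) {
  sm <- series_matrix(series)
  m <- nrow(sm$pfree)
  if (m < 2) abort("jackknife needs at least 2 repeats.")
  subsets <- jackknife_subsets(m, j_ratio)
  fits <- lapply(subsets, function(keep)
    fit_plateau_curve(sm$times, colMeans(sm$pfree[keep, , drop = FALSE]), window))
  A_i <- vapply(fits, function(f) f$A, 1)
  ok_i <- vapply(fits, function(f) f$ok, TRUE)
  if (!any(ok_i)) abort("all jackknife subset fits failed.")
  A_ok <- A_i[ok_i]
  ns <- length(A_ok)
  k <- length(subsets[[1]])
  d <- m - k
  # delete-d jackknife variance; reduces to the classic (m-1)/m * sum(...)
  # leave-one-out formula when d = 1 and all subsets succeed
  sigma_A <- if (ns < 2) NA_real_ else
    sqrt(k / (d * ns) * sum((A_ok - mean(A_ok))^2))
  full <- fit_plateau_curve(sm$times, colMeans(sm$pfree), window)
  full$m_repeats <- m
  full$sigma_A <- sigma_A
  full$j_ratio <- j_ratio
  full$A_jack <- mean(A_ok)
  full$n_failed <- sum(!ok_i)
  full$subsets <- tibble(subset = seq_along(fits), A = A_i, ok = ok_i)
  full
}

#' Scan fit windows and map the error surfaces
#'
#' Repeats the plateau fit and jackknife over a grid of window start times
#' and durations, tabulating `A`, `tau`, `sigma_A` and — when a reference
#' plateau `A_ref` (e.g. from long equilibrated runs) is supplied — the
#' squared error `(A - A_ref)^2`. Failed fits are data, not errors: their
#' cells carry `ok = FALSE` and infinite `sq_error`, reproducing the
#' "nonsensical fit" regions of short-window protocols.
#'
#' @param series A repeat series.
#' @param starts Vector of window start times.
#' @param durations Vector of window durations.
#' @param A_ref Optional reference plateau for the squared-error surface.
#' @param j_ratio Jackknife ratio (default 0.9); set `NULL` to skip the
#'   jackknife (faster).
#' @return A tibble with one row per grid cell: `t_start`, `duration`,
#'   `t_end`, `A`, `tau`, `ok`, `sigma_A`, and `sq_error` when `A_ref` is
#'   given.
#' @export
window_scan <- function(series, starts, durations, A_ref = NULL, j_ratio = 0.9) {
  sm <- series_matrix(series)
  grid <- tidyr::expand_grid(t_start = starts, duration = durations)
  res <- purrr::pmap(grid, function(t_start, duration) {
    window <- c(t_start, t_start + duration)
    if (window[2] > max(sm$times) + 1e-9)
      return(tibble(A = NA_real_, tau = NA_real_, ok = FALSE, sigma_A = NA_real_))
    f <- if (is.null(j_ratio)) fit_plateau_curve(sm$times, colMeans(sm$pfree), window)
         else jackknife_plateau(series, window, j_ratio)
    tibble(A = f$A, tau = f$tau, ok = f$ok, sigma_A = f$sigma_A %||% NA_real_)
  })
  out <- dplyr::bind_cols(grid, dplyr::bind_rows(res))
  out$t_end <- out$t_start + out$duration
  if (!is.null(A_ref)) {
    out$sq_error <- ifelse(out$ok, (out$A - A_ref)^2, Inf)
  }
  out
}

#' Automatic fit-window selection
#'
#' Implements the self-consistent window heuristic: start the fit where the
#' repeat-mean curve has decayed to `1/e` of its initial deviation from a
#' running plateau estimate, and fit for `duration_factor` decay times,
#' floored at `min_duration` to prevent false convergence. The plateau
#' estimate and the fitted `tau` are iterated to self-consistency.
#'
#' The 1/e criterion is applied to the normalised deviation
#' \eqn{(p(t) - \hat A)/(p(0) - \hat A)}, which for a pure exponential
#' crosses `1/e` exactly at `t = tau`.
#'
#' @param series A repeat series.
#' @param min_duration Minimum window duration (default 1e4 time units).
#' @param duration_factor Window duration as a multiple of the fitted decay
#'   time (default 1.5).
#' @param max_iter Iteration cap (default 10).
#' @return `c(t_start, t_end)`, also carrying the final fit as attribute
#'   `"fit"`.
#' @export
auto_window <- function(series, min_duration = 1e4, duration_factor = 1.5,
                        max_iter = 10) {
  sm <- series_matrix(series)
  times <- sm$times
  p <- colMeans(sm$pfree)
  if (length(times) < 12) abort("series too short for automatic window selection.")
  # light smoothing so a single noisy frame cannot trigger the criterion
  k <- min(5L, length(p))
  ps <- as.numeric(stats::filter(p, rep(1 / k, k), sides = 2))
  ps[is.na(ps)] <- p[is.na(ps)]
  A_hat <- mean(tail(p, max(2L, length(p) %/% 10)))
  window <- NULL
  for (it in seq_len(max_iter)) {
    dev <- (ps - A_hat) / (ps[1] - A_hat)
    crossed <- which(dev <= exp(-1))
    if (length(crossed) == 0)
      abort(paste("p_free has not decayed to 1/e of its initial deviation;",
                  "run longer simulations before fitting."),
            class = "micellekin_insufficient_data")
    t_start <- times[crossed[1]]
    duration <- max(min_duration,
                    if (!is.null(window)) duration_factor * fit$tau else min_duration)
    duration <- min(duration, max(times) - t_start)
    new_window <- c(t_start, t_start + duration)
    fit <- fit_plateau_curve(times, p, new_window)
    if (!fit$ok) {
      # extend toward the full series and retry once per iteration
      new_window[2] <- max(times)
      fit <- fit_plateau_curve(times, p, new_window)
      if (!fit$ok)
        abort(paste0("series too short for a self-consistent plateau fit (",
                     fit$flag, "); run longer simulations."),
              class = "micellekin_insufficient_data")
    }
    A_hat <- fit$A
    if (!is.null(window) && isTRUE(all.equal(window, new_window, tolerance = 1e-3))) {
      window <- new_window
      break
    }
    window <- new_window
  }
  structure(window, fit = fit)
}
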