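## ggplot2 views of the main result types.

#' @export
autoplot.size_distribution <- function(object, log_scale = TRUE, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$n, y = .data$c)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "aggregate size n", y = expression(c[n]),
                  title = "Aggregate size distribution")
  if (log_scale) p <- p + ggplot2::scale_y_log10()
  p
}

#' @export
autoplot.kinetic_trajectory <- function(object, sizes = NULL, n_star = 6, ...) {
  df <- tidy(object)
  if (is.null(sizes)) {
    summ <- summarize_kinetics(object, n_star = n_star)
    return(
      ggplot2::ggplot(summ, ggplot2::aes(x = .data$time, y = .data$p_free)) +
        ggplot2::geom_line() +
        ggplot2::labs(x = "time (reduced units)", y = expression(p[free]),
                      title = "Free-surfactant fraction")
    )
  }
  df <- filter(df, .data$n %in% sizes)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$c,
                                   colour = factor(.data$n))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (reduced units)", y = expression(c[n]),
                  colour = "n", title = "Aggregate concentrations")
}

#' @export
autoplot.spectral_result <- function(object, ...) {
  df <- slow_mode_vector(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n, y = .data$v_scaled)) +
    ggplot2::geom_col(width = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = "aggregate size n",
                  y = "slow-mode component (relative)",
                  title = sprintf("Slow relaxation pathway (tau2 = %.3g)", object$tau2))
}

#' @export
autoplot.plateau_fit <- function(object, series = NULL, ...) {
  p <- ggplot2::ggplot()
  if (!is.null(series)) {
    ms <- mean_series(series)
    p <- p + ggplot2::geom_point(data = ms,
      ggplot2::aes(x = .data$time, y = .data$p_free), size = 0.5, alpha = 0.5)
  }
  if (object$ok && !is.na(object$tau)) {
    tt <- seq(object$window[1], object$window[2], length.out = 200)
    curve <- tibble(time = tt,
                    p_free = object$A + (object$B - object$A) *
                      exp(-(tt - object$window[1]) / object$tau))
    p <- p + ggplot2::geom_line(data = curve,
      ggplot2::aes(x = .data$time, y = .data$p_free), colour = "red")
  }
  p + ggplot2::geom_hline(yintercept = object$A, linetype = 2) +
    ggplot2::labs(x = "time (reduced units)", y = expression(p[free]),
                  title = sprintf("Plateau fit: A = %.4g", object$A))
}

#' Heatmaps of the window-scan error surfaces
#'
#' @param scan A [window_scan()] tibble.
#' @param what `"sigma_A"` (default) or `"sq_error"`.
#' @return A ggplot; failed-fit cells are shown in a distinct fill.
#' @export
plot_window_scan <- function(scan, what = c("sigma_A", "sq_error")) {
  what <- match.arg(what)
  if (what == "sq_error" && !"sq_error" %in% names(scan))
    abort("scan has no `sq_error` column; supply `A_ref` to window_scan().")
  scan$value <- log10(pmax(scan[[what]], 1e-300))
  scan$value[!scan$ok | !is.finite(scan$value)] <- NA
  ggplot2::ggplot(scan, ggplot2::aes(x = .data$t_start, y = .data$duration,
                                     fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(na.value = "grey20") +
    ggplot2::labs(x = "window start", y = "window duration",
                  fill = paste0("log10 ", what),
                  title = "Fit-window scan (failed fits in grey)")
}

#' Micelle size evolution heatmap
#'
#' @param records Aggregate records (`run`, `time`, `n`, `count`).
#' @param time_bins Bin edges (default 20 bins over the recorded range).
#' @return A ggplot of the log mean frequency per (time bin, size).
#' @export
plot_size_histogram <- function(records, time_bins = NULL) {
  time_bins <- time_bins %||%
    seq(min(records$time), max(records$time) + 1e-9, length.out = 21)
  h <- size_histogram(records, time_bins, log_counts = TRUE)
  ggplot2::ggplot(h, ggplot2::aes(x = .data$time_bin, y = .data$n,
                                  fill = .data$frequency)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(na.value = "white") +
    ggplot2::labs(x = "time", y = "aggregate size n",
                  fill = "log10 freq", title = "Micelle size evolution")
}
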