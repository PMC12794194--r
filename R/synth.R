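## Synthetic finite-box repeat generator.
##
## Emulates the output of replicate coarse-grained simulation runs: at each
## recorded frame time the box's aggregate composition is drawn from the
## kinetic model's evolving size distribution. Aggregates are sampled iid
## with probability c_n(t) / sum_m c_m(t), conditioned — via a renewal
## dynamic program over the remaining mass — on filling the box with
## exactly n_molecules surfactants. The conditioning makes the draw exact
## (no truncated aggregates) while preserving the iid-aggregate model.
##
## Finite boxes are genuinely biased observers: the expected sampled mass
## fraction in small aggregates differs from the macroscopic fraction by
## O(1/n_molecules) (a ratio-of-sums effect, not an artifact of the
## sampler). expected_box_pfree() computes that finite-box expectation
## exactly, so tests and protocols can compare against the generator's true
## mean rather than the macroscopic value.

## probability that iid aggregate draws from `prob` sum exactly to
## 0..n_molecules (renewal mass function)
fill_probabilities <- function(prob, n_molecules) {
  f <- numeric(n_molecules + 1)
  f[1] <- 1
  n_max <- length(prob)
  for (m in seq_len(n_molecules)) {
    k <- min(m, n_max)
    f[m + 1] <- sum(prob[1:k] * f[m:(m - k + 1)])
  }
  f
}

## one box draw; returns counts per size
sample_box_composition <- function(n_molecules, prob, fill) {
  n_max <- length(prob)
  counts <- integer(n_max)
  m <- n_molecules
  while (m > 0) {
    k <- min(m, n_max)
    w <- prob[1:k] * fill[m:(m - k + 1)]
    x <- sample.int(k, 1L, prob = w)
    counts[x] <- counts[x] + 1L
    m <- m - x
  }
  counts
}

#' Exact finite-box expectation of p_free under the sampling model
#'
#' Computes, by dynamic programming over the remaining mass, the exact
#' expectation of the free-surfactant mass fraction in a box of
#' `n_molecules` filled by iid aggregate draws from the distribution,
#' conditioned on exact fill. This is the true mean of the synthetic
#' generator at that state — it approaches the macroscopic
#' \eqn{\sum_{n \le n^*} n c_n / \sum_n n c_n} as `n_molecules` grows, with
#' a finite-box deviation of order `1/n_molecules`.
#'
#' @param dist A `size_distribution`, or a bare numeric vector of
#'   concentrations `c_1..c_n_max`.
#' @param n_molecules Box size in surfactant molecules.
#' @param n_star Submicellar cutoff (default 6).
#' @return Expected `p_free` (a single number).
#' @export
expected_box_pfree <- function(dist, n_molecules, n_star = 6) {
  conc <- if (is.data.frame(dist)) dist$c else as.numeric(dist)
  conc <- pmax(conc, 0)
  prob <- conc / sum(conc)
  fill <- fill_probabilities(prob, n_molecules)
  n_max <- length(prob)
  g <- numeric(n_molecules + 1)
  for (m in seq_len(n_molecules)) {
    k <- min(m, n_max)
    w <- prob[1:k] * fill[m:(m - k + 1)]
    w <- w / sum(w)
    x <- seq_len(k)
    g[m + 1] <- sum(w * (x * (x <= n_star) + g[m - x + 1]))
  }
  g[n_molecules + 1] / n_molecules
}

#' Generate synthetic finite-box repeat runs from a kinetic trajectory
#'
#' For each repeat and each frame time, draws the aggregate composition of
#' a box of `n_molecules` surfactants from the trajectory's size
#' distribution at that time (iid aggregate draws conditioned on exact
#' fill) and records the per-frame `p_free` together with the full
#' composition. Every sampled frame conserves molecules exactly. Output is
#' deterministic for a fixed `seed`; each repeat uses an independent
#' substream derived from it.
#'
#' @param traj A [integrate_kinetics()] trajectory.
#' @param n_molecules Surfactant molecules per box (default 300).
#' @param frame_times Frame times to sample; must be members of
#'   `traj$times` (frames are never interpolated). Default: all trajectory
#'   times.
#' @param n_repeats Number of repeat runs (default 10).
#' @param seed Master seed for reproducibility.
#' @param n_star Submicellar cutoff used for `p_free` (default 6).
#' @param keep_records Also return per-frame aggregate compositions
#'   (default TRUE; disable to save memory in large scans).
#' @return A list with `series` (long tibble `run`, `time`, `p_free`,
#'   classed `repeat_series`) and `records` (tibble `run`, `time`, `n`,
#'   `count`, or `NULL`), plus the generating `n_molecules`, `n_star` and
#'   `seed` as attributes of `series`.
#' @export
#' @examples
#' p <- calibrate_to_peak()
#' r <- build_rates(equilibrium_distribution(p, 0.01, 60))
#' traj <- integrate_kinetics(r, times = seq(0, 2000, 20))
#' synth_repeats(traj, n_repeats = 2, seed = 1)$series
synth_repeats <- function(traj, n_molecules = 300, frame_times = NULL,
                          n_repeats = 10, seed = NULL, n_star = 6,
                          keep_records = TRUE) {
  stopifnot(inherits(traj, "kinetic_trajectory"))
  if (n_molecules < 1) abort("`n_molecules` must be >= 1.")
  frame_times <- frame_times %||% traj$times
  idx <- match(frame_times, traj$times)
  if (anyNA(idx))
    abort("all `frame_times` must be recorded trajectory times (frames are not interpolated).")
  if (!is.null(seed)) set.seed(seed)
  # per-repeat substream seeds drawn once from the master stream
  rep_seeds <- sample.int(.Machine$integer.max, n_repeats)
  n_max <- ncol(traj$states)
  probs <- lapply(idx, function(i) {
    cc <- pmax(traj$states[i, ], 0)
    cc / sum(cc)
  })
  fills <- lapply(probs, fill_probabilities, n_molecules = n_molecules)
  free_sizes <- seq_len(n_max) <= n_star
  series <- vector("list", n_repeats)
  records <- if (keep_records) vector("list", n_repeats) else NULL
  for (r in seq_len(n_repeats)) {
    set.seed(rep_seeds[r])
    pf <- numeric(length(idx))
    recs <- if (keep_records) vector("list", length(idx)) else NULL
    for (i in seq_along(idx)) {
      counts <- sample_box_composition(n_molecules, probs[[i]], fills[[i]])
      pf[i] <- sum(seq_len(n_max)[free_sizes] * counts[free_sizes]) / n_molecules
      if (keep_records) {
        nz <- which(counts > 0)
        recs[[i]] <- tibble(run = sprintf("run%02d", r), time = frame_times[i],
                            n = nz, count = counts[nz])
      }
    }
    series[[r]] <- tibble(run = sprintf("run%02d", r), time = frame_times, p_free = pf)
    if (keep_records) records[[r]] <- bind_rows(recs)
  }
  out_series <- as_repeat_series(bind_rows(series))
  attr(out_series, "n_molecules") <- n_molecules
  attr(out_series, "n_star") <- n_star
  attr(out_series, "seed") <- seed
  list(series = out_series,
       records = if (keep_records) bind_rows(records) else NULL)
}

#' Time-binned micelle size histogram
#'
#' Averages per-frame aggregate counts over runs within each time bin,
#' producing the matrix behind micelle-size-evolution heatmaps. With
#' `log_counts = TRUE` the mean frequencies are log10-transformed and
#' zero-count cells are masked (`NA`).
#'
#' @param records Tibble of aggregate records (`run`, `time`, `n`,
#'   `count`).
#' @param time_bins Vector of bin edges covering the record times.
#' @param log_counts Return log10 of the mean frequency? (default FALSE)
#' @return A tibble with columns `time_bin` (bin midpoint), `n` and
#'   `frequency`.
#' @export
size_histogram <- function(records, time_bins, log_counts = FALSE) {
  if (nrow(records) == 0) abort("`records` is empty.")
  bins <- cut(records$time, breaks = time_bins, include.lowest = TRUE, right = FALSE)
  if (anyNA(bins)) abort("`time_bins` must cover all record times.")
  mids <- (head(time_bins, -1) + tail(time_bins, -1)) / 2
  # number of (run, frame) observations per bin, for frequency normalisation
  obs <- records |>
    mutate(bin = bins) |>
    group_by(.data$bin) |>
    summarise(n_obs = dplyr::n_distinct(paste(.data$run, .data$time)), .groups = "drop")
  out <- records |>
    mutate(bin = bins) |>
    group_by(.data$bin, .data$n) |>
    summarise(total = sum(.data$count), .groups = "drop") |>
    left_join(obs, by = "bin") |>
    mutate(frequency = .data$total / .data$n_obs,
           time_bin = mids[as.integer(.data$bin)]) |>
    select("time_bin", "n", "frequency")
  if (log_counts) {
    out$frequency <- ifelse(out$frequency > 0, log10(out$frequency), NA_real_)
  }
  arrange(out, .data$time_bin, .data$n)
}
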