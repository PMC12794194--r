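## End-to-end protocol: calibrate the landscape, build rates, integrate the
## kinetics, generate (or load) repeat series, select a fit window, fit the
## plateau with jackknife uncertainty, and convert to a CMC.

config_schema <- list(
  surfactant = c("name", "charged", "beta", "molar_mass", "wt_percent",
                 "ctot_mM", "solution_density"),
  thermo = c("g", "gamma", "h", "lambda3", "target_peak_n", "c1",
             "aspect_ratio"),
  kinetics = c("n_max", "t_end", "dt", "rtol", "atol_factor"),
  protocol = c("n_star", "n_repeats", "n_molecules", "j_ratio", "window",
               "auto_window", "min_duration", "seed", "crowding"),
  io = c("series_file", "output_dir")
)

default_config <- function() {
  list(
    surfactant = list(name = "toy", charged = FALSE, beta = NULL,
                      molar_mass = NULL, wt_percent = NULL, ctot_mM = NULL,
                      solution_density = 1),
    thermo = list(g = NULL, gamma = NULL, h = NULL, lambda3 = 1,
                  target_peak_n = 20, c1 = 0.01, aspect_ratio = 5),
    kinetics = list(n_max = 60, t_end = 2e4, dt = 20, rtol = 1e-8,
                    atol_factor = 1e-12),
    protocol = list(n_star = 6, n_repeats = 10, n_molecules = 300,
                    j_ratio = 0.9, window = c(5000, 15000),
                    auto_window = FALSE, min_duration = 1e4, seed = 1,
                    crowding = FALSE),
    io = list(series_file = NULL, output_dir = NULL)
  )
}

#' Read and validate a pipeline configuration
#'
#' Configurations are YAML with blocks `surfactant`, `thermo`, `kinetics`,
#' `protocol` and `io`; unknown blocks or keys are rejected. Every omitted
#' key falls back to the protocol defaults (submicellar cutoff 6, 10
#' repeats of 300 molecules, jackknife ratio 0.9, fit window from 5000 for
#' 10000 time units).
#'
#' @param path Path to a YAML file, or a named list with the same
#'   structure.
#' @return A validated config list (class `micellekin_config`).
#' @export
read_run_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  if (!is.list(cfg)) abort("config must be a YAML mapping.")
  bad_blocks <- setdiff(names(cfg), names(config_schema))
  if (length(bad_blocks) > 0)
    abort(sprintf("unknown config block(s): %s.", paste(bad_blocks, collapse = ", ")))
  for (blk in names(cfg)) {
    bad <- setdiff(names(cfg[[blk]]), config_schema[[blk]])
    if (length(bad) > 0)
      abort(sprintf("unknown key(s) in block '%s': %s.", blk, paste(bad, collapse = ", ")))
  }
  out <- default_config()
  for (blk in names(cfg)) out[[blk]] <- modifyList(out[[blk]], cfg[[blk]])
  if (isTRUE(out$surfactant$charged) && is.null(out$surfactant$beta))
    abort("ionic surfactants need an explicit `surfactant.beta` (counterion binding degree).")
  structure(out, class = "micellekin_config")
}

resolve_params <- function(cfg) {
  th <- cfg$thermo
  if (!is.null(th$g) && !is.null(th$gamma) && !is.null(th$h)) {
    nucleation_params(th$g, th$gamma, th$h, lambda3 = th$lambda3,
                      aspect_ratio = th$aspect_ratio)
  } else {
    calibrate_to_peak(target_peak_n = th$target_peak_n, c1 = th$c1,
                      aspect_ratio = th$aspect_ratio,
                      n_star = cfg$protocol$n_star, h = th$h,
                      lambda3 = th$lambda3)
  }
}

resolve_ctot_mM <- function(s) {
  if (!is.null(s$ctot_mM)) return(s$ctot_mM)
  if (!is.null(s$wt_percent) && !is.null(s$molar_mass))
    return(wtpercent_to_mM(s$wt_percent, s$molar_mass, s$solution_density %||% 1))
  NULL
}

#' Run the full short-time CMC protocol
#'
#' Chains the whole pipeline: calibrate the free-energy landscape, build
#' detailed-balance rates, integrate the kinetics from a pure-monomer
#' start, generate synthetic finite-box repeats (or load a recorded repeat
#' series), choose the fit window, fit the exponential plateau with
#' jackknife uncertainty, and convert the plateau into a CMC. The report
#' embeds the resolved configuration, seed and a config hash so every run
#' is reproducible from its own output.
#'
#' @param config A [read_run_config()] object, a path to a YAML config, or
#'   a plain list of overrides.
#' @return A list of class `micellekin_report`: `config`, `params`,
#'   `spectrum` (glance row), `fit` (the jackknifed [fit_plateau()]),
#'   `window`, `series`, `cmc` (tibble with `C_free`, `CMC` and
#'   uncertainties, when a concentration scale is configured) and
#'   `provenance`.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- if (inherits(config, "micellekin_config")) config else read_run_config(config)
  pr <- cfg$protocol
  kin <- cfg$kinetics
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
            parent = e))
  }
  params <- stage("calibrate", resolve_params(cfg))
  eq <- stage("equilibrium", equilibrium_distribution(params, cfg$thermo$c1, kin$n_max))
  rates <- stage("rates", build_rates(eq))
  spectrum <- stage("spectrum", relaxation_spectrum(rates))
  if (!is.null(cfg$io$series_file)) {
    series <- stage("load-series", read_pfree_series(cfg$io$series_file))
    traj <- NULL
  } else {
    traj <- stage("integrate", integrate_kinetics(
      rates, times = seq(0, kin$t_end, by = kin$dt),
      rtol = kin$rtol, atol_factor = kin$atol_factor))
    series <- stage("synthesize", synth_repeats(
      traj, n_molecules = pr$n_molecules, n_repeats = pr$n_repeats,
      seed = pr$seed, n_star = pr$n_star, keep_records = FALSE)$series)
  }
  window <- if (isTRUE(pr$auto_window)) {
    stage("auto-window", as.numeric(auto_window(series, min_duration = pr$min_duration)))
  } else unlist(pr$window)
  fit <- stage("fit", jackknife_plateau(series, window, j_ratio = pr$j_ratio))
  ctot_mM <- resolve_ctot_mM(cfg$surfactant)
  cmc <- NULL
  if (!is.null(ctot_mM) && fit$ok) {
    cf <- pfree_to_cfree(fit$A, ctot_mM, fit$sigma_A)
    phi <- if (!is.null(cfg$surfactant$molar_mass))
      molar_volume(cfg$surfactant$molar_mass) * ctot_mM / 1000 else 0
    est <- if (isTRUE(cfg$surfactant$charged)) {
      cmc_ionic(cf$C_free, ctot_mM, beta = cfg$surfactant$beta, phi = phi)
    } else {
      cmc_nonionic(cf$C_free, phi = phi, crowding = isTRUE(pr$crowding))
    }
    # first-order error propagation through the conversion
    dcmc <- if (cf$C_free > 0 && !is.na(cf$sigma_Cfree))
      est * abs(grad_log_cmc(cf$C_free, ctot_mM, cfg, phi)) * cf$sigma_Cfree else NA_real_
    cmc <- tibble(C_tot_mM = ctot_mM, C_free_mM = cf$C_free,
                  sigma_Cfree_mM = cf$sigma_Cfree, phi = phi,
                  CMC_mM = est, sigma_CMC_mM = dcmc)
  }
  report <- list(
    config = cfg, params = params, spectrum = glance(spectrum),
    fit = fit, window = window, series = series, cmc = cmc,
    provenance = list(seed = pr$seed,
                      package_version = as.character(utils::packageVersion("micellekin")),
                      config_hash = rlang::hash(cfg))
  )
  class(report) <- "micellekin_report"
  if (!is.null(cfg$io$output_dir)) write_report(report, cfg$io$output_dir)
  report
}

## d log(CMC) / d C_free, for error propagation
grad_log_cmc <- function(C_free, C_tot, cfg, phi) {
  if (isTRUE(cfg$surfactant$charged)) {
    beta <- cfg$surfactant$beta
    counter <- beta * C_free + (1 - beta) * C_tot / (1 - phi)
    (1 / C_free + beta^2 / counter) / (1 + beta)
  } else {
    1 / C_free
  }
}

#' @export
print.micellekin_report <- function(x, ...) {
  cat("== micellekin CMC report ==\n")
  cat(sprintf("surfactant: %s (%s)\n", x$config$surfactant$name,
              if (isTRUE(x$config$surfactant$charged)) "ionic" else "nonionic"))
  cat(sprintf("landscape:  g = %.4g, gamma = %.4g, h = %.4g\n",
              x$params$g, x$params$gamma, x$params$h))
  cat(sprintf("slow mode:  tau2 = %.4g (separation %.2fx, monomer component %.3g)\n",
              x$spectrum$tau2, x$spectrum$separation, x$spectrum$monomer_component))
  cat(sprintf("window:     [%g, %g]\n", x$window[1], x$window[2]))
  cat(sprintf("plateau:    A = %.5g +/- %.3g  (tau = %.4g)\n",
              x$fit$A, x$fit$sigma_A, x$fit$tau))
  if (!is.null(x$cmc)) {
    cat(sprintf("C_free:     %.4g +/- %.3g mM  (C_tot = %.4g mM, phi = %.3g)\n",
                x$cmc$C_free_mM, x$cmc$sigma_Cfree_mM, x$cmc$C_tot_mM, x$cmc$phi))
    cat(sprintf("CMC:        %.4g +/- %.3g mM\n", x$cmc$CMC_mM, x$cmc$sigma_CMC_mM))
  }
  cat(sprintf("provenance: seed %s, config %s\n", x$provenance$seed,
              x$provenance$config_hash))
  invisible(x)
}

report_json <- function(report) {
  jsonlite::toJSON(list(
    surfactant = report$config$surfactant,
    landscape = report$params[c("g", "gamma", "h", "lambda3")],
    spectrum = as.list(report$spectrum),
    window = report$window,
    fit = as.list(glance(report$fit)),
    cmc = if (!is.null(report$cmc)) as.list(report$cmc),
    provenance = report$provenance
  ), auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
}

write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(report_json(report), file.path(dir, "report.json"))
  con <- file(file.path(dir, "report.txt"), "w")
  sink(con); print(report); sink(); close(con)
  write_pfree_series(report$series, file.path(dir, "pfree_series.tsv"))
  invisible(dir)
}

#' Window-scan study over a configured system
#'
#' Generates (or loads) the repeat series exactly as [run_pipeline()] would
#' and maps the jackknife-uncertainty surface — and, when a reference
#' plateau is available, the squared-error surface — over a grid of fit
#' windows. The uncertainty surface is the practical guide to choosing fit
#' windows when no long-run reference exists.
#'
#' @param config As in [run_pipeline()].
#' @param starts,durations Window grids; defaults span the recorded range.
#' @param A_ref Optional reference plateau; defaults to the deterministic
#'   equilibrium free fraction of the configured model (synthetic runs
#'   only).
#' @return A list with `scan` (the [window_scan()] tibble), `window` (the
#'   auto-selected window) and `series`.
#' @export
report_scan <- function(config = list(), starts = NULL, durations = NULL,
                        A_ref = NULL) {
  cfg <- if (inherits(config, "micellekin_config")) config else read_run_config(config)
  pr <- cfg$protocol
  kin <- cfg$kinetics
  params <- resolve_params(cfg)
  eq <- equilibrium_distribution(params, cfg$thermo$c1, kin$n_max)
  rates <- build_rates(eq)
  if (!is.null(cfg$io$series_file)) {
    series <- read_pfree_series(cfg$io$series_file)
  } else {
    traj <- integrate_kinetics(rates, times = seq(0, kin$t_end, by = kin$dt),
                               rtol = kin$rtol, atol_factor = kin$atol_factor)
    series <- synth_repeats(traj, n_molecules = pr$n_molecules,
                            n_repeats = pr$n_repeats, seed = pr$seed,
                            n_star = pr$n_star, keep_records = FALSE)$series
    if (is.null(A_ref)) {
      part <- partition_free_micellar(eq, pr$n_star)
      A_ref <- part$p_free
    }
  }
  t_max <- max(series$time)
  starts <- starts %||% seq(0, t_max / 2, length.out = 6)
  durations <- durations %||% seq(t_max / 8, t_max / 2, length.out = 4)
  scan <- window_scan(series, starts, durations, A_ref = A_ref,
                      j_ratio = pr$j_ratio)
  window <- tryCatch(as.numeric(auto_window(series, min_duration = pr$min_duration)),
                     error = function(e) NULL)
  list(scan = scan, window = window, series = series)
}
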