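## CMC conversion: from the fitted plateau to a critical micelle
## concentration, for nonionic and ionic surfactants, plus the
## Stauff-Klevens homologous-series extrapolation and unit helpers.

#' Free surfactant concentration from the fitted plateau
#'
#' Since `A = p_free(Inf)` and the total surfactant content of the box is
#' known, `C_free = A * C_tot`; the plateau uncertainty propagates linearly,
#' `sigma_Cfree = sigma_A * C_tot`.
#'
#' @param A Fitted plateau (dimensionless free fraction). Values outside
#'   `[0, 1]` are flagged with a warning but still converted, for
#'   diagnostics.
#' @param C_tot Total surfactant concentration (mM).
#' @param sigma_A Optional plateau standard deviation.
#' @return A one-row tibble with `C_free` and `sigma_Cfree` (NA when
#'   `sigma_A` is missing).
#' @export
#' @examples
#' pfree_to_cfree(0.0482, C_tot = 35.5)
pfree_to_cfree <- function(A, C_tot, sigma_A = NA_real_) {
  if (!is.finite(A) || A < 0 || A > 1)
    warn(sprintf("plateau A = %.4g lies outside [0, 1]; conversion returned for diagnostics only.", A))
  tibble(C_free = A * C_tot, sigma_Cfree = sigma_A * C_tot)
}

#' CMC of a nonionic surfactant
#'
#' For nonionic (and zwitterionic) surfactants above the CMC the free
#' surfactant concentration plateaus at the CMC: `CMC = C_free`. With
#' `crowding = TRUE` the reduction of volume accessible to free surfactant
#' by the micelles themselves is compensated with the accessible-volume
#' factor `CMC = C_free / (1 - phi)`, an approximation using the surfactant
#' packing fraction `phi = V_m * C_tot`.
#'
#' @param C_free Free surfactant concentration (mM), > 0.
#' @param phi Surfactant packing fraction in `[0, 1)` (default 0).
#' @param crowding Apply the accessible-volume correction? (default FALSE)
#' @return CMC in mM (vectorised over `C_free`).
#' @export
cmc_nonionic <- function(C_free, phi = 0, crowding = FALSE) {
  if (any(C_free <= 0)) abort("`C_free` must be positive.")
  if (any(phi < 0 | phi >= 1)) abort("`phi` must lie in [0, 1).")
  if (crowding) C_free / (1 - phi) else C_free
}

#' CMC of an ionic surfactant (charge-phase model)
#'
#' Inverts the charge-phase relation between the free surfactant
#' concentration and the CMC,
#' \deqn{\log C_{free} + \beta \log\!\Big(\beta C_{free} +
#'   (1-\beta)\frac{C_{tot}}{1-\phi}\Big) = (1+\beta)\log \mathrm{CMC},}
#' in closed form:
#' \deqn{\mathrm{CMC} = \Big[C_{free}\,\big(\beta C_{free} +
#'   (1-\beta) C_{tot}/(1-\phi)\big)^{\beta}\Big]^{1/(1+\beta)}.}
#' `beta` is the degree of counterion binding to micelles; adding surfactant
#' above the CMC adds counterions, depressing `C_free` (a common-ion
#' effect), which this inversion compensates. At `beta = 0` the relation
#' reduces to the nonionic `CMC = C_free`. Natural logarithms are used
#' throughout; any consistent base cancels.
#'
#' @param C_free Free surfactant concentration (mM), > 0.
#' @param C_tot Total surfactant concentration (mM), > 0.
#' @param beta Counterion binding degree in `[0, 1]`. No default: the value
#'   is surfactant-specific and must be chosen explicitly.
#' @param phi Surfactant packing fraction in `[0, 1)` (default 0).
#' @return CMC in mM (vectorised).
#' @export
#' @examples
#' cmc_ionic(C_free = 2, C_tot = 30, beta = 0.7, phi = 0.01)
#' cmc_ionic(C_free = 2, C_tot = 30, beta = 0)  # = C_free
cmc_ionic <- function(C_free, C_tot, beta, phi = 0) {
  if (missing(beta)) abort("`beta` (counterion binding degree) must be given explicitly.")
  if (any(beta < 0 | beta > 1)) abort("`beta` must lie in [0, 1].")
  if (any(C_free <= 0) || any(C_tot <= 0)) abort("`C_free` and `C_tot` must be positive.")
  if (any(phi < 0 | phi >= 1)) abort("`phi` must lie in [0, 1).")
  if (all(beta == 0)) return(C_free)  # exact reduction to the nonionic case
  counter <- beta * C_free + (1 - beta) * C_tot / (1 - phi)
  if (any(counter <= 0)) abort("non-positive counterion term inside the logarithm.")
  exp((log(C_free) + beta * log(counter)) / (1 + beta))
}

#' Stauff-Klevens homologous-series extrapolation
#'
#' The CMC of a homologous surfactant series decreases by an approximately
#' constant factor per added tail unit (carbon or coarse-grained bead):
#' `log CMC` is linear in the tail length. `stauff_klevens()` fits that
#' geometric law — exactly, when only two chain lengths are given — and
#' returns the per-unit ratio together with an extrapolator, so CMCs of
#' longer-tailed members that are inaccessible to direct simulation can be
#' predicted from shorter ones.
#'
#' @param data Data frame with columns `tail_length` (number of tail units;
#'   at least two distinct values) and `cmc` (mM, positive).
#' @return An object of class `stauff_klevens` with elements `ratio` (CMC
#'   factor per added tail unit), `intercept`, `fit` (the underlying `lm` on
#'   the log scale, `NULL` for the two-point case) and `data`.
#' @export
#' @examples
#' sk <- stauff_klevens(data.frame(tail_length = c(5, 6), cmc = c(1.19, 0.11)))
#' sk$ratio                # ~ 0.092 per bead
#' predict(sk, tail_length = 8)  # three beads past C10: ~ 9e-4 mM
stauff_klevens <- function(data) {
  if (!all(c("tail_length", "cmc") %in% names(data)))
    abort("`data` needs columns `tail_length` and `cmc`.")
  data <- as_tibble(data)
  if (nrow(data) < 2 || length(unique(data$tail_length)) < 2)
    abort("need CMCs at >= 2 distinct tail lengths.")
  if (any(data$cmc <= 0)) abort("CMCs must be positive.")
  if (nrow(data) == 2) {
    d <- diff(data$tail_length)
    ratio <- (data$cmc[2] / data$cmc[1])^(1 / d)
    slope <- log(ratio)
    intercept <- log(data$cmc[1]) - slope * data$tail_length[1]
    fit <- NULL
  } else {
    fit <- lm(log(cmc) ~ tail_length, data = data)
    slope <- coef(fit)[["tail_length"]]
    intercept <- coef(fit)[["(Intercept)"]]
    ratio <- exp(slope)
  }
  structure(list(ratio = ratio, intercept = intercept, fit = fit, data = data),
            class = "stauff_klevens")
}

#' @export
print.stauff_klevens <- function(x, ...) {
  cat("<stauff_klevens>\n")
  cat(sprintf("  CMC ratio per added tail unit: %.4g\n", x$ratio))
  cat(sprintf("  fitted on %d chain lengths (%s)\n", nrow(x$data),
              paste(x$data$tail_length, collapse = ", ")))
  invisible(x)
}

#' @export
predict.stauff_klevens <- function(object, tail_length, ...) {
  exp(object$intercept + log(object$ratio) * tail_length)
}

#' @export
tidy.stauff_klevens <- function(x, ...) {
  tibble(term = c("ratio_per_unit", "log_intercept"),
         estimate = c(x$ratio, x$intercept))
}

#' Concentration and molar-volume unit helpers
#'
#' `wtpercent_to_mM()` converts a weight-percent concentration to mM:
#' `mM = 1e4 * wt_percent * solution_density / molar_mass` (density in
#' g/cm^3, molar mass in g/mol). `molar_volume()` gives the surfactant
#' molar volume in L/mol under the unit-density assumption,
#' `V_m = molar_mass / 1000`; `V_m * C_tot` (with `C_tot` in mol/L) is the
#' surfactant packing fraction `phi`.
#'
#' @param wt_percent Concentration in percent by weight (>= 0).
#' @param molar_mass Molar mass in g/mol (> 0).
#' @param solution_density Solution density in g/cm^3 (default 1).
#' @return Concentration in mM, or molar volume in L/mol.
#' @export
#' @examples
#' wtpercent_to_mM(1, molar_mass = 100)    # 100 mM
#' molar_volume(288.4)                     # SDS: 0.2884 L/mol
wtpercent_to_mM <- function(wt_percent, molar_mass, solution_density = 1) {
  if (any(wt_percent < 0)) abort("`wt_percent` must be >= 0.")
  if (any(molar_mass <= 0) || any(solution_density <= 0))
    abort("`molar_mass` and `solution_density` must be positive.")
  1e4 * wt_percent * solution_density / molar_mass
}

#' @rdname wtpercent_to_mM
#' @export
molar_volume <- function(molar_mass) {
  if (any(molar_mass <= 0)) abort("`molar_mass` must be positive.")
  molar_mass / 1000
}

#' Combine per-concentration CMC estimates
#'
#' The multi-concentration protocol estimates a CMC at each sampled total
#' concentration and reports the unweighted mean with its standard
#' deviation.
#'
#' @param cmc Vector of per-concentration CMC estimates (mM).
#' @return One-row tibble with `cmc_mean`, `cmc_sd` and `n`.
#' @export
combine_cmc <- function(cmc) {
  cmc <- cmc[is.finite(cmc)]
  tibble(cmc_mean = mean(cmc),
         cmc_sd = if (length(cmc) > 1) sd(cmc) else NA_real_,
         n = length(cmc))
}
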