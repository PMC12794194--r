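## Relaxation-spectrum analysis of the kinetic Jacobian.
##
## Linearizing the rate equations about a state c gives dc/dt = M (c - c*)
## with M the instantaneous Jacobian; its right eigenvalues are the decay
## constants of the relaxation pathways. Mass conservation contributes one
## exact zero eigenvalue (left null vector 1, 2, ..., n_max), excluded when
## reading off time scales. At equilibrium the smallest nonzero decay
## constant is the slow micelle-redistribution pathway, conventionally tau2.

#' Relaxation spectrum of the stepwise association kinetics
#'
#' Computes eigenvalues and right eigenvectors of the kinetic Jacobian at a
#' given state (default: the equilibrium distribution behind `rates`).
#' Eigenvalues are sorted by magnitude of their real part; the conservation
#' (zero) mode is identified by threshold and excluded from time scales; the
#' slow mode is the smallest remaining decay constant, with
#' `tau2 = 1/|Re(lambda_slow)|`.
#'
#' Right eigenvectors are stored raw and rescaled per unit reference
#' concentration (`scaled_vectors`, component-wise `v_n / c_n`). The raw
#' components are dominated by the monomer scale (monomers are orders of
#' magnitude more concentrated than any single micelle size); the relative
#' components expose the structure of the slow pathway: near-zero monomer
#' change, negative below the micellar mode and positive above it (micelle
#' growth at quasi-conserved micelle number). The sign convention makes the
#' monomer component of each eigenvector non-negative (falling back to the
#' largest-magnitude component when the monomer entry is zero).
#'
#' @param rates A [build_rates()] object.
#' @param state State about which to linearize; defaults to the equilibrium
#'   distribution behind `rates`.
#' @param zero_tol Relative threshold below which an eigenvalue counts as
#'   the conservation mode (default 1e-9 of the spectral radius).
#' @return An object of class `spectral_result` with elements `values`
#'   (complex eigenvalues, sorted by `|Re|`), `vectors`, `scaled_vectors`,
#'   `zero_mode_index`, `slow_mode_index`, `tau2`, `state` and `n_max`.
#'   Complex-pair edge cases are reported via a warning; real parts are used
#'   for time scales.
#' @export
#' @examples
#' p <- calibrate_to_peak()
#' r <- build_rates(equilibrium_distribution(p, 0.01, 60))
#' sp <- relaxation_spectrum(r)
#' sp$tau2
relaxation_spectrum <- function(rates, state = NULL, zero_tol = 1e-9) {
  n_max <- rate_nmax(rates)
  eq <- equilibrium_of(rates)
  state <- state %||% eq$c
  stopifnot(length(state) == n_max)
  M <- kinetic_jacobian(state, rates)
  eg <- eigen(M)
  ord <- order(abs(Re(eg$values)))
  values <- eg$values[ord]
  vectors <- eg$vectors[, ord, drop = FALSE]
  if (is.complex(values) && any(abs(Im(values)) > 1e-8 * max(abs(values))))
    warn("complex eigenvalue pairs present; real parts are used for time scales.")
  scale_max <- max(abs(Re(values)))
  is_zero <- abs(Re(values)) < zero_tol * scale_max
  zero_idx <- which(is_zero)
  if (length(zero_idx) > 1)
    warn(sprintf("%d eigenvalues fall below the zero-mode threshold.", length(zero_idx)))
  nonzero <- which(!is_zero)
  slow_idx <- if (length(nonzero) > 0) nonzero[1] else NA_integer_
  # sign convention: monomer component non-negative
  vecs <- Re(vectors)
  for (k in seq_len(ncol(vecs))) {
    s <- sign(vecs[1, k])
    if (s == 0) s <- sign(vecs[which.max(abs(vecs[, k])), k])
    if (s < 0) vecs[, k] <- -vecs[, k]
  }
  ref <- eq$c
  scaled <- vecs / ref
  scaled <- sweep(scaled, 2, apply(abs(scaled), 2, max), "/")
  structure(
    list(values = values, vectors = vecs, scaled_vectors = scaled,
         zero_mode_index = if (length(zero_idx) > 0) zero_idx[1] else NA_integer_,
         slow_mode_index = slow_idx,
         tau2 = if (is.na(slow_idx)) NA_real_ else 1 / abs(Re(values[slow_idx])),
         state = state, n_max = n_max),
    class = "spectral_result"
  )
}

#' @export
print.spectral_result <- function(x, ...) {
  cat(sprintf("<spectral_result>  %d modes\n", length(x$values)))
  cat(sprintf("  zero mode: #%d (|lambda| = %.3e)\n",
              x$zero_mode_index, abs(Re(x$values[x$zero_mode_index]))))
  if (!is.na(x$slow_mode_index)) {
    lam <- abs(Re(x$values[x$slow_mode_index]))
    nxt <- abs(Re(x$values[x$slow_mode_index + 1]))
    cat(sprintf("  slow mode: #%d, lambda = %.4e, tau2 = %.4g (next mode %.2fx faster)\n",
                x$slow_mode_index, -lam, x$tau2, nxt / lam))
  }
  invisible(x)
}

#' @export
tidy.spectral_result <- function(x, ...) {
  tibble(
    mode = seq_along(x$values),
    lambda_re = Re(x$values),
    lambda_im = Im(x$values),
    tau = ifelse(abs(Re(x$values)) > 0, 1 / abs(Re(x$values)), Inf),
    zero_mode = seq_along(x$values) == x$zero_mode_index,
    slow_mode = seq_along(x$values) == x$slow_mode_index
  )
}

#' @export
glance.spectral_result <- function(x, ...) {
  lam <- abs(Re(x$values))
  slow <- x$slow_mode_index
  tibble(
    n_max = x$n_max,
    lambda_zero = lam[x$zero_mode_index],
    lambda_slow = lam[slow],
    tau2 = x$tau2,
    separation = if (!is.na(slow) && slow < length(lam)) lam[slow + 1] / lam[slow] else NA_real_,
    monomer_component = abs(x$scaled_vectors[1, slow])
  )
}

#' Slow-mode eigenvector as a tibble
#'
#' @param spectrum A [relaxation_spectrum()] result.
#' @return Tibble with columns `n`, `v` (raw component) and `v_scaled`
#'   (relative to the reference equilibrium concentration, max-normalised).
#' @export
slow_mode_vector <- function(spectrum) {
  k <- spectrum$slow_mode_index
  if (is.na(k)) abort("no slow mode identified.")
  tibble(n = seq_len(spectrum$n_max),
         v = spectrum$vectors[, k],
         v_scaled = spectrum$scaled_vectors[, k])
}
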