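## Shared fixtures, computed lazily and cached for the whole test session.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, fn) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, fn(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

## the reference calibrated system: micellar mode at 20, saddle at 6,
## c1 = 0.01, truncation 60
std_params <- function() fixture("params", function() calibrate_to_peak())

std_eq <- function() fixture("eq", function() {
  equilibrium_distribution(std_params(), c1 = 0.01, n_max = 60)
})

std_rates <- function() fixture("rates", function() build_rates(std_eq()))

std_traj <- function() fixture("traj", function() {
  integrate_kinetics(std_rates(), times = seq(0, 2e4, by = 20))
})

std_series <- function() fixture("series", function() {
  synth_repeats(std_traj(), n_molecules = 300, n_repeats = 10,
                seed = 101, keep_records = FALSE)$series
})

## exponential repeat series with iid Gaussian noise, for fit/jackknife tests
noisy_exp_series <- function(m = 10, A = 0.05, B = 1, tau = 4000,
                             times = seq(0, 2e4, by = 20), sd = 0.01,
                             seed = 1) {
  set.seed(seed)
  truth <- A + (B - A) * exp(-times / tau)
  dplyr::bind_rows(lapply(seq_len(m), function(r) {
    tibble::tibble(run = sprintf("r%02d", r), time = times,
                   p_free = pmin(1, pmax(0, truth + rnorm(length(times), sd = sd))))
  }))
}

## independent brute-force single-linkage oracle: all molecule pairs, all
## 27 periodic images enumerated explicitly, components by BFS
oracle_cluster_sizes <- function(frame, cutoff) {
  pos <- frame$positions
  mol <- frame$molecule
  L <- frame$box_length
  n_mol <- max(mol)
  shifts <- as.matrix(expand.grid(c(-L, 0, L), c(-L, 0, L), c(-L, 0, L)))
  adj <- matrix(FALSE, n_mol, n_mol)
  nb <- nrow(pos)
  for (i in seq_len(nb - 1)) {
    for (j in (i + 1):nb) {
      if (mol[i] == mol[j]) next
      d2 <- min(vapply(seq_len(nrow(shifts)), function(s) {
        v <- pos[i, ] - (pos[j, ] + shifts[s, ])
        sum(v * v)
      }, 1))
      if (d2 <= cutoff^2) adj[mol[i], mol[j]] <- adj[mol[j], mol[i]] <- TRUE
    }
  }
  seen <- rep(FALSE, n_mol)
  sizes <- integer(0)
  for (s in seq_len(n_mol)) {
    if (seen[s]) next
    queue <- s
    seen[s] <- TRUE
    comp <- 0L
    while (length(queue) > 0) {
      v <- queue[1]
      queue <- queue[-1]
      comp <- comp + 1L
      nbrs <- which(adj[v, ] & !seen)
      seen[nbrs] <- TRUE
      queue <- c(queue, nbrs)
    }
    sizes <- c(sizes, comp)
  }
  sort(sizes, decreasing = TRUE)
}

## random periodic fixture: n_mol molecules of 1..3 beads, some beads
## placed near other molecules so nontrivial clusters form
random_frame <- function(n_mol, seed, box = 8) {
  set.seed(seed)
  pos <- NULL
  mol <- integer(0)
  centers <- matrix(runif(n_mol * 3, 0, box), ncol = 3)
  # drop some molecules near earlier ones to force contacts
  near <- runif(n_mol) < 0.4
  for (i in which(near & seq_len(n_mol) > 1)) {
    j <- sample.int(i - 1, 1)
    centers[i, ] <- (centers[j, ] + rnorm(3, sd = 0.6)) %% box
  }
  for (i in seq_len(n_mol)) {
    nb <- sample(1:3, 1)
    beads <- centers[rep(i, nb), , drop = FALSE] +
      matrix(rnorm(3 * nb, sd = 0.3), ncol = 3)
    pos <- rbind(pos, beads)
    mol <- c(mol, rep(i, nb))
  }
  md_frame(pos, mol, box_length = box)
}

## place aggregates of given sizes in a box, well separated, beads chained
## 0.5 apart, so clustering must recover exactly those sizes
frame_from_sizes <- function(sizes, box = 40, cutoff = 1.0) {
  k <- length(sizes)
  grid_n <- ceiling(k^(1 / 3))
  spacing <- box / grid_n
  stopifnot(spacing > 2 * cutoff + max(sizes) * 0.25)
  pos <- NULL
  mol <- integer(0)
  mol_id <- 0L
  for (a in seq_len(k)) {
    cx <- ((a - 1) %% grid_n + 0.5) * spacing
    cy <- (((a - 1) %/% grid_n) %% grid_n + 0.5) * spacing
    cz <- ((a - 1) %/% grid_n^2 + 0.5) * spacing
    for (m in seq_len(sizes[a])) {
      mol_id <- mol_id + 1L
      # one bead per molecule, chained 0.25 apart inside the aggregate
      pos <- rbind(pos, c(cx + (m - 1) * 0.25, cy, cz))
      mol <- c(mol, mol_id)
    }
  }
  md_frame(pos, mol, box_length = box)
}

## bisection oracle for the ionic charge-phase relation (log form)
oracle_cmc_ionic <- function(C_free, C_tot, beta, phi) {
  lhs <- log(C_free) + beta * log(beta * C_free + (1 - beta) * C_tot / (1 - phi))
  uniroot(function(lcmc) (1 + beta) * lcmc - lhs,
          lower = log(C_free) - 50, upper = log(C_free) + 50,
          tol = 1e-14)$root |> exp()
}
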