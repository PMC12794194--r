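## Clustering of coordinate frames into aggregates.
##
## Two surfactant molecules belong to the same aggregate when any bead of
## one lies within a cutoff of any bead of the other under the minimum-image
## convention in a periodic cubic box (molecule-level single linkage through
## bead contacts). A cell list keeps the cost near-linear in bead count.

#' Construct a coordinate frame
#'
#' @param positions Numeric matrix with 3 columns (x, y, z bead
#'   coordinates); wrapped into `[0, box_length)` on construction.
#' @param molecule Integer or character vector of molecule labels, one per
#'   bead.
#' @param box_length Cubic box edge (reduced length units, > 0).
#' @param time Optional frame time.
#' @return An object of class `md_frame`.
#' @export
md_frame <- function(positions, molecule, box_length, time = NA_real_) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3) abort("`positions` must have three columns (x, y, z).")
  if (length(molecule) != nrow(positions))
    abort("every bead needs a molecule label.")
  if (!is.numeric(box_length) || length(box_length) != 1 || box_length <= 0)
    abort("`box_length` must be a single positive number.")
  structure(
    list(positions = positions %% box_length,
         molecule = as.integer(factor(molecule, levels = unique(molecule))),
         molecule_labels = unique(molecule),
         box_length = box_length, time = time),
    class = "md_frame"
  )
}

#' @export
print.md_frame <- function(x, ...) {
  cat(sprintf("<md_frame>  %d beads, %d molecules, box %.4g%s\n",
              nrow(x$positions), length(x$molecule_labels), x$box_length,
              if (is.na(x$time)) "" else sprintf(", t = %g", x$time)))
  invisible(x)
}

#' Cluster a frame into aggregates
#'
#' Single-linkage clustering of molecules: two molecules are linked when any
#' bead pair (one bead from each) lies within `cutoff` under the
#' minimum-image convention. Neighbour search uses a cell list with cells at
#' least `cutoff` wide, so each bead is compared only against beads in its
#' 27 neighbouring cells.
#'
#' @param frame An [md_frame()].
#' @param cutoff Contact distance in reduced length units (default 1, the
#'   solvent-bead interaction range); must be below half the box edge for
#'   the minimum image to be unambiguous.
#' @return Integer vector of aggregate sizes (in molecules), sorted
#'   decreasingly.
#' @export
cluster_frame <- function(frame, cutoff = 1.0) {
  stopifnot(inherits(frame, "md_frame"))
  L <- frame$box_length
  if (cutoff >= L / 2)
    abort(sprintf("`cutoff` (%.3g) must be < box_length/2 (%.3g) for the minimum-image convention.",
                  cutoff, L / 2))
  pos <- frame$positions
  mol <- frame$molecule
  n_mol <- max(mol)
  n_bead <- nrow(pos)
  if (n_bead == 0) return(integer(0))
  # cell list: grid of cells >= cutoff wide
  n_cell <- max(1L, floor(L / cutoff))
  if (n_cell < 3) {
    pairs <- bead_pairs_brute(pos, L, cutoff)
  } else {
    pairs <- bead_pairs_cells(pos, L, cutoff, n_cell)
  }
  # union-find over molecules (path halving)
  parent <- seq_len(n_mol)
  uf_find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (length(pairs) > 0) {
    mi <- mol[pairs[, 1]]
    mj <- mol[pairs[, 2]]
    keep <- mi != mj
    for (k in which(keep)) {
      ri <- uf_find(mi[k])
      rj <- uf_find(mj[k])
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n_mol), uf_find, 1L)
  sort(as.integer(table(roots)), decreasing = TRUE)
}

## all candidate bead pairs within cutoff, brute force (small systems and
## oracle for the cell list)
bead_pairs_brute <- function(pos, L, cutoff) {
  n <- nrow(pos)
  if (n < 2) return(matrix(integer(0), ncol = 2))
  idx <- utils::combn(n, 2)
  d <- pos[idx[1, ], , drop = FALSE] - pos[idx[2, ], , drop = FALSE]
  d <- d - L * round(d / L)
  hit <- rowSums(d * d) <= cutoff^2
  cbind(idx[1, hit], idx[2, hit])
}

bead_pairs_cells <- function(pos, L, cutoff, n_cell) {
  cell_sz <- L / n_cell
  cxyz <- pmin(floor(pos / cell_sz), n_cell - 1)  # guard beads at L - eps
  cid <- 1 + cxyz[, 1] + n_cell * (cxyz[, 2] + n_cell * cxyz[, 3])
  by_cell <- split(seq_len(nrow(pos)), cid)
  offsets <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  out <- vector("list", length(by_cell) * 14)
  oi <- 0L
  cut2 <- cutoff^2
  for (cname in names(by_cell)) {
    c0 <- as.integer(cname) - 1L
    x0 <- c0 %% n_cell
    y0 <- (c0 %/% n_cell) %% n_cell
    z0 <- c0 %/% (n_cell * n_cell)
    beads0 <- by_cell[[cname]]
    for (r in seq_len(nrow(offsets))) {
      x1 <- (x0 + offsets[r, 1]) %% n_cell
      y1 <- (y0 + offsets[r, 2]) %% n_cell
      z1 <- (z0 + offsets[r, 3]) %% n_cell
      c1 <- 1 + x1 + n_cell * (y1 + n_cell * z1)
      if (c1 < as.integer(cname)) next   # each unordered cell pair once
      beads1 <- by_cell[[as.character(c1)]]
      if (is.null(beads1)) next
      if (c1 == as.integer(cname)) {
        if (length(beads0) < 2) next
        idx <- utils::combn(length(beads0), 2)
        ii <- beads0[idx[1, ]]
        jj <- beads0[idx[2, ]]
      } else {
        g <- expand.grid(i = beads0, j = beads1)
        ii <- g$i
        jj <- g$j
      }
      d <- pos[ii, , drop = FALSE] - pos[jj, , drop = FALSE]
      d <- d - L * round(d / L)
      hit <- rowSums(d * d) <= cut2
      if (any(hit)) {
        oi <- oi + 1L
        out[[oi]] <- cbind(ii[hit], jj[hit])
      }
    }
  }
  if (oi == 0L) matrix(integer(0), ncol = 2) else do.call(rbind, out[seq_len(oi)])
}

#' Aggregate observables from a sequence of coordinate frames
#'
#' Clusters each frame and records, per frame, the free-surfactant mass
#' fraction `p_free` (aggregates of size `<= n_star`), the micelle count
#' and the mean micelle size, along with the per-size aggregate counts.
#'
#' @param frames List of [md_frame()] objects sharing the same molecule
#'   count.
#' @param n_star Submicellar cutoff (default 6).
#' @param cutoff Clustering contact distance (default 1).
#' @param run_id Run label attached to the output (default "run1").
#' @return A list with `series` (tibble `run`, `time`, `p_free`) and
#'   `records` (tibble `run`, `time`, `n`, `count`).
#' @export
series_from_frames <- function(frames, n_star = 6, cutoff = 1.0, run_id = "run1") {
  if (length(frames) == 0) abort("`frames` is empty.")
  n_mols <- vapply(frames, function(f) length(f$molecule_labels), 1L)
  if (length(unique(n_mols)) != 1)
    abort("all frames must contain the same number of molecules.")
  times <- vapply(seq_along(frames), function(i) {
    ti <- frames[[i]]$time
    if (is.na(ti)) as.numeric(i - 1) else ti
  }, 1)
  rows <- purrr::map2(frames, times, function(f, ti) {
    sizes <- cluster_frame(f, cutoff)
    part <- partition_free_micellar(sizes, n_star)
    counts <- table(sizes)
    list(
      series = tibble(run = run_id, time = ti, p_free = part$p_free),
      records = tibble(run = run_id, time = ti,
                       n = as.integer(names(counts)),
                       count = as.integer(counts))
    )
  })
  list(series = bind_rows(purrr::map(rows, "series")),
       records = bind_rows(purrr::map(rows, "records")))
}
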