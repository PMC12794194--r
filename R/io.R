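## Plain-text interchange formats: size distributions, aggregate-series
## tables, p_free repeat tables and extended-XYZ-like coordinate frames.
## All tables are delimited text with a header line; round-trips are
## lossless at double precision.

#' Read and write size distributions
#'
#' Two-column tab-separated text `(n, c)`; header comment lines (prefixed
#' `#`) record the generating parameters `(g, gamma, h, c1, lambda3)` when
#' available and are restored on read.
#'
#' @param dist A `size_distribution`.
#' @param path File path.
#' @return `read_size_distribution()` returns a `size_distribution`;
#'   `write_size_distribution()` returns `path` invisibly.
#' @export
write_size_distribution <- function(dist, path) {
  params <- attr(dist, "params")
  hdr <- c("# size distribution: aggregate number densities c_n vs size n")
  if (!is.null(params)) {
    hdr <- c(hdr, sprintf("# g=%.17g gamma=%.17g h=%.17g c1=%.17g lambda3=%.17g",
                          params$g, params$gamma, params$h,
                          attr(dist, "c1"), params$lambda3))
  }
  writeLines(c(hdr, "n\tc",
               sprintf("%d\t%.17g", dist$n, dist$c)), path)
  invisible(path)
}

#' @rdname write_size_distribution
#' @export
read_size_distribution <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  df <- readr::read_tsv(I(grep("^#", lines, invert = TRUE, value = TRUE)),
                        col_types = "id", progress = FALSE)
  params <- NULL
  pline <- grep("g=", hdr, value = TRUE)
  if (length(pline) == 1) {
    kv <- regmatches(pline, gregexpr("[a-z0-9]+=[-+0-9.eE]+", pline))[[1]]
    vals <- setNames(as.numeric(sub(".*=", "", kv)), sub("=.*", "", kv))
    if (all(c("g", "gamma", "h", "lambda3") %in% names(vals)))
      params <- nucleation_params(vals[["g"]], vals[["gamma"]], vals[["h"]],
                                  vals[["lambda3"]])
  }
  out <- as_size_distribution(df)
  attr(out, "params") <- params
  out
}

#' Read and write aggregate-series tables
#'
#' Long-format tab-separated text with columns `run`, `time`, `n`, `count`
#' (one row per aggregate size per frame per run), and the companion
#' p_free table with columns `run`, `time`, `p_free`. Times are in reduced
#' time units. Malformed rows and missing columns raise parse errors naming
#' the offender.
#'
#' @param records Tibble `run`, `time`, `n`, `count`.
#' @param series Tibble `run`, `time`, `p_free`.
#' @param path File path.
#' @param align For `read_pfree_series()`: how to treat runs with unequal
#'   time grids — `"error"` (default) or `"intersect"` (keep the shared
#'   grid).
#' @return Readers return tibbles; writers return `path` invisibly.
#' @export
write_aggregate_records <- function(records, path) {
  check_columns(records, c("run", "time", "n", "count"), "aggregate records")
  readr::write_tsv(records, path)
  invisible(path)
}

#' @rdname write_aggregate_records
#' @export
read_aggregate_records <- function(path) {
  df <- read_table_checked(path, c("run", "time", "n", "count"), "cdii")
  if (any(df$count < 0) || any(df$n < 1))
    abort("aggregate records must have n >= 1 and count >= 0.")
  df
}

#' @rdname write_aggregate_records
#' @export
write_pfree_series <- function(series, path) {
  check_columns(series, c("run", "time", "p_free"), "p_free series")
  readr::write_tsv(series, path)
  invisible(path)
}

#' @rdname write_aggregate_records
#' @export
read_pfree_series <- function(path, align = c("error", "intersect")) {
  align <- match.arg(align)
  df <- read_table_checked(path, c("run", "time", "p_free"), "cdd")
  grids <- split(df$time, df$run)
  shared <- Reduce(intersect, grids)
  if (!all(vapply(grids, function(g) length(g) == length(shared), TRUE))) {
    if (align == "error")
      abort("runs have unequal time grids; use align = \"intersect\" to keep the shared frames.")
    df <- filter(df, .data$time %in% shared)
  }
  as_repeat_series(df)
}

check_columns <- function(df, need, what) {
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    abort(sprintf("%s is missing column(s): %s.", what, paste(miss, collapse = ", ")))
  invisible(df)
}

read_table_checked <- function(path, need, types) {
  hdr <- strsplit(readLines(path, n = 1), "\t")[[1]]
  miss <- setdiff(need, hdr)
  if (length(miss) > 0)
    abort(sprintf("parse error in '%s': missing column(s) %s.",
                  path, paste(miss, collapse = ", ")))
  spec <- do.call(readr::cols, as.list(setNames(strsplit(types, "")[[1]], need)))
  df <- suppressWarnings(readr::read_tsv(path, col_types = spec, progress = FALSE))
  probs <- readr::problems(df)
  if (nrow(probs) > 0)
    abort(sprintf("parse error in '%s' at line %d: expected %s.",
                  path, probs$row[1], probs$expected[1]))
  df[need]
}

#' Read coordinate frames from extended-XYZ-like text
#'
#' Parses a concatenation of frames in the schema
#' \preformatted{
#' <n_beads>
#' box_length=<L> time=<t>
#' <species> <x> <y> <z> <molecule>
#' ...
#' }
#' (whitespace-separated; the species column is kept but unused by the
#' clustering). Coordinates are wrapped into the periodic box.
#'
#' @param path File path.
#' @return A list of [md_frame()] objects.
#' @export
read_xyz_frames <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1
  while (i <= length(lines)) {
    if (!grepl("^\\s*\\d+\\s*$", lines[i]))
      abort(sprintf("parse error in '%s' at line %d: expected a bead count.", path, i))
    nb <- as.integer(lines[i])
    cm <- lines[i + 1]
    get_num <- function(key) {
      m <- regmatches(cm, regexec(paste0(key, "=([-+0-9.eE]+)"), cm))[[1]]
      if (length(m) < 2) NA_real_ else as.numeric(m[2])
    }
    L <- get_num("box_length")
    if (is.na(L))
      abort(sprintf("parse error in '%s' at line %d: comment line must carry box_length=<L>.", path, i + 1))
    body <- lines[i + 2:(nb + 1)]
    tok <- strsplit(trimws(body), "\\s+")
    bad <- which(vapply(tok, length, 1L) < 5)
    if (length(bad) > 0)
      abort(sprintf("parse error in '%s' at line %d: need <species> <x> <y> <z> <molecule>.",
                    path, i + 1 + bad[1]))
    pos <- t(vapply(tok, function(x) as.numeric(x[2:4]), numeric(3)))
    mol <- vapply(tok, function(x) x[5], "")
    frames[[length(frames) + 1]] <- md_frame(pos, mol, L, time = get_num("time"))
    i <- i + nb + 2
  }
  frames
}

#' @rdname read_xyz_frames
#' @param frames List of [md_frame()] objects.
#' @param species Optional bead species labels recycled across beads
#'   (default `"B"`).
#' @export
write_xyz_frames <- function(frames, path, species = "B") {
  out <- unlist(lapply(frames, function(f) {
    nb <- nrow(f$positions)
    sp <- rep_len(species, nb)
    c(sprintf("%d", nb),
      sprintf("box_length=%.17g time=%.17g", f$box_length,
              if (is.na(f$time)) 0 else f$time),
      sprintf("%s %.17g %.17g %.17g %s", sp,
              f$positions[, 1], f$positions[, 2], f$positions[, 3],
              f$molecule_labels[f$molecule]))
  }))
  writeLines(out, path)
  invisible(path)
}
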