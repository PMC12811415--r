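#' @title MNM sweep profiles
#' @description
#' The pipeline's central statistic: the number of DBSCAN clusters as a
#' function of the minimum number of molecules (MNM) at a fixed epsilon
#' radius.  Per region of interest the profile is normalized so that its
#' peak is 1 ("normalized to 1"), then profiles from many cells are
#' aggregated by their per-grid-value mean and standard deviation, and
#' conditions are compared through their modal MNM — the grid value
#' where the mean normalized profile peaks.
#' @name sweep_profiles
NULL

#' Default MNM grid
#'
#' The sweep range runs from 10 to 1,200; the grid uses step 10 up to
#' 100 and step 50 above (the range is fixed by the analysis design, the
#' spacing is a package choice).
#' @export
default_mnm_grid <- function() c(seq(10L, 100L, 10L), seq(150L, 1200L, 50L))

#' Channel defaults for the epsilon radius
#'
#' 75 nm for channel A (Alexa Fluor 647 anti-CBM3a) and 125 nm for
#' channel B (PA-GFP-dockerin).
#' @param channel `"A_af647"` or `"B_pagfp"`.
#' @export
default_eps <- function(channel = c("A_af647", "B_pagfp")) {
  switch(match.arg(channel), A_af647 = 75, B_pagfp = 125)
}

.check_grid <- function(mnm_grid) {
  if (length(mnm_grid) == 0)
    stop("mnm_grid must be non-empty", call. = FALSE)
  if (any(!is.finite(mnm_grid)) || any(mnm_grid < 1) ||
      any(mnm_grid != round(mnm_grid)) || any(diff(mnm_grid) <= 0))
    stop("mnm_grid must be strictly ascending integers >= 1",
         call. = FALSE)
  as.integer(mnm_grid)
}

#' Normalize a cluster-count profile
#'
#' @param counts Non-negative cluster counts over the grid.
#' @param mode `"max"` (default; peak scaled to 1) or `"sum"`
#'   (profile sums to 1).  All-zero counts map to all zeros.
#' @return Normalized values in `[0, 1]`.
#' @export
normalize_profile <- function(counts, mode = c("max", "sum")) {
  mode <- match.arg(mode)
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be non-negative", call. = FALSE)
  denom <- if (mode == "max") max(counts) else sum(counts)
  if (denom == 0) return(rep(0, length(counts)))
  counts / denom
}

#' Sweep MNM at fixed epsilon over a localization table
#'
#' Runs DBSCAN once per grid value (reusing one neighbour-list
#' computation at the fixed epsilon radius) and records the cluster
#' count, raw and normalized.
#'
#' @param table A [loc_table()] (typically already clipped to one ROI).
#' @param eps Epsilon radius in nm; defaults to the channel's standard
#'   radius.
#' @param mnm_grid Strictly ascending integer grid, see
#'   [default_mnm_grid()].
#' @param roi_id,condition Metadata tags carried into exports.
#' @param normalization Passed to [normalize_profile()].
#' @return A `sweep_profile`: list with `eps`, `mnm_grid`, `counts`,
#'   `normalized`, `roi_id`, `condition`.
#' @export
sweep_mnm <- function(table, eps = NULL, mnm_grid = default_mnm_grid(),
                      roi_id = "", condition = "",
                      normalization = "max") {
  stopifnot(inherits(table, "loc_table"))
  if (is.null(eps)) eps <- default_eps(attr(table, "channel"))
  mnm_grid <- .check_grid(mnm_grid)
  if (!is.numeric(eps) || length(eps) != 1 || eps <= 0)
    stop("eps must be a single positive radius (nm)", call. = FALSE)
  nbrs <- .eps_neighbors(.loc_xy(table), eps)
  counts <- vapply(mnm_grid,
                   function(m) .dbscan_labels(nbrs, m)$n_clusters,
                   integer(1))
  structure(list(eps = as.numeric(eps), mnm_grid = mnm_grid,
                 counts = counts,
                 normalized = normalize_profile(counts, normalization),
                 roi_id = as.character(roi_id),
                 condition = as.character(condition)),
            class = "sweep_profile")
}

#' @export
print.sweep_profile <- function(x, ...) {
  cat(sprintf(
    "<sweep_profile> roi '%s' (%s), eps = %g nm, %d grid values, peak %d clusters at mnm = %d\n",
    x$roi_id, x$condition, x$eps, length(x$mnm_grid),
    max(x$counts), x$mnm_grid[which.max(x$counts)]))
  invisible(x)
}

#' Flatten sweep profiles to a table
#'
#' @param profiles A `sweep_profile` or list of them.
#' @return `data.frame` with `roi_id`, `condition`, `eps`, `mnm`,
#'   `count`, `normalized`.
#' @export
profile_table <- function(profiles) {
  if (inherits(profiles, "sweep_profile")) profiles <- list(profiles)
  do.call(rbind, lapply(profiles, function(p)
    data.frame(roi_id = p$roi_id, condition = p$condition, eps = p$eps,
               mnm = p$mnm_grid, count = p$counts,
               normalized = p$normalized)))
}

#' Aggregate normalized profiles across ROIs
#'
#' Per-cell-then-averaged aggregation: each ROI's profile is normalized
#' on its own before the per-grid-value arithmetic mean and standard
#' deviation are taken.
#'
#' @param profiles List of `sweep_profile`s sharing the same grid (and
#'   nominally the same condition).
#' @return An `aggregate_profile`: `mnm_grid`, `mean_normalized`,
#'   `sd_normalized`, `n_rois`, `condition`, `eps`.
#' @export
aggregate_profiles <- function(profiles) {
  if (inherits(profiles, "sweep_profile")) profiles <- list(profiles)
  if (length(profiles) < 1)
    stop("need at least one profile", call. = FALSE)
  grid <- profiles[[1]]$mnm_grid
  for (p in profiles) {
    stopifnot(inherits(p, "sweep_profile"))
    if (!identical(p$mnm_grid, grid))
      stop("all profiles must share the same mnm_grid", call. = FALSE)
  }
  mat <- do.call(rbind, lapply(profiles, function(p) p$normalized))
  sds <- if (nrow(mat) > 1) apply(mat, 2, stats::sd) else
    rep(0, ncol(mat))
  structure(list(mnm_grid = grid,
                 mean_normalized = colMeans(mat),
                 sd_normalized = sds,
                 n_rois = length(profiles),
                 condition = profiles[[1]]$condition,
                 eps = profiles[[1]]$eps),
            class = "aggregate_profile")
}

#' Modal MNM of an aggregate profile
#'
#' The grid value maximizing the mean normalized cluster count; ties go
#' to the smallest grid value.
#' @param profile An `aggregate_profile`.
#' @export
modal_mnm <- function(profile) {
  stopifnot(inherits(profile, "aggregate_profile"))
  profile$mnm_grid[which.max(profile$mean_normalized)]
}

#' Compare two condition-level aggregate profiles
#'
#' @param a,b `aggregate_profile`s on the same grid.
#' @return List: `mnm_grid`, per-grid `mean_diff` (a - b), each
#'   condition's `modal_mnm`, and `distance` — the maximum absolute
#'   difference between the mean normalized profiles (in `[0, 1]`; 1
#'   when the profiles have disjoint support).
#' @export
compare_conditions <- function(a, b) {
  stopifnot(inherits(a, "aggregate_profile"),
            inherits(b, "aggregate_profile"))
  if (!identical(a$mnm_grid, b$mnm_grid))
    stop("profiles must share the same mnm_grid", call. = FALSE)
  diff <- a$mean_normalized - b$mean_normalized
  list(mnm_grid = a$mnm_grid, mean_diff = diff,
       modal_mnm_a = modal_mnm(a), modal_mnm_b = modal_mnm(b),
       condition_a = a$condition, condition_b = b$condition,
       distance = if (length(diff) > 0) max(abs(diff)) else 0)
}
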