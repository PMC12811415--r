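#' @title Density-based clustering of localizations
#' @description
#' A from-scratch DBSCAN tailored to 2D single-molecule localization
#' coordinates.  A localization is a *core* molecule when its closed
#' epsilon-neighbourhood (Euclidean distance <= eps, the point itself
#' included) contains at least MNM molecules; clusters propagate from
#' core molecules, density-connected non-core members are *border*
#' molecules, and everything else is *noise*.  Cluster ids are dense
#' integers from 0 in order of discovery; noise is -1.  Border points
#' reachable from several clusters go to the cluster whose expansion
#' reaches them first in deterministic input order.
#' @name dbscan_core
NULL

#' Clustering parameters
#'
#' @param eps Epsilon radius in nm (> 0): the maximum center-to-center
#'   distance at which two localizations count as spatial neighbours.
#' @param mnm Minimum number of molecules (>= 1) within the epsilon
#'   radius for a localization to be a core molecule (self included).
#' @export
cluster_params <- function(eps, mnm) {
  if (!is.numeric(eps) || length(eps) != 1 || !is.finite(eps) || eps <= 0)
    stop("eps must be a single positive radius (nm)", call. = FALSE)
  if (!is.numeric(mnm) || length(mnm) != 1 || !is.finite(mnm) ||
      mnm < 1 || mnm != round(mnm))
    stop("mnm must be a single integer >= 1", call. = FALSE)
  structure(list(eps = as.numeric(eps), mnm = as.integer(mnm)),
            class = "cluster_params")
}

# Coerce input to an n x 2 numeric coordinate matrix (nm).
.as_xy <- function(points) {
  if (inherits(points, "loc_table")) return(.loc_xy(points))
  points <- as.matrix(points)
  if (length(points) == 0) return(matrix(numeric(), ncol = 2))
  if (ncol(points) < 2)
    stop("points must have two coordinate columns", call. = FALSE)
  storage.mode(points) <- "double"
  points[, 1:2, drop = FALSE]
}

# Fixed-radius neighbour lists via grid binning.  Cells have side eps, so
# neighbours of a point can only live in the 3x3 block around its cell.
# Returns a list of integer index vectors (self always included).
.eps_neighbors <- function(xy, eps) {
  n <- nrow(xy)
  if (n == 0) return(list())
  if (any(!is.finite(xy)))
    stop("points must be finite (no NA/NaN coordinates)", call. = FALSE)
  cx <- as.integer(floor(xy[, 1] / eps))
  cy <- as.integer(floor(xy[, 2] / eps))
  cx <- cx - min(cx) + 1L
  cy <- cy - min(cy) + 1L
  ncy <- max(cy) + 2L
  code <- cx * ncy + cy
  cells <- split(seq_len(n), code)
  cell_code <- as.integer(names(cells))
  # candidate indices for each occupied cell = union over its 3x3 block
  offs <- as.vector(outer((-1:1) * ncy, -1:1, `+`))
  cand <- lapply(seq_along(cells), function(ci) {
    hits <- match(cell_code[ci] + offs, cell_code)
    sort(unlist(cells[hits[!is.na(hits)]], use.names = FALSE))
  })
  eps2 <- eps * eps
  out <- vector("list", n)
  for (ci in seq_along(cells)) {
    idx <- cells[[ci]]
    cnd <- cand[[ci]]
    dx <- outer(xy[idx, 1], xy[cnd, 1], `-`)
    dy <- outer(xy[idx, 2], xy[cnd, 2], `-`)
    within <- dx * dx + dy * dy <= eps2
    for (k in seq_along(idx))
      out[[idx[k]]] <- cnd[within[k, ]]
  }
  out
}

# Label points given precomputed neighbour lists; the sweep reuses the
# neighbour lists across many mnm values.
.dbscan_labels <- function(nbrs, mnm) {
  n <- length(nbrs)
  labels <- rep(-1L, n)
  if (n == 0)
    return(list(labels = labels, roles = character(0), n_clusters = 0L))
  core <- lengths(nbrs) >= mnm
  cid <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != -1L) next
    labels[i] <- cid
    frontier <- i
    while (length(frontier) > 0) {
      nb <- unique(unlist(nbrs[frontier], use.names = FALSE))
      new <- nb[labels[nb] == -1L]
      labels[new] <- cid
      frontier <- new[core[new]]
    }
    cid <- cid + 1L
  }
  roles <- ifelse(core, "core", ifelse(labels >= 0L, "border", "noise"))
  list(labels = labels, roles = roles, n_clusters = cid)
}

#' Epsilon-neighbourhood query
#'
#' Indices of all points at Euclidean distance <= `eps` (inclusive
#' boundary) from the point at index `center`, the point itself included.
#'
#' @param points Coordinate matrix (nm) or [loc_table()].
#' @param center Index of the query point in `points`.
#' @param eps Radius in nm, > 0.
#' @return Sorted integer vector of neighbour indices.
#' @export
region_query <- function(points, center, eps) {
  xy <- .as_xy(points)
  if (!is.numeric(eps) || length(eps) != 1 || eps <= 0)
    stop("eps must be a single positive radius (nm)", call. = FALSE)
  center <- as.integer(center)
  if (length(center) != 1 || is.na(center) || center < 1 ||
      center > nrow(xy))
    stop("center must index a point in `points`", call. = FALSE)
  d2 <- (xy[, 1] - xy[center, 1])^2 + (xy[, 2] - xy[center, 2])^2
  which(d2 <= eps * eps)
}

#' DBSCAN clustering with core/border/noise roles
#'
#' @param points Coordinate matrix (nm) or [loc_table()].
#' @param params A [cluster_params()]; alternatively pass `eps` and
#'   `mnm` directly.
#' @param eps,mnm Used when `params` is missing.
#' @return A `cluster_labeling`: list with integer `labels`
#'   (-1 = noise, 0..k-1 cluster ids in order of discovery), character
#'   `roles` (`"core"`, `"border"`, `"noise"`), `params` and
#'   `n_clusters`.
#' @examples
#' xy <- cbind(c(0, 10, 20, 500), c(0, 10, 0, 500))
#' dbscan_cluster(xy, eps = 50, mnm = 3)
#' @export
dbscan_cluster <- function(points, params = NULL, eps = NULL, mnm = NULL) {
  if (is.null(params)) params <- cluster_params(eps, mnm)
  stopifnot(inherits(params, "cluster_params"))
  xy <- .as_xy(points)
  res <- .dbscan_labels(.eps_neighbors(xy, params$eps), params$mnm)
  structure(list(labels = res$labels, roles = res$roles,
                 params = params, n_clusters = res$n_clusters),
            class = "cluster_labeling")
}

#' @export
print.cluster_labeling <- function(x, ...) {
  cat(sprintf(
    "<cluster_labeling> %d points, %d clusters (eps = %g nm, mnm = %d); %d noise\n",
    length(x$labels), x$n_clusters, x$params$eps, x$params$mnm,
    sum(x$labels == -1L)))
  invisible(x)
}

#' Export a labeling as a flat table
#'
#' @param labeling A `cluster_labeling` from [dbscan_cluster()].
#' @param points The coordinates that were clustered.
#' @return `data.frame` with `index`, `x`, `y`, `cluster`, `role`.
#' @export
labeling_table <- function(labeling, points) {
  stopifnot(inherits(labeling, "cluster_labeling"))
  xy <- .as_xy(points)
  if (nrow(xy) != length(labeling$labels))
    stop("labeling and points disagree in length", call. = FALSE)
  data.frame(index = seq_len(nrow(xy)), x = xy[, 1], y = xy[, 2],
             cluster = labeling$labels, role = labeling$roles)
}

#' Area of the epsilon-neighbourhood disc
#'
#' @param eps Radius in nm, >= 0.
#' @return Disc area pi * eps^2, converted to square microns.  For the
#'   channel-A radius of 75 nm this is 0.01767 um^2 (~0.018 um^2).
#' @export
eps_disc_area <- function(eps) {
  if (!is.numeric(eps) || any(!is.finite(eps)) || any(eps < 0))
    stop("eps must be >= 0", call. = FALSE)
  pi * eps^2 / 1e6
}

#' Local molecular density within an epsilon disc
#'
#' @param count Number of molecules in the disc, >= 0.
#' @param eps Disc radius in nm, > 0.
#' @return Density in molecules per square micron.
#' @export
local_density <- function(count, eps) {
  if (!is.numeric(count) || any(!is.finite(count)) || any(count < 0))
    stop("count must be >= 0", call. = FALSE)
  if (!is.numeric(eps) || any(!is.finite(eps)) || any(eps <= 0))
    stop("eps must be > 0", call. = FALSE)
  count / eps_disc_area(eps)
}
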