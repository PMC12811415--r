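#' @title Two-channel colocalization
#' @description
#' Coordinate-based colocalization of the red (CBM3a) and green
#' (unoccupied cohesin) channels.  At localization level, the fraction
#' of channel-A localizations with at least one channel-B localization
#' within a distance threshold (and vice versa); at cluster level,
#' nearest-centroid distances between detected clusters.  The default
#' threshold equals the channel-A clustering radius (75 nm), a declared
#' choice since image-overlay "yellow" colocalization carries no
#' explicit distance.
#' @name colocalization
NULL

# for each point of a, is any point of b within d?  Grid-binned scan.
.near_any <- function(axy, bxy, d) {
  na <- nrow(axy)
  if (na == 0) return(logical(0))
  if (nrow(bxy) == 0) return(rep(FALSE, na))
  all_xy <- rbind(axy, bxy)
  cx <- as.integer(floor(all_xy[, 1] / d))
  cy <- as.integer(floor(all_xy[, 2] / d))
  cx <- cx - min(cx) + 1L; cy <- cy - min(cy) + 1L
  ncy <- max(cy) + 2L
  code <- cx * ncy + cy
  bcode <- code[-seq_len(na)]
  cells <- split(seq_len(nrow(bxy)), bcode)
  cell_code <- as.integer(names(cells))
  offs <- as.vector(outer((-1:1) * ncy, -1:1, `+`))
  d2 <- d * d
  out <- logical(na)
  for (i in seq_len(na)) {
    hits <- match(code[i] + offs, cell_code)
    cnd <- unlist(cells[hits[!is.na(hits)]], use.names = FALSE)
    if (length(cnd) == 0) next
    out[i] <- any((bxy[cnd, 1] - axy[i, 1])^2 +
                    (bxy[cnd, 2] - axy[i, 2])^2 <= d2)
  }
  out
}

#' Localization-level colocalization fractions
#'
#' @param a,b [loc_table()]s (channels A and B).
#' @param d Distance threshold in nm, > 0; default 75 nm.
#' @return A `coloc_result`: `distance_threshold`, `frac_A_near_B`,
#'   `frac_B_near_A`, `n_A`, `n_B`.  An empty channel reports fraction
#'   0 with its count flagging the emptiness.
#' @export
coloc_fraction <- function(a, b, d = 75) {
  stopifnot(inherits(a, "loc_table"), inherits(b, "loc_table"))
  if (!is.numeric(d) || length(d) != 1 || !is.finite(d) || d <= 0)
    stop("d must be a single positive distance (nm)", call. = FALSE)
  axy <- .loc_xy(a); bxy <- .loc_xy(b)
  fa <- if (nrow(axy) == 0) 0 else mean(.near_any(axy, bxy, d))
  fb <- if (nrow(bxy) == 0) 0 else mean(.near_any(bxy, axy, d))
  structure(list(distance_threshold = d,
                 frac_A_near_B = fa, frac_B_near_A = fb,
                 n_A = nrow(axy), n_B = nrow(bxy)),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf(
    "<coloc_result> d = %g nm: %.1f%% of %d A near B; %.1f%% of %d B near A\n",
    x$distance_threshold, 100 * x$frac_A_near_B, x$n_A,
    100 * x$frac_B_near_A, x$n_B))
  invisible(x)
}

#' Cluster centroids of a labeling
#'
#' Arithmetic mean of member coordinates per cluster (core and border
#' members; noise excluded).
#'
#' @param labeling A `cluster_labeling`.
#' @param points The clustered coordinates.
#' @return `data.frame` with `cluster`, `cx`, `cy`, `n`.
#' @export
cluster_centroids <- function(labeling, points) {
  stopifnot(inherits(labeling, "cluster_labeling"))
  xy <- .as_xy(points)
  keep <- labeling$labels >= 0L
  if (!any(keep))
    return(data.frame(cluster = integer(), cx = numeric(),
                      cy = numeric(), n = integer()))
  f <- factor(labeling$labels[keep],
              levels = sort(unique(labeling$labels[keep])))
  data.frame(cluster = as.integer(levels(f)),
             cx = as.numeric(tapply(xy[keep, 1], f, mean)),
             cy = as.numeric(tapply(xy[keep, 2], f, mean)),
             n = as.integer(table(f)))
}

#' Cluster-level colocalization
#'
#' For each channel-A cluster: distance to the nearest channel-B
#' cluster centroid and a colocalized flag (distance <= d).
#'
#' @param labels_a,labels_b `cluster_labeling`s for the two channels.
#' @param table_a,table_b The corresponding [loc_table()]s.
#' @param d Distance threshold in nm, > 0.
#' @return `data.frame` with one row per channel-A cluster: `cluster_a`,
#'   `n_a`, `nearest_cluster_b`, `centroid_distance`, `colocalized`.
#'   Empty when channel A has no clusters; `nearest_cluster_b` is NA
#'   (distance Inf, flag FALSE) when channel B has none.
#' @export
cluster_coloc <- function(labels_a, table_a, labels_b, table_b, d = 75) {
  if (!is.numeric(d) || length(d) != 1 || d <= 0)
    stop("d must be a single positive distance (nm)", call. = FALSE)
  ca <- cluster_centroids(labels_a, table_a)
  cb <- cluster_centroids(labels_b, table_b)
  if (nrow(ca) == 0)
    return(data.frame(cluster_a = integer(), n_a = integer(),
                      nearest_cluster_b = integer(),
                      centroid_distance = numeric(),
                      colocalized = logical()))
  if (nrow(cb) == 0)
    return(data.frame(cluster_a = ca$cluster, n_a = ca$n,
                      nearest_cluster_b = NA_integer_,
                      centroid_distance = Inf, colocalized = FALSE))
  dist2 <- outer(ca$cx, cb$cx, `-`)^2 + outer(ca$cy, cb$cy, `-`)^2
  nearest <- apply(dist2, 1, which.min)
  dmin <- sqrt(dist2[cbind(seq_len(nrow(ca)), nearest)])
  data.frame(cluster_a = ca$cluster, n_a = ca$n,
             nearest_cluster_b = cb$cluster[nearest],
             centroid_distance = dmin,
             colocalized = dmin <= d)
}
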