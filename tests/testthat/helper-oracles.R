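# Independent brute-force oracles.  These deliberately avoid the
# package's internal code paths: full distance matrices instead of grid
# binning, winding-number point-in-polygon instead of the even-odd rule,
# scalar loops instead of vectorized expansion.

bf_region_query <- function(xy, center, eps) {
  d <- sqrt((xy[, 1] - xy[center, 1])^2 + (xy[, 2] - xy[center, 2])^2)
  which(d <= eps)
}

# Reference DBSCAN: materialize the full neighbour graph, expand with an
# explicit seed queue in input order (original-algorithm style).
bf_dbscan <- function(xy, eps, mnm) {
  n <- nrow(xy)
  if (n == 0) return(list(labels = integer(0), core = logical(0),
                          n_clusters = 0L))
  A <- as.matrix(stats::dist(xy)) <= eps
  diag(A) <- TRUE
  core <- rowSums(A) >= mnm
  labels <- rep(-1L, n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != -1L) next
    labels[i] <- cid
    queue <- i
    head <- 1L
    while (head <= length(queue)) {
      p <- queue[head]; head <- head + 1L
      for (q in which(A[p, ])) {
        if (labels[q] == -1L) {
          labels[q] <- cid
          if (core[q]) queue <- c(queue, q)
        }
      }
    }
    cid <- cid + 1L
  }
  list(labels = labels, core = core, n_clusters = cid)
}

# union-find connected components of the eps-neighbour graph
uf_components <- function(xy, eps) {
  n <- nrow(xy)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  D <- as.matrix(stats::dist(xy))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && D[i, j] <= eps) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  length(unique(vapply(seq_len(n), find, integer(1))))
}

# two labelings induce the same partition on `subset`?
same_partition <- function(l1, l2, subset = seq_along(l1)) {
  a <- l1[subset]; b <- l2[subset]
  if (length(a) == 0) return(TRUE)
  key_a <- match(a, unique(a))
  key_b <- match(b, unique(b))
  all(key_a == key_b)
}

# winding-number point-in-polygon (strict interior) + boundary distance
ray_cast_oracle <- function(px, py, v) {
  nv <- nrow(v)
  vapply(seq_along(px), function(k) {
    # boundary: distance to any edge ~ 0
    for (i in seq_len(nv)) {
      a <- v[i, ]; b <- v[if (i == nv) 1 else i + 1, ]
      ab2 <- sum((b - a)^2)
      t <- if (ab2 == 0) 0 else
        min(1, max(0, ((px[k] - a[1]) * (b[1] - a[1]) +
                         (py[k] - a[2]) * (b[2] - a[2])) / ab2))
      pr <- a + t * (b - a)
      if (sqrt((px[k] - pr[1])^2 + (py[k] - pr[2])^2) < 1e-7) return(TRUE)
    }
    # winding number via summed signed angles
    ang <- 0
    for (i in seq_len(nv)) {
      a <- v[i, ]; b <- v[if (i == nv) 1 else i + 1, ]
      a1 <- atan2(a[2] - py[k], a[1] - px[k])
      a2 <- atan2(b[2] - py[k], b[1] - px[k])
      da <- a2 - a1
      if (da > pi) da <- da - 2 * pi
      if (da < -pi) da <- da + 2 * pi
      ang <- ang + da
    }
    abs(ang) > pi
  }, logical(1))
}

# scalar point-to-segment distance
dist_seg_oracle <- function(px, py, a, b) {
  ab2 <- sum((b - a)^2)
  t <- if (ab2 == 0) 0 else
    min(1, max(0, ((px - a[1]) * (b[1] - a[1]) +
                     (py - a[2]) * (b[2] - a[2])) / ab2))
  pr <- a + t * (b - a)
  sqrt((px - pr[1])^2 + (py - pr[2])^2)
}

# distance to a polygon boundary
dist_polygon_oracle <- function(px, py, v) {
  nv <- nrow(v)
  min(vapply(seq_len(nv), function(i)
    dist_seg_oracle(px, py, v[i, ], v[if (i == nv) 1 else i + 1, ]),
    numeric(1)))
}

bf_coloc <- function(axy, bxy, d) {
  if (nrow(axy) == 0 || nrow(bxy) == 0)
    return(list(fa = 0, fb = 0))
  D <- sqrt(outer(axy[, 1], bxy[, 1], `-`)^2 +
              outer(axy[, 2], bxy[, 2], `-`)^2)
  list(fa = mean(apply(D, 1, min) <= d),
       fb = mean(apply(D, 2, min) <= d))
}

# --- fixture builders -------------------------------------------------------

# Gaussian blob of localizations as a plain coordinate matrix
make_blob <- function(n, cx, cy, sd = 30) {
  cbind(stats::rnorm(n, cx, sd), stats::rnorm(n, cy, sd))
}

make_table <- function(xy, channel = "A_af647", uncertainty = NULL,
                       field_extent = NULL) {
  xy[xy < 0] <- 0
  n <- nrow(xy)
  loc_table(xy[, 1], xy[, 2], frame = sample.int(1000, n, replace = TRUE),
            uncertainty = if (is.null(uncertainty))
              stats::runif(n, 5, 40) else rep(uncertainty, n),
            channel = channel, field_extent = field_extent)
}

# k well-separated planted clusters on a grid, rendered through the
# generator; spacing must exceed the recovery separation bound.
make_separated_scene_xy <- function(k, seed, spacing = 700,
                                    n_cipa = 20, dispersion = 40,
                                    background_density = 0.2) {
  cols <- ceiling(sqrt(k))
  centers <- cbind(
    500 + spacing * ((seq_len(k) - 1) %% cols),
    500 + spacing * ((seq_len(k) - 1) %/% cols))
  clusters <- data.frame(cluster_id = seq_len(k), class = "cell",
                         cx = centers[, 1], cy = centers[, 2],
                         dispersion = dispersion, n_cipa = n_cipa)
  geom <- scene_geometry(field_extent = c(500 + spacing * cols + 500,
                                          500 + spacing * cols + 500))
  render_localizations(
    clusters, stoich = cellulosome_stoichiometry(),
    model = emitter_model(mean_localizations = 5, precision_sigma = 20,
                          background_density = background_density),
    geometry = geom, seed = seed)
}
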