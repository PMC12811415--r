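#' @title Synthetic two-channel SMLM scenes
#' @description
#' Generates ground-truth localization datasets with the statistical
#' structure the analysis assumes: rod-shaped bacterial cells (2D
#' capsules) and substrate particles (polygons) decorated with planted
#' clusters of cellulosome complexes, an enzyme-microbe-substrate (EMS)
#' contact zone where bound presets concentrate cluster mass, a diffuse
#' cell-surface labeling background, per-emitter blinking (geometric
#' number of localizations), isotropic Gaussian localization error and a
#' homogeneous Poisson field background.  Channel A (Alexa Fluor 647
#' anti-CBM3a) marks primary scaffoldins; channel B (PA-GFP-dockerin)
#' marks unoccupied type I cohesins, so channel-B cluster signal scales
#' with `1 - occupancy_prob`.
#' @name synthetic_scene
NULL

.SCENE_PRESETS <- c("log_bound", "stationary_bound",
                    "log_detached", "stationary_detached")

#' Cellulosome stoichiometry
#'
#' Counts and labeling probabilities of the cellulosome assembly: each
#' primary scaffoldin (CipA) carries `cipA_cohesins` type I cohesins and
#' one CBM3a; an anchor scaffoldin of valency `anchor_valency` (e.g. the
#' heptavalent OlpB) can hold that many CipA molecules.
#'
#' @param cipA_cohesins Type I cohesins per CipA (default 9).
#' @param anchor_valency Type II cohesins per anchor scaffoldin
#'   (default 7).
#' @param occupancy_prob Probability a type I cohesin carries an enzyme.
#' @param label_eff_A Probability a CipA's CBM3a yields a channel-A
#'   emitter.
#' @param label_eff_B Probability an unoccupied cohesin yields a
#'   channel-B emitter.
#' @export
cellulosome_stoichiometry <- function(cipA_cohesins = 9L,
                                      anchor_valency = 7L,
                                      occupancy_prob = 0.9,
                                      label_eff_A = 0.8,
                                      label_eff_B = 0.8) {
  cipA_cohesins <- as.integer(cipA_cohesins)
  anchor_valency <- as.integer(anchor_valency)
  if (length(cipA_cohesins) != 1 || is.na(cipA_cohesins) ||
      cipA_cohesins < 0)
    stop("cipA_cohesins must be an integer >= 0", call. = FALSE)
  if (length(anchor_valency) != 1 || is.na(anchor_valency) ||
      anchor_valency < 0)
    stop("anchor_valency must be an integer >= 0", call. = FALSE)
  for (p in list(occupancy_prob, label_eff_A, label_eff_B))
    if (!is.numeric(p) || length(p) != 1 || is.na(p) || p < 0 || p > 1)
      stop("probabilities must lie in [0, 1]", call. = FALSE)
  structure(list(cipA_cohesins = cipA_cohesins,
                 anchor_valency = anchor_valency,
                 occupancy_prob = occupancy_prob,
                 label_eff_A = label_eff_A,
                 label_eff_B = label_eff_B),
            class = "cellulosome_stoichiometry")
}

#' Maximum enzyme count of a cell-anchored complex
#'
#' The number of glycoside hydrolases a fully loaded anchor can carry:
#' `anchor_valency * cipA_cohesins`.  For the heptavalent anchor with
#' nine cohesins per CipA this is 63.
#'
#' @param stoich A [cellulosome_stoichiometry()].
#' @return Integer enzyme capacity.
#' @examples
#' max_enzyme_capacity(cellulosome_stoichiometry(9, 7)) # 63
#' @export
max_enzyme_capacity <- function(stoich = cellulosome_stoichiometry()) {
  stopifnot(inherits(stoich, "cellulosome_stoichiometry"))
  stoich$anchor_valency * stoich$cipA_cohesins
}

#' Emitter photophysics and noise model
#'
#' @param mean_localizations Mean number of localizations per emitter
#'   (blinking), >= 1; the count is `1 + Geometric`, so memoryless with
#'   the given mean.
#' @param precision_sigma Isotropic Gaussian localization error sd, nm.
#' @param background_density Homogeneous Poisson background,
#'   localizations per square micron (per channel).
#' @export
emitter_model <- function(mean_localizations = 5,
                          precision_sigma = 20,
                          background_density = 2) {
  if (!is.numeric(mean_localizations) || mean_localizations < 1)
    stop("mean_localizations must be >= 1", call. = FALSE)
  if (!is.numeric(precision_sigma) || precision_sigma <= 0)
    stop("precision_sigma must be > 0", call. = FALSE)
  if (!is.numeric(background_density) || background_density < 0)
    stop("background_density must be >= 0", call. = FALSE)
  structure(list(mean_localizations = as.numeric(mean_localizations),
                 precision_sigma = as.numeric(precision_sigma),
                 background_density = as.numeric(background_density)),
            class = "emitter_model")
}

# ---- geometry primitives ---------------------------------------------------

# distance from points (px, py) to segment a-b (vectorized over points)
.dist_point_segment <- function(px, py, a, b) {
  abx <- b[1] - a[1]; aby <- b[2] - a[2]
  len2 <- abx^2 + aby^2
  t <- if (len2 == 0) rep(0, length(px)) else
    pmin(1, pmax(0, ((px - a[1]) * abx + (py - a[2]) * aby) / len2))
  sqrt((px - (a[1] + t * abx))^2 + (py - (a[2] + t * aby))^2)
}

.polygon_edges <- function(v) {
  nv <- nrow(v)
  list(from = v, to = v[c(2:nv, 1), , drop = FALSE])
}

.dist_point_polygon_boundary <- function(px, py, v) {
  e <- .polygon_edges(v)
  d <- rep(Inf, length(px))
  for (k in seq_len(nrow(v)))
    d <- pmin(d, .dist_point_segment(px, py, e$from[k, ], e$to[k, ]))
  d
}

.polygons_overlap <- function(a, b) {
  if (any(.point_in_polygon(a[, 1], a[, 2], b))) return(TRUE)
  if (any(.point_in_polygon(b[, 1], b[, 2], a))) return(TRUE)
  ea <- .polygon_edges(a); eb <- .polygon_edges(b)
  for (i in seq_len(nrow(a)))
    for (j in seq_len(nrow(b)))
      if (.seg_cross(ea$from[i, ], ea$to[i, ], eb$from[j, ], eb$to[j, ]))
        return(TRUE)
  FALSE
}

# capsule = projected rod: two spine endpoints + radius
.capsule <- function(p1, p2, radius) {
  list(p1 = as.numeric(p1), p2 = as.numeric(p2), radius = as.numeric(radius))
}

.capsule_perimeter <- function(cell) {
  L <- sqrt(sum((cell$p2 - cell$p1)^2))
  2 * L + 2 * pi * cell$radius
}

# point on the capsule outline at arc-length s from a fixed origin
.capsule_perimeter_point <- function(cell, s) {
  L <- sqrt(sum((cell$p2 - cell$p1)^2))
  r <- cell$radius
  u <- if (L > 0) (cell$p2 - cell$p1) / L else c(1, 0)
  nv <- c(-u[2], u[1])
  s <- s %% (2 * L + 2 * pi * r)
  out <- matrix(NA_real_, length(s), 2)
  for (k in seq_along(s)) {
    si <- s[k]
    if (si < L) {
      out[k, ] <- cell$p1 + si * u + r * nv
    } else if (si < L + pi * r) {
      th <- (si - L) / r
      out[k, ] <- cell$p2 + r * (cos(th) * nv + sin(th) * u)
    } else if (si < 2 * L + pi * r) {
      out[k, ] <- cell$p2 - (si - L - pi * r) * u - r * nv
    } else {
      th <- (si - 2 * L - pi * r) / r
      out[k, ] <- cell$p1 + r * (-cos(th) * nv - sin(th) * u)
    }
  }
  out
}

# signed containment helper: distance from the capsule surface
.dist_capsule_surface <- function(px, py, cell) {
  abs(.dist_point_segment(px, py, cell$p1, cell$p2) - cell$radius)
}

.sample_in_polygon <- function(n, v) {
  if (n == 0) return(matrix(numeric(), ncol = 2))
  lo <- apply(v, 2, min); hi <- apply(v, 2, max)
  out <- matrix(NA_real_, 0, 2)
  while (nrow(out) < n) {
    m <- max(2 * (n - nrow(out)), 16)
    px <- stats::runif(m, lo[1], hi[1])
    py <- stats::runif(m, lo[2], hi[2])
    keep <- .point_in_polygon(px, py, v)
    out <- rbind(out, cbind(px[keep], py[keep]))
  }
  out[seq_len(n), , drop = FALSE]
}

.sample_on_polygon_boundary <- function(n, v, band) {
  if (n == 0) return(matrix(numeric(), ncol = 2))
  e <- .polygon_edges(v)
  len <- sqrt(rowSums((e$to - e$from)^2))
  edge <- sample.int(nrow(v), n, replace = TRUE, prob = len)
  t <- stats::runif(n)
  base <- e$from[edge, , drop = FALSE] +
    t * (e$to[edge, , drop = FALSE] - e$from[edge, , drop = FALSE])
  # jitter toward the centroid so decorated points hug the surface
  cen <- colMeans(v)
  dirx <- cen[1] - base[, 1]; diry <- cen[2] - base[, 2]
  nrm <- pmax(sqrt(dirx^2 + diry^2), 1e-9)
  d <- stats::runif(n, 0, band)
  cbind(base[, 1] + d * dirx / nrm, base[, 2] + d * diry / nrm)
}

#' Scene geometry
#'
#' @param field_extent `(width, height)` in nm.
#' @param cells List of capsules, each `list(p1, p2, radius)` in nm
#'   (spine endpoints plus radius).
#' @param particles List of vertex matrices (substrate particles).
#' @param contact_zones List of vertex matrices marking EMS interfaces;
#'   each must touch at least one cell outline and one particle.
#' @export
scene_geometry <- function(field_extent = c(6000, 6000),
                           cells = list(), particles = list(),
                           contact_zones = list()) {
  field_extent <- as.numeric(field_extent)
  stopifnot(length(field_extent) == 2, all(field_extent > 0))
  inside_field <- function(xy)
    all(xy[, 1] >= 0 & xy[, 1] <= field_extent[1] &
        xy[, 2] >= 0 & xy[, 2] <= field_extent[2])
  cells <- lapply(cells, function(c0) .capsule(c0$p1, c0$p2, c0$radius))
  for (cell in cells) {
    r <- cell$radius
    box <- rbind(cell$p1 + c(-r, -r), cell$p1 + c(r, r),
                 cell$p2 + c(-r, -r), cell$p2 + c(r, r))
    if (!inside_field(box))
      stop("cell outline extends outside field_extent", call. = FALSE)
  }
  particles <- lapply(particles, function(p) {
    p <- as.matrix(p); storage.mode(p) <- "double"; p
  })
  contact_zones <- lapply(contact_zones, function(p) {
    p <- as.matrix(p); storage.mode(p) <- "double"; p
  })
  for (p in c(particles, contact_zones))
    if (!inside_field(p))
      stop("polygon extends outside field_extent", call. = FALSE)
  for (cz in contact_zones) {
    touches_cell <- any(vapply(cells, function(cell) {
      any(.dist_point_segment(cz[, 1], cz[, 2], cell$p1, cell$p2) <=
            cell$radius * 1.75)
    }, logical(1)))
    touches_particle <- any(vapply(particles, function(p)
      .polygons_overlap(cz, p), logical(1)))
    if (!touches_cell || !touches_particle)
      stop("each contact zone must touch a cell outline and a particle",
           call. = FALSE)
  }
  structure(list(field_extent = field_extent, cells = cells,
                 particles = particles, contact_zones = contact_zones),
            class = "scene_geometry")
}

#' Default geometry for a condition preset
#'
#' One rod-shaped cell (2.4 um spine, 400 nm radius) in a 6 x 6 um
#' field; bound presets add one substrate particle next to the cell and
#' a contact zone spanning the interface.
#'
#' @param preset One of the four condition presets.
#' @param field_extent `(width, height)` nm.
#' @export
default_scene_geometry <- function(preset = .SCENE_PRESETS,
                                   field_extent = c(6000, 6000)) {
  preset <- match.arg(preset)
  cell <- list(p1 = c(1500, 3000), p2 = c(3900, 3000), radius = 400)
  if (preset %in% c("log_bound", "stationary_bound")) {
    particle <- rbind(c(4250, 1700), c(5700, 1500), c(5800, 3000),
                      c(5600, 4400), c(4400, 4300), c(4150, 3000))
    contact <- rbind(c(3900, 2500), c(4600, 2400), c(4700, 3500),
                     c(3950, 3550))
    scene_geometry(field_extent, cells = list(cell),
                   particles = list(particle),
                   contact_zones = list(contact))
  } else {
    scene_geometry(field_extent, cells = list(cell))
  }
}

#' Planted-cluster parameters for a condition preset
#'
#' Per surface class (`cell` perimeter band, `particle` surface,
#' `contact` zone): the expected cluster count (`n_mean`, Poisson unless
#' `count_dist = "fixed"`), a lognormal size distribution for the number
#' of CipA complexes per cluster (`size_meanlog`, `size_sdlog`, minimum
#' 1) and the isotropic Gaussian cluster dispersion (nm).
#' `surface_bg_per_um` is the diffuse cell-surface emitter rate
#' (emitters per micron of cell perimeter, per channel) that makes
#' log-phase cells look "interconnected" at low MNM.
#'
#' Magnitudes are synthetic choices, not measured values: log-phase
#' presets use more and larger cell-surface clusters than stationary
#' ones, and `stationary_bound` shifts cluster mass into the contact
#' zone.
#'
#' @param preset One of the four condition presets.
#' @export
preset_params <- function(preset = .SCENE_PRESETS) {
  preset <- match.arg(preset)
  cls <- function(n_mean, size_mean, size_sdlog = 0.3, dispersion = 40,
                  count_dist = "poisson")
    list(n_mean = n_mean, size_meanlog = log(size_mean),
         size_sdlog = size_sdlog, dispersion = dispersion,
         count_dist = count_dist)
  switch(preset,
    log_bound = list(
      cell = cls(8, 80), particle = cls(3, 30), contact = cls(2, 50),
      surface_bg_per_um = 30),
    log_detached = list(
      cell = cls(8, 80), surface_bg_per_um = 30),
    stationary_bound = list(
      cell = cls(3, 25), particle = cls(4, 40), contact = cls(5, 70),
      surface_bg_per_um = 8),
    stationary_detached = list(
      cell = cls(3, 20), surface_bg_per_um = 6))
}

# width of the perimeter band that holds surface-attached clusters (nm)
.SURFACE_BAND <- 100

#' Plant ground-truth clusters on scene surfaces
#'
#' Draws cluster counts and sizes from the preset's distributions and
#' places centers on their surface class: the cell perimeter band, the
#' particle surface, or uniformly inside a contact zone.
#'
#' @param geometry A [scene_geometry()].
#' @param preset Condition preset (controls which classes exist).
#' @param params Per-class distributions, see [preset_params()].
#' @param seed Integer seed; same seed, same output.
#' @return `data.frame` with `cluster_id`, `class`, `cx`, `cy`,
#'   `dispersion`, `n_cipa`.
#' @export
plant_clusters <- function(geometry, preset = .SCENE_PRESETS,
                           params = preset_params(preset), seed = 1L) {
  preset <- match.arg(preset)
  stopifnot(inherits(geometry, "scene_geometry"))
  want <- intersect(c("cell", "particle", "contact"), names(params))
  if ("cell" %in% want && length(geometry$cells) == 0)
    stop("preset plants cell-surface clusters but geometry has no cells",
         call. = FALSE)
  if ("particle" %in% want && length(geometry$particles) == 0)
    stop("preset '", preset,
         "' plants particle clusters but geometry has no particles",
         call. = FALSE)
  if ("contact" %in% want && length(geometry$contact_zones) == 0)
    stop("preset '", preset,
         "' plants contact-zone clusters but geometry has no contact zones",
         call. = FALSE)
  withr::with_seed(seed, {
    rows <- list()
    for (class in want) {
      p <- params[[class]]
      k <- if (identical(p$count_dist, "fixed")) as.integer(round(p$n_mean))
           else stats::rpois(1, p$n_mean)
      if (k == 0) next
      sizes <- pmax(1L, as.integer(round(
        stats::rlnorm(k, p$size_meanlog, p$size_sdlog))))
      centers <- switch(class,
        cell = {
          which_cell <- sample.int(length(geometry$cells), k, replace = TRUE)
          t(vapply(seq_len(k), function(i) {
            cell <- geometry$cells[[which_cell[i]]]
            s <- stats::runif(1, 0, .capsule_perimeter(cell))
            base <- .capsule_perimeter_point(cell, s)[1, ]
            # radial jitter within the surface band
            mid <- 0.5 * (cell$p1 + cell$p2)
            dirv <- base - mid
            dirv <- dirv / max(sqrt(sum(dirv^2)), 1e-9)
            base + stats::runif(1, -.SURFACE_BAND / 2, .SURFACE_BAND / 2) * dirv
          }, numeric(2)))
        },
        particle = {
          which_p <- sample.int(length(geometry$particles), k, replace = TRUE)
          t(vapply(seq_len(k), function(i)
            .sample_on_polygon_boundary(1, geometry$particles[[which_p[i]]],
                                        .SURFACE_BAND)[1, ],
            numeric(2)))
        },
        contact = {
          which_z <- sample.int(length(geometry$contact_zones), k,
                                replace = TRUE)
          t(vapply(seq_len(k), function(i)
            .sample_in_polygon(1, geometry$contact_zones[[which_z[i]]])[1, ],
            numeric(2)))
        })
      rows[[class]] <- data.frame(class = class, cx = centers[, 1],
                                  cy = centers[, 2],
                                  dispersion = p$dispersion,
                                  n_cipa = sizes)
    }
    out <- if (length(rows) > 0) do.call(rbind, rows) else
      data.frame(class = character(), cx = numeric(), cy = numeric(),
                 dispersion = numeric(), n_cipa = integer())
    rownames(out) <- NULL
    cbind(cluster_id = seq_len(nrow(out)), out)
  })
}

# localization count per emitter: 1 + Geometric, mean = m
.rblink <- function(n, mean) {
  if (n == 0) return(integer(0))
  1L + stats::rgeom(n, prob = 1 / mean)
}

# expand emitters (true positions) into localizations for one channel
.emit_localizations <- function(ex, ey, cluster_id, origin, model,
                                field_extent, n_frames) {
  n_em <- length(ex)
  nloc <- .rblink(n_em, model$mean_localizations)
  idx <- rep.int(seq_len(n_em), nloc)
  total <- length(idx)
  x <- ex[idx] + stats::rnorm(total, 0, model$precision_sigma)
  y <- ey[idx] + stats::rnorm(total, 0, model$precision_sigma)
  x <- pmin(pmax(x, 0), field_extent[1])
  y <- pmin(pmax(y, 0), field_extent[2])
  data.frame(x = x, y = y,
             frame = sample.int(n_frames, total, replace = TRUE),
             uncertainty = stats::rgamma(total, shape = 25,
                                         rate = 25 / model$precision_sigma),
             emitter_id = idx,
             true_x = ex[idx], true_y = ey[idx],
             cluster_id = cluster_id[idx],
             origin = if (n_em > 0) origin[idx] else character(0))
}

#' Render planted clusters into two localization tables
#'
#' Applies the labeling stoichiometry (per CipA: a channel-A emitter
#' with probability `label_eff_A`; per unoccupied type I cohesin,
#' Binomial(`cipA_cohesins`, `1 - occupancy_prob`), a channel-B emitter
#' with probability `label_eff_B`), blinking, localization error,
#' diffuse cell-surface labeling and the uniform field background.
#'
#' @param clusters Planted clusters from [plant_clusters()].
#' @param stoich A [cellulosome_stoichiometry()].
#' @param model An [emitter_model()].
#' @param geometry A [scene_geometry()] (field extent, cells for the
#'   surface background); `NULL` means a field inferred from the
#'   clusters and no surface background.
#' @param surface_bg_per_um Diffuse cell-surface emitters per micron of
#'   cell perimeter, per channel.
#' @param n_frames Frames available for the synthetic `frame` column.
#' @param seed Integer seed.
#' @return List with `A_af647` and `B_pagfp` [loc_table()]s and a
#'   per-localization `truth` data.frame (`channel`, `row`,
#'   `emitter_id`, `true_x`, `true_y`, `cluster_id` (NA for background),
#'   `origin`).
#' @export
render_localizations <- function(clusters,
                                 stoich = cellulosome_stoichiometry(),
                                 model = emitter_model(),
                                 geometry = NULL,
                                 surface_bg_per_um = 0,
                                 n_frames = 15000L, seed = 1L) {
  stopifnot(inherits(stoich, "cellulosome_stoichiometry"),
            inherits(model, "emitter_model"))
  if (!is.null(geometry)) stopifnot(inherits(geometry, "scene_geometry"))
  field_extent <- if (!is.null(geometry)) geometry$field_extent else {
    if (nrow(clusters) > 0)
      c(max(clusters$cx) + 500, max(clusters$cy) + 500) else c(1000, 1000)
  }
  withr::with_seed(seed, {
    # --- true emitter positions per channel -------------------------------
    k <- nrow(clusters)
    em <- list(A = list(), B = list())
    for (i in seq_len(k)) {
      ni <- clusters$n_cipa[i]
      px <- stats::rnorm(ni, clusters$cx[i], clusters$dispersion[i])
      py <- stats::rnorm(ni, clusters$cy[i], clusters$dispersion[i])
      px <- pmin(pmax(px, 0), field_extent[1])
      py <- pmin(pmax(py, 0), field_extent[2])
      has_a <- stats::runif(ni) < stoich$label_eff_A
      unocc <- stats::rbinom(ni, stoich$cipA_cohesins,
                             1 - stoich$occupancy_prob)
      n_b <- stats::rbinom(ni, unocc, stoich$label_eff_B)
      em$A[[length(em$A) + 1L]] <-
        data.frame(x = px[has_a], y = py[has_a],
                   cluster_id = rep.int(clusters$cluster_id[i], sum(has_a)))
      bi <- rep.int(seq_len(ni), n_b)
      em$B[[length(em$B) + 1L]] <-
        data.frame(x = px[bi], y = py[bi],
                   cluster_id = rep.int(clusters$cluster_id[i], length(bi)))
    }
    # --- diffuse cell-surface background (both channels) -------------------
    surf <- list(A = NULL, B = NULL)
    if (surface_bg_per_um > 0 && !is.null(geometry) &&
        length(geometry$cells) > 0) {
      for (ch in c("A", "B")) {
        pts <- list()
        for (cell in geometry$cells) {
          per_um <- .capsule_perimeter(cell) / 1000
          m <- stats::rpois(1, surface_bg_per_um * per_um)
          if (m == 0) next
          s <- stats::runif(m, 0, .capsule_perimeter(cell))
          base <- .capsule_perimeter_point(cell, s)
          mid <- 0.5 * (cell$p1 + cell$p2)
          dirx <- base[, 1] - mid[1]; diry <- base[, 2] - mid[2]
          nrm <- pmax(sqrt(dirx^2 + diry^2), 1e-9)
          d <- stats::runif(m, -.SURFACE_BAND / 2, .SURFACE_BAND / 2)
          pts[[length(pts) + 1L]] <-
            cbind(pmin(pmax(base[, 1] + d * dirx / nrm, 0), field_extent[1]),
                  pmin(pmax(base[, 2] + d * diry / nrm, 0), field_extent[2]))
        }
        if (length(pts) > 0) surf[[ch]] <- do.call(rbind, pts)
      }
    }
    # --- assemble channels -------------------------------------------------
    build_channel <- function(cluster_em, surf_xy, channel) {
      cl <- if (length(cluster_em) > 0) do.call(rbind, cluster_em) else
        data.frame(x = numeric(), y = numeric(), cluster_id = integer())
      parts <- list(
        .emit_localizations(cl$x, cl$y, cl$cluster_id,
                            rep("cluster", nrow(cl)), model,
                            field_extent, n_frames))
      if (!is.null(surf_xy) && nrow(surf_xy) > 0)
        parts[[2L]] <- .emit_localizations(
          surf_xy[, 1], surf_xy[, 2], rep(NA_integer_, nrow(surf_xy)),
          rep("cell_surface", nrow(surf_xy)), model, field_extent, n_frames)
      # uniform field background: one localization per event, uncertainty
      # drawn like real ones
      area_um2 <- prod(field_extent) / 1e6
      nbg <- stats::rpois(1, model$background_density * area_um2)
      if (nbg > 0) {
        bx <- stats::runif(nbg, 0, field_extent[1])
        by <- stats::runif(nbg, 0, field_extent[2])
        parts[[length(parts) + 1L]] <- data.frame(
          x = bx, y = by,
          frame = sample.int(n_frames, nbg, replace = TRUE),
          uncertainty = stats::rgamma(nbg, shape = 25,
                                      rate = 25 / model$precision_sigma),
          emitter_id = NA_integer_, true_x = bx, true_y = by,
          cluster_id = NA_integer_, origin = "field_bg")
      }
      all <- do.call(rbind, parts)
      tab <- loc_table(all$x, all$y, all$frame, all$uncertainty,
                       channel = channel, field_extent = field_extent,
                       provenance = "synthetic")
      truth <- data.frame(channel = rep(channel, nrow(all)),
                          row = seq_len(nrow(all)),
                          emitter_id = all$emitter_id,
                          true_x = all$true_x, true_y = all$true_y,
                          cluster_id = all$cluster_id, origin = all$origin)
      list(table = tab, truth = truth)
    }
    a <- build_channel(em$A, surf$A, "A_af647")
    b <- build_channel(em$B, surf$B, "B_pagfp")
    list(A_af647 = a$table, B_pagfp = b$table,
         truth = rbind(a$truth, b$truth))
  })
}

#' Simulate a full synthetic scene for a condition preset
#'
#' @param preset `log_bound`, `stationary_bound`, `log_detached` or
#'   `stationary_detached` (growth phase x substrate attachment).
#' @param seed Integer master seed; planting and rendering use seeds
#'   derived from it, so the same `(preset, seed)` reproduces the scene
#'   exactly.
#' @param geometry,params,stoich,model Overrides for the preset
#'   defaults.
#' @param n_frames Frames for the synthetic `frame` column.
#' @return An `smlm_scene`: geometry, planted `clusters`, per-channel
#'   `tables`, per-localization `truth`, preset and seed.
#' @export
simulate_scene <- function(preset = .SCENE_PRESETS, seed = 1L,
                           geometry = NULL, params = NULL,
                           stoich = cellulosome_stoichiometry(),
                           model = emitter_model(), n_frames = 15000L) {
  preset <- match.arg(preset)
  seed <- as.integer(seed)
  if (is.null(geometry)) geometry <- default_scene_geometry(preset)
  if (is.null(params)) params <- preset_params(preset)
  clusters <- plant_clusters(geometry, preset, params,
                             seed = .derive_seed(seed, 1L))
  rendered <- render_localizations(
    clusters, stoich = stoich, model = model, geometry = geometry,
    surface_bg_per_um = params$surface_bg_per_um %||% 0,
    n_frames = n_frames, seed = .derive_seed(seed, 2L))
  structure(list(geometry = geometry, preset = preset, seed = seed,
                 params = params, stoich = stoich, model = model,
                 clusters = clusters,
                 tables = rendered[c("A_af647", "B_pagfp")],
                 truth = rendered$truth),
            class = "smlm_scene")
}

#' @export
print.smlm_scene <- function(x, ...) {
  cat(sprintf(
    "<smlm_scene> preset %s, seed %d: %d planted clusters, %d + %d localizations\n",
    x$preset, x$seed, nrow(x$clusters),
    nrow(x$tables$A_af647), nrow(x$tables$B_pagfp)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stream-split a master seed into independent 31-bit stage seeds
.derive_seed <- function(seed, k) {
  as.integer((as.double(seed %% 2147483647L) * 48271 + 7919 * k) %%
               2147483647)
}

#' Score a clustering against a scene's ground truth
#'
#' A planted cluster counts as *matched* when more than half of its
#' localizations carry one and the same detected cluster id.  Planted
#' clusters that produced no localizations in the requested channel are
#' excluded from the denominator.
#'
#' @param labeling A `cluster_labeling` of the scene's table for
#'   `channel`.
#' @param scene An `smlm_scene`.
#' @param channel `"A_af647"` or `"B_pagfp"`.
#' @return List: `n_detected`, `n_planted`, `frac_matched`,
#'   `frac_background_noise` (fraction of background localizations,
#'   field and cell-surface, labeled noise).
#' @export
evaluate_recovery <- function(labeling, scene, channel = "A_af647") {
  stopifnot(inherits(labeling, "cluster_labeling"),
            inherits(scene, "smlm_scene"))
  if (!channel %in% names(scene$tables))
    stop("channel not present in scene: ", channel, call. = FALSE)
  truth <- scene$truth[scene$truth$channel == channel, , drop = FALSE]
  if (nrow(truth) != length(labeling$labels))
    stop("labeling does not index the scene's ", channel, " table",
         call. = FALSE)
  labels <- labeling$labels[truth$row]
  planted <- unique(truth$cluster_id[!is.na(truth$cluster_id)])
  matched <- vapply(planted, function(p) {
    lp <- labels[!is.na(truth$cluster_id) & truth$cluster_id == p]
    lp_cl <- lp[lp >= 0]
    length(lp_cl) > 0 && max(tabulate(lp_cl + 1L)) > 0.5 * length(lp)
  }, logical(1))
  bg <- is.na(truth$cluster_id)
  list(n_detected = labeling$n_clusters,
       n_planted = length(planted),
       frac_matched = if (length(planted) > 0) mean(matched) else 1,
       frac_background_noise = if (any(bg)) mean(labels[bg] == -1L) else 1)
}
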