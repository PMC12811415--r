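test_that("enzyme capacity is the product of valency and cohesin count", {
  expect_identical(max_enzyme_capacity(cellulosome_stoichiometry(9, 7)), 63L)
  expect_identical(max_enzyme_capacity(cellulosome_stoichiometry(9, 1)), 9L)
  expect_identical(max_enzyme_capacity(cellulosome_stoichiometry(9, 0)), 0L)
  # multiplicative and symmetric in the two counts
  for (ab in list(c(2, 5), c(4, 4), c(11, 3))) {
    expect_identical(
      max_enzyme_capacity(cellulosome_stoichiometry(ab[1], ab[2])),
      max_enzyme_capacity(cellulosome_stoichiometry(ab[2], ab[1])))
    expect_identical(
      max_enzyme_capacity(cellulosome_stoichiometry(ab[1], ab[2])),
      as.integer(ab[1] * ab[2]))
  }
  expect_error(cellulosome_stoichiometry(occupancy_prob = 1.2), "\\[0, 1\\]")
})

test_that("scene geometry validates containment and contact zones", {
  expect_error(
    scene_geometry(c(1000, 1000),
                   cells = list(list(p1 = c(100, 500), p2 = c(950, 500),
                                     radius = 200))),
    "outside")
  # contact zone not touching any particle
  expect_error(
    scene_geometry(c(6000, 6000),
                   cells = list(list(p1 = c(1000, 3000), p2 = c(3000, 3000),
                                     radius = 300)),
                   particles = list(rbind(c(5000, 5000), c(5800, 5000),
                                          c(5400, 5800))),
                   contact_zones = list(rbind(c(3200, 2800), c(3600, 2800),
                                              c(3600, 3200), c(3200, 3200)))),
    "contact zone")
  for (preset in c("log_bound", "stationary_bound", "log_detached",
                   "stationary_detached"))
    expect_s3_class(default_scene_geometry(preset), "scene_geometry")
})

test_that("plant_clusters is deterministic and respects surface classes", {
  geom <- default_scene_geometry("log_bound")
  a <- plant_clusters(geom, "log_bound", seed = 42)
  b <- plant_clusters(geom, "log_bound", seed = 42)
  expect_identical(a, b)
  expect_false(identical(a, plant_clusters(geom, "log_bound", seed = 43)))

  # bound preset without particles -> configuration error
  geom_np <- default_scene_geometry("log_detached")
  expect_error(plant_clusters(geom_np, "log_bound", seed = 1),
               "no particles")

  # zero-count request -> empty list
  p0 <- preset_params("log_detached")
  p0$cell$n_mean <- 0; p0$cell$count_dist <- "fixed"
  expect_equal(nrow(plant_clusters(geom_np, "log_detached", p0, seed = 1)),
               0L)

  # fixed count k -> exactly k clusters, each on its surface class
  pk <- preset_params("log_bound")
  for (cls in c("cell", "particle", "contact")) {
    pk[[cls]]$count_dist <- "fixed"
    pk[[cls]]$n_mean <- 4
  }
  planted <- plant_clusters(geom, "log_bound", pk, seed = 5)
  expect_equal(nrow(planted), 12L)
  expect_equal(as.vector(table(planted$class)[c("cell", "contact",
                                                "particle")]),
               c(4L, 4L, 4L))
  cell <- geom$cells[[1]]
  for (i in seq_len(nrow(planted))) {
    x <- planted$cx[i]; y <- planted$cy[i]
    ok <- switch(planted$class[i],
      cell = abs(dist_seg_oracle(x, y, cell$p1, cell$p2) -
                   cell$radius) <= 51,
      particle = dist_polygon_oracle(x, y, geom$particles[[1]]) <= 101,
      contact = ray_cast_oracle(x, y, geom$contact_zones[[1]]))
    expect_true(ok, label = sprintf("cluster %d on class %s", i,
                                    planted$class[i]))
  }
})

test_that("render_localizations obeys its counting contracts", {
  # no clusters, no background -> both channels empty
  empty <- data.frame(cluster_id = integer(), class = character(),
                      cx = numeric(), cy = numeric(),
                      dispersion = numeric(), n_cipa = integer())
  out <- render_localizations(
    empty, model = emitter_model(background_density = 0), seed = 1)
  expect_equal(nrow(out$A_af647), 0L)
  expect_equal(nrow(out$B_pagfp), 0L)

  # full occupancy -> channel B carries only background
  one <- data.frame(cluster_id = 1L, class = "cell", cx = 500, cy = 500,
                    dispersion = 30, n_cipa = 50L)
  out2 <- render_localizations(
    one, stoich = cellulosome_stoichiometry(occupancy_prob = 1),
    model = emitter_model(background_density = 0), seed = 2)
  expect_equal(nrow(out2$B_pagfp), 0L)
  expect_gt(nrow(out2$A_af647), 0L)

  # degenerate blinking (N = 1), perfect labeling, vanishing error:
  # channel-A localization count equals total planted CipA count
  out3 <- render_localizations(
    one, stoich = cellulosome_stoichiometry(label_eff_A = 1),
    model = emitter_model(mean_localizations = 1, precision_sigma = 1e-9,
                          background_density = 0),
    seed = 3)
  expect_equal(nrow(out3$A_af647), 50L)
  expect_equal(out3$A_af647$x, out3$truth$true_x[out3$truth$channel ==
                                                   "A_af647"],
               tolerance = 1e-6)
})

test_that("emitter counts match stoichiometry expectations over seeds", {
  # expected channel-A emitters per cluster = n_cipa * label_eff_A;
  # expected unoccupied cohesins per CipA = cohesins * (1 - occupancy)
  stoich <- cellulosome_stoichiometry(cipA_cohesins = 9,
                                      occupancy_prob = 0.6,
                                      label_eff_A = 0.7, label_eff_B = 1)
  one <- data.frame(cluster_id = 1L, class = "cell", cx = 500, cy = 500,
                    dispersion = 30, n_cipa = 40L)
  model <- emitter_model(mean_localizations = 1, precision_sigma = 1e-9,
                         background_density = 0)
  n_a <- n_b <- numeric(200)
  for (s in 1:200) {
    out <- render_localizations(one, stoich, model, seed = s)
    n_a[s] <- nrow(out$A_af647)   # one localization per emitter
    n_b[s] <- nrow(out$B_pagfp)
  }
  exp_a <- 40 * 0.7
  se_a <- sqrt(40 * 0.7 * 0.3) / sqrt(200)
  expect_lt(abs(mean(n_a) - exp_a), 3 * se_a)
  exp_b <- 40 * 9 * 0.4          # label_eff_B = 1
  se_b <- sqrt(40 * 9 * 0.4 * 0.6) / sqrt(200)
  expect_lt(abs(mean(n_b) - exp_b), 3 * se_b)
})

test_that("scenes are reproducible bit for bit from (preset, seed)", {
  for (preset in c("log_bound", "stationary_detached")) {
    s1 <- simulate_scene(preset, seed = 17)
    s2 <- simulate_scene(preset, seed = 17)
    expect_identical(as.data.frame(s1$tables$A_af647),
                     as.data.frame(s2$tables$A_af647))
    expect_identical(as.data.frame(s1$tables$B_pagfp),
                     as.data.frame(s2$tables$B_pagfp))
    expect_identical(s1$clusters, s2$clusters)
    s3 <- simulate_scene(preset, seed = 18)
    expect_false(identical(as.data.frame(s1$tables$A_af647),
                           as.data.frame(s3$tables$A_af647)))
  }
})

test_that("evaluate_recovery agrees with an exhaustive overlap oracle", {
  rend <- make_separated_scene_xy(4, seed = 9)
  scene <- structure(list(tables = rend[c("A_af647", "B_pagfp")],
                          truth = rend$truth, preset = "log_detached",
                          seed = 9L),
                     class = "smlm_scene")
  lab <- dbscan_cluster(scene$tables$A_af647, eps = 75, mnm = 10)
  rep <- evaluate_recovery(lab, scene, "A_af647")
  # exhaustive planted x detected contingency matrix
  truth <- scene$truth[scene$truth$channel == "A_af647", ]
  labels <- lab$labels[truth$row]
  planted <- sort(unique(truth$cluster_id[!is.na(truth$cluster_id)]))
  matched <- vapply(planted, function(p) {
    sel <- !is.na(truth$cluster_id) & truth$cluster_id == p
    tab <- table(factor(labels[sel], levels = c(-1, 0:max(0, labels))))
    best <- max(tab[names(tab) != "-1"])
    best > 0.5 * sum(sel)
  }, logical(1))
  expect_equal(rep$frac_matched, mean(matched))
  expect_equal(rep$n_planted, length(planted))
  expect_true(rep$frac_background_noise >= 0 &&
                rep$frac_background_noise <= 1)

  # ground-truth labeling scores perfectly
  ids <- truth$cluster_id
  gt <- structure(list(
    labels = ifelse(is.na(ids), -1L, as.integer(ids) - 1L),
    roles = ifelse(is.na(ids), "noise", "core"),
    params = cluster_params(75, 10),
    n_clusters = length(planted)), class = "cluster_labeling")
  rep_gt <- evaluate_recovery(gt, scene, "A_af647")
  expect_equal(rep_gt$frac_matched, 1)
  expect_equal(rep_gt$frac_background_noise, 1)

  # all-noise labeling: nothing matched, all background flagged noise
  allnoise <- structure(list(
    labels = rep(-1L, length(ids)),
    roles = rep("noise", length(ids)),
    params = cluster_params(75, 10), n_clusters = 0L),
    class = "cluster_labeling")
  rep_n <- evaluate_recovery(allnoise, scene, "A_af647")
  expect_equal(rep_n$frac_matched, 0)
  expect_equal(rep_n$frac_background_noise, 1)

  expect_error(evaluate_recovery(lab, scene, "C_nope"), "channel")
})
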