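test_that("region_query matches the brute-force distance scan", {
  set.seed(21)
  xy <- matrix(runif(400, 0, 1000), ncol = 2)
  for (center in sample.int(200, 25))
    expect_identical(region_query(xy, center, 75),
                     bf_region_query(xy, center, 75))
  # single point: neighbourhood is itself
  expect_identical(region_query(matrix(c(5, 5), 1), 1, 10), 1L)
  # inclusive boundary at exactly eps
  two <- rbind(c(0, 0), c(75, 0))
  expect_identical(region_query(two, 1, 75), c(1L, 2L))
  expect_identical(region_query(two, 2, 75), c(1L, 2L))
})

test_that("dbscan handles degenerate inputs per contract", {
  # single point below mnm -> noise
  lab <- dbscan_cluster(matrix(c(1, 1), 1), eps = 50, mnm = 2)
  expect_identical(lab$labels, -1L)
  expect_identical(lab$roles, "noise")
  # empty input -> empty labeling, no error
  lab0 <- dbscan_cluster(matrix(numeric(), ncol = 2), eps = 50, mnm = 2)
  expect_identical(lab0$n_clusters, 0L)
  expect_length(lab0$labels, 0)
  # NaN coordinates rejected
  expect_error(dbscan_cluster(rbind(c(1, NaN)), eps = 50, mnm = 1),
               "finite")
  # fully connected neighbourhood graph -> one cluster, no noise
  set.seed(4)
  xy <- matrix(runif(40, 0, 50), ncol = 2)
  lab1 <- dbscan_cluster(xy, eps = 100, mnm = 10)
  expect_identical(lab1$n_clusters, 1L)
  expect_true(all(lab1$labels == 0L))
  expect_true(all(lab1$roles == "core"))
})

test_that("dbscan matches the O(n^2) reference on random instances", {
  set.seed(31)
  for (rep in 1:25) {
    n <- sample(30:250, 1)
    # a mix of uniform points and tight blobs over a ~1.5 um field
    k <- sample(0:3, 1)
    xy <- matrix(runif(2 * n, 0, 1500), ncol = 2)
    if (k > 0)
      for (i in seq_len(k))
        xy <- rbind(xy, make_blob(sample(10:40, 1),
                                  runif(1, 100, 1400),
                                  runif(1, 100, 1400), sd = 25))
    eps <- sample(c(25, 50, 75, 100, 150, 200), 1)
    mnm <- sample(2:50, 1)
    got <- dbscan_cluster(xy, eps = eps, mnm = mnm)
    ref <- bf_dbscan(xy, eps, mnm)
    core_got <- got$roles == "core"
    expect_identical(core_got, unname(ref$core))
    expect_identical(got$n_clusters, ref$n_clusters)
    expect_true(same_partition(got$labels, ref$labels, which(core_got)))
  }
})

test_that("labeling invariants hold on random instances", {
  set.seed(41)
  for (rep in 1:10) {
    xy <- rbind(matrix(runif(200, 0, 1000), ncol = 2),
                make_blob(60, 300, 300, 20),
                make_blob(60, 700, 700, 20))
    eps <- 75; mnm <- sample(3:20, 1)
    lab <- dbscan_cluster(xy, eps = eps, mnm = mnm)
    # noise <-> label -1
    expect_identical(lab$roles == "noise", lab$labels == -1L)
    D <- as.matrix(dist(xy))
    deg <- rowSums(D <= eps)
    # every core point has >= mnm neighbours (self included)
    expect_true(all(deg[lab$roles == "core"] >= mnm))
    expect_true(all(deg[lab$roles != "core"] < mnm))
    for (cid in seq_len(lab$n_clusters) - 1L) {
      members <- which(lab$labels == cid)
      core_m <- members[lab$roles[members] == "core"]
      expect_gt(length(core_m), 0)
      # border points sit within eps of a core point of their cluster
      for (b in members[lab$roles[members] == "border"])
        expect_true(min(D[b, core_m]) <= eps)
    }
  }
})

test_that("core sets shrink and noise grows as mnm increases", {
  set.seed(51)
  xy <- rbind(make_blob(150, 400, 400, 40), make_blob(80, 900, 900, 30),
              matrix(runif(100, 0, 1200), ncol = 2))
  prev_core <- NULL
  prev <- NULL
  for (mnm in c(2, 5, 10, 20, 40, 80, 150)) {
    lab <- dbscan_cluster(xy, eps = 75, mnm = mnm)
    core <- which(lab$roles == "core")
    clustered <- sum(lab$labels >= 0)
    noise <- sum(lab$labels == -1L)
    if (!is.null(prev)) {
      expect_true(all(core %in% prev_core))  # subset relation
      expect_lte(clustered, prev["clustered"])
      expect_gte(noise, prev["noise"])
    }
    prev_core <- core
    prev <- c(clustered = clustered, noise = noise)
  }
})

test_that("core partition is invariant under input reordering", {
  set.seed(61)
  xy <- rbind(make_blob(50, 200, 200, 25), make_blob(50, 700, 300, 25),
              matrix(runif(60, 0, 900), ncol = 2))
  lab <- dbscan_cluster(xy, eps = 75, mnm = 5)
  for (rep in 1:3) {
    perm <- sample.int(nrow(xy))
    lab_p <- dbscan_cluster(xy[perm, ], eps = 75, mnm = 5)
    # roles are order-independent; partition of core points matches
    expect_identical(lab_p$roles, lab$roles[perm])
    core_idx <- which(lab$roles[perm] == "core")
    expect_true(same_partition(lab_p$labels, lab$labels[perm], core_idx))
  }
})

test_that("mnm = 1 reduces to eps-graph connected components", {
  set.seed(71)
  for (rep in 1:5) {
    xy <- matrix(runif(2 * sample(30:80, 1), 0, 600), ncol = 2)
    lab <- dbscan_cluster(xy, eps = 60, mnm = 1)
    expect_identical(lab$n_clusters, uf_components(xy, 60))
    expect_true(all(lab$labels >= 0))  # no noise at mnm = 1
  }
})

test_that("eps-disc geometry and local density are exact", {
  expect_equal(eps_disc_area(75), pi * 75^2 / 1e6)
  expect_equal(signif(eps_disc_area(75), 2), 0.018)
  expect_identical(eps_disc_area(0), 0)
  expect_equal(eps_disc_area(125), pi * 125^2 / 1e6)  # 0.04908739 um^2
  expect_error(eps_disc_area(-1), ">= 0")

  expect_identical(local_density(0, 75), 0)
  expect_equal(local_density(40, 75), 40 / (pi * 75^2 / 1e6))
  expect_equal(local_density(80, 75), 2 * local_density(40, 75))
  expect_error(local_density(1, 0), "> 0")
})

test_that("labeling exports as a flat table", {
  set.seed(81)
  xy <- rbind(make_blob(30, 100, 100, 15), matrix(runif(20, 0, 600), ncol = 2))
  lab <- dbscan_cluster(xy, eps = 75, mnm = 5)
  tab <- labeling_table(lab, xy)
  expect_named(tab, c("index", "x", "y", "cluster", "role"))
  expect_equal(tab$cluster, lab$labels)
  expect_error(labeling_table(lab, xy[-1, ]), "disagree")
})
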