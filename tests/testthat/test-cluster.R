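test_that("superposed RMSD removes rigid motions and is symmetric", {
  set.seed(1)
  x <- matrix(rnorm(30), 10, 3)
  expect_equal(superpose_rmsd(x, x), 0, tolerance = 1e-12)
  shifted <- sweep(x, 2, c(0, 0, 5), "+")
  expect_lt(superpose_rmsd(x, shifted), 1e-10)
  th <- 0.7
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, byrow = TRUE)
  expect_lt(superpose_rmsd(x, x %*% rot), 1e-6)
  y <- x + matrix(rnorm(30, sd = 0.3), 10, 3)
  expect_equal(superpose_rmsd(x, y), superpose_rmsd(y, x), tolerance = 1e-12)
  expect_error(superpose_rmsd(x, x[1:5, ]), "mismatched")
})

test_that("superposed RMSD matches a brute-force rotational search on 4-point toys", {
  set.seed(2)
  for (i in 1:5) {
    a <- matrix(rnorm(12), 4, 3)
    b <- a
    b[1, ] <- b[1, ] + c(0.5, 0, 0)    # displace one point by half a unit
    b <- b %*% qr.Q(qr(matrix(rnorm(9), 3))) + rep(rnorm(3), each = 4)
    impl <- superpose_rmsd(a, b)
    oracle <- oracle_superposed_rmsd(a, b)
    expect_lt(abs(impl - oracle), 1e-3)
    expect_lte(impl, oracle + 1e-9)    # closed form can never be beaten
  }
})

test_that("superposed RMSD agrees with an independent reference implementation", {
  skip_if_not_installed("bio3d")
  set.seed(3)
  for (i in 1:5) {
    a <- matrix(rnorm(36), 12, 3)
    b <- a + matrix(rnorm(36, sd = 0.2), 12, 3)
    ref <- bio3d::rmsd(as.numeric(t(a)), as.numeric(t(b)), fit = TRUE)
    expect_lt(abs(superpose_rmsd(a, b) - ref), 6e-4)  # bio3d prints 3 decimals
  }
})

test_that("degenerate cluster counts behave as forced by the definitions", {
  toy <- toy_basin_coords(c(0, 0.4, 0.9), m = 4, seed = 4)
  m1 <- cluster_frames(toy$coords, 1L)
  expect_identical(m1$k, 1L)
  expect_equal(m1$weights, 1)
  d <- rmsd_matrix(toy$coords)
  expect_identical(m1$representatives, which.min(rowSums(d)))
  # k = n: every frame its own cluster; Eq-5 estimate equals the plain mean
  mn <- cluster_frames(toy$coords, 12L)
  vals <- rnorm(12)
  expect_equal(weighted_estimate(mn, vals), mean(vals), tolerance = 1e-12)
  expect_error(cluster_frames(toy$coords, 13L), "k must be")
})

test_that("cluster-weighted estimates follow hand arithmetic", {
  toy <- toy_basin_coords(c(0, 0.5, 1.1), m = 4, seed = 5)
  m <- cluster_frames(toy$coords, 3L)
  # constant property: weights are irrelevant
  expect_equal(weighted_estimate(m, rep(7.7, 12)), 7.7, tolerance = 1e-12)
  # hand-built weights through cluster sizes 5/3/2
  toy2 <- toy_basin_coords(c(0, 0.5, 1.1), m = 2, seed = 6)
  coords <- toy2$coords[c(rep(1L, 5), rep(3L, 3), rep(5L, 2)), , ]
  vals <- c(rep(10, 5), rep(20, 3), rep(30, 2))
  m2 <- cluster_frames(coords, 3L)
  expect_equal(sort(m2$weights), c(0.2, 0.3, 0.5))
  expect_equal(weighted_estimate(m2, vals), 0.5 * 10 + 0.3 * 20 + 0.2 * 30,
               tolerance = 1e-9)
  bad <- vals; bad[m2$representatives[1]] <- NA
  expect_error(weighted_estimate(m2, bad), "missing property value")
})

test_that("well-separated basins are recovered exactly and weights sum to one", {
  sys <- dna_duplex("GC")
  cfg <- generator_config(n_frames = 60L, basin_displacement = 1.0,
                          coord_noise = 0.1, rise_jitter = 0)
  tr <- sample_trajectory(sys, "neutral", cfg, seed = 8)
  m <- cluster_frames(tr, 3L)
  expect_equal(sum(m$weights), 1, tolerance = 1e-12)
  # labels match the latent basins up to renaming
  tab <- table(m$labels, tr$latent$basin)
  expect_identical(sum(apply(tab, 1, max)), 60L)
  for (c in 1:3) expect_true(m$labels[m$representatives[c]] == c)
  # permuting frames renames labels but preserves the partition
  p <- sample(60)
  mp <- cluster_frames(tr$coords[p, , ], 3L)
  canon <- function(blocks) {
    blocks <- unname(lapply(blocks, function(b) sort(as.integer(b))))
    blocks[order(vapply(blocks, min, integer(1)))]
  }
  expect_identical(canon(split(p, mp$labels)), canon(split(1:60, m$labels)))
})

test_that("agglomerative partitions match exhaustive enumeration on small sets", {
  toy <- toy_basin_coords(c(0, 0.45, 1.0), m = 3, jitter = 0.03, seed = 9)
  d <- rmsd_matrix(toy$coords)   # 9 frames
  for (k in 2:3) {
    m <- cluster_frames(d, k)
    best <- oracle_best_dispersion(d, k)
    expect_lt(abs(m$dispersion - best), 1e-9)
  }
  toy2 <- toy_basin_coords(c(0, 0.6), m = 5, jitter = 0.03, seed = 10)
  d2 <- rmsd_matrix(toy2$coords) # 10 frames
  m2 <- cluster_frames(d2, 2L)
  expect_lt(abs(m2$dispersion - oracle_best_dispersion(d2, 2L)), 1e-9)
})

test_that("convergence scans report exact relative errors and converged k", {
  sys <- dna_duplex("GG")
  cfg <- small_config(n_frames = 60L)
  tn <- sample_trajectory(sys, "neutral", cfg, seed = 12)
  tc <- sample_trajectory(sys, "cation", cfg, seed = 12)
  rep <- convergence_scan(tn, tc, sys, k_grid = 2:6)
  expect_identical(rep$k_grid, 2:6)
  # RUE arithmetic: recompute one entry by hand
  est <- rep$estimates$vie[3]
  expect_equal(rep$rue$vie[3], abs(est - rep$reference["vie"]) /
                 abs(rep$reference["vie"]) * 100,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_true(all(rep$rue[, -1] >= 0, na.rm = TRUE))
  expect_true(all(rep$converged_k %in% 2:6, na.rm = TRUE))
  # constant property: zero RUE everywhere, earliest evaluable convergence
  tn0 <- tn; tn0$energy <- rep(5.5, 60)
  tc0 <- tc; tc0$energy <- rep(4.7, 60)
  rep0 <- convergence_scan(tn0, tc0, sys, k_grid = 2:5)
  expect_equal(unname(rep0$rue$vie), rep(0, 4), tolerance = 1e-12)
  expect_equal(unname(rep0$converged_k["vie"]), 3)  # first point with a predecessor
  expect_equal(unname(rep0$mrue["vie"]), 0, tolerance = 1e-12)
  # a zero reference makes that property's RUE undefined, with a warning
  she0 <- reference_electrode((mean(tn$energy) + mean(tc$energy)) / 2)
  expect_warning(repz <- convergence_scan(tn, tc, sys, k_grid = 2:4,
                                          electrode = she0),
                 "zero")
  expect_true(all(is.na(repz$rue$e_ox)))
})

test_that("converged-window MRUE shrinks as basins separate further", {
  sys <- dna_duplex("GA")
  run <- function(disp) {
    cfg <- generator_config(n_frames = 100L, basin_displacement = disp)
    tn <- sample_trajectory(sys, "neutral", cfg, seed = 14)
    tc <- sample_trajectory(sys, "cation", cfg, seed = 14)
    mean(convergence_scan(tn, tc, sys, k_grid = 2:8)$mrue)
  }
  expect_lte(run(1.2), run(0.25) + 1e-9)
})
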