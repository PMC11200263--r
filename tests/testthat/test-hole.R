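test_that("charge differences map to hole distributions with clamping and renormalization", {
  # already normalized input passes through
  h <- hole_fractions(rep(0, 8), c(0.7, 0.3, rep(0, 6)))
  expect_equal(h$fractions, c(0.7, 0.3, rep(0, 6)), tolerance = 1e-12)
  expect_equal(h$clamped_mass, 0)
  # slightly negative spectator difference is clamped and logged
  h2 <- hole_fractions(rep(0, 8), c(0.72, 0.30, -0.02, rep(0, 5)))
  expect_equal(h2$fractions[1:2], c(0.7058823529, 0.2941176471), tolerance = 1e-9)
  expect_equal(h2$clamped_mass, 0.02, tolerance = 1e-12)
  # leaked charge renormalizes to a simplex
  h3 <- hole_fractions(rep(0, 8), c(0.45, 0.45, rep(0, 6)))
  expect_equal(h3$fractions[1:2], c(0.5, 0.5))
  expect_equal(h3$raw_sum, 0.9, tolerance = 1e-12)
  expect_error(hole_fractions(rep(0, 8), rep(-0.1, 8)), "no hole")
})

test_that("both delocalization numbers hit the localized and uniform endpoints", {
  loc <- c(1, rep(0, 7))
  uni <- rep(1 / 8, 8)
  expect_equal(deloc_n(loc), 1, tolerance = 1e-12)
  expect_equal(deloc_n(uni), 8, tolerance = 1e-12)
  expect_equal(deloc_nprime(loc), 1, tolerance = 1e-12)
  expect_equal(deloc_nprime(uni), 8, tolerance = 1e-12)
  expect_equal(deloc_nprime(c(0.5, 0.5, rep(0, 6))), 2, tolerance = 1e-12)
})

test_that("mid-case fixtures match independently computed values", {
  q <- c(0.6, 0.3, 0.1, rep(0, 5))
  expect_equal(deloc_n(q), 2.4545555959, tolerance = 1e-9)
  expect_equal(deloc_n(q), oracle_effective_number(q), tolerance = 1e-12)
  expect_equal(deloc_nprime(q), 2.1739130435, tolerance = 1e-9)
})

test_that("n' agrees with the loop comparator on 1000 random distributions and never exceeds n", {
  set.seed(42)
  for (i in 1:1000) {
    q <- random_fractions()
    expect_equal(deloc_nprime(q), oracle_participation(q), tolerance = 1e-12)
    expect_lte(deloc_nprime(q), deloc_n(q) + 1e-12)
    expect_gte(deloc_n(q), 1 - 1e-12); expect_lte(deloc_n(q), 8 + 1e-12)
  }
})

test_that("indices are invariant to base order and to uniform rescaling before normalization", {
  set.seed(7)
  for (i in 1:50) {
    q <- random_fractions()
    p <- sample(8)
    expect_equal(deloc_n(q[p]), deloc_n(q), tolerance = 1e-12)
    expect_equal(deloc_nprime(q[p]), deloc_nprime(q), tolerance = 1e-12)
    # rescaled charge differences renormalize to the same distribution
    h <- hole_fractions(rep(0, 8), 0.37 * q)
    expect_equal(h$fractions, q, tolerance = 1e-12)
  }
})

test_that("moving hole mass toward the dominant base never increases either index", {
  set.seed(11)
  for (i in 1:200) {
    q <- random_fractions()
    o <- order(q, decreasing = TRUE)
    hi <- o[1]; lo <- o[8]
    eps <- stats::runif(1, 0, q[lo])
    q2 <- q; q2[hi] <- q2[hi] + eps; q2[lo] <- q2[lo] - eps
    expect_lte(deloc_nprime(q2), deloc_nprime(q) + 1e-12)
    expect_lte(deloc_n(q2), deloc_n(q) + 1e-12)
  }
})

test_that("ensemble summaries carry frozen statistics and the guanine signature", {
  sys <- dna_duplex("ds-poly(GA-CT)")
  tr <- sample_trajectory(sys, "neutral", generator_config(), seed = 5)
  s <- hole_summary(tr, sys)
  expect_equal(sum(s$per_base_percent), 100, tolerance = 0.1)
  expect_identical(s$arrangement, "stacked")
  # the hole concentrates on guanine positions
  gmass <- sum(s$per_base_percent[sys$qm1$base == "G"])
  amass <- sum(s$per_base_percent[sys$qm1$base == "A"])
  pyr <- sum(s$per_base_percent[!sys$qm1$base %in% c("G", "A")])
  expect_gt(gmass, amass)
  expect_gt(amass, pyr)
  expect_gt(max(s$per_base_percent[sys$qm1$base == "G"]),
            max(s$per_base_percent[sys$qm1$base != "G"]))
  # identical frames give zero SD; two-frame mean is the midpoint
  tiny <- tr
  tiny$q_neutral <- tr$q_neutral[c(1, 1), ]; tiny$q_cation <- tr$q_cation[c(1, 1), ]
  tiny$frame_id <- 1:2; tiny$energy <- tr$energy[c(1, 1)]
  s0 <- hole_summary(tiny)
  expect_equal(s0$n_sd, 0)
})

test_that("ensemble n of every preset lies in the ds-DNA plausibility band", {
  cfg <- generator_config()
  for (nm in duplex_presets()) {
    sys <- dna_duplex(nm)
    s <- hole_summary(sample_trajectory(sys, "neutral", cfg, seed = 2), sys)
    expect_gt(s$n_mean, 1.3)
    expect_lt(s$n_mean, 2.5)
    expect_gte(s$nprime_mean, 1)
  }
})
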