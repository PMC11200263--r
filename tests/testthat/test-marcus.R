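test_that("ensemble means and SDs follow hand arithmetic", {
  m <- ensemble_means(c(5, 6), c(4, 5))
  expect_equal(m$mean_vie, 5.5)
  expect_equal(m$sd_vie, 0.7071067812, tolerance = 1e-9)
  m2 <- ensemble_means(rep(5.2, 4), rep(4.4, 4))
  expect_equal(m2$sd_vie, 0)
  expect_equal(m2$mean_vae, 4.4)
})

test_that("the Marcus chain reproduces the worked example", {
  el <- reference_electrode(4.28)
  r <- oxidation_potential(list(mean_vie = 5.40, mean_vae = 4.80,
                                sd_vie = 0, sd_vae = 0), electrode = el)
  expect_equal(r$e_ox, 0.82, tolerance = 1e-12)
  expect_equal(r$lambda_reorg, 0.30, tolerance = 1e-12)
  expect_equal(r$sd_eox, 0)
  # mean gaps equal to the electrode give a vanishing potential
  r0 <- oxidation_potential(list(mean_vie = 4.28, mean_vae = 4.28),
                            electrode = el)
  expect_equal(r0$e_ox, 0, tolerance = 1e-12)
})

test_that("shifting all gaps by +c shifts e_ox by c and leaves lambda alone", {
  set.seed(1)
  vie <- 5.5 + rnorm(50, sd = 0.2)
  vae <- 4.7 + rnorm(50, sd = 0.2)
  a <- marcus_redox(vie, vae)
  b <- marcus_redox(vie + 0.37, vae + 0.37)
  expect_equal(b$e_ox - a$e_ox, 0.37, tolerance = 1e-12)
  expect_equal(b$lambda_reorg, a$lambda_reorg, tolerance = 1e-12)
  # permutation invariance of the record order
  p <- sample(50)
  expect_equal(marcus_redox(vie[p], vae[p])$e_ox, a$e_ox, tolerance = 1e-12)
  # SD propagation treats the trajectories as independent
  expect_equal(a$sd_eox, sqrt(sd(vie)^2 + sd(vae)^2) / 2, tolerance = 1e-12)
})

test_that("estimated e_ox recovers the analytic truth within 4 standard errors", {
  sys <- dna_duplex("GA")
  el <- reference_electrode()
  for (n in c(200L, 5000L)) {
    cfg <- generator_config(n_frames = n)
    tn <- sample_trajectory(sys, "neutral", cfg, seed = 9)
    tc <- sample_trajectory(sys, "cation", cfg, seed = 9)
    est <- marcus_redox(tn, tc, electrode = el, system = sys)
    gt <- ground_truth(sys, cfg, electrode = el)
    se <- sqrt(gt$sd_vie^2 / n + gt$sd_vae^2 / n) / 2
    expect_lt(abs(est$e_ox - gt$e_ox), 4 * se)
  }
})

test_that("degenerate and malformed ensembles are rejected", {
  expect_error(ensemble_means(numeric(0), c(4, 5)), "empty")
  expect_error(ensemble_means(5.0, c(4, 5)), "at least 2")
  expect_error(oxidation_potential(list(mean_vie = NaN, mean_vae = 4.8)), "finite")
  expect_error(oxidation_potential(list(mean_vie = -5.4, mean_vae = 4.8)), "sign")
  sys <- dna_duplex("GA")
  tn <- sample_trajectory(sys, "neutral", small_config())
  expect_error(ensemble_means(tn, tn), "expected a cation")
  expect_warning(oxidation_potential(list(mean_vie = 4.0, mean_vae = 5.0)),
                 "reorganization")
  expect_error(reference_electrode(-1), "positive")
})

test_that("systems rank by oxidation potential with stable ties", {
  mk <- function(e, name) {
    s <- oxidation_potential(list(mean_vie = e + 4.28 + 0.3,
                                  mean_vae = e + 4.28 - 0.3),
                             system = name)
    s
  }
  tab <- compare_systems(list(mk(0.91, "b"), mk(0.73, "a"), mk(0.91, "c")))
  expect_equal(tab$system, c("a", "b", "c"))
  expect_equal(tab$e_ox[1], 0.73, tolerance = 1e-12)
  one <- compare_systems(mk(0.5, "solo"))
  expect_identical(nrow(one), 1L)
})
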