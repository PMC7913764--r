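test_that("mechanism probabilities have the right limits", {
  seg <- list(diameter_cm = 0.2, length_cm = 1, branch_deg = 30, gravity_deg = 0)
  # vanishing particle and residence: deposition vanishes in the joint limit
  p_seq <- vapply(c(1e-6, 1e-9, 1e-12),
                  function(t) deposition_probability_segment(1e-3, seg, 100, t),
                  numeric(1))
  expect_true(all(diff(p_seq) < 0))
  expect_lt(p_seq[3], 1e-4)  # residual is the vanishing impaction term
  # long residence: sedimentation certainty
  expect_equal(prob_sedimentation(2, 1e6, 0.2, 0), 1)
  expect_equal(prob_diffusion(0.5, 1e6, 0.2), 1, tolerance = 1e-6)
  # no bend, no impaction
  expect_equal(prob_impaction(5, 300, 0.2, 0), 0)
  # probabilities bounded
  p <- deposition_probability_segment(10, seg, 5000, 10)
  expect_true(p >= 0 && p <= 1)
})

test_that("extrathoracic curve is zero at zero size and monotone in d^2 Q", {
  expect_equal(extrathoracic_deposition(0, 30), 0)
  d <- seq(0.5, 12, by = 0.5)
  p <- extrathoracic_deposition(d, 30)
  expect_true(all(diff(p) > 0))
  expect_gt(extrathoracic_deposition(10, 30), 10 * extrathoracic_deposition(1, 30) / 20)
  expect_gt(extrathoracic_deposition(10, 30), extrathoracic_deposition(1, 30))
  # disabled filter
  expect_equal(extrathoracic_deposition(10, 30, coef = c(scale = Inf, power = 1)), 0)
})

test_that("airway path sampling is seed-reproducible and respects the medians", {
  geom <- default_airway_geometry()
  p1 <- sample_airway_path(geom, seed = 33)
  p2 <- sample_airway_path(geom, seed = 33)
  expect_identical(p1, p2)

  # zero geometric spread: path equals the median geometry
  g0 <- geom$generations
  g0$gsd <- 1
  g0$branch_max_deg <- g0$branch_min_deg
  g0$gravity_max_deg <- g0$gravity_min_deg
  degen <- airway_geometry(g0, frc_cm3 = geom$frc_cm3)
  pd <- sample_airway_path(degen, seed = 1)
  expect_equal(pd$diameter_cm, g0$diameter_cm, tolerance = 1e-12)
  expect_equal(pd$length_cm, g0$length_cm, tolerance = 1e-12)

  # sampling-distribution oracle: mean sampled diameter ~ lognormal mean
  n <- 4000
  set.seed(8)
  for (j in c(1, 10, 20)) {
    draws <- g0$diameter_cm[j] * geom$generations$gsd[j]^rnorm(n)
    lnsd <- log(geom$generations$gsd[j])
    expected <- g0$diameter_cm[j] * exp(lnsd^2 / 2)
    se <- sd(draws) / sqrt(n)
    expect_lt(abs(mean(draws) - expected), 3 * se + 1e-12)
  }
})

test_that("geometry invariants are enforced", {
  g <- default_airway_geometry()$generations
  g$diameter_cm[3] <- 2  # wider than the trachea
  expect_error(airway_geometry(g), "non-increasing")
  expect_error(airway_geometry(default_airway_geometry()$generations, frc_cm3 = -1), "frc")
})

test_that("generation volumes sum to the FRC", {
  geom <- default_airway_geometry()
  v <- generation_volumes(geom)
  expect_equal(sum(v$total_cm3), geom$frc_cm3)
  expect_true(all(v$alveolar_cm3[geom$generations$region == "bronchial"] == 0))
})

test_that("simulation conserves particles, is deterministic, and tallies lung exactly", {
  r <- simulate_deposition(c(2, 2), breathing_pattern(breath_hold = 5),
                           n_particles = 4000, seed = 11)
  expect_equal(r$extrathoracic + r$lung + r$exhaled, 100)
  expect_equal(r$lung, r$bronchial + r$acinar)
  expect_equal(sum(r$counts), r$n_particles)
  r2 <- simulate_deposition(c(2, 2), breathing_pattern(breath_hold = 5),
                            n_particles = 4000, seed = 11)
  expect_identical(r$counts, r2$counts)
})

test_that("longer breath-hold cannot lose lung deposition; coarser aerosols impact the throat more", {
  for (mmad in c(1.55, 2.33)) {
    r5 <- simulate_deposition(c(mmad, 2), breathing_pattern(breath_hold = 5),
                              n_particles = 4000, seed = 3)
    r10 <- simulate_deposition(c(mmad, 2), breathing_pattern(breath_hold = 10),
                               n_particles = 4000, seed = 3)
    expect_gte(r10$lung, r5$lung)
  }
  rA <- simulate_deposition(c(1, 1.8), breathing_pattern(), n_particles = 4000, seed = 5)
  rB <- simulate_deposition(c(6, 1.8), breathing_pattern(), n_particles = 4000, seed = 5)
  expect_gt(rB$extrathoracic, rA$extrathoracic)
})

test_that("a respirable aerosol deposits more in the acinar than the bronchial region", {
  r <- simulate_deposition(c(2, 2),
                           breathing_pattern(inhaled_volume = 1.7,
                                             inhalation_time = 3.2,
                                             breath_hold = 10),
                           n_particles = 6000, seed = 17)
  expect_gt(r$acinar, r$bronchial)
})

test_that("Monte Carlo matches the analytic single-tube formula within 3 SE", {
  d_t <- 0.1; len <- 10
  tube <- single_tube_geometry(d_t, len, branch_deg = 0, gravity_deg = 0)
  vol <- pi / 4 * d_t^2 * len
  t_res <- 1
  bp <- breathing_pattern(inhaled_volume = vol / 1000, inhalation_time = t_res,
                          breath_hold = 0, exhalation_time = t_res)
  n <- 2e4
  r <- simulate_deposition(c(2, 1), bp, geometry = tube, n_particles = n,
                           seed = 23, et_coef = c(scale = Inf, power = 1))
  q <- vol / t_res
  seg <- list(diameter_cm = d_t, length_cm = len, branch_deg = 0, gravity_deg = 0)
  p1 <- deposition_probability_segment(2, seg, q, t_res)
  expected <- 1 - (1 - p1)^2   # inhalation + exhalation pass
  se <- sqrt(expected * (1 - expected) / n)
  expect_gt(p1, 0.05)  # the configuration actually exercises deposition
  expect_lt(abs(r$lung / 100 - expected), 3 * se)
})

test_that("regional standard errors shrink as n^(-1/2)", {
  r1 <- simulate_deposition(c(2, 2), breathing_pattern(), n_particles = 1000, seed = 2)
  r2 <- simulate_deposition(c(2, 2), breathing_pattern(), n_particles = 100000, seed = 2)
  ratio <- r1$se[["acinar"]] / r2$se[["acinar"]]
  expect_gt(ratio, 6)
  expect_lt(ratio, 16)
})

test_that("APSD input can come straight from an impactor run", {
  fx <- generate_fixture("impactor_run", list(mmad = 1.74, gsd = 2), noise_sd = 0)
  r <- simulate_deposition(fx$data, breathing_pattern(), n_particles = 2000, seed = 4)
  expect_equal(r$mmad, 1.74, tolerance = 0.02)
  expect_equal(r$extrathoracic + r$lung + r$exhaled, 100)
})
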