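zero_stages <- function() setNames(rep(0, 9), names(aci_cutoffs()))

test_that("emitted dose and mass balance", {
  st <- zero_stages()
  run <- make_run(st, device = 300, capsules = 200, loaded = 500)
  expect_equal(emitted_dose(run), 0)

  st["stage3"] <- 120; st["filter"] <- 80
  run2 <- make_run(st, throat = 50, device = 30, capsules = 20)
  expect_equal(emitted_dose(run2), 250)
  # ED + device + capsules == total recovered, exactly
  expect_equal(emitted_dose(run2) + run2$mass_device + run2$mass_capsules,
               50 + 120 + 80 + 30 + 20)
})

test_that("emitted fraction reproduces printed ratios", {
  expect_equal(emitted_fraction(5.98, 8.26), 72.4, tolerance = 1e-3)
  expect_equal(emitted_fraction(4.24, 5.07), 83.6, tolerance = 1e-2)
  expect_equal(emitted_fraction(0, 5), 0)
  expect_error(emitted_fraction(1, 0), "loaded")
})

test_that("cumulative undersize: hand-counted and degenerate cases", {
  st <- zero_stages(); st["filter"] <- 100
  cu <- cumulative_undersize(make_run(st))
  expect_true(all(cu$fraction == 1))

  st2 <- zero_stages(); st2["stage2"] <- 50; st2["stage4"] <- 50
  cu2 <- cumulative_undersize(make_run(st2))
  expect_equal(cu2$fraction[cu2$cutoff_um == 3.3], 0.5)
  expect_equal(cu2$fraction[cu2$cutoff_um == 5.8], 1.0)
  expect_equal(cu2$fraction[cu2$cutoff_um == 9.0], 1.0)
  expect_equal(cu2$fraction[cu2$cutoff_um == 2.1], 0)

  # non-decreasing in diameter, bounded in [0, 1]
  st3 <- lognormal_stage_masses(2.4, 1.9)
  cu3 <- cumulative_undersize(make_run(st3))
  expect_true(all(diff(rev(cu3$fraction)) >= 0))
  expect_true(all(cu3$fraction >= 0 & cu3$fraction <= 1))
  expect_error(cumulative_undersize(make_run(zero_stages(), throat = 10)), "sized mass")
})

test_that("empirical undersize matches the generating lognormal CDF at the cut-offs", {
  st <- lognormal_stage_masses(2.0, 2.0)
  cu <- cumulative_undersize(make_run(st))
  expect_equal(cu$fraction,
               plnorm(cu$cutoff_um, meanlog = log(2), sdlog = log(2)),
               tolerance = 1e-12)
})

test_that("log-probability fit recovers lognormal APSDs across the inhalable range", {
  for (mmad in c(0.8, 1.55, 2.33, 5, 8)) {
    for (gsd in c(1.3, 2, 3)) {
      st <- lognormal_stage_masses(mmad, gsd)
      fit <- fit_mmad_gsd(cumulative_undersize(make_run(st)))
      expect_equal(fit$mmad, mmad, tolerance = 0.02)
      expect_equal(fit$gsd, gsd, tolerance = 0.02)
    }
  }
})

test_that("degenerate distributions are rejected by the fit", {
  # everything below the lowest cut-off: no interior points
  st <- zero_stages(); st["filter"] <- 100
  expect_error(fit_mmad_gsd(cumulative_undersize(make_run(st))), "at least 2")
})

test_that("fine particle dose follows the fitted lognormal CDF at 5 um", {
  st <- lognormal_stage_masses(2, 2, total = 1000)
  run <- make_run(st)
  fit <- fit_mmad_gsd(cumulative_undersize(run))
  expect_equal(fine_particle_dose(run, fit) / 1000,
               pnorm(log(5 / 2) / log(2)), tolerance = 1e-6)
  # everything under 5 um when the aerosol is fine and narrow
  expect_equal(fine_particle_dose(run, list(mmad = 1, gsd = 1.0001)), 1000)
  # median exactly at the threshold: half the sized mass
  expect_equal(fine_particle_dose(run, list(mmad = 5, gsd = 1.5)), 500)
})

test_that("fine particle fraction reproduces printed ratios and scale invariance", {
  expect_equal(fine_particle_fraction(4.52, 5.98), 75.6, tolerance = 1e-3)
  expect_equal(fine_particle_fraction(2.51, 3.40), 73.8, tolerance = 1e-3)
  expect_equal(fine_particle_fraction(0, 4), 0)

  st <- lognormal_stage_masses(1.8, 2.2)
  r1 <- make_run(st, throat = 100)
  r2 <- make_run(st * 7, throat = 700)
  m1 <- aerodynamic_metrics(r1)
  m2 <- aerodynamic_metrics(r2)
  expect_equal(m1$fpf_pct, m2$fpf_pct, tolerance = 1e-12)
  expect_equal(m1$ef_pct, m2$ef_pct, tolerance = 1e-12)
})

test_that("inhaled volume is flow times time", {
  expect_equal(inhaled_volume(28.3, 4), 1.886667, tolerance = 1e-6)
  expect_equal(inhaled_volume(60, 60), 60)
  expect_equal(inhaled_volume(28.3, 0), 0)
})

test_that("generator/reducer round trip on a full synthetic run", {
  fx <- generate_fixture("impactor_run",
                         list(mmad = 2.0, gsd = 2.0, ed_ug = 5000,
                              throat_fraction = 0.15, ef = 0.75),
                         noise_sd = 0, seed = 2)
  am <- aerodynamic_metrics(fx$data)
  expect_equal(am$mmad_um, 2.0, tolerance = 0.02)
  expect_equal(am$gsd, 2.0, tolerance = 0.02)
  expect_equal(am$ed_ug, 5000, tolerance = 1e-9)
  expect_equal(am$ef_pct, 75, tolerance = 1e-9)
})

test_that("impactor CSV reader round trips a generated run", {
  fx <- generate_fixture("impactor_run", list(mmad = 1.74, gsd = 2.1),
                         noise_sd = 0, seed = 9, dir = withr::local_tempdir())
  run <- read_impactor_csv(fx$files[1], fx$files[2])
  expect_equal(emitted_dose(run), emitted_dose(fx$data), tolerance = 1e-9)
  expect_equal(aerodynamic_metrics(run)$mmad_um, 1.74, tolerance = 0.02)
})
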