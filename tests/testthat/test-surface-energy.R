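test_that("Wu residual vanishes at forward-consistent angles and at the null solid", {
  # non-wetting null solid
  expect_equal(wu_residual(180, probe_water(), 0, 0), 0)
  # forward evaluation oracle: angles generated from known components
  gd <- 42.34; gp <- 31.03
  th_w <- wu_contact_angle(probe_water(), gd, gp)
  th_d <- wu_contact_angle(probe_diiodomethane(), gd, gp)
  expect_equal(th_w, 30.3, tolerance = 0.01)
  expect_equal(th_d, 22.7, tolerance = 0.01)
  expect_equal(wu_residual(th_w, probe_water(), gd, gp), 0, tolerance = 1e-10)
  expect_equal(wu_residual(th_d, probe_diiodomethane(), gd, gp), 0, tolerance = 1e-10)
})

test_that("solve_wu inverts forward-computed contact angles", {
  e <- solve_wu(contact_angle(probe_water(), 30.3),
                contact_angle(probe_diiodomethane(), 22.7))
  expect_equal(e$gamma_d, 42.34, tolerance = 1e-3)
  expect_equal(e$gamma_p, 31.03, tolerance = 1e-3)
  expect_equal(e$gamma_total, e$gamma_d + e$gamma_p)
  # residuals below the solver tolerance
  expect_lt(abs(wu_residual(30.3, probe_water(), e$gamma_d, e$gamma_p)), 1e-8)
  expect_lt(abs(wu_residual(22.7, probe_diiodomethane(), e$gamma_d, e$gamma_p)), 1e-8)
})

test_that("solve_wu round trips admissible synthetic components to 1e-6", {
  set.seed(21)
  pts <- sample_admissible_energy(25)
  for (i in seq_len(nrow(pts))) {
    gd <- pts[i, 1]; gp <- pts[i, 2]
    w <- contact_angle(probe_water(), wu_contact_angle(probe_water(), gd, gp))
    d <- contact_angle(probe_diiodomethane(),
                       wu_contact_angle(probe_diiodomethane(), gd, gp))
    e <- solve_wu(w, d)
    expect_equal(e$gamma_d, gd, tolerance = 1e-6 / max(1, gd))
    expect_equal(e$gamma_p, gp, tolerance = 1e-6 / max(1, gp))
    # order of the observations does not matter
    e2 <- solve_wu(d, w)
    expect_equal(e2$gamma_d, e$gamma_d, tolerance = 1e-8)
  }
})

test_that("total surface energy rises as either contact angle falls", {
  th_w <- seq(70, 30, by = -10)
  gs <- vapply(th_w, function(t) {
    solve_wu(contact_angle(probe_water(), t),
             contact_angle(probe_diiodomethane(), 40))$gamma_total
  }, numeric(1))
  expect_true(all(diff(gs) > 0))
  th_d <- seq(60, 20, by = -10)
  gs2 <- vapply(th_d, function(t) {
    solve_wu(contact_angle(probe_water(), 60),
             contact_angle(probe_diiodomethane(), t))$gamma_total
  }, numeric(1))
  expect_true(all(diff(gs2) > 0))
})

test_that("identical probe liquids are rejected as underdetermined", {
  expect_error(solve_wu(contact_angle(probe_water(), 40),
                        contact_angle(probe_water(), 50)),
               "underdetermined")
})

test_that("polarity and cohesion work reproduce printed component arithmetic", {
  expect_equal(polarity(13.89, 59.38), 23.39, tolerance = 1e-3)
  expect_equal(polarity(36.89, 82.54), 44.69, tolerance = 1e-3)
  expect_equal(polarity(0, 55), 0)
  expect_equal(cohesion_work(82.54), 165.08)
  expect_equal(cohesion_work(59.38), 118.76)
  expect_equal(cohesion_work(0), 0)
  expect_error(polarity(10, 0), "gamma_total")
})

test_that("surface_energy derived fields satisfy their identities", {
  e <- surface_energy(45.49, 13.89)
  expect_equal(e$gamma_total, 59.38)
  expect_equal(e$cohesion_work, 2 * e$gamma_total)
  expect_equal(e$polarity, e$gamma_p / e$gamma_total * 100)
})

test_that("contact-angle table reduction recovers per-label components", {
  fx <- generate_fixture("contact_angles",
                         list(gamma_d = 36.15, gamma_p = 25.69, label = "s"),
                         noise_sd = 0, seed = 5, dir = withr::local_tempdir())
  tab <- surface_energy_table(read_contact_angles_csv(fx$files[1]))
  expect_equal(tab$gamma_d, 36.15, tolerance = 1e-5)
  expect_equal(tab$gamma_p, 25.69, tolerance = 1e-5)
})
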