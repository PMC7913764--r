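flat_scan <- function(level = 100) {
  tt <- seq(3, 40, by = 0.01)
  diffractogram(tt, rep(level, length(tt)))
}

test_that("peak integration: flat signal, analytic triangle, Gaussian quadrature", {
  p1 <- peak_set(6.6, window = 0.25)
  expect_equal(integrate_peaks(flat_scan(), p1), 0)

  # unit-height triangle of half-width w on a flat baseline: area = w
  tt <- seq(3, 40, by = 0.01)
  w <- 0.2
  tri <- pmax(0, 1 - abs(tt - 11.4) / w)
  d <- diffractogram(tt, 30 + tri)
  expect_equal(integrate_peaks(d, peak_set(11.4, window = 0.3)), w, tolerance = 1e-3)

  # Gaussian amplitude A, sd sigma: area A sigma sqrt(2 pi) within 1%
  A <- 250; sigma <- 0.05
  g <- A * exp(-(tt - 18.7)^2 / (2 * sigma^2))
  dg <- diffractogram(tt, 10 + g)
  expect_equal(integrate_peaks(dg, peak_set(18.7, window = 0.25)),
               A * sigma * sqrt(2 * pi), tolerance = 0.01)
})

test_that("windows outside the scan range are rejected", {
  expect_error(integrate_peaks(flat_scan(), peak_set(40, window = 0.25)), "scan range")
})

test_that("crystallinity is the sample/reference peak-area ratio", {
  fx <- generate_fixture("diffractogram", list(crystallinity = 0.71), noise_sd = 0)
  expect_equal(crystallinity_percent(fx$data$sample, fx$data$reference),
               71, tolerance = 1e-6)
  # identity and linearity
  expect_equal(crystallinity_percent(fx$data$reference, fx$data$reference), 100)
  half <- diffractogram(fx$data$reference$two_theta,
                        fx$data$reference$intensity / 2)
  # halving all intensities halves the baseline too: areas scale linearly
  expect_equal(crystallinity_percent(half, fx$data$reference), 50, tolerance = 1e-9)
})

test_that("crystallinity is linear in sample peak amplitude", {
  fx1 <- generate_fixture("diffractogram", list(crystallinity = 0.2), noise_sd = 0)
  fx2 <- generate_fixture("diffractogram", list(crystallinity = 0.6), noise_sd = 0)
  c1 <- crystallinity_percent(fx1$data$sample, fx1$data$reference)
  c2 <- crystallinity_percent(fx2$data$sample, fx2$data$reference)
  expect_equal(c2 / c1, 3, tolerance = 1e-6)
})

test_that("a flat additive offset does not change the crystallinity index", {
  fx <- generate_fixture("diffractogram", list(crystallinity = 0.5), noise_sd = 0)
  shifted <- diffractogram(fx$data$sample$two_theta,
                           fx$data$sample$intensity + 500)
  expect_equal(crystallinity_percent(shifted, fx$data$reference),
               crystallinity_percent(fx$data$sample, fx$data$reference),
               tolerance = 1e-9)
})

test_that("per-peak averaging agrees with the total-area ratio for uniform attenuation", {
  fx <- generate_fixture("diffractogram", list(crystallinity = 0.53), noise_sd = 0)
  expect_equal(
    crystallinity_percent(fx$data$sample, fx$data$reference, method = "per_peak"),
    crystallinity_percent(fx$data$sample, fx$data$reference, method = "total_area"),
    tolerance = 1e-6)
})

test_that("XY files round trip through the reader/writer", {
  fx <- generate_fixture("diffractogram", list(crystallinity = 0.7), noise_sd = 0,
                         dir = withr::local_tempdir())
  d <- read_xy(fx$files[1])
  expect_equal(d$intensity, fx$data$sample$intensity, tolerance = 1e-9)
})
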