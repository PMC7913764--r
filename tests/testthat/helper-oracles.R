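# Independent oracles used across the suite.

# Sauter mean by numerical moment integration of the lognormal number
# density (count-median derived from the volume-median convention).
sauter_mean_quadrature <- function(median_v, gsd) {
  lns <- log(gsd)
  cmd <- median_v * exp(-3 * lns^2)
  dens <- function(d) stats::dlnorm(d, meanlog = log(cmd), sdlog = lns)
  m3 <- stats::integrate(function(d) d^3 * dens(d), 0, Inf, rel.tol = 1e-10)$value
  m2 <- stats::integrate(function(d) d^2 * dens(d), 0, Inf, rel.tol = 1e-10)$value
  m3 / m2
}

# Withdrawal correction by explicit summation (independent of the
# vectorized implementation).
corrected_conc_by_summation <- function(conc, vs, v) {
  out <- numeric(length(conc))
  for (n in seq_along(conc)) {
    removed <- 0
    if (n > 1) for (i in 1:(n - 1)) removed <- removed + conc[i]
    out[n] <- conc[n] + vs / v * removed
  }
  out
}

# Noise-free cascade-impactor stage masses for a lognormal APSD: the
# forward model of the sizing regression.
lognormal_stage_masses <- function(mmad, gsd, total = 1000) {
  cuts <- aci_cutoffs()
  cdf <- plnorm(cuts, meanlog = log(mmad), sdlog = log(gsd))
  upper <- c(Inf, cuts[-length(cuts)])
  band <- plnorm(upper, meanlog = log(mmad), sdlog = log(gsd)) - cdf
  stats::setNames(total * band, names(cuts))
}

make_run <- function(stages, throat = 0, device = 0, capsules = 0,
                     loaded = sum(stages) + throat + device + capsules) {
  impactor_run(mass_device = device, mass_capsules = capsules,
               mass_induction_port = throat, mass_stages = stages,
               loaded_api = loaded)
}

# admissible surface-energy pairs: both probe liquids must give a real
# contact angle (no complete wetting)
sample_admissible_energy <- function(n, lo = 5, hi = 60) {
  out <- matrix(NA_real_, 0, 2)
  while (nrow(out) < n) {
    gd <- runif(1, lo, hi); gp <- runif(1, lo, hi)
    ok <- tryCatch({
      wu_contact_angle(probe_water(), gd, gp)
      wu_contact_angle(probe_diiodomethane(), gd, gp)
      TRUE
    }, error = function(e) FALSE)
    if (ok) out <- rbind(out, c(gd, gp))
  }
  out
}
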