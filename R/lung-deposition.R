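# Aerosol mechanics at body conditions (CGS units):
# T = 310 K, air viscosity 1.89e-4 g/(cm s), mean free path 0.0712 um,
# unit-density spheres by the aerodynamic-diameter convention.
.aero <- list(T_K = 310, mu = 1.89e-4, lambda_um = 0.0712,
              g = 981, kB = 1.380649e-16, rho0 = 1)

#' Cunningham slip correction factor
#'
#' @param d_um Particle diameter in µm, > 0.
#' @return Dimensionless slip correction, >= 1.
#' @export
slip_correction <- function(d_um) {
  stopifnot(all(d_um > 0))
  kn2 <- 2 * .aero$lambda_um / d_um
  1 + kn2 * (1.257 + 0.4 * exp(-1.1 / kn2))
}

#' Terminal settling velocity of an aerodynamic-diameter sphere
#'
#' Stokes settling with slip correction for a unit-density sphere of the
#' given aerodynamic diameter.
#'
#' @param d_ae_um Aerodynamic diameter, µm.
#' @return Settling velocity in cm/s.
#' @export
settling_velocity <- function(d_ae_um) {
  d_cm <- d_ae_um * 1e-4
  .aero$rho0 * .aero$g * slip_correction(d_ae_um) * d_cm^2 / (18 * .aero$mu)
}

#' Brownian diffusion coefficient of a particle
#'
#' Stokes--Einstein with slip correction.
#'
#' @param d_um Particle diameter, µm.
#' @return Diffusion coefficient in cm^2/s.
#' @export
particle_diffusivity <- function(d_um) {
  d_cm <- d_um * 1e-4
  .aero$kB * .aero$T_K * slip_correction(d_um) / (3 * pi * .aero$mu * d_cm)
}

# relaxation time tau = v_s / g, s
.relax_time <- function(d_ae_um) settling_velocity(d_ae_um) / .aero$g

#' Per-mechanism deposition probabilities in a cylindrical airway
#'
#' Analytic single-tube deposition efficiencies used by the stochastic lung
#' model:
#' * impaction at the inlet bifurcation (Yeh--Schum form): with Stokes number
#'   `Stk = tau * u / r` and `eps = theta_branch * Stk`,
#'   `P = 1 - (2/pi) acos(eps) + (1/pi) sin(2 acos(eps))` for `eps < 1`,
#'   else 1;
#' * gravitational sedimentation in a tube inclined `phi` from the
#'   horizontal: `P = 1 - exp(-4 v_s t cos(phi) / (pi d))`;
#' * Brownian diffusion in laminar flow (Gormley--Kennedy):
#'   with `x = 4 D t / (pi d^2)`, `P = 5.50 x^(2/3) - 3.77 x` for
#'   `x < 0.009`, else `P = 1 - 0.819 exp(-11.5 x) - 0.0975 exp(-70.1 x)`.
#'
#' All inputs are vectorized; probabilities are clipped to `[0, 1]`.
#'
#' @param d_ae_um Aerodynamic diameter, µm.
#' @param u Mean air speed in the airway, cm/s.
#' @param d_tube Airway diameter, cm.
#' @param branch_deg Branching angle, degrees.
#' @param residence_s Residence time in the airway, s.
#' @param gravity_deg Airway axis angle from the horizontal plane, degrees.
#' @return Probability in `[0, 1]`.
#' @name deposition_mechanisms
NULL

#' @rdname deposition_mechanisms
#' @export
prob_impaction <- function(d_ae_um, u, d_tube, branch_deg) {
  stk <- .relax_time(d_ae_um) * u / (d_tube / 2)
  eps <- pmin(branch_deg * pi / 180 * stk, 1)
  a <- acos(eps)
  pmin(pmax(1 - 2 / pi * a + sin(2 * a) / pi, 0), 1)
}

#' @rdname deposition_mechanisms
#' @export
prob_sedimentation <- function(d_ae_um, residence_s, d_tube, gravity_deg) {
  vs <- settling_velocity(d_ae_um)
  p <- 1 - exp(-4 * vs * residence_s * cos(gravity_deg * pi / 180) / (pi * d_tube))
  pmin(pmax(p, 0), 1)
}

#' @rdname deposition_mechanisms
#' @export
prob_diffusion <- function(d_ae_um, residence_s, d_tube) {
  x <- 4 * particle_diffusivity(d_ae_um) * residence_s / (pi * d_tube^2)
  p <- ifelse(x < 0.009,
              5.50 * x^(2 / 3) - 3.77 * x,
              1 - 0.819 * exp(-11.5 * x) - 0.0975 * exp(-70.1 * x))
  pmin(pmax(p, 0), 1)
}

# still-air (breath-hold) variants: sedimentation uses the same tube
# geometry factor; diffusion uses the first radial diffusion mode of a
# cylinder, P = 1 - exp(-5.784 D t / a^2)
prob_diffusion_still <- function(d_ae_um, t_s, d_tube) {
  a <- d_tube / 2
  p <- 1 - exp(-5.784 * particle_diffusivity(d_ae_um) * t_s / a^2)
  pmin(pmax(p, 0), 1)
}

# combine independent mechanisms
.combine_probs <- function(...) {
  ps <- list(...)
  q <- 1
  for (p in ps) q <- q * (1 - pmin(pmax(p, 0), 1))
  1 - q
}

#' Total deposition probability in one airway segment
#'
#' Combines impaction, sedimentation and diffusion as
#' `P = 1 - (1-P_imp)(1-P_sed)(1-P_diff)`.
#'
#' @param d_ae_um Aerodynamic diameter, µm.
#' @param segment List or one-row data frame with `diameter_cm`, `length_cm`,
#'   `branch_deg`, `gravity_deg` (as produced by [sample_airway_path()]).
#' @param flow_cm3s Air flow through the individual airway, cm^3/s.
#' @param residence_s Residence time in the segment, s.
#' @return Probability in `[0, 1]`.
#' @export
deposition_probability_segment <- function(d_ae_um, segment, flow_cm3s, residence_s) {
  d_t <- segment$diameter_cm
  u <- flow_cm3s / (pi / 4 * d_t^2)
  .combine_probs(
    prob_impaction(d_ae_um, u, d_t, segment$branch_deg),
    prob_sedimentation(d_ae_um, residence_s, d_t, segment$gravity_deg),
    prob_diffusion(d_ae_um, residence_s, d_t)
  )
}

#' Extrathoracic (mouth-throat) deposition probability
#'
#' Empirical impaction-parameter curve, monotone non-decreasing in
#' `d_ae^2 * Q`: `P = x / (1 + x)` with
#' `x = (d_ae^2 * Q / scale)^power`. Default coefficients describe oral
#' inhalation; the nasal coefficients are provided for completeness but are
#' not exercised by the shipped studies.
#'
#' @param d_ae_um Aerodynamic diameter, µm.
#' @param flow_lpm Inhalation flow rate, L/min.
#' @param mode `"oral"` or `"nasal"`.
#' @param coef Optional named vector `c(scale=, power=)` overriding the
#'   mode defaults (scale in µm^2 L/min). `scale = Inf` disables the filter.
#' @return Probability in `[0, 1]`.
#' @export
extrathoracic_deposition <- function(d_ae_um, flow_lpm, mode = c("oral", "nasal"),
                                     coef = NULL) {
  mode <- match.arg(mode)
  stopifnot(all(d_ae_um >= 0), flow_lpm > 0)
  if (is.null(coef)) {
    coef <- if (mode == "oral") c(scale = 500, power = 1.2) else c(scale = 150, power = 1.1)
  }
  if (!is.finite(coef[["scale"]])) return(rep(0, length(d_ae_um)))
  x <- (d_ae_um^2 * flow_lpm / coef[["scale"]])^coef[["power"]]
  x / (1 + x)
}

#' Breathing pattern
#'
#' @param inhaled_volume Inhaled volume IV, litres (default 1.7, a COPD
#'   patient inhaling through a capsule device).
#' @param inhalation_time Inhalation time, s (default 3.2).
#' @param breath_hold Post-inhalation breath-hold, s.
#' @param exhalation_time Exhalation time, s; defaults to the inhalation
#'   time.
#' @param mode `"oral"` or `"nasal"`.
#' @return Object of class `breathing_pattern`.
#' @export
breathing_pattern <- function(inhaled_volume = 1.7, inhalation_time = 3.2,
                              breath_hold = 5, exhalation_time = inhalation_time,
                              mode = c("oral", "nasal")) {
  mode <- match.arg(mode)
  stopifnot(inhaled_volume > 0, inhalation_time > 0,
            breath_hold >= 0, exhalation_time >= 0)
  structure(list(inhaled_volume = inhaled_volume,
                 inhalation_time = inhalation_time,
                 breath_hold = breath_hold,
                 exhalation_time = exhalation_time, mode = mode),
            class = "breathing_pattern")
}

#' Monte Carlo regional lung deposition
#'
#' Stochastic simulation of aerosol deposition in a randomized asymmetric
#' airway tree. Each particle draws an aerodynamic diameter from the
#' lognormal APSD, passes the extrathoracic filter, penetrates the tree to a
#' volumetric depth drawn uniformly over the inhaled volume (air-front
#' picture: residence in a generation equals its gas volume over the flow),
#' and can deposit in each traversed segment by impaction, sedimentation or
#' diffusion. During the breath-hold, sedimentation and diffusion act for the
#' hold duration in the terminal segment reached; exhalation retraces the
#' same sampled path at the exhalation flow. Tallies are integer particle
#' counts, so the regional percentages conserve mass exactly.
#'
#' @param apsd Either a numeric vector `c(mmad, gsd)` (µm, dimensionless) or
#'   an [impactor_run()], which is reduced via [fit_mmad_gsd()] first.
#' @param breathing A [breathing_pattern()].
#' @param geometry An [airway_geometry()]; defaults to the shipped
#'   whole-lung tree.
#' @param n_particles Number of simulated particles.
#' @param seed Integer seed; identical seeds give identical results, and the
#'   same underlying random numbers are reused across parameter variations
#'   so that, e.g., lengthening the breath-hold can only add deposition.
#' @param et_coef Optional extrathoracic coefficient override, see
#'   [extrathoracic_deposition()].
#' @return Object of class `deposition_result`: regional percentages
#'   (`extrathoracic`, `bronchial`, `acinar`, `lung`, `exhaled`), binomial
#'   standard errors (`se`), particle counts and `n_particles`.
#' @export
simulate_deposition <- function(apsd, breathing = breathing_pattern(),
                                geometry = default_airway_geometry(),
                                n_particles = 10000, seed = 1, et_coef = NULL) {
  stopifnot(inherits(breathing, "breathing_pattern"),
            inherits(geometry, "airway_geometry"),
            n_particles >= 1)
  if (inherits(apsd, "impactor_run")) {
    fit <- fit_mmad_gsd(cumulative_undersize(apsd))
    mmad <- fit$mmad; gsd <- fit$gsd
  } else {
    stopifnot(is.numeric(apsd), length(apsd) == 2L)
    mmad <- apsd[[1]]; gsd <- apsd[[2]]
  }
  if (!(mmad > 0 && gsd >= 1)) stop("invalid APSD: need mmad > 0, gsd >= 1", call. = FALSE)

  n <- as.integer(n_particles)
  g <- geometry$generations
  G <- nrow(g)
  vol <- generation_volumes(geometry)
  iv_cm3 <- breathing$inhaled_volume * 1000
  q_in <- iv_cm3 / breathing$inhalation_time
  q_ex <- if (breathing$exhalation_time > 0) iv_cm3 / breathing$exhalation_time else NA_real_

  set.seed(seed)
  # fixed draw order so that runs with the same seed share random numbers
  d_ae <- mmad * gsd^stats::rnorm(n)
  u_et <- stats::runif(n)
  v_pen <- stats::runif(n) * iv_cm3
  d_air <- l_air <- br_ang <- gr_ang <- matrix(0, n, G)
  for (j in seq_len(G)) {
    d_air[, j] <- g$diameter_cm[j] * g$gsd[j]^stats::rnorm(n)
    l_air[, j] <- g$length_cm[j] * g$gsd[j]^stats::rnorm(n)
    br_ang[, j] <- stats::runif(n, g$branch_min_deg[j], g$branch_max_deg[j])
    gr_ang[, j] <- stats::runif(n, g$gravity_min_deg[j], g$gravity_max_deg[j])
  }
  u_dep <- matrix(stats::runif(n * (2L * G + 1L)), n, 2L * G + 1L)

  flow_lpm <- breathing$inhaled_volume / breathing$inhalation_time * 60
  p_et <- extrathoracic_deposition(d_ae, flow_lpm, breathing$mode, coef = et_coef)
  in_et <- u_et < p_et

  # deepest generation reached: first k with cumulative volume >= penetration
  k_reach <- pmin(findInterval(v_pen, vol$cumulative_cm3) + 1L, G)

  phase_probs <- function(q_flow) {
    p <- matrix(0, n, G)
    for (j in seq_len(G)) {
      qa <- q_flow / g$n_airways[j]
      u <- qa / (pi / 4 * d_air[, j]^2)
      tr <- vol$total_cm3[j] / q_flow
      p[, j] <- .combine_probs(
        prob_impaction(d_ae, u, d_air[, j], br_ang[, j]),
        prob_sedimentation(d_ae, tr, d_air[, j], gr_ang[, j]),
        prob_diffusion(d_ae, tr, d_air[, j]))
    }
    p
  }
  reach_mask <- outer(rep(1L, n), seq_len(G)) <= k_reach  # n x G: j <= k_reach
  p_in <- phase_probs(q_in) * reach_mask
  idxK <- cbind(seq_len(n), k_reach)
  p_hold <- if (breathing$breath_hold > 0) {
    .combine_probs(
      prob_sedimentation(d_ae, breathing$breath_hold, d_air[idxK], gr_ang[idxK]),
      prob_diffusion_still(d_ae, breathing$breath_hold, d_air[idxK]))
  } else rep(0, n)
  p_out <- if (is.na(q_ex)) matrix(0, n, G) else phase_probs(q_ex) * reach_mask

  # event sequence per particle: inhalation gens 1..K, hold at K,
  # exhalation gens K..1 (masked generations have probability 0)
  p_seq <- cbind(p_in, p_hold, p_out[, G:1, drop = FALSE])
  hit <- u_dep < p_seq
  first <- max.col(cbind(hit, TRUE) * 1, ties.method = "first")
  deposited <- first <= 2L * G + 1L

  gen_of <- integer(n)
  in_phase <- deposited & first <= G
  gen_of[in_phase] <- first[in_phase]
  hold_phase <- deposited & first == G + 1L
  gen_of[hold_phase] <- k_reach[hold_phase]
  out_phase <- deposited & first > G + 1L
  gen_of[out_phase] <- 2L * G + 2L - first[out_phase]

  region <- rep("exhaled", n)
  region[in_et] <- "extrathoracic"
  tree <- !in_et & deposited
  region[tree] <- g$region[gen_of[tree]]

  counts <- c(extrathoracic = sum(region == "extrathoracic"),
              bronchial = sum(region == "bronchial"),
              acinar = sum(region == "acinar"),
              exhaled = sum(region == "exhaled"))
  pct <- 100 * counts / n
  se <- 100 * sqrt(pct / 100 * (1 - pct / 100) / n)
  structure(list(
    extrathoracic = unname(pct["extrathoracic"]),
    bronchial = unname(pct["bronchial"]),
    acinar = unname(pct["acinar"]),
    lung = unname(pct["bronchial"] + pct["acinar"]),
    exhaled = unname(pct["exhaled"]),
    se = se, counts = counts, n_particles = n,
    mmad = mmad, gsd = gsd, seed = seed
  ), class = "deposition_result")
}

#' @export
print.deposition_result <- function(x, ...) {
  cat(sprintf("Regional deposition (n = %d particles, MMAD %.2f um, GSD %.2f):\n",
              x$n_particles, x$mmad, x$gsd))
  cat(sprintf("  extrathoracic %6.2f %%   lung %6.2f %% (bronchial %.2f, acinar %.2f)   exhaled %6.2f %%\n",
              x$extrathoracic, x$lung, x$bronchial, x$acinar, x$exhaled))
  invisible(x)
}
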