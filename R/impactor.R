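#' Andersen cascade impactor stage cut-off diameters
#'
#' Effective cut-off aerodynamic diameters for ACI stages 0--7 and the final
#' filter at the calibration flow rate of 28.3 L/min: 9.0, 5.8, 4.7, 3.3,
#' 2.1, 1.1, 0.7 and 0.4 µm (filter: 0). Stage 0's nominal 9.0--10.0 µm band
#' is represented by its lower cut-off; mass above it has no upper size
#' bound. Cut-offs can optionally be rescaled to another flow rate with the
#' usual `d50 ~ Q^(-1/2)` law, which is off by default because the
#' calibration table is used as printed.
#'
#' @param flow_rate Flow rate in L/min.
#' @param rescale Rescale the 28.3 L/min calibration cut-offs to `flow_rate`.
#' @return Named numeric vector `stage0`..`stage7`, `filter` (µm).
#' @export
aci_cutoffs <- function(flow_rate = 28.3, rescale = FALSE) {
  d <- c(stage0 = 9.0, stage1 = 5.8, stage2 = 4.7, stage3 = 3.3,
         stage4 = 2.1, stage5 = 1.1, stage6 = 0.7, stage7 = 0.4, filter = 0)
  if (rescale && flow_rate != 28.3) d <- d * sqrt(28.3 / flow_rate)
  d
}

#' One Andersen cascade impactor experiment
#'
#' Drug masses recovered from each washed location after actuation: the
#' inhaler device, the capsules, the induction port (throat) and the
#' collection plates of stages 0--7 plus the terminal filter.
#'
#' @param mass_device,mass_capsules,mass_induction_port Masses in µg, >= 0.
#' @param mass_stages Named numeric vector of stage masses in µg with names
#'   `stage0`..`stage7` and `filter`.
#' @param loaded_api Drug mass loaded into the capsules, µg.
#' @param flow_rate Flow rate, L/min (default 28.3).
#' @param inhalation_time Inhalation duration per actuation, s (default 4).
#' @param label Sample label.
#' @return Object of class `impactor_run`.
#' @export
impactor_run <- function(mass_device, mass_capsules, mass_induction_port,
                         mass_stages, loaded_api, flow_rate = 28.3,
                         inhalation_time = 4, label = "") {
  wanted <- names(aci_cutoffs())
  stopifnot(is.numeric(mass_stages), !is.null(names(mass_stages)))
  if (!setequal(names(mass_stages), wanted)) {
    stop("mass_stages must be named stage0..stage7 and filter", call. = FALSE)
  }
  mass_stages <- mass_stages[wanted]
  m <- c(mass_device, mass_capsules, mass_induction_port, mass_stages, loaded_api)
  if (any(!is.finite(m)) || any(m < 0)) {
    stop("all masses must be finite and non-negative", call. = FALSE)
  }
  structure(list(mass_device = mass_device, mass_capsules = mass_capsules,
                 mass_induction_port = mass_induction_port,
                 mass_stages = mass_stages, loaded_api = loaded_api,
                 flow_rate = flow_rate, inhalation_time = inhalation_time,
                 label = as.character(label)),
            class = "impactor_run")
}

#' Emitted dose
#'
#' Drug leaving the device and capsules and reaching the impactor:
#' induction-port mass plus all stage and filter masses (equivalently, total
#' recovered minus device and capsule residues).
#'
#' @param run An [impactor_run()].
#' @return ED in µg.
#' @export
emitted_dose <- function(run) {
  stopifnot(inherits(run, "impactor_run"))
  run$mass_induction_port + sum(run$mass_stages)
}

#' Emitted fraction
#'
#' @param ed Emitted dose, µg.
#' @param loaded Loaded drug mass, µg, > 0.
#' @return EF in percent.
#' @export
emitted_fraction <- function(ed, loaded) {
  stopifnot(is.numeric(ed), is.numeric(loaded))
  if (any(loaded <= 0)) stop("loaded dose must be > 0", call. = FALSE)
  ed / loaded * 100
}

# sized mass: everything with a calibrated cut-off (stages + filter);
# the induction port has none and is excluded from sizing
sized_mass <- function(run) sum(run$mass_stages)

#' Cumulative undersize distribution from stage masses
#'
#' For each stage cut-off diameter, the fraction of the impactor-sized mass
#' (stages 0--7 plus filter; the induction port has no calibrated cut-off
#' and is excluded) collected on locations with a smaller cut-off, i.e. the
#' empirical probability that a particle's aerodynamic diameter is below the
#' cut-off.
#'
#' @param run An [impactor_run()].
#' @return Data frame with columns `cutoff_um` (descending, stages 0--7) and
#'   `fraction` in `[0, 1]`, non-decreasing with diameter.
#' @export
cumulative_undersize <- function(run) {
  stopifnot(inherits(run, "impactor_run"))
  total <- sized_mass(run)
  if (total <= 0) stop("no sized mass on stages or filter", call. = FALSE)
  cuts <- aci_cutoffs(run$flow_rate)
  stage_cuts <- cuts[setdiff(names(cuts), "filter")]
  frac <- vapply(stage_cuts, function(d) {
    sum(run$mass_stages[cuts[names(run$mass_stages)] < d]) / total
  }, numeric(1))
  data.frame(cutoff_um = unname(stage_cuts), fraction = unname(frac))
}

#' MMAD and GSD by log-probability regression
#'
#' Fits the classical log-probability line: probit-transformed cumulative
#' undersize fraction against `log10` cut-off diameter by least squares,
#' using only points with fraction strictly inside (0, 1). The mass median
#' aerodynamic diameter is the 50% point, `MMAD = 10^(-intercept/slope)`,
#' and `GSD = 10^(1/slope)`.
#'
#' @param cum Data frame as returned by [cumulative_undersize()], columns
#'   `cutoff_um` and `fraction`.
#' @return List with `mmad` (µm), `gsd`, `slope`, `intercept`, `n_points`.
#' @export
fit_mmad_gsd <- function(cum) {
  stopifnot(is.data.frame(cum), all(c("cutoff_um", "fraction") %in% names(cum)))
  use <- cum$fraction > 0 & cum$fraction < 1 & cum$cutoff_um > 0
  if (sum(use) < 2L) {
    stop("need at least 2 points with cumulative fraction strictly in (0, 1)",
         call. = FALSE)
  }
  x <- log10(cum$cutoff_um[use])
  y <- stats::qnorm(cum$fraction[use])
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  if (!is.finite(slope) || slope <= 0) {
    stop("degenerate size distribution: non-positive log-probability slope",
         call. = FALSE)
  }
  list(mmad = 10^(-intercept / slope), gsd = 10^(1 / slope),
       slope = slope, intercept = intercept, n_points = sum(use))
}

#' Fine particle dose
#'
#' Mass of sized drug with aerodynamic diameter under 5 µm, evaluated from
#' the fitted log-probability line (lognormal CDF at exactly 5.0 µm) rather
#' than by truncating at the nearest stage cut-off.
#'
#' @param run An [impactor_run()].
#' @param fit A fit from [fit_mmad_gsd()]; computed from `run` when omitted.
#' @param d_fine Fine-particle threshold, µm (default 5).
#' @return FPD in µg.
#' @export
fine_particle_dose <- function(run, fit = NULL, d_fine = 5) {
  stopifnot(inherits(run, "impactor_run"))
  if (is.null(fit)) fit <- fit_mmad_gsd(cumulative_undersize(run))
  frac_under <- stats::plnorm(d_fine, meanlog = log(fit$mmad), sdlog = log(fit$gsd))
  sized_mass(run) * frac_under
}

#' Fine particle fraction
#'
#' @param fpd Fine particle dose, µg.
#' @param ed Emitted dose, µg, > 0.
#' @return FPF in percent.
#' @export
fine_particle_fraction <- function(fpd, ed) {
  stopifnot(is.numeric(fpd), is.numeric(ed))
  if (any(ed <= 0)) stop("emitted dose must be > 0", call. = FALSE)
  fpd / ed * 100
}

#' Inhaled volume of an impactor actuation
#'
#' @param flow Flow rate, L/min.
#' @param t Inhalation time, s.
#' @return Volume in litres, `flow * t / 60`.
#' @export
#' @examples
#' inhaled_volume(28.3, 4)  # 1.89 L
inhaled_volume <- function(flow, t) {
  stopifnot(is.numeric(flow), is.numeric(t), all(flow >= 0), all(t >= 0))
  flow * t / 60
}

#' Full aerodynamic reduction of an impactor run
#'
#' @param run An [impactor_run()].
#' @return One-row data frame with `ed_ug`, `ef_pct`, `fpd_ug`, `fpf_pct`,
#'   `mmad_um`, `gsd`.
#' @export
aerodynamic_metrics <- function(run) {
  stopifnot(inherits(run, "impactor_run"))
  ed <- emitted_dose(run)
  fit <- fit_mmad_gsd(cumulative_undersize(run))
  fpd <- fine_particle_dose(run, fit)
  data.frame(ed_ug = ed,
             ef_pct = emitted_fraction(ed, run$loaded_api),
             fpd_ug = fpd,
             fpf_pct = fine_particle_fraction(fpd, ed),
             mmad_um = fit$mmad, gsd = fit$gsd)
}
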