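#' Dissolution run with sampling withdrawal
#'
#' A paddle-apparatus dissolution time series in which an aliquot of
#' `sample_volume` mL is withdrawn at each sampling time and replaced with
#' fresh medium, diluting the vessel.
#'
#' @param times Sampling times in minutes, strictly increasing
#'   (protocol default `c(5, 10, 15, 30, 60)`).
#' @param measured_conc Measured drug concentrations at `times`, µg/mL.
#' @param vessel_volume Medium volume V in mL (default 50, the estimated
#'   lung-lining fluid volume the protocol emulates).
#' @param sample_volume Withdrawn aliquot Vs in mL (default 5).
#' @param dose Drug dose placed in the vessel, µg (default 1500).
#' @return Object of class `dissolution_run`.
#' @export
dissolution_run <- function(times = c(5, 10, 15, 30, 60), measured_conc,
                            vessel_volume = 50, sample_volume = 5, dose = 1500) {
  stopifnot(is.numeric(times), is.numeric(measured_conc))
  if (length(times) != length(measured_conc)) {
    stop("times and measured_conc must have equal length", call. = FALSE)
  }
  if (any(diff(times) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  if (any(measured_conc < 0)) stop("concentrations must be non-negative", call. = FALSE)
  if (!(vessel_volume > sample_volume && sample_volume >= 0)) {
    stop("need vessel_volume > sample_volume >= 0", call. = FALSE)
  }
  if (dose <= 0) stop("dose must be > 0", call. = FALSE)
  structure(list(times = times, measured_conc = measured_conc,
                 vessel_volume = vessel_volume, sample_volume = sample_volume,
                 dose = dose),
            class = "dissolution_run")
}

#' Withdrawal-corrected cumulative release
#'
#' Each withdrawn aliquot removes drug that the raw concentration at later
#' time points no longer sees. The standard replacement correction adds back
#' the removed mass: `C_corr[n] = C[n] + (Vs/V) * sum_{i<n} C[i]`. Cumulative
#' release is then `C_corr * V / dose * 100`.
#'
#' @param r A [dissolution_run()].
#' @return Data frame with columns `time_min`, `measured_conc`,
#'   `corrected_conc`, `released_pct`.
#' @export
#' @examples
#' r <- dissolution_run(c(5, 10, 15), c(10, 12, 13))
#' corrected_release_percent(r)
corrected_release_percent <- function(r) {
  stopifnot(inherits(r, "dissolution_run"))
  ratio <- r$sample_volume / r$vessel_volume
  prior <- c(0, cumsum(r$measured_conc))[seq_along(r$measured_conc)]
  corr <- r$measured_conc + ratio * prior
  data.frame(time_min = r$times,
             measured_conc = r$measured_conc,
             corrected_conc = corr,
             released_pct = corr * r$vessel_volume / r$dose * 100)
}

#' Horizontal diffusion-cell run
#'
#' @param times Times in minutes, strictly increasing.
#' @param cumulative_mass Cumulative permeated drug mass at `times`, µg,
#'   non-decreasing.
#' @param area Diffusion surface A, cm^2 (default 0.785).
#' @param donor_conc Donor-phase drug concentration Cd, µg/cm^3 (default
#'   1500 µg in 9 mL).
#' @return Object of class `diffusion_run`.
#' @export
diffusion_run <- function(times, cumulative_mass, area = 0.785,
                          donor_conc = 1500 / 9) {
  stopifnot(is.numeric(times), is.numeric(cumulative_mass))
  if (length(times) != length(cumulative_mass)) {
    stop("times and cumulative_mass must have equal length", call. = FALSE)
  }
  if (any(diff(times) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  if (any(diff(cumulative_mass) < 0)) {
    stop("cumulative_mass must be non-decreasing", call. = FALSE)
  }
  if (area <= 0) stop("area must be > 0", call. = FALSE)
  structure(list(times = times, cumulative_mass = cumulative_mass,
                 area = area, donor_conc = donor_conc),
            class = "diffusion_run")
}

#' Steady flux through a membrane
#'
#' `J = m / (A * t)`: permeated mass over membrane area and duration.
#'
#' @param m Permeated mass, µg.
#' @param area Membrane area, cm^2, > 0.
#' @param t Duration, hours, > 0.
#' @return Flux in µg/cm^2/h.
#' @export
flux <- function(m, area, t) {
  stopifnot(is.numeric(m), is.numeric(area), is.numeric(t))
  if (any(area <= 0)) stop("area must be > 0", call. = FALSE)
  if (any(t <= 0)) stop("duration must be > 0", call. = FALSE)
  m / (area * t)
}

#' Permeability coefficient
#'
#' `Kp = J / Cd`: flux normalized by the donor-phase concentration.
#'
#' @param J Flux, µg/cm^2/h.
#' @param donor_conc Donor concentration Cd, µg/cm^3, > 0.
#' @return Kp in cm/h.
#' @export
#' @examples
#' permeability_coefficient(86.90, 1500 / 9)
permeability_coefficient <- function(J, donor_conc) {
  stopifnot(is.numeric(J), is.numeric(donor_conc))
  if (any(donor_conc <= 0)) stop("donor concentration must be > 0", call. = FALSE)
  J / donor_conc
}

#' Reduce a diffusion run to flux and permeability
#'
#' End-point reduction: flux from the final cumulative mass over the full
#' duration (the protocol's definition), plus the permeability coefficient.
#'
#' @param r A [diffusion_run()].
#' @return One-row data frame with `duration_h`, `mass_ug`, `flux`, `kp`.
#' @export
reduce_diffusion <- function(r) {
  stopifnot(inherits(r, "diffusion_run"))
  t_h <- (r$times[length(r$times)] - r$times[1]) / 60
  m <- r$cumulative_mass[length(r$cumulative_mass)]
  J <- flux(m, r$area, t_h)
  data.frame(duration_h = t_h, mass_ug = m, flux = J,
             kp = permeability_coefficient(J, r$donor_conc))
}
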