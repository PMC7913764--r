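#' Read laser-diffraction quantile tables
#'
#' CSV schema: `label,replicate,d10_um,d50_um,d90_um` (the `replicate`
#' column is optional; rows sharing a label are averaged).
#'
#' @param path CSV file path.
#' @return Named list of [psd_quantiles()] (mean quantiles per label).
#' @export
read_psd_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("label", "d10_um", "d50_um", "d90_um") %in% names(df)))
  out <- lapply(split(df, df$label), function(s) {
    psd_quantiles(mean(s$d10_um), mean(s$d50_um), mean(s$d90_um),
                  label = s$label[1])
  })
  out
}

#' Read bulk/tapped density replicates
#'
#' CSV schema: `label,replicate,bulk_g_cm3,tapped_g_cm3`.
#'
#' @param path CSV file path.
#' @return Named list (per label) of lists of [density_measurement()].
#' @export
read_rheology_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("label", "replicate", "bulk_g_cm3", "tapped_g_cm3") %in% names(df)))
  lapply(split(df, df$label), function(s) {
    lapply(seq_len(nrow(s)), function(i) {
      density_measurement(s$bulk_g_cm3[i], s$tapped_g_cm3[i], s$replicate[i])
    })
  })
}

#' Read contact-angle observations
#'
#' CSV schema: `label,liquid,theta_deg,replicate` with liquids `"water"` or
#' `"diiodomethane"` (custom probe liquids can be supplied to [solve_wu()]
#' directly).
#'
#' @param path CSV file path.
#' @return Data frame of the observations.
#' @export
read_contact_angles_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("label", "liquid", "theta_deg", "replicate") %in% names(df)))
  df
}

#' Solve the Wu system for every label in a contact-angle table
#'
#' Replicate angles are averaged per liquid before inversion.
#'
#' @param df Data frame as from [read_contact_angles_csv()].
#' @param liquids Named list mapping liquid names to [probe_liquid()]
#'   objects.
#' @return Data frame mirroring the usual surface-energy report: `label`,
#'   `gamma_d`, `gamma_p`, `gamma_total`, `cohesion_work`, `polarity`.
#' @export
surface_energy_table <- function(df, liquids = list(water = probe_water(),
                                                    diiodomethane = probe_diiodomethane())) {
  stopifnot(all(df$liquid %in% names(liquids)))
  rows <- lapply(split(df, df$label), function(s) {
    th <- tapply(s$theta_deg, s$liquid, mean)
    polar_name <- names(which.max(vapply(liquids[names(th)], `[[`, numeric(1), "gamma_p")))
    apolar_name <- setdiff(names(th), polar_name)[1]
    e <- solve_wu(contact_angle(liquids[[polar_name]], th[[polar_name]]),
                  contact_angle(liquids[[apolar_name]], th[[apolar_name]]),
                  label = s$label[1])
    data.frame(label = s$label[1], gamma_d = e$gamma_d, gamma_p = e$gamma_p,
               gamma_total = e$gamma_total, cohesion_work = e$cohesion_work,
               polarity = e$polarity)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read/write two-column XY diffractograms
#'
#' Whitespace-separated two-column text (2-theta, intensity).
#'
#' @param path File path.
#' @param label Label attached to the result.
#' @return [read_xy()]: a [diffractogram()].
#' @export
read_xy <- function(path, label = basename(path)) {
  df <- utils::read.table(path, col.names = c("two_theta", "intensity"))
  diffractogram(df$two_theta, df$intensity, label = label)
}

#' @rdname read_xy
#' @param d A [diffractogram()] to write.
#' @export
write_xy <- function(d, path) {
  stopifnot(inherits(d, "diffractogram"))
  utils::write.table(data.frame(d$two_theta, d$intensity), path,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a time-series CSV
#'
#' CSV schema: `time_min,value`.
#'
#' @param path CSV file path.
#' @return Data frame with `time_min` and `value`.
#' @export
read_timeseries_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("time_min", "value") %in% names(df)))
  df[order(df$time_min), ]
}

#' Read one impactor run
#'
#' CSV schema: `location,mass_ug` with locations `device`, `capsule`,
#' `throat`, `stage0`..`stage7`, `filter`; the loaded dose and actuation
#' parameters come from a JSON config with fields `loaded_api_ug`,
#' `flow_lpm`, `inhalation_time_s`, `label`.
#'
#' @param path CSV file path.
#' @param config Path to the JSON run config.
#' @return An [impactor_run()].
#' @export
read_impactor_csv <- function(path, config) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("location", "mass_ug") %in% names(df)))
  cfg <- jsonlite::fromJSON(config)
  m <- stats::setNames(df$mass_ug, df$location)
  need <- c("device", "capsule", "throat", names(aci_cutoffs()))
  if (!setequal(names(m), need)) {
    stop(sprintf("impactor CSV must contain locations: %s", paste(need, collapse = ", ")),
         call. = FALSE)
  }
  impactor_run(mass_device = m[["device"]], mass_capsules = m[["capsule"]],
               mass_induction_port = m[["throat"]],
               mass_stages = m[names(aci_cutoffs())],
               loaded_api = cfg$loaded_api_ug,
               flow_rate = cfg$flow_lpm %||% 28.3,
               inhalation_time = cfg$inhalation_time_s %||% 4,
               label = cfg$label %||% "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
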