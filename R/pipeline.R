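#' Study protocol constants
#'
#' The physical constants of the characterization protocol the package
#' reproduces: paddle dissolution in 50 mL simulated lung medium with 5 mL
#' replenished withdrawals and a 1.5 mg drug dose; a 9 mL donor diffusion
#' cell with a 0.785 cm^2 membrane; an eight-stage cascade impactor run at
#' 28.3 L/min for 4 s per actuation; and the breathing pattern of a COPD
#' patient on a capsule inhaler (1.7 L inhaled over 3.2 s, oral route,
#' breath-holds of 5 and 10 s). The milling batch suspends 2.00 g of drug,
#' diluted to a final 500 mL.
#'
#' @return Named list of constants (units in the names).
#' @export
study_protocol <- function() {
  list(
    dose_ug = 1500,
    vessel_volume_ml = 50,
    sample_volume_ml = 5,
    donor_volume_ml = 9,
    membrane_area_cm2 = 0.785,
    flow_lpm = 28.3,
    inhalation_time_s = 4,
    iv_l = 1.7,
    t_in_s = 3.2,
    breath_holds_s = c(5, 10),
    suspension_mass_g = 2.00,
    suspension_volume_ml = 500
  )
}

#' Build a fully synthetic study configuration
#'
#' Generates one fixture of every kind for each sample label under `dir`
#' (dog-fooding the package's own readers) and returns the configuration
#' consumed by [run_study()]. Per-sample ground-truth parameters emulate the
#' trends of a leucine series: slightly growing particle size, falling
#' polarity and MMAD with increasing leucine content.
#'
#' @param dir Directory for the fixture files.
#' @param seed Integer seed (fixtures are deterministic given it).
#' @param noise_sd Relative noise switch passed to the generators; the
#'   default (NULL) uses each kind's realistic default, 0 gives noiseless
#'   fixtures.
#' @return A study configuration list.
#' @export
default_study_config <- function(dir, seed = 1, noise_sd = NULL) {
  samples <- list(
    nanoMX1_LEU0 = list(psd = list(median = 3.186, gsd = 1.7),
                        rheology = list(bulk = 0.177, tapped = 0.262),
                        angles = list(gamma_d = 42.34, gamma_p = 31.03),
                        xrpd = list(crystallinity = 0.71),
                        dissolution = list(f_inf = 0.75),
                        diffusion = list(flux_target = 61.80),
                        impactor = list(mmad = 2.33, ed_ug = 5980, ef = 0.7242)),
    nanoMX1_LEU0.5 = list(psd = list(median = 3.800, gsd = 1.7),
                          rheology = list(bulk = 0.156, tapped = 0.274),
                          angles = list(gamma_d = 36.15, gamma_p = 25.69),
                          xrpd = list(crystallinity = 0.52),
                          dissolution = list(f_inf = 0.85),
                          diffusion = list(flux_target = 86.90),
                          impactor = list(mmad = 1.74, ed_ug = 4240, ef = 0.8347)),
    nanoMX1_LEU1 = list(psd = list(median = 4.396, gsd = 1.7),
                        rheology = list(bulk = 0.147, tapped = 0.204),
                        angles = list(gamma_d = 33.39, gamma_p = 16.59),
                        xrpd = list(crystallinity = 0.53),
                        dissolution = list(f_inf = 0.80),
                        diffusion = list(flux_target = 73.58),
                        impactor = list(mmad = 1.55, ed_ug = 3400, ef = 0.7522))
  )
  files <- list()
  i <- 0L
  for (lab in names(samples)) {
    s <- samples[[lab]]
    i <- i + 1L
    sd_i <- seed + 100L * i  # independent streams per sample
    f <- list(
      psd = generate_fixture("psd", c(s$psd, label = lab), noise_sd, sd_i, dir)$files,
      rheology = generate_fixture("rheology", c(s$rheology, label = lab), noise_sd, sd_i + 1L, dir)$files,
      contact_angles = generate_fixture("contact_angles", c(s$angles, label = lab), noise_sd, sd_i + 2L, dir)$files,
      diffractogram = generate_fixture("diffractogram", c(s$xrpd, label = lab), noise_sd, sd_i + 3L, dir)$files,
      dissolution = generate_fixture("dissolution", c(s$dissolution, label = lab), noise_sd, sd_i + 4L, dir)$files,
      diffusion = generate_fixture("diffusion", c(s$diffusion, label = lab), noise_sd, sd_i + 5L, dir)$files,
      impactor = generate_fixture("impactor_run", c(s$impactor, label = lab), noise_sd, sd_i + 6L, dir)$files
    )
    files[[lab]] <- f
  }
  list(samples = files, protocol = study_protocol(), seed = seed,
       deposition = list(n_particles = 5000))
}

#' Run the full study reduction
#'
#' Reads every input referenced by the configuration, runs all reductions
#' (particle size, rheology, surface energy, crystallinity, release,
#' permeation, impactor aerodynamics) and the deposition simulation for both
#' protocol breath-holds, and returns the result tables plus a log of
#' flagged inconsistencies. Missing inputs are enumerated before any
#' computation. Deterministic given the configuration seed.
#'
#' @param config A configuration list as built by [default_study_config()].
#' @return List of class `study_report`: data frames `psd`, `rheology`,
#'   `surface_energy`, `crystallinity`, `release`, `permeation`, `impactor`,
#'   `deposition`, plus `flags` (character log) and `protocol`.
#' @export
run_study <- function(config) {
  if (is.null(config$samples) || length(config$samples) == 0L) {
    stop("empty study configuration: required inputs per sample are ",
         "psd, rheology, contact_angles, diffractogram, dissolution, ",
         "diffusion and impactor fixture paths", call. = FALSE)
  }
  all_paths <- unlist(lapply(config$samples, unlist), use.names = FALSE)
  missing <- all_paths[!file.exists(all_paths)]
  if (length(missing) > 0L) {
    stop("missing input files:\n  ", paste(missing, collapse = "\n  "), call. = FALSE)
  }
  pr <- config$protocol %||% study_protocol()
  flags <- character(0)
  note <- function(...) flags <<- c(flags, sprintf(...))

  psd_rows <- list(); rheo_rows <- list(); se_rows <- list()
  xr_rows <- list(); rel_rows <- list(); perm_rows <- list()
  imp_rows <- list(); dep_rows <- list()

  for (lab in names(config$samples)) {
    f <- config$samples[[lab]]
    q <- read_psd_csv(f$psd[1])[[1]]
    fitp <- lognormal_from_quantiles(q)
    psd_rows[[lab]] <- data.frame(
      label = lab, d10_um = q$d10, d50_um = q$d50, d90_um = q$d90,
      span = span(q),
      ssa_m2_g = specific_surface_area(fitp, true_density = 1.3))

    meas <- read_rheology_csv(f$rheology[1])[[1]]
    rr <- reduce_rheology(meas, average = "ratios")
    rr <- cbind(label = lab, rr)
    if (rr$carr_index >= 26 && rr$carr_index <= 31) {
      note("%s: Carr index %.2f labelled 'poor' on the pharmacopoeial scale; reports sometimes print 'very poor' here",
           lab, rr$carr_index)
    }
    rheo_rows[[lab]] <- rr

    se_rows[[lab]] <- surface_energy_table(read_contact_angles_csv(f$contact_angles[1]))

    dsamp <- read_xy(f$diffractogram[1], label = lab)
    dref <- read_xy(f$diffractogram[2], label = paste0(lab, "_pm"))
    xr_rows[[lab]] <- data.frame(
      label = lab,
      crystallinity_pct = crystallinity_percent(dsamp, dref))

    ts <- read_timeseries_csv(f$dissolution[1])
    run <- dissolution_run(ts$time_min, ts$value,
                           vessel_volume = pr$vessel_volume_ml,
                           sample_volume = pr$sample_volume_ml,
                           dose = pr$dose_ug)
    rel <- corrected_release_percent(run)
    rel_rows[[lab]] <- cbind(label = lab, rel)

    tsd <- read_timeseries_csv(f$diffusion[1])
    drun <- diffusion_run(tsd$time_min, tsd$value, area = pr$membrane_area_cm2,
                          donor_conc = pr$dose_ug / pr$donor_volume_ml)
    perm_rows[[lab]] <- cbind(label = lab, reduce_diffusion(drun))

    irun <- read_impactor_csv(f$impactor[1], f$impactor[2])
    am <- aerodynamic_metrics(irun)
    imp_rows[[lab]] <- cbind(label = lab, am,
                             loaded_ug = irun$loaded_api,
                             inhaled_volume_l = inhaled_volume(irun$flow_rate,
                                                              irun$inhalation_time))

    for (hold in pr$breath_holds_s) {
      dep <- simulate_deposition(
        c(am$mmad_um, am$gsd),
        breathing_pattern(inhaled_volume = pr$iv_l, inhalation_time = pr$t_in_s,
                          breath_hold = hold),
        n_particles = config$deposition$n_particles %||% 5000,
        seed = config$seed %||% 1)
      dep_rows[[paste(lab, hold)]] <- data.frame(
        label = lab, breath_hold_s = hold,
        extrathoracic = dep$extrathoracic, bronchial = dep$bronchial,
        acinar = dep$acinar, lung = dep$lung, exhaled = dep$exhaled,
        n_particles = dep$n_particles)
    }
  }
  note("permeability coefficients use Cd = dose/donor volume = %.1f ug/cm^3; raw-drug runs can be solubility-limited and need a measured Cd",
       pr$dose_ug / pr$donor_volume_ml)

  rb <- function(x) { out <- do.call(rbind, x); rownames(out) <- NULL; out }
  structure(list(psd = rb(psd_rows), rheology = rb(rheo_rows),
                 surface_energy = rb(se_rows), crystallinity = rb(xr_rows),
                 release = rb(rel_rows), permeation = rb(perm_rows),
                 impactor = rb(imp_rows), deposition = rb(dep_rows),
                 flags = flags, protocol = pr),
            class = "study_report")
}

#' Write a study report to disk
#'
#' One CSV per result table plus a plain-text summary including the flag
#' log.
#'
#' @param report A `study_report` from [run_study()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_study_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tabs <- c("psd", "rheology", "surface_energy", "crystallinity",
            "release", "permeation", "impactor", "deposition")
  paths <- character(0)
  for (t in tabs) {
    p <- file.path(dir, paste0(t, ".csv"))
    utils::write.csv(report[[t]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  sm <- file.path(dir, "summary.txt")
  con <- file(sm, "w")
  writeLines(c("Study reduction summary", "=======================", "",
               sprintf("samples: %s", paste(report$psd$label, collapse = ", ")),
               "", "flags:", paste0("  - ", report$flags)), con)
  close(con)
  invisible(c(paths, sm))
}
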