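# run code with a private RNG stream, restoring the caller's state
.with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic measurement fixture
#'
#' Every generator is the forward model of exactly one reduction in the
#' package, so a noiseless fixture round-trips through its reducer to the
#' generating ground truth. Parameter defaults emulate the spray-dried
#' nano-in-micro powders the package targets (micrometre volume medians,
#' 0.1--0.3 g/cm^3 densities, MMAD around 2 µm); noise defaults are Gaussian
#' with standard deviations of the order reported for triplicate instrument
#' measurements of such powders.
#'
#' Kinds:
#' * `"psd"`: laser-diffraction quantile triples from a lognormal
#'   (`median` µm, `gsd`); noise on each quantile, µm.
#' * `"rheology"`: bulk/tapped density replicates (`bulk`, `tapped` g/cm^3,
#'   `n_rep`); noise g/cm^3 (tapped kept >= bulk).
#' * `"contact_angles"`: water and diiodomethane contact angles forward-run
#'   through the Wu equation from (`gamma_d`, `gamma_p`); noise in degrees.
#' * `"diffractogram"`: sample and physical-mixture reference scans
#'   (3--40 deg, 0.01 deg step) with Gaussian drug peaks scaled by
#'   `crystallinity`; noise in counts.
#' * `"dissolution"`: first-order release sampled with the withdrawal
#'   protocol (`k_min` 1/min, `f_inf` plateau fraction); noise µg/mL on the
#'   measured concentrations.
#' * `"diffusion"`: cumulative permeated mass from a constant flux
#'   (`flux_target` µg/cm^2/h); noise µg.
#' * `"impactor_run"`: stage masses from a lognormal APSD (`mmad`, `gsd`)
#'   with `ed_ug` emitted, a `throat_fraction` in the induction port and an
#'   emitted fraction `ef`; multiplicative noise (relative SD).
#' * `"apsd"`: an (MMAD, GSD) pair; relative noise on the MMAD.
#'
#' @param kind Fixture kind, see above.
#' @param params Named list overriding the kind's parameter defaults.
#' @param noise_sd Noise level in the kind's units; 0 gives a deterministic,
#'   exactly invertible fixture. `NULL` uses the kind default.
#' @param seed Integer seed; generation is reproducible and does not disturb
#'   the caller's RNG state.
#' @param dir Optional directory: when given, the fixture is also written in
#'   the CSV/JSON schemas the package readers consume, plus a
#'   `*_truth.json` ground-truth file.
#' @return List with `kind`, `params`, `truth` (generating ground truth),
#'   `data` (in-memory records) and `files` (paths written, or `NULL`).
#' @export
#' @examples
#' fx <- generate_fixture("contact_angles", noise_sd = 0, seed = 7)
#' fx$data$theta_deg
generate_fixture <- function(kind = c("psd", "rheology", "contact_angles",
                                      "diffractogram", "dissolution",
                                      "diffusion", "impactor_run", "apsd"),
                             params = list(), noise_sd = NULL, seed = 1,
                             dir = NULL) {
  kind <- match.arg(kind)
  if (!is.null(noise_sd) && noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  fx <- .with_seed(seed, switch(kind,
    psd = .gen_psd(params, noise_sd),
    rheology = .gen_rheology(params, noise_sd),
    contact_angles = .gen_contact_angles(params, noise_sd),
    diffractogram = .gen_diffractogram(params, noise_sd),
    dissolution = .gen_dissolution(params, noise_sd),
    diffusion = .gen_diffusion(params, noise_sd),
    impactor_run = .gen_impactor_run(params, noise_sd),
    apsd = .gen_apsd(params, noise_sd)
  ))
  fx$kind <- kind
  fx$seed <- seed
  fx$files <- if (!is.null(dir)) .write_fixture(fx, dir) else NULL
  fx
}

.merge_params <- function(defaults, params) {
  stopifnot(all(names(params) %in% names(defaults)))
  defaults[names(params)] <- params
  defaults
}

.gen_psd <- function(params, noise_sd) {
  p <- .merge_params(list(median = 3.8, gsd = 1.7, label = "synthetic", n_rep = 3L), params)
  if (is.null(noise_sd)) noise_sd <- 0.05
  q0 <- quantiles_from_lognormal(lognormal_psd(p$median, p$gsd), label = p$label)
  reps <- lapply(seq_len(p$n_rep), function(i) {
    d <- sort(abs(c(q0$d10, q0$d50, q0$d90) + stats::rnorm(3, 0, noise_sd)))
    data.frame(label = p$label, replicate = i, d10_um = d[1], d50_um = d[2], d90_um = d[3])
  })
  list(params = p,
       truth = list(median = p$median, gsd = p$gsd,
                    d10 = q0$d10, d50 = q0$d50, d90 = q0$d90,
                    span = span(q0)),
       data = do.call(rbind, reps))
}

.gen_rheology <- function(params, noise_sd) {
  p <- .merge_params(list(bulk = 0.156, tapped = 0.274, label = "synthetic", n_rep = 3L), params)
  if (is.null(noise_sd)) noise_sd <- 0.01
  reps <- lapply(seq_len(p$n_rep), function(i) {
    b <- max(1e-3, p$bulk + stats::rnorm(1, 0, noise_sd))
    t <- max(b, p$tapped + stats::rnorm(1, 0, noise_sd))
    data.frame(label = p$label, replicate = i, bulk_g_cm3 = b, tapped_g_cm3 = t)
  })
  m <- density_measurement(p$bulk, p$tapped)
  list(params = p,
       truth = list(bulk = p$bulk, tapped = p$tapped,
                    hausner_ratio = hausner_ratio(m), carr_index = carr_index(m)),
       data = do.call(rbind, reps))
}

.gen_contact_angles <- function(params, noise_sd) {
  p <- .merge_params(list(gamma_d = 42.34, gamma_p = 31.03, label = "synthetic",
                          n_rep = 3L), params)
  if (is.null(noise_sd)) noise_sd <- 0.3
  th_w <- wu_contact_angle(probe_water(), p$gamma_d, p$gamma_p)
  th_d <- wu_contact_angle(probe_diiodomethane(), p$gamma_d, p$gamma_p)
  rows <- expand.grid(replicate = seq_len(p$n_rep),
                      liquid = c("water", "diiodomethane"),
                      stringsAsFactors = FALSE)
  rows$label <- p$label
  rows$theta_deg <- ifelse(rows$liquid == "water", th_w, th_d) +
    stats::rnorm(nrow(rows), 0, noise_sd)
  rows$theta_deg <- pmin(pmax(rows$theta_deg, 0), 179.9)
  e <- surface_energy(p$gamma_d, p$gamma_p)
  list(params = p,
       truth = list(gamma_d = p$gamma_d, gamma_p = p$gamma_p,
                    gamma_total = e$gamma_total, polarity = e$polarity,
                    cohesion_work = e$cohesion_work,
                    theta_water = th_w, theta_diiodomethane = th_d),
       data = rows[, c("label", "liquid", "theta_deg", "replicate")])
}

.gen_diffractogram <- function(params, noise_sd) {
  p <- .merge_params(list(crystallinity = 0.71, amplitude = 1000, sigma = 0.08,
                          baseline = 50, label = "synthetic"), params)
  if (is.null(noise_sd)) noise_sd <- 0
  tt <- seq(3, 40, by = 0.01)
  peaks <- mx_peaks()$centers
  shape <- rowSums(vapply(peaks, function(ctr) {
    exp(-(tt - ctr)^2 / (2 * p$sigma^2))
  }, numeric(length(tt))))
  mk <- function(scale) {
    y <- p$baseline + scale * p$amplitude * shape
    if (noise_sd > 0) y <- pmax(0, y + stats::rnorm(length(tt), 0, noise_sd))
    y
  }
  list(params = p,
       truth = list(crystallinity_pct = 100 * p$crystallinity),
       data = list(
         sample = diffractogram(tt, mk(p$crystallinity), label = p$label),
         reference = diffractogram(tt, mk(1), label = paste0(p$label, "_pm"))))
}

.gen_dissolution <- function(params, noise_sd) {
  p <- .merge_params(list(k_min = 0.1386, f_inf = 0.85, dose = 1500,
                          vessel_volume = 50, sample_volume = 5,
                          times = c(5, 10, 15, 30, 60), label = "synthetic"), params)
  if (is.null(noise_sd)) noise_sd <- 0
  released <- p$f_inf * (1 - exp(-p$k_min * p$times)) * p$dose   # ug in solution
  conc_corr <- released / p$vessel_volume
  ratio <- p$sample_volume / p$vessel_volume
  conc <- numeric(length(p$times))
  for (i in seq_along(conc)) {
    conc[i] <- conc_corr[i] - ratio * sum(conc[seq_len(i - 1)])
  }
  if (noise_sd > 0) conc <- pmax(0, conc + stats::rnorm(length(conc), 0, noise_sd))
  list(params = p,
       truth = list(k_min = p$k_min, f_inf = p$f_inf,
                    released_pct = 100 * released / p$dose),
       data = data.frame(time_min = p$times, value = conc))
}

.gen_diffusion <- function(params, noise_sd) {
  p <- .merge_params(list(flux_target = 86.90, area = 0.785, donor_conc = 1500 / 9,
                          times = seq(0, 60, by = 10), label = "synthetic"), params)
  if (is.null(noise_sd)) noise_sd <- 0
  mass <- p$flux_target * p$area * p$times / 60
  if (noise_sd > 0) {
    mass <- mass + stats::rnorm(length(mass), 0, noise_sd)
    mass <- cummax(pmax(mass, 0))
  }
  list(params = p,
       truth = list(flux = p$flux_target,
                    kp = permeability_coefficient(p$flux_target, p$donor_conc)),
       data = data.frame(time_min = p$times, value = mass))
}

.gen_impactor_run <- function(params, noise_sd) {
  p <- .merge_params(list(mmad = 2.0, gsd = 2.0, ed_ug = 5000,
                          throat_fraction = 0.15, ef = 0.75,
                          flow_rate = 28.3, inhalation_time = 4,
                          label = "synthetic"), params)
  if (is.null(noise_sd)) noise_sd <- 0.03
  cuts <- aci_cutoffs(p$flow_rate)
  throat <- p$throat_fraction * p$ed_ug
  sized <- p$ed_ug - throat
  cdf <- stats::plnorm(cuts, meanlog = log(p$mmad), sdlog = log(p$gsd))
  upper <- c(Inf, cuts[-length(cuts)])
  cdf_up <- stats::plnorm(upper, meanlog = log(p$mmad), sdlog = log(p$gsd))
  band <- cdf_up - cdf          # mass fraction caught on each location
  masses <- sized * band
  if (noise_sd > 0) {
    masses <- pmax(0, masses * (1 + stats::rnorm(length(masses), 0, noise_sd)))
    throat <- max(0, throat * (1 + stats::rnorm(1, 0, noise_sd)))
  }
  names(masses) <- names(cuts)
  loaded <- p$ed_ug / p$ef
  residual <- max(0, loaded - throat - sum(masses))
  run <- impactor_run(mass_device = residual / 2, mass_capsules = residual / 2,
                      mass_induction_port = throat, mass_stages = masses,
                      loaded_api = loaded, flow_rate = p$flow_rate,
                      inhalation_time = p$inhalation_time, label = p$label)
  list(params = p,
       truth = list(mmad = p$mmad, gsd = p$gsd, ed_ug = p$ed_ug,
                    ef_pct = 100 * p$ef, throat_fraction = p$throat_fraction),
       data = run)
}

.gen_apsd <- function(params, noise_sd) {
  p <- .merge_params(list(mmad = 2.0, gsd = 2.0, label = "synthetic"), params)
  if (is.null(noise_sd)) noise_sd <- 0
  mmad <- p$mmad * exp(stats::rnorm(1, 0, noise_sd))
  list(params = p,
       truth = list(mmad = p$mmad, gsd = p$gsd),
       data = c(mmad = mmad, gsd = p$gsd))
}

# write a fixture in the schemas the readers consume; returns file paths
.write_fixture <- function(fx, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stem <- file.path(dir, paste0(fx$kind, "_", fx$params$label))
  files <- character(0)
  wcsv <- function(df, path) {
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    path
  }
  files <- switch(fx$kind,
    psd = wcsv(fx$data, paste0(stem, ".csv")),
    rheology = wcsv(fx$data, paste0(stem, ".csv")),
    contact_angles = wcsv(fx$data, paste0(stem, ".csv")),
    dissolution = wcsv(fx$data, paste0(stem, ".csv")),
    diffusion = wcsv(fx$data, paste0(stem, ".csv")),
    apsd = wcsv(data.frame(mmad_um = fx$data[["mmad"]], gsd = fx$data[["gsd"]]),
                paste0(stem, ".csv")),
    diffractogram = {
      f1 <- paste0(stem, "_sample.xy")
      f2 <- paste0(stem, "_reference.xy")
      write_xy(fx$data$sample, f1)
      write_xy(fx$data$reference, f2)
      c(f1, f2)
    },
    impactor_run = {
      run <- fx$data
      df <- data.frame(
        location = c("device", "capsule", "throat", names(run$mass_stages)),
        mass_ug = c(run$mass_device, run$mass_capsules,
                    run$mass_induction_port, unname(run$mass_stages)))
      f1 <- wcsv(df, paste0(stem, ".csv"))
      f2 <- paste0(stem, "_config.json")
      jsonlite::write_json(list(loaded_api_ug = run$loaded_api,
                                flow_lpm = run$flow_rate,
                                inhalation_time_s = run$inhalation_time,
                                label = run$label),
                           f2, auto_unbox = TRUE, digits = NA)
      c(f1, f2)
    })
  truth_file <- paste0(stem, "_truth.json")
  jsonlite::write_json(fx$truth, truth_file, auto_unbox = TRUE, digits = NA)
  c(files, truth_file)
}
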