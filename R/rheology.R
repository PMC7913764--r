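#' Bulk/tapped density measurement
#'
#' One replicate of a tapped-density experiment. Tapping consolidates the
#' powder, so `tapped >= bulk` is enforced.
#'
#' @param bulk Bulk (poured) density, g/cm^3.
#' @param tapped Tapped density, g/cm^3.
#' @param replicate Replicate identifier.
#' @return Object of class `density_measurement`.
#' @export
density_measurement <- function(bulk, tapped, replicate = 1L) {
  stopifnot(is.numeric(bulk), is.numeric(tapped),
            length(bulk) == 1L, length(tapped) == 1L)
  if (bulk <= 0) stop("bulk density must be > 0", call. = FALSE)
  if (tapped < bulk) stop("tapped density cannot be below bulk density", call. = FALSE)
  structure(list(bulk = bulk, tapped = tapped, replicate = as.integer(replicate)),
            class = "density_measurement")
}

#' Hausner ratio
#'
#' `HR = rho_tapped / rho_bulk`, >= 1; larger values mean a more cohesive,
#' worse-flowing powder.
#'
#' @param m A [density_measurement()] object.
#' @return Dimensionless Hausner ratio.
#' @export
#' @examples
#' hausner_ratio(density_measurement(0.156, 0.274))
hausner_ratio <- function(m) {
  stopifnot(inherits(m, "density_measurement"))
  m$tapped / m$bulk
}

#' Carr (compressibility) index
#'
#' `CI = (rho_tapped - rho_bulk) / rho_tapped * 100`, in percent.
#'
#' @param m A [density_measurement()] object.
#' @return Carr index in percent, in `[0, 100)`.
#' @export
carr_index <- function(m) {
  stopifnot(inherits(m, "density_measurement"))
  (m$tapped - m$bulk) / m$tapped * 100
}

#' Pharmacopoeial flowability class from a Carr index
#'
#' Maps the Carr compressibility index to the standard pharmacopoeial
#' flow-character scale. Boundary values are assigned to the better
#' (lower-index) class.
#'
#' @param ci Carr index in percent, >= 0.
#' @return Character label, one of `"excellent"`, `"good"`, `"fair"`,
#'   `"passable"`, `"poor"`, `"very poor"`, `"very, very poor"`.
#' @export
#' @examples
#' flowability_class(c(5, 33, 43.09))
flowability_class <- function(ci) {
  stopifnot(is.numeric(ci), all(ci >= 0))
  breaks <- c(10, 15, 20, 25, 31, 37)
  labels <- c("excellent", "good", "fair", "passable", "poor",
              "very poor", "very, very poor")
  labels[findInterval(ci, breaks, left.open = TRUE) + 1L]
}

#' Reduce replicated density measurements
#'
#' Computes mean bulk/tapped densities, Hausner ratio, Carr index and the
#' flowability class from a set of replicates. Two averaging paths exist:
#' `"ratios"` (default) computes HR and CI per replicate and averages the
#' ratios; `"densities"` averages the densities first and takes the ratio of
#' means. The two differ slightly for noisy replicates.
#'
#' @param measurements List of [density_measurement()] objects.
#' @param average `"ratios"` or `"densities"`.
#' @return One-row data frame with columns `bulk`, `tapped`, `hausner_ratio`,
#'   `carr_index`, `flowability`, `n`.
#' @export
reduce_rheology <- function(measurements, average = c("ratios", "densities")) {
  average <- match.arg(average)
  stopifnot(length(measurements) >= 1L,
            all(vapply(measurements, inherits, TRUE, "density_measurement")))
  bulk <- vapply(measurements, `[[`, numeric(1), "bulk")
  tapped <- vapply(measurements, `[[`, numeric(1), "tapped")
  if (average == "ratios") {
    hr <- mean(vapply(measurements, hausner_ratio, numeric(1)))
    ci <- mean(vapply(measurements, carr_index, numeric(1)))
  } else {
    m <- density_measurement(mean(bulk), mean(tapped))
    hr <- hausner_ratio(m)
    ci <- carr_index(m)
  }
  data.frame(bulk = mean(bulk), tapped = mean(tapped),
             hausner_ratio = hr, carr_index = ci,
             flowability = flowability_class(ci), n = length(measurements))
}
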