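#' Laser-diffraction particle size quantiles
#'
#' Container for the volume-distribution quantiles reported by laser
#' diffraction: `D[0.1]`, `D[0.5]` (volume median) and `D[0.9]`, all in
#' micrometres.
#'
#' @param d10,d50,d90 Quantile diameters in µm; must satisfy
#'   `0 < d10 <= d50 <= d90`.
#' @param label Optional sample label.
#' @return An object of class `psd_quantiles`.
#' @seealso [span()], [quantiles_from_lognormal()]
#' @export
#' @examples
#' q <- psd_quantiles(1.834, 3.800, 7.389, label = "spray-dried")
#' span(q)
psd_quantiles <- function(d10, d50, d90, label = "") {
  stopifnot(is.numeric(d10), is.numeric(d50), is.numeric(d90),
            length(d10) == 1L, length(d50) == 1L, length(d90) == 1L)
  if (!(d10 > 0 && d50 > 0 && d90 > 0)) {
    stop("all quantiles must be strictly positive", call. = FALSE)
  }
  if (!(d10 <= d50 && d50 <= d90)) {
    stop("quantiles must be ordered: d10 <= d50 <= d90", call. = FALSE)
  }
  structure(list(d10 = d10, d50 = d50, d90 = d90, label = as.character(label)),
            class = "psd_quantiles")
}

#' @export
print.psd_quantiles <- function(x, ...) {
  cat(sprintf("PSD quantiles%s: D[0.1] = %.3g  D[0.5] = %.3g  D[0.9] = %.3g um  (Span = %.3g)\n",
              if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
              x$d10, x$d50, x$d90, span(x)))
  invisible(x)
}

#' Distribution Span
#'
#' Width measure of a volume particle-size distribution,
#' `Span = (D[0.9] - D[0.1]) / D[0.5]`. A high Span denotes a broad
#' distribution; Span < 2 is commonly taken as monodisperse enough for
#' accurate inhaler dosing.
#'
#' @param q A [psd_quantiles()] object.
#' @return Dimensionless Span.
#' @export
#' @examples
#' span(psd_quantiles(2.719, 9.913, 29.49))  # raw, broad powder
span <- function(q) {
  stopifnot(inherits(q, "psd_quantiles"))
  if (q$d50 == 0) stop("d50 must be non-zero", call. = FALSE)
  (q$d90 - q$d10) / q$d50
}

#' Parametric lognormal particle size distribution
#'
#' Parametric stand-in for a measured volume distribution: volume-median
#' diameter and geometric standard deviation.
#'
#' @param median Volume-median diameter in µm, > 0.
#' @param gsd Geometric standard deviation, >= 1.
#' @return An object of class `lognormal_psd`.
#' @export
lognormal_psd <- function(median, gsd) {
  stopifnot(is.numeric(median), is.numeric(gsd),
            length(median) == 1L, length(gsd) == 1L)
  if (median <= 0) stop("median must be > 0", call. = FALSE)
  if (gsd < 1) stop("gsd must be >= 1", call. = FALSE)
  structure(list(median = median, gsd = gsd), class = "lognormal_psd")
}

#' Quantile triple of a lognormal distribution
#'
#' `D[p] = median * gsd^z_p` with `z_p` the standard normal quantile, so the
#' 10/50/90% points use `z = -1.2816, 0, +1.2816`.
#'
#' @param p A [lognormal_psd()] object.
#' @param label Passed to the returned [psd_quantiles()].
#' @return A [psd_quantiles()] object.
#' @export
quantiles_from_lognormal <- function(p, label = "") {
  stopifnot(inherits(p, "lognormal_psd"))
  z <- stats::qnorm(c(0.1, 0.5, 0.9))
  d <- p$median * p$gsd^z
  psd_quantiles(d[1], d[2], d[3], label = label)
}

#' Fit a lognormal PSD to a quantile triple
#'
#' Least-squares fit of `log(d) = log(median) + log(gsd) * z` through the
#' three probit-transformed quantile points. For data that are exactly
#' lognormal this is exact.
#'
#' @param q A [psd_quantiles()] object.
#' @return A [lognormal_psd()] object.
#' @export
lognormal_from_quantiles <- function(q) {
  stopifnot(inherits(q, "psd_quantiles"))
  z <- stats::qnorm(c(0.1, 0.5, 0.9))
  y <- log(c(q$d10, q$d50, q$d90))
  fit <- stats::lm.fit(cbind(1, z), y)
  lognormal_psd(exp(fit$coefficients[[1]]), max(1, exp(fit$coefficients[[2]])))
}

#' Specific surface area of a spherical lognormal powder
#'
#' Mass (volume) specific surface area of spheres, `SSA = 6 / (rho * D32)`,
#' with `D32` the Sauter mean diameter of the lognormal distribution.
#'
#' Convention: `median` is the *volume*-median diameter (laser diffraction
#' reports volume distributions), for which the Hatch--Choate relation gives
#' `D32 = median * exp(-0.5 * log(gsd)^2)`. Equivalently, in terms of the
#' count-median diameter CMD = median * exp(-3 log(gsd)^2), this is the
#' classical `D32 = CMD * exp(2.5 * log(gsd)^2)`.
#'
#' Instrument SSA values depend on the optical model and true particle shape,
#' so this spherical estimate matches measured values only in order of
#' magnitude.
#'
#' @param p A [lognormal_psd()] object (diameters in µm).
#' @param true_density Particle (true) density in g/cm^3, > 0.
#' @return SSA in m^2/g.
#' @export
#' @examples
#' specific_surface_area(lognormal_psd(1, 1), 1)  # monodisperse 1 um sphere: 6 m2/g
specific_surface_area <- function(p, true_density) {
  stopifnot(inherits(p, "lognormal_psd"))
  if (!is.numeric(true_density) || length(true_density) != 1L || true_density <= 0) {
    stop("true_density must be a positive scalar (g/cm^3)", call. = FALSE)
  }
  d32 <- sauter_mean(p)
  # with d in um and rho in g/cm^3, 6/(rho d) is numerically m^2/g
  6 / (true_density * d32)
}

#' Sauter mean diameter of a lognormal PSD
#'
#' @param p A [lognormal_psd()] object with volume-median `median`.
#' @return D32 in µm.
#' @export
sauter_mean <- function(p) {
  stopifnot(inherits(p, "lognormal_psd"))
  p$median * exp(-0.5 * log(p$gsd)^2)
}
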