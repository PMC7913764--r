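#' X-ray powder diffractogram
#'
#' @param two_theta Strictly increasing 2-theta grid in degrees.
#' @param intensity Non-negative intensities (counts), same length.
#' @param label Sample label.
#' @return Object of class `diffractogram`.
#' @export
diffractogram <- function(two_theta, intensity, label = "") {
  stopifnot(is.numeric(two_theta), is.numeric(intensity))
  if (length(two_theta) != length(intensity)) {
    stop("two_theta and intensity must have the same length", call. = FALSE)
  }
  if (any(diff(two_theta) <= 0)) stop("two_theta must be strictly increasing", call. = FALSE)
  if (any(intensity < 0)) stop("intensities must be non-negative", call. = FALSE)
  structure(list(two_theta = two_theta, intensity = intensity,
                 label = as.character(label)),
            class = "diffractogram")
}

#' Characteristic peak set
#'
#' @param centers Peak centers in degrees 2-theta.
#' @param window Half-width of the integration window around each center,
#'   degrees (default 0.25).
#' @return Object of class `peak_set`.
#' @export
#' @seealso [mx_peaks()], [leu_peaks()]
peak_set <- function(centers, window = 0.25) {
  stopifnot(is.numeric(centers), length(centers) >= 1L,
            is.numeric(window), window > 0)
  structure(list(centers = sort(centers), window = window), class = "peak_set")
}

#' Default characteristic peak positions
#'
#' Meloxicam's crystalline reflections with the highest intensities
#' (6.6, 11.4, 13.1, 13.5, 15.1, 18.7, 19.3, 25.9, 26.4 deg 2-theta) and
#' l-leucine's (6.12, 24.39, 30.61 deg). Leucine peaks are excluded when
#' scoring drug crystallinity.
#'
#' @param window Integration half-width in degrees.
#' @return A [peak_set()].
#' @export
mx_peaks <- function(window = 0.25) {
  peak_set(c(6.6, 11.4, 13.1, 13.5, 15.1, 18.7, 19.3, 25.9, 26.4), window)
}

#' @rdname mx_peaks
#' @export
leu_peaks <- function(window = 0.25) {
  peak_set(c(6.12, 24.39, 30.61), window)
}

# trapezoidal area of one peak above a linear local baseline drawn
# between the window edges; negative net areas are clipped to 0
.peak_area <- function(two_theta, intensity, center, window) {
  lo <- center - window
  hi <- center + window
  if (lo < min(two_theta) || hi > max(two_theta)) {
    stop(sprintf("peak window [%.2f, %.2f] falls outside the scan range", lo, hi),
         call. = FALSE)
  }
  inside <- two_theta > lo & two_theta < hi
  ylo <- stats::approx(two_theta, intensity, xout = lo)$y
  yhi <- stats::approx(two_theta, intensity, xout = hi)$y
  x <- c(lo, two_theta[inside], hi)
  y <- c(ylo, intensity[inside], yhi)
  base <- ylo + (yhi - ylo) * (x - lo) / (hi - lo)
  max(0, pracma::trapz(x, y - base))
}

#' Integrated characteristic-peak area
#'
#' Sums, over the peaks of `p`, the trapezoidal area of the diffractogram
#' above a linear local baseline drawn between the edges of each
#' `center +/- window` interval. A flat offset therefore contributes nothing.
#'
#' @param d A [diffractogram()].
#' @param p A [peak_set()].
#' @param per_peak If `TRUE`, return the vector of per-peak areas instead of
#'   their sum.
#' @return Area in counts·degree (non-negative).
#' @export
integrate_peaks <- function(d, p, per_peak = FALSE) {
  stopifnot(inherits(d, "diffractogram"), inherits(p, "peak_set"))
  areas <- vapply(p$centers, function(ctr) {
    .peak_area(d$two_theta, d$intensity, ctr, p$window)
  }, numeric(1))
  if (per_peak) areas else sum(areas)
}

#' Residual crystallinity relative to a reference
#'
#' Crystallinity index of a processed sample relative to a physical-mixture
#' reference with the same drug loading, as the ratio of summed
#' characteristic-peak areas (times 100). With `method = "per_peak"` the mean
#' of per-peak area ratios is used instead; the two agree when all peaks are
#' attenuated uniformly.
#'
#' @param sample,reference [diffractogram()] objects on the same scan grid.
#' @param p A [peak_set()]; defaults to the drug's characteristic peaks.
#' @param method `"total_area"` (default) or `"per_peak"`.
#' @return Crystallinity in percent (clipped below at 0; values slightly
#'   above 100 are possible for noisy data and are not clipped).
#' @export
crystallinity_percent <- function(sample, reference, p = mx_peaks(),
                                  method = c("total_area", "per_peak")) {
  method <- match.arg(method)
  stopifnot(inherits(sample, "diffractogram"), inherits(reference, "diffractogram"))
  if (!isTRUE(all.equal(sample$two_theta, reference$two_theta))) {
    stop("sample and reference must share the same 2-theta grid", call. = FALSE)
  }
  if (method == "total_area") {
    ref <- integrate_peaks(reference, p)
    if (ref <= 0) stop("reference peak area is zero", call. = FALSE)
    ratio <- integrate_peaks(sample, p) / ref
  } else {
    a_s <- integrate_peaks(sample, p, per_peak = TRUE)
    a_r <- integrate_peaks(reference, p, per_peak = TRUE)
    if (all(a_r <= 0)) stop("reference peak areas are all zero", call. = FALSE)
    keep <- a_r > 0
    ratio <- mean(a_s[keep] / a_r[keep])
  }
  max(0, 100 * ratio)
}
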