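#' Randomized asymmetric airway tree geometry
#'
#' Statistical description of a dichotomously branching airway tree: one row
#' per generation class with median diameter and length (cm), the geometric
#' standard deviation used when sampling individual airways, uniform ranges
#' for the branching angle (relative to the parent axis) and the gravity
#' angle (airway axis relative to the horizontal plane), and a region label
#' (`"bronchial"` conducting airways or `"acinar"` gas-exchange region).
#' Generation `g` holds `2^(g-1)` parallel airways.
#'
#' @param generations Data frame with columns `generation`, `region`,
#'   `diameter_cm`, `length_cm`, `gsd`, `branch_min_deg`, `branch_max_deg`,
#'   `gravity_min_deg`, `gravity_max_deg`.
#' @param frc_cm3 Functional residual capacity the tree is scaled to, cm^3.
#'   The air volume not contained in the duct lumina is attributed to
#'   alveoli attached to the acinar generations, proportionally to their
#'   airway counts.
#' @return Object of class `airway_geometry`.
#' @export
#' @seealso [default_airway_geometry()], [single_tube_geometry()]
airway_geometry <- function(generations, frc_cm3 = 3300) {
  need <- c("generation", "region", "diameter_cm", "length_cm", "gsd",
            "branch_min_deg", "branch_max_deg", "gravity_min_deg", "gravity_max_deg")
  stopifnot(is.data.frame(generations), all(need %in% names(generations)))
  g <- generations[order(generations$generation), need]
  if (!all(g$generation == seq_len(nrow(g)))) {
    stop("generations must be numbered 1..G without gaps", call. = FALSE)
  }
  if (!all(g$region %in% c("bronchial", "acinar"))) {
    stop("region must be 'bronchial' or 'acinar'", call. = FALSE)
  }
  if (any(g$diameter_cm <= 0) || any(g$length_cm <= 0)) {
    stop("diameters and lengths must be positive", call. = FALSE)
  }
  br <- g$region == "bronchial"
  if (any(diff(g$diameter_cm[br]) > 1e-12) || any(diff(g$length_cm[br]) > 1e-12)) {
    stop("median diameters and lengths must be non-increasing across bronchial generations",
         call. = FALSE)
  }
  if (any(g$gsd < 1)) stop("airway gsd must be >= 1", call. = FALSE)
  if (frc_cm3 <= 0) stop("frc_cm3 must be > 0", call. = FALSE)
  g$n_airways <- 2^(g$generation - 1)
  structure(list(generations = g, frc_cm3 = frc_cm3), class = "airway_geometry")
}

#' @export
print.airway_geometry <- function(x, ...) {
  g <- x$generations
  cat(sprintf("Airway geometry: %d generations (%d bronchial, %d acinar), FRC = %g cm^3\n",
              nrow(g), sum(g$region == "bronchial"), sum(g$region == "acinar"),
              x$frc_cm3))
  invisible(x)
}

#' Default whole-lung geometry
#'
#' Reads the airway-tree parameter table shipped with the package: 24
#' generation classes (16 bronchial, 8 acinar) with Weibel-type median
#' dimensions rescaled to a functional residual capacity of 3300 cm^3,
#' log-normal inter-airway variability and uniform angle ranges emulating an
#' asymmetric branching tree.
#'
#' @param file Optional path to a geometry JSON file with the same schema.
#' @return An [airway_geometry()].
#' @export
default_airway_geometry <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "airway_geometry.json", package = "aerodpi")
  }
  if (!nzchar(file) || !file.exists(file)) stop("geometry file not found", call. = FALSE)
  j <- jsonlite::fromJSON(file)
  airway_geometry(as.data.frame(j$generations), frc_cm3 = j$frc_cm3)
}

#' Degenerate single-tube geometry
#'
#' One deterministic airway segment with fixed angles and no inter-airway
#' variability. Used to compare the Monte Carlo simulator against analytic
#' single-tube deposition formulas.
#'
#' @param diameter_cm,length_cm Tube dimensions, cm.
#' @param branch_deg Branching angle, degrees (0 = no bend, no impaction).
#' @param gravity_deg Tube axis angle from the horizontal plane
#'   (0 = horizontal, maximal sedimentation).
#' @param region Region label for the tally.
#' @return An [airway_geometry()] with a single generation and FRC equal to
#'   the tube volume (every simulated particle traverses the full tube).
#' @export
single_tube_geometry <- function(diameter_cm, length_cm, branch_deg = 0,
                                 gravity_deg = 0, region = "bronchial") {
  df <- data.frame(generation = 1L, region = region,
                   diameter_cm = diameter_cm, length_cm = length_cm, gsd = 1,
                   branch_min_deg = branch_deg, branch_max_deg = branch_deg,
                   gravity_min_deg = gravity_deg, gravity_max_deg = gravity_deg)
  airway_geometry(df, frc_cm3 = pi / 4 * diameter_cm^2 * length_cm)
}

#' Per-generation gas volumes of the tree
#'
#' Duct volume of each generation (`n_airways * pi/4 * d^2 * L` from the
#' median dimensions) plus the alveolar volume attached to the acinar
#' generations, which absorbs the difference between the FRC and the total
#' duct volume in proportion to airway counts.
#'
#' @param geometry An [airway_geometry()].
#' @return Data frame with `generation`, `duct_cm3`, `alveolar_cm3`,
#'   `total_cm3`, `cumulative_cm3`.
#' @export
generation_volumes <- function(geometry) {
  stopifnot(inherits(geometry, "airway_geometry"))
  g <- geometry$generations
  duct <- g$n_airways * pi / 4 * g$diameter_cm^2 * g$length_cm
  alv <- numeric(nrow(g))
  ac <- g$region == "acinar"
  spare <- geometry$frc_cm3 - sum(duct)
  if (any(ac) && spare > 0) {
    w <- g$n_airways[ac]
    alv[ac] <- spare * w / sum(w)
  }
  total <- duct + alv
  data.frame(generation = g$generation, duct_cm3 = duct, alveolar_cm3 = alv,
             total_cm3 = total, cumulative_cm3 = cumsum(total))
}

#' Sample one random airway path
#'
#' Draws a single root-to-terminal path through the tree: per generation,
#' diameter and length are drawn log-normally around the class medians and
#' the branching and gravity angles uniformly within their ranges.
#'
#' @param geometry An [airway_geometry()].
#' @param seed Optional integer seed for reproducibility.
#' @return Data frame with one row per generation: `generation`, `region`,
#'   `diameter_cm`, `length_cm`, `branch_deg`, `gravity_deg`.
#' @export
sample_airway_path <- function(geometry, seed = NULL) {
  stopifnot(inherits(geometry, "airway_geometry"))
  if (!is.null(seed)) set.seed(seed)
  g <- geometry$generations
  n <- nrow(g)
  data.frame(
    generation = g$generation,
    region = g$region,
    diameter_cm = g$diameter_cm * g$gsd^stats::rnorm(n),
    length_cm = g$length_cm * g$gsd^stats::rnorm(n),
    branch_deg = stats::runif(n, g$branch_min_deg, g$branch_max_deg),
    gravity_deg = stats::runif(n, g$gravity_min_deg, g$gravity_max_deg)
  )
}
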