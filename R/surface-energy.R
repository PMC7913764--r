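#' Probe liquid for contact-angle goniometry
#'
#' A probe liquid is characterized by the dispersive (`gamma_d`) and polar
#' (`gamma_p`) components of its surface tension, in mN/m. The two default
#' liquids shipped with the package are the classical pair used for the
#' harmonic-mean method: distilled water (gamma_d = 22.6, gamma_p = 50.2) and
#' diiodomethane (gamma_d = 49.0, gamma_p = 1.8).
#'
#' @param name Liquid name.
#' @param gamma_d,gamma_p Dispersive and polar surface-tension components,
#'   mN/m, non-negative with a positive sum.
#' @return Object of class `probe_liquid`.
#' @export
#' @examples
#' probe_water()
#' probe_liquid("formamide", 39.5, 18.7)
probe_liquid <- function(name, gamma_d, gamma_p) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(gamma_d), is.numeric(gamma_p))
  if (gamma_d < 0 || gamma_p < 0 || gamma_d + gamma_p <= 0) {
    stop("surface-tension components must be non-negative with positive total",
         call. = FALSE)
  }
  structure(list(name = name, gamma_d = gamma_d, gamma_p = gamma_p,
                 gamma_total = gamma_d + gamma_p),
            class = "probe_liquid")
}

#' @rdname probe_liquid
#' @export
probe_water <- function() probe_liquid("water", gamma_d = 22.6, gamma_p = 50.2)

#' @rdname probe_liquid
#' @export
probe_diiodomethane <- function() probe_liquid("diiodomethane", gamma_d = 49.0, gamma_p = 1.8)

#' A single contact-angle observation
#'
#' @param liquid A [probe_liquid()].
#' @param theta Contact angle in degrees, in `[0, 180)`.
#' @return Object of class `contact_angle`.
#' @export
contact_angle <- function(liquid, theta) {
  stopifnot(inherits(liquid, "probe_liquid"), is.numeric(theta), length(theta) == 1L)
  if (theta < 0 || theta >= 180) stop("theta must be in [0, 180) degrees", call. = FALSE)
  structure(list(liquid = liquid, theta = theta), class = "contact_angle")
}

# harmonic-mean interaction term, with the 0/0 -> 0 limit convention
.hm <- function(a, b) ifelse(a + b == 0, 0, a * b / (a + b))

#' Wu harmonic-mean equation residual
#'
#' The Wu equation relates the contact angle theta of a probe liquid on a
#' solid to the dispersive/polar surface free-energy components of both
#' phases:
#' `(1 + cos theta) gamma_l = 4 [ gsd*gld/(gsd+gld) + gsp*glp/(gsp+glp) ]`.
#' This function returns left-hand side minus right-hand side, which is zero
#' iff the equation holds.
#'
#' @param theta Contact angle in degrees.
#' @param liquid A [probe_liquid()].
#' @param gsd,gsp Candidate solid dispersive and polar components, mN/m, >= 0.
#' @return Residual in mN/m.
#' @export
wu_residual <- function(theta, liquid, gsd, gsp) {
  stopifnot(inherits(liquid, "probe_liquid"), all(gsd >= 0), all(gsp >= 0))
  lhs <- (1 + cos(theta * pi / 180)) * liquid$gamma_total
  rhs <- 4 * (.hm(gsd, liquid$gamma_d) + .hm(gsp, liquid$gamma_p))
  lhs - rhs
}

#' Forward contact angle predicted by the Wu equation
#'
#' Inverts the Wu equation for theta at known solid components. Errors when
#' the solid is so high-energy that the liquid wets it completely
#' (`cos theta > 1`): no finite contact angle exists and the solid cannot be
#' characterized with that liquid.
#'
#' @inheritParams wu_residual
#' @return Contact angle in degrees.
#' @export
wu_contact_angle <- function(liquid, gsd, gsp) {
  stopifnot(inherits(liquid, "probe_liquid"), gsd >= 0, gsp >= 0)
  cost <- 4 * (.hm(gsd, liquid$gamma_d) + .hm(gsp, liquid$gamma_p)) /
    liquid$gamma_total - 1
  if (cost > 1) {
    stop(sprintf("complete wetting of (%.3g, %.3g) by %s: no contact angle exists",
                 gsd, gsp, liquid$name), call. = FALSE)
  }
  acos(max(-1, cost)) * 180 / pi
}

#' Solid surface free energy record
#'
#' @param gamma_d,gamma_p Dispersive and polar components, mN/m, >= 0.
#' @param label Sample label.
#' @return Object of class `surface_energy` with derived fields
#'   `gamma_total = gamma_d + gamma_p`, `polarity = gamma_p/gamma_total*100`
#'   (percent) and `cohesion_work = 2*gamma_total` (mN/m).
#' @export
surface_energy <- function(gamma_d, gamma_p, label = "") {
  stopifnot(is.numeric(gamma_d), is.numeric(gamma_p), gamma_d >= 0, gamma_p >= 0)
  gamma_d <- unname(gamma_d)
  gamma_p <- unname(gamma_p)
  gs <- gamma_d + gamma_p
  structure(list(gamma_d = gamma_d, gamma_p = gamma_p, gamma_total = gs,
                 polarity = if (gs > 0) gamma_p / gs * 100 else 0,
                 cohesion_work = 2 * gs, label = as.character(label)),
            class = "surface_energy")
}

#' @export
print.surface_energy <- function(x, ...) {
  cat(sprintf(
    "Surface free energy%s: gamma_d = %.2f  gamma_p = %.2f  gamma = %.2f mN/m  (Wc = %.2f mN/m, Pol = %.2f%%)\n",
    if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
    x$gamma_d, x$gamma_p, x$gamma_total, x$cohesion_work, x$polarity))
  invisible(x)
}

#' Solve the Wu equations for the solid surface free energy
#'
#' Inverts the two-liquid Wu harmonic-mean system for the dispersive and
#' polar surface free-energy components of a solid, given one contact angle
#' per probe liquid (conventionally one polar liquid such as water and one
#' apolar liquid such as diiodomethane). A damped Newton iteration with an
#' analytic Jacobian is run from multiple starting points on a coarse grid
#' over `[0, 100]^2` mN/m; iterates are clipped to `[0, 200]^2`.
#'
#' @param obs_polar,obs_apolar Two [contact_angle()] observations on distinct
#'   probe liquids, at least one of which must have a polar component.
#' @param tol Convergence tolerance on the maximum absolute residual, mN/m.
#' @param label Sample label attached to the result.
#' @return A [surface_energy()] object.
#' @export
#' @examples
#' w <- contact_angle(probe_water(), 30.3)
#' d <- contact_angle(probe_diiodomethane(), 22.7)
#' solve_wu(w, d)
solve_wu <- function(obs_polar, obs_apolar, tol = 1e-10, label = "") {
  stopifnot(inherits(obs_polar, "contact_angle"), inherits(obs_apolar, "contact_angle"))
  l1 <- obs_polar$liquid
  l2 <- obs_apolar$liquid
  if (isTRUE(all.equal(c(l1$gamma_d, l1$gamma_p), c(l2$gamma_d, l2$gamma_p)))) {
    stop("the two probe liquids are identical: the system is underdetermined",
         call. = FALSE)
  }
  if (l1$gamma_p == 0 && l2$gamma_p == 0) {
    stop("at least one probe liquid must have a polar component", call. = FALSE)
  }

  lhs <- c((1 + cos(obs_polar$theta * pi / 180)) * l1$gamma_total,
           (1 + cos(obs_apolar$theta * pi / 180)) * l2$gamma_total)
  ld <- c(l1$gamma_d, l2$gamma_d)
  lp <- c(l1$gamma_p, l2$gamma_p)

  fres <- function(x) lhs - 4 * (.hm(x[1], ld) + .hm(x[2], lp))
  jac <- function(x) {
    # d/dx of 4*x*a/(x+a) is 4*a^2/(x+a)^2 (0 when both are 0)
    j1 <- ifelse(x[1] + ld == 0, 0, -4 * ld^2 / (x[1] + ld)^2)
    j2 <- ifelse(x[2] + lp == 0, 0, -4 * lp^2 / (x[2] + lp)^2)
    cbind(j1, j2)
  }

  newton <- function(x0) {
    x <- x0
    r <- fres(x)
    for (it in seq_len(100)) {
      J <- jac(x)
      step <- tryCatch(solve(J, -r), error = function(e) NULL)
      if (is.null(step)) return(NULL)
      lambda <- 1
      repeat {
        xn <- pmin(pmax(x + lambda * step, 0), 200)
        rn <- fres(xn)
        if (sum(abs(rn)) < sum(abs(r)) || lambda < 1e-6) break
        lambda <- lambda / 2
      }
      x <- xn; r <- rn
      if (max(abs(r)) < tol) return(list(x = x, resid = r))
    }
    NULL
  }

  starts <- as.matrix(expand.grid(gd = seq(5, 95, by = 15), gp = seq(0, 90, by = 15)))
  roots <- list()
  for (i in seq_len(nrow(starts))) {
    sol <- newton(starts[i, ])
    if (!is.null(sol)) roots[[length(roots) + 1L]] <- sol
  }
  if (length(roots) == 0L) {
    stop(sprintf(paste0("Wu system did not converge in [0, 200]^2 ",
                        "(angles %.2f deg on %s, %.2f deg on %s)"),
                 obs_polar$theta, l1$name, obs_apolar$theta, l2$name),
         call. = FALSE)
  }
  xs <- t(vapply(roots, `[[`, numeric(2), "x"))
  res <- vapply(roots, function(r) sum(abs(r$resid)), numeric(1))
  best <- which.min(res)
  distinct <- sum(!duplicated(round(xs, 4)))
  if (distinct > 1L) {
    warning("multiple Wu roots found; returning the one with the smallest residual")
  }
  surface_energy(xs[best, 1], xs[best, 2], label = label)
}

#' Polarity of a surface
#'
#' Polar fraction of the total surface free energy, in percent:
#' `Pol = gamma_p / gamma_total * 100`.
#'
#' @param gamma_p Polar component, mN/m.
#' @param gamma_total Total surface free energy, mN/m, > 0.
#' @return Percent polarity.
#' @export
polarity <- function(gamma_p, gamma_total) {
  stopifnot(is.numeric(gamma_p), is.numeric(gamma_total))
  if (any(gamma_total <= 0)) stop("gamma_total must be > 0", call. = FALSE)
  gamma_p / gamma_total * 100
}

#' Work of cohesion
#'
#' Energy per unit area required to separate a column of a material,
#' `Wc = 2 * gamma_s`.
#'
#' @param gamma_total Total surface free energy, mN/m, >= 0.
#' @return Cohesion work in mN/m.
#' @export
cohesion_work <- function(gamma_total) {
  stopifnot(is.numeric(gamma_total), all(gamma_total >= 0))
  2 * gamma_total
}
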