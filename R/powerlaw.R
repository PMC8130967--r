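# Two-parameter power-law surrogate for the effective diffusivity of a
# finite-size tracer amid obstacles:
#   tr(D0)/(d * D_free) = (1 - phi/phi_c)^mu / (1 - phi),  phi < phi_c,
# where phi is the inaccessible area fraction, phi_c the critical
# (trapping/percolation) fraction and mu an empirical exponent.

#' Physical constants for the free-solution diffusivity
#'
#' Defaults describe a 10 nm-radius vesicle in water-like cytosol at
#' body temperature.  The Boltzmann constant defaults to the CODATA
#' value 1.380649e-23 J/K.
#'
#' @param k_B Boltzmann constant, J/K.
#' @param T_K absolute temperature, K.
#' @param eta dynamic viscosity, Pa s.
#' @param R_m particle (vesicle) radius, m.
#' @return object of class `physical_constants`.
#' @export
physical_constants <- function(k_B = 1.380649e-23, T_K = 310.15,
                               eta = 0.692e-3, R_m = 10e-9) {
  stopifnot(k_B > 0, T_K >= 0, eta > 0, R_m > 0)
  structure(list(k_B = k_B, T_K = T_K, eta = eta, R_m = R_m),
            class = "physical_constants")
}

#' Stokes-Einstein free-solution diffusivity
#'
#' `D = k_B T / (6 pi eta R)`, converted from m^2/s to um^2/s.
#'
#' @param c a [physical_constants()] object.
#' @return diffusivity in um^2/s.
#' @export
stokes_einstein <- function(c = physical_constants()) {
  stopifnot(inherits(c, "physical_constants"))
  c$k_B * c$T_K / (6 * pi * c$eta * c$R_m) * 1e12
}

# model: D_rel(phi) for parameters p = c(phi_c, mu)
.powerlaw_eval <- function(phi, phi_c, mu, floor = 0) {
  out <- ifelse(phi < phi_c,
                (1 - phi / phi_c)^mu / (1 - phi),
                floor)
  pmax(out, floor)
}

#' Fit the two-parameter power law to (phi, D_rel) points
#'
#' Constrained nonlinear least squares (Levenberg-Marquardt with box
#' constraints `0 <= phi_c <= 1`, `mu >= 0`), multistarted over five
#' initial points to avoid boundary traps; the best-SSE solution is
#' kept.  `D_rel` is the relative diffusivity `tr(D0)/(d * D_free)`.
#'
#' @param phi inaccessible area fractions in `[0, 1)`.
#' @param D_rel matching relative diffusivities in `[0, 1]`.
#' @return object of class `power_law`: `phi_c`, `mu`, `r_squared`,
#'   `n_points`.
#' @export
fit_power_law <- function(phi, D_rel) {
  stopifnot(length(phi) == length(D_rel), length(phi) >= 3,
            all(phi >= 0), all(phi < 1),
            all(D_rel >= 0), all(D_rel <= 1 + 1e-8))
  if (diff(range(phi)) < 1e-12)
    stop("degenerate fit input: all phi equal")
  resid_fun <- function(p) D_rel - .powerlaw_eval(phi, p[1], p[2])
  starts <- rbind(c(min(1, max(phi) + 0.1), 1),
                  c(min(1, max(phi) + 0.3), 1.5),
                  c(0.62, 1.2),
                  c(0.9, 2),
                  c(0.5, 0.8))
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    ft <- tryCatch(
      minpack.lm::nls.lm(par = starts[s, ], fn = resid_fun,
                         lower = c(0, 0), upper = c(1, 50),
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-15, ptol = 1e-15)),
      error = function(e) NULL)
    if (is.null(ft)) next
    sse <- sum(resid_fun(ft$par)^2)
    if (is.null(best) || sse < best$sse)
      best <- list(par = ft$par, sse = sse)
  }
  if (is.null(best)) stop("power-law fit failed from all starting points")
  ss_tot <- sum((D_rel - mean(D_rel))^2)
  structure(list(phi_c = best$par[1], mu = best$par[2],
                 r_squared = 1 - best$sse / ss_tot,
                 n_points = length(phi)),
            class = "power_law")
}

#' @export
print.power_law <- function(x, ...) {
  cat(sprintf("Power law: phi_c = %.4f, mu = %.4f (R^2 = %.4f, n = %d)\n",
              x$phi_c, x$mu, x$r_squared, x$n_points))
  invisible(x)
}

#' Predict the effective diffusivity from the power law
#'
#' `D = D_invitro (1 - phi/phi_c)^mu / (1 - phi)` for `phi < phi_c`;
#' tracers are trapped at `phi >= phi_c`, where the configured floor
#' (default 0) is returned.
#'
#' @param phi inaccessible area fraction(s) in `[0, 1]`.
#' @param p a `power_law` fit (or list with `phi_c`, `mu`).
#' @param D_invitro free-solution diffusivity in um^2/s.
#' @param floor relative diffusivity floor for trapped states (e.g.
#'   `1e-9` to keep a macroscopic stiffness matrix nonsingular).
#' @return diffusivity in um^2/s (vectorized over `phi`).
#' @export
predict_D0 <- function(phi, p, D_invitro = 1, floor = 0) {
  stopifnot(all(phi >= 0), all(phi <= 1))
  D_invitro * .powerlaw_eval(phi, p$phi_c, p$mu, floor = floor)
}

#' Write / read power-law parameters as JSON
#' @param p a `power_law`.
#' @param path JSON file path.
#' @return `path` invisibly; `read_power_law` returns a `power_law`.
#' @export
write_power_law <- function(p, path) {
  jsonlite::write_json(unclass(p), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_power_law
#' @export
read_power_law <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = TRUE),
            class = "power_law")
}
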