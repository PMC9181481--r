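#' Parametric vacuum-interface-bulk free energy surface
#'
#' Builds the one-dimensional model potential used as ground truth by the
#' synthetic umbrella-sampling engine.  The surface is even in `z` and has
#' three regimes along the slab normal: a vacuum plateau at `g_vacuum`
#' (the gas-phase reference, 0 by convention), a bulk-water plateau at
#' `g_bulk` (which plays the role of the hydration free energy of the
#' generated species), and a pair of mirrored Gaussian interface wells at
#' `+/- z_interface` whose depth is calibrated so that the global minimum
#' of the surface equals `g_surface_min` (the gas-to-surface free energy).
#'
#' The vacuum-to-bulk transition uses a compact-support quintic smoothstep
#' centred at `z_interface` with half-width `w_switch`, so the plateaus are
#' attained exactly: `G(0) = g_bulk` and `G(z) = g_vacuum` for
#' `|z| >= z_interface + w_switch`.  The well amplitude is solved
#' numerically (monotone root find on the grid minimum) rather than set to
#' `g_surface_min` directly, because the well sits on the shoulder of the
#' switching region.
#'
#' @param g_bulk Bulk plateau level, kJ/mol.
#' @param g_surface_min Interface well level (global minimum), kJ/mol.
#'   Must not lie above the plateau minimum; if it equals the background
#'   minimum no well is added.
#' @param g_vacuum Vacuum plateau level, kJ/mol (default 0, the gas-phase
#'   reference).
#' @param z_interface Position of the interface well centre, nm (> 0).
#' @param w_interface Gaussian half-width of the well, nm.
#' @param w_switch Half-width of the smoothstep switching region, nm.
#' @param z_max Half-extent of the coordinate domain, nm.
#' @return An object of class `potential_model`.
#' @examples
#' m <- potential_model(g_bulk = -4, g_surface_min = -10, z_interface = 1.5)
#' pmf_value(m, c(0, 1.5, 3.9))
#' @export
potential_model <- function(g_bulk, g_surface_min, g_vacuum = 0,
                            z_interface = 1.6, w_interface = 0.25,
                            w_switch = 0.2, z_max = 4.0) {
  stopifnot(is.numeric(g_bulk), length(g_bulk) == 1L, is.finite(g_bulk),
            is.numeric(g_surface_min), length(g_surface_min) == 1L,
            is.finite(g_surface_min),
            is.numeric(g_vacuum), length(g_vacuum) == 1L, is.finite(g_vacuum))
  if (z_interface <= 0) abort("`z_interface` must be > 0 nm.")
  if (w_interface <= 0 || w_switch <= 0) {
    abort("`w_interface` and `w_switch` must be > 0 nm.")
  }
  if (z_interface + w_switch >= z_max) {
    abort("switching region must close before `z_max`: need z_interface + w_switch < z_max.")
  }

  model <- structure(
    list(g_vacuum = g_vacuum, g_bulk = g_bulk,
         g_surface_min = g_surface_min,
         z_interface = z_interface, w_interface = w_interface,
         w_switch = w_switch, z_max = z_max, well_depth = 0),
    class = "potential_model"
  )

  # Calibrate the well amplitude so the grid minimum hits g_surface_min.
  zg <- seq(0, z_max, length.out = 4001L)
  bg <- .pmf_background(model, zg)
  min_bg <- min(bg)
  if (g_surface_min > min_bg + 1e-9) {
    warn(paste0("`g_surface_min` (", g_surface_min,
                ") lies above the plateau minimum (", round(min_bg, 6),
                "); no interface well added."))
  } else if (g_surface_min < min_bg - 1e-12) {
    bg_at_wells <- .pmf_background(model, z_interface)
    a_hi <- bg_at_wells - g_surface_min + abs(g_bulk - g_vacuum) + 1
    f <- function(a) {
      model$well_depth <- a
      .pmf_min(model, zg) - g_surface_min
    }
    model$well_depth <- stats::uniroot(f, c(0, a_hi), tol = 1e-12)$root
  }
  model$z_min_true <- .pmf_argmin(model, zg)
  model
}

# Quintic smoothstep: 0 -> 1 on t in [0, 1], C2 at both ends.
.smoothstep <- function(t) t * t * t * (t * (6 * t - 15) + 10)
.smoothstep_deriv <- function(t) 30 * t * t * (t - 1) * (t - 1)

# Even switch S(z): 1 in the slab, 0 in vacuum, smoothstep in between.
.pmf_switch <- function(model, z) {
  a <- abs(z)
  lo <- model$z_interface - model$w_switch
  hi <- model$z_interface + model$w_switch
  s <- numeric(length(a))
  s[a <= lo] <- 1
  mid <- a > lo & a < hi
  s[mid] <- .smoothstep((hi - a[mid]) / (2 * model$w_switch))
  s
}

.pmf_background <- function(model, z) {
  model$g_vacuum + (model$g_bulk - model$g_vacuum) * .pmf_switch(model, z)
}

.pmf_wells <- function(model, z) {
  w2 <- 2 * model$w_interface^2
  model$well_depth * (exp(-(z - model$z_interface)^2 / w2) +
                        exp(-(z + model$z_interface)^2 / w2))
}

.pmf_value_raw <- function(model, z) {
  .pmf_background(model, z) - .pmf_wells(model, z)
}

.pmf_min <- function(model, zg) {
  v <- .pmf_value_raw(model, zg)
  i <- which.min(v)
  lo <- zg[max(1L, i - 2L)]; hi <- zg[min(length(zg), i + 2L)]
  stats::optimize(function(z) .pmf_value_raw(model, z), c(lo, hi),
                  tol = 1e-12)$objective
}

.pmf_argmin <- function(model, zg) {
  v <- .pmf_value_raw(model, zg)
  i <- which.min(v)
  lo <- zg[max(1L, i - 2L)]; hi <- zg[min(length(zg), i + 2L)]
  stats::optimize(function(z) .pmf_value_raw(model, z), c(lo, hi),
                  tol = 1e-12)$minimum
}

.check_domain <- function(model, z) {
  if (any(!is.finite(z))) abort("`z` must be finite (nm).")
  if (any(abs(z) > model$z_max + 1e-9)) {
    abort(paste0("z out of domain: |z| must be <= z_max = ", model$z_max,
                 " nm."))
  }
}

#' Evaluate the model free energy surface
#'
#' @param model A [potential_model()].
#' @param z Positions in nm, `|z| <= z_max`.
#' @return Free energy values in kJ/mol, even in `z`.
#' @export
pmf_value <- function(model, z) {
  stopifnot(inherits(model, "potential_model"))
  .check_domain(model, z)
  .pmf_value_raw(model, z)
}

#' Analytic gradient of the model free energy surface
#'
#' Derivative dG/dz in kJ mol^-1 nm^-1, used by the Langevin sampler.
#'
#' @inheritParams pmf_value
#' @return Gradient values, odd in `z`.
#' @export
pmf_gradient <- function(model, z) {
  stopifnot(inherits(model, "potential_model"))
  .check_domain(model, z)
  a <- abs(z)
  lo <- model$z_interface - model$w_switch
  hi <- model$z_interface + model$w_switch
  ds <- numeric(length(z))
  mid <- a > lo & a < hi
  # dS/d|z| then chain rule through |z|.
  ds[mid] <- -.smoothstep_deriv((hi - a[mid]) / (2 * model$w_switch)) /
    (2 * model$w_switch)
  ds <- ds * sign(z)
  g_bg <- (model$g_bulk - model$g_vacuum) * ds
  w2 <- model$w_interface^2
  g_w <- model$well_depth *
    (exp(-(z - model$z_interface)^2 / (2 * w2)) * (z - model$z_interface) +
       exp(-(z + model$z_interface)^2 / (2 * w2)) * (z + model$z_interface)) / w2
  g_bg + g_w
}

#' @export
print.potential_model <- function(x, ...) {
  cat("<potential_model>\n")
  cat(sprintf("  plateaus: vacuum %.3f, bulk %.3f kJ/mol\n",
              x$g_vacuum, x$g_bulk))
  cat(sprintf("  interface wells at +/-%.3f nm (sigma %.3f nm), min %.3f kJ/mol\n",
              x$z_interface, x$w_interface, x$g_surface_min))
  cat(sprintf("  switch half-width %.3f nm, domain |z| <= %.2f nm\n",
              x$w_switch, x$z_max))
  invisible(x)
}
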