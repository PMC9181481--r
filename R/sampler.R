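#' Langevin sampler configuration
#'
#' Settings for the overdamped Langevin surrogate that replaces the MD
#' engine.  Time is in reduced units: only the stationary (Boltzmann)
#' distribution of each biased window matters for the downstream WHAM
#' analysis, so no mapping of `dt` to physical nanoseconds is claimed.
#'
#' @param dt Integration time step (reduced units).  Must keep the
#'   single-step diffusive displacement `sqrt(2 * diffusion * dt)` below a
#'   fifth of the interface well width (checked against the model at
#'   sampling time).
#' @param diffusion Diffusion coefficient, nm^2 per unit time.
#' @param temperature Temperature in kelvin.
#' @param n_steps Integration steps per window.
#' @param stride Record one sample every `stride` steps.
#' @param seed Base RNG seed; window `i` uses `seed + i` so replicates are
#'   reproducible independently of execution order.
#' @return A list of class `sampler_config`.
#' @export
sampler_config <- function(dt = 2.5e-5, diffusion = 1.0, temperature = 300,
                           n_steps = 1.2e7, stride = 100, seed = 1) {
  if (dt <= 0 || diffusion <= 0) abort("`dt` and `diffusion` must be > 0.")
  if (temperature <= 0) abort("`temperature` must be > 0 K.")
  if (n_steps < 0 || n_steps != round(n_steps)) {
    abort("`n_steps` must be a non-negative integer.")
  }
  if (stride < 1 || stride != round(stride)) {
    abort("`stride` must be a positive integer.")
  }
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort("`seed` must be a single finite number.")
  }
  structure(list(dt = dt, diffusion = diffusion, temperature = temperature,
                 n_steps = as.integer(n_steps), stride = as.integer(stride),
                 seed = as.integer(seed)),
            class = "sampler_config")
}

.check_sampler_stability <- function(model, cfg) {
  step_scale <- sqrt(2 * cfg$diffusion * cfg$dt)
  if (step_scale >= model$w_interface / 5) {
    abort(paste0("unstable sampler settings: sqrt(2*D*dt) = ",
                 signif(step_scale, 4), " nm must be < w_interface/5 = ",
                 signif(model$w_interface / 5, 4), " nm."))
  }
  invisible(TRUE)
}

#' Sample one umbrella window
#'
#' Runs an Euler-Maruyama overdamped Langevin chain on the biased
#' potential `G(z) + k/2 (z - center)^2`, starting at the restraint
#' centre, and records one sample every `stride` steps.  The Gaussian
#' increments are drawn from R's RNG after `set.seed(seed)`, so the chain
#' is fully reproducible.
#'
#' @param model A [potential_model()].
#' @param center Restraint centre z0, nm.
#' @param force_constant Harmonic force constant k, kJ mol^-1 nm^-2.
#' @param cfg A [sampler_config()].
#' @param seed Seed for this window (default: `cfg$seed`).
#' @return Numeric vector of reaction-coordinate samples, nm.
#' @export
sample_window <- function(model, center, force_constant = 2000, cfg,
                          seed = cfg$seed) {
  stopifnot(inherits(model, "potential_model"),
            inherits(cfg, "sampler_config"))
  if (force_constant <= 0) abort("`force_constant` must be > 0.")
  if (abs(center) > model$z_max + 1e-9) {
    abort("restraint centre lies outside the model domain.")
  }
  .check_sampler_stability(model, cfg)
  if (cfg$n_steps == 0L) return(numeric(0))
  rt <- rt_kj(cfg$temperature)
  set.seed(as.integer(seed))
  noise <- rnorm(cfg$n_steps)
  langevin_chain(center, center, force_constant, cfg$dt, cfg$diffusion, rt,
                 cfg$n_steps, cfg$stride, noise,
                 model$g_vacuum, model$g_bulk, model$z_interface,
                 model$w_interface, model$w_switch, model$well_depth,
                 model$z_max)
}

#' Sample every window of a placement scheme
#'
#' Applies [sample_window()] to each row of a [window_scheme()], seeding
#' window `i` with `cfg$seed + i` (counter-based, order-independent).
#'
#' @param model A [potential_model()].
#' @param scheme A [window_scheme()] tibble (or any data frame with a
#'   `center` column; a `window` id column is added if absent).
#' @param force_constant Harmonic force constant, kJ mol^-1 nm^-2, shared
#'   by all windows.
#' @param cfg A [sampler_config()].
#' @return A window tibble: `window`, `center`, `force_constant`, `seed`,
#'   `samples` (list-column of nm values), `n_equilibration` (0).
#' @examples
#' m <- potential_model(-4, -10)
#' ws <- window_scheme(3, 1, 2, -1.5, 1.5)
#' w <- sample_windows(m, ws, cfg = sampler_config(n_steps = 2000, seed = 7))
#' @export
sample_windows <- function(model, scheme, force_constant = 2000, cfg) {
  stopifnot(is.data.frame(scheme), "center" %in% names(scheme))
  ids <- if ("window" %in% names(scheme)) scheme$window else
    seq_len(nrow(scheme))
  seeds <- cfg$seed + as.integer(ids)
  samples <- purrr::map2(scheme$center, seeds, function(z0, s) {
    tryCatch(
      sample_window(model, z0, force_constant, cfg, seed = s),
      error = function(e) {
        abort(paste0("window at z0 = ", z0, " nm: ", conditionMessage(e)))
      })
  })
  tibble::tibble(window = as.integer(ids), center = scheme$center,
                 force_constant = force_constant, seed = as.integer(seeds),
                 samples = samples, n_equilibration = 0L)
}
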