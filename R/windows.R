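#' Umbrella window placement scheme
#'
#' Reproduces the staggered-replicate window layout of interfacial
#' umbrella-sampling studies: `n_positions` simultaneous restraint
#' positions spaced `position_spacing` nm apart, replicated
#' `n_replicates` times with each replicate shifted by
#' `position_spacing / n_replicates`, so that the pooled centres tile the
#' coordinate range uniformly.  Seven positions 1 nm apart replicated 12
#' times over \[-3.5, 3.5\] nm gives the canonical 84 windows with 1/12 nm
#' effective spacing; 20 replicates gives a 0.05 nm shift.
#'
#' @param n_positions Restraint positions per replicate (positive integer).
#' @param position_spacing Distance between simultaneous positions, nm.
#' @param n_replicates Number of staggered replicates (positive integer).
#' @param z_min,z_max Coverage bounds, nm.
#' @return A tibble of class `window_scheme` with one row per window:
#'   `window` (id), `replicate`, `position`, `center` (nm).  The effective
#'   centre spacing is stored in attribute `"delta"`.
#' @examples
#' ws <- window_scheme(7, 1.0, 12, -3.5, 3.5)
#' nrow(ws) # 84
#' @export
window_scheme <- function(n_positions = 7, position_spacing = 1.0,
                          n_replicates = 12, z_min = -3.5, z_max = 3.5) {
  if (n_positions < 1 || n_positions != round(n_positions) ||
      n_replicates < 1 || n_replicates != round(n_replicates)) {
    abort("`n_positions` and `n_replicates` must be positive integers.")
  }
  if (position_spacing <= 0) abort("`position_spacing` must be > 0 nm.")
  if (z_max <= z_min) abort("need z_max > z_min.")
  span <- z_max - z_min
  if (n_positions * position_spacing > span + 1e-9) {
    abort("scheme does not fit: n_positions * position_spacing exceeds the coverage range.")
  }
  delta <- position_spacing / n_replicates
  grid <- tidyr::expand_grid(replicate = seq_len(n_replicates),
                             position = seq_len(n_positions))
  out <- grid |>
    dplyr::mutate(center = z_min + (.data$position - 1) * position_spacing +
                    (.data$replicate - 1) * delta) |>
    dplyr::mutate(window = dplyr::row_number(), .before = 1)
  attr(out, "delta") <- delta
  attr(out, "z_range") <- c(z_min, z_max)
  class(out) <- c("window_scheme", class(out))
  out
}

#' Drop the equilibration segment of each window
#'
#' Removes the leading `floor(fraction * n)` samples from every window's
#' time series, mirroring the convention of analysing only the last part
#' of each biased run (by default the final two thirds, i.e. the last
#' 4 ns of a 6 ns window).
#'
#' @param windows A window tibble with a `samples` list-column, as
#'   returned by [sample_windows()].
#' @param fraction Fraction of leading samples to discard, in `[0, 1)`.
#' @return The window tibble with trimmed `samples` and updated
#'   `n_equilibration` counts.
#' @export
discard_equilibration <- function(windows, fraction = 1 / 3) {
  .check_window_tbl(windows)
  if (!is.numeric(fraction) || length(fraction) != 1L || !is.finite(fraction) ||
      fraction < 0 || fraction >= 1) {
    abort("`fraction` must lie in [0, 1).")
  }
  n_drop <- vapply(windows$samples, function(s) floor(fraction * length(s)),
                   numeric(1))
  windows$samples <- purrr::map2(windows$samples, n_drop,
                                 function(s, k) if (k > 0) s[-seq_len(k)] else s)
  windows$n_equilibration <- as.integer(n_drop) +
    (windows$n_equilibration %||% 0L)
  windows
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.check_window_tbl <- function(windows) {
  if (!is.data.frame(windows) ||
      !all(c("window", "center", "force_constant", "samples") %in%
             names(windows))) {
    abort(paste("expected a window tibble with columns `window`, `center`,",
                "`force_constant` and a `samples` list-column."))
  }
  if (any(vapply(windows$force_constant, function(k) k <= 0, logical(1)))) {
    abort("all force constants must be > 0 kJ mol^-1 nm^-2.")
  }
  invisible(windows)
}
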