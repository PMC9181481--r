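#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a free energy profile
#'
#' @param x A `fep_profile`.
#' @param ... Unused.
#' @return A plain tibble with `z` (nm), `g` (kJ/mol) and, when present,
#'   `se` (kJ/mol).
#' @export
tidy.fep_profile <- function(x, ...) {
  tibble::as_tibble(unclass(x)[intersect(c("z", "g", "se"), names(x))])
}

#' One-row summary of a free energy profile
#'
#' @param x A `fep_profile`.
#' @param ... Unused.
#' @return A tibble with the grid size, occupancy, temperature,
#'   reference convention and solver diagnostics.
#' @export
glance.fep_profile <- function(x, ...) {
  tibble::tibble(n_bins = nrow(x), n_occupied = sum(is.finite(x$g)),
                 bin_width = attr(x, "bin_width"),
                 temperature = attr(x, "temperature"),
                 reference = attr(x, "reference"),
                 symmetrized = isTRUE(attr(x, "symmetrized")),
                 iterations = attr(x, "iterations"),
                 residual = attr(x, "residual"))
}

#' Tidy a set of free energy landmarks
#'
#' @param x A `fep_landmarks` object.
#' @param ... Unused.
#' @return A long tibble with `quantity` and `value` (kJ/mol, or nm for
#'   `z_min`).
#' @export
tidy.fep_landmarks <- function(x, ...) {
  tibble::tibble(quantity = c("dg_gs", "dg_sl", "dg_hydr", "z_min"),
                 value = c(x$dg_gs, x$dg_sl, x$dg_hydr, x$z_min))
}

#' Plot a free energy profile
#'
#' Line plot of the profile with a ribbon of plus/minus one bootstrap
#' standard error when available.
#'
#' @param object A `fep_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fep_profile <- function(object, ...) {
  d <- tidy(object)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$z, y = .data$g))
  if (!is.null(d[["se"]])) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$g - .data$se, ymax = .data$g + .data$se),
      fill = "steelblue", alpha = 0.3, na.rm = TRUE)
  }
  p + ggplot2::geom_line(na.rm = TRUE, colour = "steelblue4") +
    ggplot2::labs(x = "z (nm)", y = expression(Delta * G ~ "(kJ/mol)")) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the free energy profiles of a pipeline run
#'
#' Overlays the per-species profiles of a [run_pipeline()] result.
#'
#' @param result A [run_pipeline()] result (uses `$profiles`).
#' @return A ggplot object.
#' @export
plot_profiles <- function(result) {
  d <- purrr::imap(result$profiles,
                   function(p, nm) dplyr::mutate(tidy(p), species = nm)) |>
    dplyr::bind_rows()
  ggplot2::ggplot(d, ggplot2::aes(x = .data$z, y = .data$g,
                                  colour = .data$species)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::labs(x = "z (nm)", y = expression(Delta * G ~ "(kJ/mol)"),
                  colour = NULL) +
    ggplot2::theme_minimal()
}
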