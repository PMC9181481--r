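#' Extract free energy landmarks from a profile
#'
#' Reads the three thermodynamic landmarks of an interfacial free energy
#' profile referenced to the gas phase:
#' * `dg_gs` — gas to surface: the minimum of `g` over the interface
#'   search region (the vacuum plateau is the zero);
#' * `dg_hydr` — hydration free energy: the mean of `g` over the bulk
#'   plateau region;
#' * `dg_sl` — surface to liquid: `dg_hydr - dg_gs`, so the additive
#'   identity `dg_gs + dg_sl = dg_hydr` holds by construction.
#'
#' Regions are intervals of `|z|`; a symmetrized profile is expected and
#' the `z >= 0` half is used.  Ties in the minimum go to the smaller
#' `|z|`.
#'
#' @param profile A referenced (and normally symmetrized) `fep_profile`.
#' @param vacuum_region,interface_region,bulk_region Length-2 intervals
#'   of `|z|` in nm.
#' @return An object of class `fep_landmarks`: a list with `dg_gs`,
#'   `dg_sl`, `dg_hydr`, `z_min` and the three regions.
#' @export
extract_landmarks <- function(profile, vacuum_region = c(3.0, 3.5),
                              interface_region = c(0.8, 2.6),
                              bulk_region = c(0.0, 0.7)) {
  stopifnot(inherits(profile, "fep_profile"))
  if (identical(attr(profile, "reference"), "unreferenced")) {
    abort("profile must be referenced to the vacuum plateau first; see set_reference().")
  }
  half <- profile[profile$z >= 0, , drop = FALSE]
  pick <- function(region, what) {
    sel <- is.finite(half$g) & half$z >= region[1] & half$z <= region[2]
    if (!any(sel)) {
      abort(paste0(what, " region [", region[1], ", ", region[2],
                   "] nm contains no occupied bins."))
    }
    sel
  }
  isel <- pick(interface_region, "interface")
  bsel <- pick(bulk_region, "bulk")
  gi <- half$g[isel]
  zi <- half$z[isel]
  gmin <- min(gi)
  cand <- which(gi <= gmin + 1e-12)
  z_min <- zi[cand[which.min(abs(zi[cand]))]]
  dg_gs <- gmin
  dg_hydr <- mean(half$g[bsel])
  structure(list(dg_gs = dg_gs, dg_sl = dg_hydr - dg_gs, dg_hydr = dg_hydr,
                 z_min = z_min,
                 regions = list(vacuum = vacuum_region,
                                interface = interface_region,
                                bulk = bulk_region)),
            class = "fep_landmarks")
}

#' @export
print.fep_landmarks <- function(x, ...) {
  cat(sprintf("<fep_landmarks> dG_gs = %.3f, dG_sl = %.3f, dG_hydr = %.3f kJ/mol (minimum at z = %.3f nm)\n",
              x$dg_gs, x$dg_sl, x$dg_hydr, x$z_min))
  invisible(x)
}

#' Boltzmann concentration enhancement
#'
#' Equilibrium concentration ratio `exp(-dg / (R T))` of a species at
#' the surface (use the gas-to-surface free energy) or in bulk water
#' (use the hydration free energy) relative to the gas phase.
#'
#' @param dg Free energy change(s), kJ/mol.
#' @param temperature Kelvin.
#' @return Dimensionless fold enhancement(s).
#' @examples
#' concentration_enhancement(-22.04, 300) # ~6.9e3
#' @export
concentration_enhancement <- function(dg, temperature = 300) {
  if (any(!is.finite(dg))) abort("`dg` must be finite (kJ/mol).")
  exp(-dg / rt_kj(temperature))
}

#' Classify a species as hydrophilic or hydrophobic
#'
#' Hydrophilic means a negative hydration free energy (bulk water is
#' favourable relative to the gas phase); hydrophobic means positive.
#' An exact zero is classified hydrophobic with a warning.
#'
#' @param dg_hydr Hydration free energy (or energies), kJ/mol.
#' @return Character vector, `"hydrophilic"` or `"hydrophobic"`.
#' @export
classify_species <- function(dg_hydr) {
  if (any(!is.finite(dg_hydr))) abort("`dg_hydr` must be finite (kJ/mol).")
  if (any(dg_hydr == 0)) {
    warn("dg_hydr exactly 0: classified hydrophobic by boundary convention.")
  }
  ifelse(dg_hydr < 0, "hydrophilic", "hydrophobic")
}

#' Henry constant container
#'
#' @param value Positive solubility constant.
#' @param convention Either `"mol_m3_pa"` (concentration per partial
#'   pressure, mol m^-3 Pa^-1, the compilation convention) or
#'   `"dimensionless"` (aqueous/gas concentration ratio `H_cc`).
#' @param temperature Kelvin; Henry compilations are referenced to
#'   298.15 K.
#' @return A list of class `henry_constant`.
#' @export
henry_constant <- function(value, convention = c("mol_m3_pa", "dimensionless"),
                           temperature = 298.15) {
  convention <- match.arg(convention)
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value) ||
      value <= 0) {
    abort("Henry constant `value` must be a single positive number.")
  }
  if (temperature <= 0) abort("`temperature` must be > 0 K.")
  structure(list(value = value, convention = convention,
                 temperature = temperature),
            class = "henry_constant")
}

#' Hydration free energy from a Henry's-law constant
#'
#' Converts a solubility Henry constant to the dimensionless
#' aqueous/gaseous concentration ratio `H_cc` (`H_cc = H_cp * R * T`
#' for the mol m^-3 Pa^-1 convention, with R in J mol^-1 K^-1) and
#' returns the corresponding hydration free energy
#' `-R T ln(H_cc)` in kJ/mol.
#'
#' @param h A [henry_constant()], or a positive number interpreted with
#'   `convention` and `temperature`.
#' @param convention,temperature Used only when `h` is a bare number.
#' @return Hydration free energy, kJ/mol.
#' @examples
#' henry_to_dghydr(henry_constant(1e-4)) # 3.46 kJ/mol
#' @export
henry_to_dghydr <- function(h, convention = "mol_m3_pa",
                            temperature = 298.15) {
  if (!inherits(h, "henry_constant")) {
    h <- henry_constant(h, convention, temperature)
  }
  h_cc <- switch(h$convention,
                 mol_m3_pa = h$value * GAS_CONSTANT_J * h$temperature,
                 dimensionless = h$value,
                 abort("unknown Henry constant convention."))
  -rt_kj(h$temperature) * log(h_cc)
}

#' Summarize one species from its free energy profile
#'
#' Composes [extract_landmarks()], [concentration_enhancement()] (surface
#' from the gas-to-surface free energy, bulk from the hydration free
#' energy), [classify_species()] and, when a Henry constant is supplied,
#' [henry_to_dghydr()] into a one-row tidy summary.
#'
#' @param profile A referenced `fep_profile`.
#' @param name Species label.
#' @param regions Named list with `vacuum`, `interface`, `bulk` intervals
#'   (|z| in nm) for [extract_landmarks()].
#' @param temperature Kelvin, for the Boltzmann enhancements.
#' @param henry Optional [henry_constant()] for the experimental
#'   hydration free energy column.
#' @return A one-row tibble: `species`, `dg_gs`, `dg_sl`, `dg_hydr`,
#'   `z_min`, `enhancement_surface`, `enhancement_bulk`, `hydro_class`,
#'   `dg_hydr_expt`, `temperature`.
#' @export
summarize_species <- function(profile, name, regions = NULL,
                              temperature = 300, henry = NULL) {
  regions <- regions %||% list(vacuum = c(3.0, 3.5),
                               interface = c(0.8, 2.6),
                               bulk = c(0.0, 0.7))
  lm <- tryCatch(
    extract_landmarks(profile, regions$vacuum, regions$interface,
                      regions$bulk),
    error = function(e) abort(paste0(name, ": ", conditionMessage(e))))
  tibble::tibble(
    species = name,
    dg_gs = lm$dg_gs, dg_sl = lm$dg_sl, dg_hydr = lm$dg_hydr,
    z_min = lm$z_min,
    enhancement_surface = concentration_enhancement(lm$dg_gs, temperature),
    enhancement_bulk = concentration_enhancement(lm$dg_hydr, temperature),
    hydro_class = classify_species(lm$dg_hydr),
    dg_hydr_expt = if (is.null(henry)) NA_real_ else henry_to_dghydr(henry),
    temperature = temperature
  )
}
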