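# Plain-text formats: per-window time series (two columns: time index,
# z in nm, '#' headers) plus a metadata file listing, per window,
# `path center force_constant` -- the de-facto umbrella-sampling input
# format of standard WHAM tools.

.header_lines <- function(fields) {
  paste0("# ", names(fields), ": ", vapply(fields, format, character(1)))
}

#' Write umbrella windows to disk
#'
#' Writes one whitespace-delimited time-series file per window (columns:
#' sample index, z in nm) and a metadata file with one line per window:
#' `path center force_constant`.
#'
#' @param windows A window tibble (see [sample_windows()]).
#' @param dir Output directory (created if needed).
#' @param metadata Name of the metadata file within `dir`.
#' @return The metadata file path, invisibly.
#' @export
write_windows <- function(windows, dir, metadata = "metadata.dat") {
  .check_window_tbl(windows)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- sprintf("window_%03d.dat", windows$window)
  for (i in seq_len(nrow(windows))) {
    s <- windows$samples[[i]]
    hdr <- .header_lines(list(
      window = windows$window[i], center_nm = windows$center[i],
      force_constant = windows$force_constant[i],
      seed = windows$seed[i] %||% NA,
      n_equilibration = windows$n_equilibration[i] %||% 0L))
    con <- file.path(dir, paths[i])
    writeLines(c(hdr, sprintf("%d %.8f", seq_along(s), s)), con)
  }
  meta_path <- file.path(dir, metadata)
  writeLines(c("# path center_nm force_constant",
               sprintf("%s %.8f %.8f", paths, windows$center,
                       windows$force_constant)),
             meta_path)
  invisible(meta_path)
}

#' Read umbrella windows from a metadata file
#'
#' Reads the format written by [write_windows()] (also produced by
#' typical MD pull-code post-processing): a metadata file of
#' `path center force_constant` lines and per-window text files whose
#' last column is the reaction coordinate in nm.
#'
#' @param metadata Path to the metadata file; window paths are resolved
#'   relative to its directory.
#' @return A window tibble usable by [build_histograms()].
#' @export
read_windows <- function(metadata) {
  if (!file.exists(metadata)) {
    abort(paste0("metadata file not found: ", metadata))
  }
  meta <- utils::read.table(metadata, comment.char = "#",
                            col.names = c("path", "center",
                                          "force_constant"),
                            stringsAsFactors = FALSE)
  base <- dirname(metadata)
  samples <- purrr::map(meta$path, function(p) {
    fp <- if (file.exists(p)) p else file.path(base, p)
    if (!file.exists(fp)) abort(paste0("window file not found: ", p))
    d <- utils::read.table(fp, comment.char = "#")
    d[[ncol(d)]]
  })
  tibble::tibble(window = seq_len(nrow(meta)), center = meta$center,
                 force_constant = meta$force_constant, seed = NA_integer_,
                 samples = samples, n_equilibration = 0L)
}

#' Write a free energy profile as a tab-separated table
#'
#' Columns `z`, `g` (and `se` when present) preceded by '#' header lines
#' recording temperature, reference convention, bin width and solver
#' diagnostics -- enough to re-run the stage that produced the file.
#'
#' @param profile A `fep_profile`.
#' @param path Output file path.
#' @param extra Optional named list of additional header fields.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path, extra = list()) {
  stopifnot(inherits(profile, "fep_profile"))
  fields <- c(list(temperature_K = attr(profile, "temperature"),
                   reference = attr(profile, "reference"),
                   bin_width_nm = attr(profile, "bin_width"),
                   symmetrized = isTRUE(attr(profile, "symmetrized")),
                   iterations = attr(profile, "iterations"),
                   residual_kJ_mol = attr(profile, "residual")),
              extra)
  cols <- intersect(c("z", "g", "se"), names(profile))
  body <- do.call(sprintf, c(list(paste(rep("%.10g", length(cols)),
                                        collapse = "\t")),
                             lapply(cols, function(cn) profile[[cn]])))
  writeLines(c(.header_lines(fields),
               paste(cols, collapse = "\t"), body), path)
  invisible(path)
}

#' Read a free energy profile written by [write_profile()]
#'
#' @param path File path.
#' @return A `fep_profile` tibble.
#' @export
read_profile <- function(path) {
  if (!file.exists(path)) abort(paste0("profile file not found: ", path))
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key, default = NA) {
    m <- grep(paste0("^# ", key, ": "), hdr, value = TRUE)
    if (length(m) == 0L) default else sub(paste0("^# ", key, ": "), "", m[1])
  }
  d <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                         sep = "\t")
  new_fep_profile(d$z, d$g, se = d[["se"]],
                  temperature = as.numeric(get("temperature_K", 300)),
                  reference = get("reference", "unreferenced"),
                  bin_width = as.numeric(get("bin_width_nm", NA)),
                  symmetrized = identical(get("symmetrized", "FALSE"),
                                          "TRUE"))
}

#' Read a pipeline run configuration from YAML
#'
#' @param path YAML file with the fields accepted by [run_pipeline()].
#' @return A named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  yaml::read_yaml(path)
}

#' Write a pipeline run configuration to YAML
#'
#' Round-trips losslessly with [read_run_config()].
#'
#' @param config Named list of run settings.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path, precision = 15)
  invisible(path)
}
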