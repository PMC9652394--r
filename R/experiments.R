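# Pipeline layer: the g-ratio and imperfection sweeps, transmission-ratio
# tables at the benchmark wavelengths, spectrum crossings and anti-resonant
# band edges, and CSV/JSON output.

#' Preset simulation grids
#'
#' `"default"` uses 15.6 nm transverse and 25 nm axial steps on a 4 um
#' window; `"coarse"` doubles the axial step (50 nm), which changes port
#' transmissions by well under the scalar-model uncertainty while halving
#' run time, and is the profile used by the packaged sweeps.
#'
#' @param profile `"default"` or `"coarse"`.
#' @return A [grid_spec()].
#' @export
default_grid <- function(profile = c("coarse", "default")) {
  profile <- match.arg(profile)
  grid_spec(extent = 4, dx = 4 / 256, dz = if (profile == "coarse") 0.05 else 0.025)
}

#' Preset wavelength grids (nm)
#'
#' @param profile `"coarse"` (25 nm steps) or `"default"` (5 nm steps), both
#'   spanning the simulated 300-900 nm band.
#' @return Numeric vector of wavelengths in nanometers.
#' @export
default_lambda_nm <- function(profile = c("coarse", "default")) {
  profile <- match.arg(profile)
  seq(300, 900, by = if (profile == "coarse") 25 else 5)
}

# Benchmark wavelengths of the ratio tables (nm): shortest simulated,
# two optogenetic stimulation lines, and the long-wavelength end.
ratio_wavelengths_nm <- c(300, 473, 540, 900)

interp_T <- function(spectrum, wavelength_nm, channel) {
  col <- paste0("T_", channel)
  stats::approx(spectrum$wavelength_nm, spectrum[[col]],
                xout = wavelength_nm, rule = 2)$y
}

#' Transmission-ratio table versus a reference configuration
#'
#' For each configuration, the ratio `T(config) / T(reference)` of the
#' launch-site channel at the benchmark wavelengths 300, 473, 540, 900 nm
#' (linear interpolation on the shared wavelength grid).
#'
#' @param spectra named list of [transmission_spectrum()] results sharing a
#'   wavelength grid.
#' @param reference name of the reference configuration in `spectra`.
#' @param channel `"myelin"` or `"axon"` output channel.
#' @param wavelength_nm benchmark wavelengths (default 300/473/540/900).
#' @return Data frame: one row per configuration (reference row included,
#'   identically 1), columns `config` then one per wavelength.
#' @export
ratio_table <- function(spectra, reference, channel,
                        wavelength_nm = ratio_wavelengths_nm) {
  stopifnot(reference %in% names(spectra))
  ref <- interp_T(spectra[[reference]], wavelength_nm, channel)
  rows <- lapply(names(spectra), function(nm) {
    v <- interp_T(spectra[[nm]], wavelength_nm, channel) / ref
    as.data.frame(c(list(config = nm), stats::setNames(as.list(v),
                                                       paste0("nm", wavelength_nm))))
  })
  out <- do.call(rbind, rows)
  attr(out, "reference") <- reference
  attr(out, "channel") <- channel
  out
}

#' Sweep over g-ratios
#'
#' Computes transmission spectra for g in {0.6, 0.7, 0.78} (axon radius and
#' all other parameters at their defaults) for one launch site, and the
#' ratio table of the launch-site channel referenced to g = 0.78 (the
#' thinnest sheath).
#'
#' @param site launch site, `"myelin"` or `"axon"`.
#' @param grid a [grid_spec()] (default the coarse preset).
#' @param lambda_nm wavelength grid in nm (default the coarse preset).
#' @param g_ratios g-ratios to sweep (default `c(0.6, 0.7, 0.78)`).
#' @param reference_g reference g-ratio for the ratio table (default 0.78).
#' @param base arguments passed to every [fiber_spec()] call.
#' @return List of class `sweep_result`: `spectra` (named list), `ratios`
#'   (see [ratio_table()]), `site`, `grid`, `lambda_nm`.
#' @export
run_gratio_sweep <- function(site = c("myelin", "axon"),
                             grid = default_grid(),
                             lambda_nm = default_lambda_nm(),
                             g_ratios = c(0.6, 0.7, 0.78),
                             reference_g = 0.78,
                             base = list()) {
  site <- match.arg(site)
  labels <- sprintf("g%.2f", g_ratios)
  spectra <- stats::setNames(lapply(g_ratios, function(g) {
    spec <- do.call(fiber_spec, c(list(g_ratio = g), base))
    transmission_spectrum(spec, grid, site, lambda_nm)
  }), labels)
  ref <- sprintf("g%.2f", reference_g)
  structure(list(spectra = spectra,
                 ratios = ratio_table(spectra, ref, channel = site),
                 site = site, grid = grid, lambda_nm = lambda_nm),
            class = "sweep_result")
}

#' Sweep over biological imperfections
#'
#' Computes spectra for the normal (straight) fiber, the bent fiber and the
#' sheath-variation fiber, optionally each with a node of Ranvier, and the
#' ratio table referenced to the normal fiber (normal-with-node when
#' `with_node`).
#'
#' @inheritParams run_gratio_sweep
#' @param with_node add the node of Ranvier to every configuration.
#' @return A `sweep_result` (see [run_gratio_sweep()]).
#' @export
run_imperfection_sweep <- function(site = c("myelin", "axon"),
                                   with_node = FALSE,
                                   grid = default_grid(),
                                   lambda_nm = default_lambda_nm(),
                                   base = list()) {
  site <- match.arg(site)
  mk <- function(...) do.call(fiber_spec, c(list(...), list(node = with_node), base))
  specs <- list(normal = mk(),
                bend = mk(bend = TRUE),
                variation = mk(variation = TRUE))
  spectra <- lapply(specs, function(s) {
    # geometry invariants re-checked before propagation
    stopifnot(all(outer_radius(seq(0, s$length_um, length.out = 64), s) >= s$r_axon))
    transmission_spectrum(s, grid, site, lambda_nm)
  })
  structure(list(spectra = spectra,
                 ratios = ratio_table(spectra, "normal", channel = site),
                 site = site, grid = grid, lambda_nm = lambda_nm,
                 with_node = with_node),
            class = "sweep_result")
}

#' Crossing wavelength of two transmission curves
#'
#' Locates sign changes of `T_a - T_b` on the shared wavelength grid and
#' interpolates each crossing linearly.  Returns the first (shortest
#' wavelength) crossing; all crossings are attached as attribute
#' `"all_crossings"`.  When the curves never cross, returns `NA` with a
#' warning.
#'
#' @param spec_a,spec_b [transmission_spectrum()] results on one grid.
#' @param channel `"axon"` or `"myelin"`.
#' @return Crossing wavelength in nm (or `NA`).
#' @export
crossing_wavelength <- function(spec_a, spec_b, channel = c("myelin", "axon")) {
  channel <- match.arg(channel)
  if (!isTRUE(all.equal(spec_a$wavelength_nm, spec_b$wavelength_nm)))
    stop("spectra must share one wavelength grid")
  d <- spec_a[[paste0("T_", channel)]] - spec_b[[paste0("T_", channel)]]
  wl <- spec_a$wavelength_nm
  ok <- is.finite(d)
  d <- d[ok]; wl <- wl[ok]
  if (!length(d) || all(d == 0)) {
    warning("transmission curves do not cross")
    return(NA_real_)
  }
  cross <- numeric(0)
  for (i in seq_len(length(d) - 1)) {
    if (d[i] == 0) cross <- c(cross, wl[i])
    else if (d[i] * d[i + 1] < 0)
      cross <- c(cross, wl[i] + (wl[i + 1] - wl[i]) * d[i] / (d[i] - d[i + 1]))
  }
  if (d[length(d)] == 0) cross <- c(cross, wl[length(d)])
  cross <- unique(cross)
  if (!length(cross)) {
    warning("transmission curves do not cross")
    return(NA_real_)
  }
  structure(cross[1], all_crossings = cross)
}

#' Anti-resonant band edge of an axon-launch spectrum
#'
#' The upper edge of the enhanced axon-transmission (anti-resonant) band:
#' the wavelength where the axon-port and myelin-port curves of one spectrum
#' cross, interpolated linearly.
#'
#' @param spectrum an axon-launch [transmission_spectrum()].
#' @return Band-edge wavelength in nm (or `NA` when the curves never cross).
#' @export
band_edge <- function(spectrum) {
  b <- spectrum
  b$T_axon <- b$T_myelin          # reuse the two-spectrum crossing finder
  crossing_wavelength(spectrum, b, channel = "axon")
}

#' Write sweep outputs to disk
#'
#' One CSV per spectrum (`spectrum_<label>.csv`, columns wavelength_nm,
#' T_axon, T_myelin, T_total), the ratio table (`ratios.csv`) and a JSON
#' manifest (`manifest.json`) recording the full configuration, grid and
#' package version.
#'
#' @param result a `sweep_result`.
#' @param path output directory (created if missing).
#' @param specs optional named list of [fiber_spec()]s to embed in the
#'   manifest.
#' @return Character vector of written file paths, invisibly.
#' @export
write_outputs <- function(result, path, specs = NULL) {
  stopifnot(inherits(result, "sweep_result"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (nm in names(result$spectra)) {
    f <- file.path(path, sprintf("spectrum_%s.csv", nm))
    utils::write.csv(as.data.frame(result$spectra[[nm]]), f, row.names = FALSE)
    files <- c(files, f)
  }
  f <- file.path(path, "ratios.csv")
  utils::write.csv(result$ratios, f, row.names = FALSE)
  files <- c(files, f)
  manifest <- list(
    site = result$site,
    with_node = result$with_node,
    lambda_nm = result$lambda_nm,
    grid = result$grid[c("extent", "dx", "dy", "dz", "pad", "nx", "ny")],
    specs = lapply(specs, function(s) {
      s <- unclass(s)
      s$constants <- unclass(s$constants)
      s
    }),
    package_version = as.character(utils::packageVersion("nervearrow")),
    r_version = R.version.string)
  f <- file.path(path, "manifest.json")
  jsonlite::write_json(manifest, f, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files <- c(files, f)
  invisible(files)
}
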