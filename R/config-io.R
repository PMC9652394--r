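# Flat keyed YAML serialization of fiber configurations.

fiber_config_keys <- c(
  "r_axon_um", "g_ratio", "length_um",
  "n_axon", "n_myelin", "n_fluid",
  "bend.enabled", "bend.amplitude_um",
  "variation.enabled", "variation.amplitude_um", "variation.factor_v",
  "variation.phase_rad",
  "node.enabled", "node.length_um", "node.center_um")

#' Write a fiber configuration file
#'
#' Serializes a [fiber_spec()] as a flat keyed YAML file (keys
#' `r_axon_um`, `g_ratio`, `length_um`, `n_axon`, `n_myelin`, `n_fluid`,
#' `bend.enabled`, `bend.amplitude_um`, `variation.enabled`,
#' `variation.amplitude_um`, `variation.factor_v`, `variation.phase_rad`,
#' `node.enabled`, `node.length_um`, `node.center_um`).
#'
#' @param spec a [fiber_spec()].
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_fiber_config <- function(spec, path) {
  stopifnot(inherits(spec, "fiber_spec"))
  cst <- spec$constants
  cfg <- list(
    r_axon_um = spec$r_axon, g_ratio = spec$g_ratio,
    length_um = spec$length_um,
    n_axon = cst$n_axon, n_myelin = cst$n_myelin, n_fluid = cst$n_fluid,
    "bend.enabled" = spec$bend, "bend.amplitude_um" = spec$bend_amplitude,
    "variation.enabled" = spec$variation,
    "variation.amplitude_um" = spec$variation_amplitude,
    "variation.factor_v" = spec$variation_factor,
    "variation.phase_rad" = spec$variation_phase,
    "node.enabled" = spec$node, "node.length_um" = spec$node_length,
    "node.center_um" = spec$node_center)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Read a fiber configuration file
#'
#' @param path a YAML file written by [write_fiber_config()] (missing keys
#'   fall back to the [fiber_spec()] defaults).
#' @return A [fiber_spec()].
#' @export
read_fiber_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), fiber_config_keys)
  if (length(unknown))
    warning("ignoring unknown config keys: ", paste(unknown, collapse = ", "))
  g <- function(key, default) if (!is.null(cfg[[key]])) cfg[[key]] else default
  length_um <- g("length_um", 27)
  fiber_spec(
    r_axon = g("r_axon_um", 0.4),
    g_ratio = g("g_ratio", 0.7),
    length_um = length_um,
    bend = isTRUE(g("bend.enabled", FALSE)),
    bend_amplitude = g("bend.amplitude_um", 0.2),
    variation = isTRUE(g("variation.enabled", FALSE)),
    variation_amplitude = g("variation.amplitude_um", 0.2),
    variation_factor = g("variation.factor_v", 0.3),
    variation_phase = g("variation.phase_rad", 0),
    node = isTRUE(g("node.enabled", FALSE)),
    node_length = g("node.length_um", 0.7),
    node_center = g("node.center_um", length_um / 2),
    constants = optical_constants(n_axon = g("n_axon", 1.38),
                                  n_myelin = g("n_myelin", 1.44),
                                  n_fluid = g("n_fluid", 1.34)))
}
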