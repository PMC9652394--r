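# Fabry-Perot / anti-resonance analysis of the myelin annulus, treated as a
# planar high-index layer at fixed axial effective index n_eff.  At
# transverse resonance (round-trip transverse phase = multiple of pi) the
# layer is transparent and light leaks out of the axon; between resonances
# (anti-resonance) the layer reflects strongly and the low-index axon guides.

#' Planar Fabry-Perot model of the myelin sheath
#'
#' @param t_myelin layer (sheath) thickness, micrometers (> 0).
#' @param n_layer layer index (myelin, default 1.44).
#' @param n_inner index on the axon side (default 1.38).
#' @param n_outer index on the fluid side (default 1.34).
#' @param n_eff axial effective index of the analysed ray/mode; must be
#'   below `n_layer`.  Default 1.0297, the assumed anti-resonant-core value.
#' @return An object of class `slab_model`.
#' @export
slab_model <- function(t_myelin, n_layer = 1.44, n_inner = 1.38,
                       n_outer = 1.34, n_eff = 1.0297) {
  stopifnot(t_myelin > 0, n_layer > 0)
  if (n_eff >= n_layer) stop("n_eff must be below the layer index")
  structure(list(t_myelin = t_myelin, n_layer = n_layer, n_inner = n_inner,
                 n_outer = n_outer, n_eff = n_eff), class = "slab_model")
}

#' Slab model derived from a fiber specification
#'
#' @param spec a [fiber_spec()].
#' @param n_eff axial effective index (default 1.0297).
#' @return A [slab_model()] with the fiber's sheath thickness and media.
#' @export
slab_from_fiber <- function(spec, n_eff = 1.0297) {
  stopifnot(inherits(spec, "fiber_spec"))
  cst <- spec$constants
  slab_model(spec$t_myelin, n_layer = cst$n_myelin, n_inner = cst$n_axon,
             n_outer = cst$n_fluid, n_eff = n_eff)
}

#' Transverse phase accumulated across the sheath
#'
#' One transverse pass through the layer accumulates
#' `phi = (2 pi / lambda) t sqrt(n_layer^2 - n_eff^2)`.
#' Resonance (layer transparency) occurs at `phi = m pi`.
#'
#' @param lambda wavelengths in micrometers (vectorized).
#' @param slab a [slab_model()].
#' @return Phases in radians.
#' @export
transverse_phase <- function(lambda, slab) {
  stopifnot(inherits(slab, "slab_model"), all(lambda > 0))
  (2 * pi / lambda) * slab$t_myelin * sqrt(slab$n_layer^2 - slab$n_eff^2)
}

#' Fabry-Perot resonance wavelengths of the sheath
#'
#' Solves `transverse_phase(lambda) = m pi`, i.e.
#' `lambda_m = 2 t sqrt(n_layer^2 - n_eff^2) / m`.
#'
#' @param slab a [slab_model()].
#' @param m_max highest resonance order (>= 1).
#' @return Data frame with columns `m` and `lambda_um`, strictly decreasing
#'   in wavelength.
#' @export
#' @examples
#' resonance_wavelengths(slab_model(thickness_from_g(0.4, 0.7)), 3)
resonance_wavelengths <- function(slab, m_max = 5) {
  stopifnot(inherits(slab, "slab_model"), m_max >= 1)
  m <- seq_len(m_max)
  data.frame(m = m,
             lambda_um = 2 * slab$t_myelin *
               sqrt(slab$n_layer^2 - slab$n_eff^2) / m)
}

#' Is a wavelength anti-resonant for the sheath?
#'
#' TRUE when the transverse phase sits farther than `tol` from the nearest
#' multiple of pi — the Fabry-Perot layer then reflects and the axon guides.
#'
#' @param lambda wavelengths in micrometers (vectorized).
#' @param slab a [slab_model()].
#' @param tol phase distance threshold in radians, in (0, pi/2); default
#'   pi/4 splits the phase circle evenly between resonant and anti-resonant.
#' @return Logical vector.
#' @export
is_antiresonant <- function(lambda, slab, tol = pi / 4) {
  if (tol <= 0 || tol >= pi / 2) stop("tol must lie in (0, pi/2)")
  phi <- transverse_phase(lambda, slab)
  d <- abs(phi - pi * round(phi / pi))
  d > tol
}

# Transverse wavenumbers, complex where the medium is evanescent at n_eff.
slab_kt <- function(lambda, n, n_eff)
  (2 * pi / lambda) * sqrt(as.complex(n^2 - n_eff^2))

#' Reflectance and transmittance of the sheath layer
#'
#' Two-interface Airy interference for a single layer between two
#' semi-infinite media, in the scalar/TE picture at fixed axial `n_eff`:
#' amplitude reflectances `r_ij = (k_i - k_j)/(k_i + k_j)` built from the
#' transverse wavenumbers `k_i = (2 pi / lambda) sqrt(n_i^2 - n_eff^2)`
#' (imaginary in evanescent media), combined as
#' `r = (r12 + r23 e^{2 i phi}) / (1 + r12 r23 e^{2 i phi})`.
#' In lossless media with both outer media propagating, `R + T = 1`.
#'
#' @param lambda wavelengths in micrometers (vectorized).
#' @param slab a [slab_model()].
#' @return Data frame with columns `lambda_um`, `R`, `T`.
#' @export
slab_rt <- function(lambda, slab) {
  stopifnot(inherits(slab, "slab_model"), all(lambda > 0))
  k1 <- slab_kt(lambda, slab$n_inner, slab$n_eff)
  k2 <- slab_kt(lambda, slab$n_layer, slab$n_eff)
  k3 <- slab_kt(lambda, slab$n_outer, slab$n_eff)
  r12 <- (k1 - k2) / (k1 + k2)
  r23 <- (k2 - k3) / (k2 + k3)
  t12 <- 2 * k1 / (k1 + k2)
  t23 <- 2 * k2 / (k2 + k3)
  ph <- exp(2i * k2 * slab$t_myelin)
  denom <- 1 + r12 * r23 * ph
  r <- (r12 + r23 * ph) / denom
  t <- t12 * t23 * exp(1i * k2 * slab$t_myelin) / denom
  Tv <- Re(k3) / Re(k1) * Mod(t)^2
  data.frame(lambda_um = lambda, R = Mod(r)^2, T = Tv)
}

#' Sheath reflectance seen from the axon
#'
#' @inheritParams slab_rt
#' @return Reflectance values in `[0, 1]`.
#' @export
slab_reflectance <- function(lambda, slab) slab_rt(lambda, slab)$R

#' Bounce-model estimate of axon-port transmission
#'
#' A meridional ray at axial index `n_eff` crosses the axon and strikes the
#' sheath `N = L sqrt(n_axon^2 - n_eff^2) / (2 r_axon n_eff)` times over a
#' fiber of length `L`; if each strike reflects with the Fabry-Perot
#' reflectance `R(lambda)`, the surviving axon power is `T = R^N`.  Maxima
#' sit at anti-resonant wavelengths, minima at the resonances.
#'
#' @param spec a [fiber_spec()].
#' @param lambda wavelengths in micrometers (vectorized).
#' @param n_eff axial effective index, below `n_axon` (default 1.0297).
#' @return Data frame `lambda_um`, `R`, `n_bounces`, `T_axon_est`.
#' @export
ray_transmission_estimate <- function(spec, lambda, n_eff = 1.0297) {
  stopifnot(inherits(spec, "fiber_spec"))
  cst <- spec$constants
  if (n_eff >= cst$n_axon)
    stop("bounce model needs n_eff < n_axon (anti-resonant axon regime)")
  slab <- slab_from_fiber(spec, n_eff = n_eff)
  R <- slab_reflectance(lambda, slab)
  N <- spec$length_um * sqrt(cst$n_axon^2 - n_eff^2) /
    (2 * spec$r_axon * n_eff)
  data.frame(lambda_um = lambda, R = R, n_bounces = N, T_axon_est = R^N)
}

#' Anti-resonance summary table over a wavelength grid
#'
#' Convenience wrapper bundling [transverse_phase()], [slab_reflectance()],
#' [is_antiresonant()] and [ray_transmission_estimate()] per wavelength.
#'
#' @param spec a [fiber_spec()].
#' @param lambda_nm wavelength grid in nanometers (default 300 to 900 by 5).
#' @param n_eff axial effective index (default 1.0297).
#' @param tol anti-resonance phase threshold (see [is_antiresonant()]).
#' @return Data frame with columns `wavelength_nm`, `transverse_phase_rad`,
#'   `reflectance`, `antiresonant`, `T_axon_est`.
#' @export
arrow_table <- function(spec, lambda_nm = seq(300, 900, by = 5),
                        n_eff = 1.0297, tol = pi / 4) {
  lam <- lambda_nm / 1000
  slab <- slab_from_fiber(spec, n_eff = n_eff)
  est <- ray_transmission_estimate(spec, lam, n_eff = n_eff)
  data.frame(wavelength_nm = lambda_nm,
             transverse_phase_rad = transverse_phase(lam, slab),
             reflectance = est$R,
             antiresonant = is_antiresonant(lam, slab, tol = tol),
             T_axon_est = est$T_axon_est)
}
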