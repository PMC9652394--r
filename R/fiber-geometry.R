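# Parametric nerve-fiber geometry: a low-index axon cylinder wrapped in a
# high-index myelin annulus, immersed in extracellular fluid, with optional
# biological imperfections (sinusoidal bend, cosine sheath-thickness
# variation, node of Ranvier).  All lengths in micrometers.

#' Refractive indices of the three fiber media
#'
#' The myelinated axon is modeled as three lossless media: the axoplasm
#' (core), the myelin sheath (annular cladding) and the extracellular fluid.
#' The physiological ordering `n_fluid < n_axon < n_myelin` makes the fiber a
#' depressed-core waveguide: the core index lies *below* the cladding index,
#' so guidance in the axon is anti-resonant (ARROW) rather than by total
#' internal reflection.
#'
#' @param n_axon refractive index of the axoplasm (default 1.38).
#' @param n_myelin refractive index of the myelin sheath (default 1.44).
#' @param n_fluid refractive index of the extracellular fluid (default 1.34).
#' @return An object of class `optical_constants`.
#' @export
#' @examples
#' optical_constants()
optical_constants <- function(n_axon = 1.38, n_myelin = 1.44, n_fluid = 1.34) {
  stopifnot(is.numeric(n_axon), is.numeric(n_myelin), is.numeric(n_fluid))
  if (any(c(n_axon, n_myelin, n_fluid) < 1))
    stop("refractive indices must be real and >= 1 (lossless media)")
  if (!(n_fluid < n_axon && n_axon < n_myelin))
    stop("index ordering must be n_fluid < n_axon < n_myelin")
  structure(list(n_axon = n_axon, n_myelin = n_myelin, n_fluid = n_fluid),
            class = "optical_constants")
}

#' @export
print.optical_constants <- function(x, ...) {
  cat(sprintf("optical constants: n_axon = %.4g, n_myelin = %.4g, n_fluid = %.4g\n",
              x$n_axon, x$n_myelin, x$n_fluid))
  invisible(x)
}

#' Myelin thickness from the g-ratio
#'
#' The g-ratio is the ratio of the axon radius to the outer radius of the
#' myelin sheath, `g = r_axon / (r_axon + t_myelin)`.  Inverting gives the
#' sheath thickness `t_myelin = r_axon (1 - g) / g`.
#'
#' @param r_axon axon radius in micrometers (> 0).
#' @param g_ratio g-ratio in (0, 1]; smaller g means thicker myelin.
#' @return Myelin thickness in micrometers.
#' @export
#' @examples
#' thickness_from_g(0.4, 0.7)
thickness_from_g <- function(r_axon, g_ratio) {
  stopifnot(all(r_axon > 0))
  if (any(g_ratio <= 0) || any(g_ratio > 1))
    stop("g_ratio must lie in (0, 1]")
  r_axon * (1 - g_ratio) / g_ratio
}

#' g-ratio from axon radius and myelin thickness
#'
#' @param r_axon axon radius in micrometers (> 0).
#' @param t_myelin myelin thickness in micrometers (>= 0).
#' @return g-ratio in (0, 1].
#' @export
#' @examples
#' g_from_radii(0.4, thickness_from_g(0.4, 0.7))
g_from_radii <- function(r_axon, t_myelin) {
  stopifnot(all(r_axon > 0))
  if (any(t_myelin < 0)) stop("t_myelin must be non-negative")
  r_axon / (r_axon + t_myelin)
}

#' Curvature of the sinusoidally bent fiber
#'
#' A fiber whose centerline is displaced by `A cos(2 pi z / L)` has peak
#' curvature `delta_kappa = 4 A (2 pi / L)^2` (the second derivative of the
#' displacement at its extrema, doubled peak-to-peak convention used in the
#' biophoton-guidance literature).
#'
#' @param amplitude_A bend amplitude in micrometers (>= 0).
#' @param length_L fiber length in micrometers (> 0).
#' @return Curvature in 1/micrometers.
#' @export
#' @examples
#' curvature(0.2, 27)
curvature <- function(amplitude_A, length_L) {
  if (any(length_L <= 0)) stop("length_L must be positive")
  if (any(amplitude_A < 0)) stop("amplitude_A must be non-negative")
  4 * amplitude_A * (2 * pi / length_L)^2
}

#' Bend amplitude from curvature
#'
#' Inverse of [curvature()]: `A = delta_kappa L^2 / (16 pi^2)`.
#'
#' @param delta_kappa curvature in 1/micrometers (>= 0).
#' @param length_L fiber length in micrometers (> 0).
#' @return Bend amplitude in micrometers.
#' @export
amplitude_from_curvature <- function(delta_kappa, length_L) {
  if (any(length_L <= 0)) stop("length_L must be positive")
  if (any(delta_kappa < 0)) stop("delta_kappa must be non-negative")
  delta_kappa * length_L^2 / (16 * pi^2)
}

#' Parametric description of one nerve fiber
#'
#' Collects every geometric and optical parameter of a single myelinated-axon
#' configuration: axon radius, g-ratio (hence myelin thickness), length, and
#' the three optional imperfections.
#'
#' * **bend**: the whole fiber centerline is displaced in the x direction by
#'   `A cos(2 pi z / L)`, a gentle arc with peak curvature
#'   `4 A (2 pi / L)^2`.
#' * **variation**: the *outer* myelin boundary ripples as
#'   `r_out(z) = r_axon + t_myelin + A cos(2 pi V z / L + phase)`; the axon
#'   radius stays constant.  Where the ripple trough would push the outer
#'   boundary inside the axon the sheath thickness is clamped at zero
#'   (locally bare axon).
#' * **node**: a node of Ranvier, an axial interval of length `node_length`
#'   in which the myelin annulus is replaced by extracellular fluid.
#'
#' @param r_axon axon radius, micrometers (default 0.4).
#' @param g_ratio g-ratio in (0, 1] (default 0.7).
#' @param length_um fiber length L, micrometers (default 27).
#' @param bend logical; enable the sinusoidal bend.
#' @param bend_amplitude bend amplitude A, micrometers (default 0.2).
#' @param variation logical; enable sheath-thickness variation.
#' @param variation_amplitude ripple amplitude, micrometers (default 0.2).
#' @param variation_factor V, ripple periods per fiber length (default 0.3).
#' @param variation_phase ripple phase, radians (default 0).
#' @param node logical; enable the node of Ranvier.
#' @param node_length node length, micrometers (default 0.7).
#' @param node_center axial position of the node center, micrometers
#'   (default L/2).
#' @param constants an [optical_constants()] object.
#' @return An object of class `fiber_spec`.
#' @export
#' @examples
#' fiber_spec()                          # straight default fiber, g = 0.7
#' fiber_spec(g_ratio = 0.6, bend = TRUE)
fiber_spec <- function(r_axon = 0.4, g_ratio = 0.7, length_um = 27,
                       bend = FALSE, bend_amplitude = 0.2,
                       variation = FALSE, variation_amplitude = 0.2,
                       variation_factor = 0.3, variation_phase = 0,
                       node = FALSE, node_length = 0.7,
                       node_center = length_um / 2,
                       constants = optical_constants()) {
  stopifnot(r_axon > 0, length_um > 0, inherits(constants, "optical_constants"))
  if (g_ratio <= 0 || g_ratio > 1) stop("g_ratio must lie in (0, 1]")
  if (node && node_length >= length_um)
    stop("node_length must be smaller than the fiber length")
  t_myelin <- thickness_from_g(r_axon, g_ratio)
  if (variation && variation_amplitude >= r_axon + t_myelin)
    stop("variation amplitude must be smaller than the outer radius ",
         "(outer boundary would cross the fiber axis)")
  if (bend && bend_amplitude < 0) stop("bend_amplitude must be non-negative")
  structure(list(
    r_axon = r_axon, g_ratio = g_ratio, t_myelin = t_myelin,
    length_um = length_um,
    bend = isTRUE(bend), bend_amplitude = bend_amplitude,
    variation = isTRUE(variation),
    variation_amplitude = variation_amplitude,
    variation_factor = variation_factor,
    variation_phase = variation_phase,
    node = isTRUE(node), node_length = node_length, node_center = node_center,
    constants = constants
  ), class = "fiber_spec")
}

#' @export
print.fiber_spec <- function(x, ...) {
  cat(sprintf("nerve fiber: r_axon = %.3g um, g = %.3g (t_myelin = %.4g um), L = %.3g um\n",
              x$r_axon, x$g_ratio, x$t_myelin, x$length_um))
  imp <- c(if (x$bend) sprintf("bend (A = %.3g um)", x$bend_amplitude),
           if (x$variation) sprintf("variation (A = %.3g um, V = %.3g)",
                                    x$variation_amplitude, x$variation_factor),
           if (x$node) sprintf("node of Ranvier (%.3g um at z = %.3g um)",
                               x$node_length, x$node_center))
  cat("imperfections:", if (length(imp)) paste(imp, collapse = ", ") else "none", "\n")
  invisible(x)
}

#' Transverse centerline offset of the (possibly bent) fiber
#'
#' @param z axial positions in micrometers, each within `[0, L]`.
#' @param spec a [fiber_spec()].
#' @return Offsets in micrometers (zero for a straight fiber).
#' @export
centerline_offset <- function(z, spec) {
  stopifnot(inherits(spec, "fiber_spec"))
  if (any(z < 0 | z > spec$length_um))
    stop("z must lie within [0, L]")
  if (!spec$bend) return(rep(0, length(z)))
  spec$bend_amplitude * cos(2 * pi * z / spec$length_um)
}

#' Outer myelin radius along the fiber
#'
#' With sheath variation enabled the outer boundary follows
#' `r_axon + t_myelin + A cos(2 pi V z / L + phase)`, clamped below at
#' `r_axon` (the sheath can locally thin to nothing but never inverts).
#'
#' @inheritParams centerline_offset
#' @return Outer radii in micrometers, measured from the local centerline.
#' @export
outer_radius <- function(z, spec) {
  stopifnot(inherits(spec, "fiber_spec"))
  if (any(z < 0 | z > spec$length_um))
    stop("z must lie within [0, L]")
  r0 <- spec$r_axon + spec$t_myelin
  if (!spec$variation) return(rep(r0, length(z)))
  r <- r0 + spec$variation_amplitude *
    cos(2 * pi * z * spec$variation_factor / spec$length_um +
          spec$variation_phase)
  pmax(r, spec$r_axon)
}

#' Axial interval covered by the node of Ranvier
#'
#' @param spec a [fiber_spec()].
#' @return Numeric length-2 vector (start, end) in micrometers, or `NULL`
#'   when the node is disabled.
#' @export
node_interval <- function(spec) {
  stopifnot(inherits(spec, "fiber_spec"))
  if (!spec$node) return(NULL)
  spec$node_center + c(-0.5, 0.5) * spec$node_length
}

#' Refractive index at arbitrary points
#'
#' Piecewise-constant three-medium index: axoplasm inside the (possibly
#' displaced) axon cylinder, myelin in the annulus up to [outer_radius()],
#' extracellular fluid elsewhere.  Inside the node-of-Ranvier interval the
#' myelin annulus is replaced by fluid (the axon remains).
#'
#' @param x,y transverse coordinates, micrometers (vectors, recycled).
#' @param z axial coordinates, micrometers (vector, recycled).
#' @param spec a [fiber_spec()].
#' @return Refractive indices, one of the three media values.
#' @export
#' @examples
#' index_at(0, 0, 13.5, fiber_spec())     # on-axis: axoplasm, 1.38
index_at <- function(x, y, z, spec) {
  stopifnot(inherits(spec, "fiber_spec"))
  n <- max(length(x), length(y), length(z))
  x <- rep_len(x, n); y <- rep_len(y, n); z <- rep_len(z, n)
  ox <- centerline_offset(z, spec)
  rho <- sqrt((x - ox)^2 + y^2)
  rout <- outer_radius(z, spec)
  cst <- spec$constants
  out <- rep(cst$n_fluid, n)
  in_node <- rep(FALSE, n)
  ni <- node_interval(spec)
  if (!is.null(ni)) in_node <- z >= ni[1] & z < ni[2]
  out[rho >= spec$r_axon & rho < rout & !in_node] <- cst$n_myelin
  out[rho < spec$r_axon] <- cst$n_axon
  out
}

#' Simulation grid specification
#'
#' Regular grid used to rasterize index maps and to propagate fields.  The
#' transverse window is square, centered on the fiber axis; axial slices sit
#' at mid-step positions `(k - 1/2) dz`.  `pad` is the clearance required
#' between the structure (including bend excursions) and the window edge,
#' where the absorbing boundary of the propagation engine lives.
#'
#' @param extent transverse window width, micrometers (default 4).
#' @param dx,dy transverse spacings, micrometers (default 4/256).
#' @param dz axial spacing, micrometers (default 0.025).
#' @param pad required structure-to-boundary clearance, micrometers
#'   (default 0.45, half the longest simulated wavelength).
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(extent = 4, dx = extent / 256, dy = dx, dz = 0.025,
                      pad = 0.45) {
  stopifnot(extent > 0, dx > 0, dy > 0, dz > 0, pad >= 0)
  nx <- as.integer(round(extent / dx))
  ny <- as.integer(round(extent / dy))
  structure(list(extent = extent, dx = dx, dy = dy, dz = dz, pad = pad,
                 nx = nx, ny = ny,
                 x = (seq_len(nx) - (nx + 1) / 2) * dx,
                 y = (seq_len(ny) - (ny + 1) / 2) * dy),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid: %d x %d transverse (%.3g um window, dx = %.4g um), dz = %.4g um\n",
              x$nx, x$ny, x$extent, x$dx, x$dz))
  invisible(x)
}

# Largest transverse structure radius over the fiber, bend excursion included.
max_structure_radius <- function(spec) {
  r0 <- spec$r_axon + spec$t_myelin
  r <- if (spec$variation) r0 + spec$variation_amplitude else r0
  if (spec$bend) r + spec$bend_amplitude else r
}

check_grid_covers <- function(spec, grid) {
  need <- 2 * (max_structure_radius(spec) + grid$pad)
  if (grid$extent < need)
    stop(sprintf("grid extent %.3g um too small: structure plus padding needs %.3g um",
                 grid$extent, need))
  invisible(TRUE)
}

#' Transverse index slice at one axial position
#'
#' With `antialias = FALSE` every pixel takes the exact [index_at()] value at
#' its center (piecewise constant, three media values).  With
#' `antialias = TRUE` pixels straddling a circular boundary take the
#' coverage-weighted blend of the two media (linear ramp of width one pixel
#' across each interface), which suppresses staircase scattering when the
#' slice is used as a beam-propagation phase screen.
#'
#' @param spec a [fiber_spec()].
#' @param grid a [grid_spec()].
#' @param z axial position, micrometers.
#' @param antialias smooth circular boundaries by subpixel coverage.
#' @return An `nx` by `ny` matrix of refractive indices.
#' @export
index_slice <- function(spec, grid, z, antialias = FALSE) {
  stopifnot(inherits(grid, "grid_spec"))
  check_grid_covers(spec, grid)
  xm <- matrix(grid$x, grid$nx, grid$ny)
  ym <- matrix(grid$y, grid$nx, grid$ny, byrow = TRUE)
  if (!antialias)
    return(matrix(index_at(as.vector(xm), as.vector(ym), z, spec),
                  grid$nx, grid$ny))
  x0 <- centerline_offset(z, spec)
  rout <- outer_radius(z, spec)
  ni <- node_interval(spec)
  in_node <- !is.null(ni) && z >= ni[1] && z < ni[2]
  cst <- spec$constants
  rho <- sqrt((xm - x0)^2 + ym^2)
  w <- grid$dx
  cov_ax <- pmin(pmax((spec$r_axon - rho) / w + 0.5, 0), 1)
  if (in_node)
    return(cst$n_fluid + (cst$n_axon - cst$n_fluid) * cov_ax)
  cov_out <- pmin(pmax((rout - rho) / w + 0.5, 0), 1)
  cst$n_fluid + (cst$n_myelin - cst$n_fluid) * cov_out +
    (cst$n_axon - cst$n_myelin) * cov_ax
}

#' Rasterize a fiber into a 3-D refractive-index map
#'
#' Samples [index_at()] at every voxel center.  Deterministic; every sample
#' is one of the three media indices (no smoothing).
#'
#' @param spec a [fiber_spec()].
#' @param grid a [grid_spec()].
#' @return An object of class `index_map`: list with the `nx x ny x nz`
#'   array `n`, the axial slice positions `z`, and the generating `spec` and
#'   `grid`.
#' @export
rasterize <- function(spec, grid) {
  stopifnot(inherits(spec, "fiber_spec"), inherits(grid, "grid_spec"))
  check_grid_covers(spec, grid)
  nz <- as.integer(round(spec$length_um / grid$dz))
  z <- (seq_len(nz) - 0.5) * grid$dz
  arr <- array(NA_real_, dim = c(grid$nx, grid$ny, nz))
  for (k in seq_len(nz)) arr[, , k] <- index_slice(spec, grid, z[k])
  structure(list(n = arr, z = z, spec = spec, grid = grid),
            class = "index_map")
}

#' @export
print.index_map <- function(x, ...) {
  cat(sprintf("index map: %d x %d x %d voxels, values {%s}\n",
              dim(x$n)[1], dim(x$n)[2], dim(x$n)[3],
              paste(sort(unique(as.vector(x$n))), collapse = ", ")))
  invisible(x)
}

#' Export an index map as a plain-text grid dump
#'
#' Writes a commented header (grid metadata, fiber parameters) followed by
#' one whitespace-separated row per voxel: `x_um y_um z_um n`.  Intended for
#' inspection and external rendering of small maps.
#'
#' @param im an [rasterize()] result.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
export_index_map <- function(im, path) {
  stopifnot(inherits(im, "index_map"))
  g <- im$grid
  hdr <- c("# nervearrow index map",
           sprintf("# nx %d ny %d nz %d", g$nx, g$ny, length(im$z)),
           sprintf("# dx_um %g dy_um %g dz_um %g extent_um %g",
                   g$dx, g$dy, g$dz, g$extent),
           sprintf("# r_axon_um %g g_ratio %g length_um %g",
                   im$spec$r_axon, im$spec$g_ratio, im$spec$length_um),
           "# columns: x_um y_um z_um n")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  xm <- rep(g$x, times = g$ny)
  ym <- rep(g$y, each = g$nx)
  for (k in seq_along(im$z)) {
    df <- cbind(xm, ym, im$z[k], as.vector(im$n[, , k]))
    write.table(format(df, digits = 8, trim = TRUE), con,
                row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
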