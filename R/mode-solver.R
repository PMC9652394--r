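# Semi-analytic scalar (weak-guidance) mode solver for the straight
# multilayer cylindrical fiber.  Fields in each annular layer are cylinder
# functions — J_l/Y_l where the layer is oscillatory (n_layer > n_eff),
# I_l/K_l where it is evanescent — matched by continuity of the field and
# its radial derivative at each interface, with pure K_l decay enforced in
# the unbounded outer medium.

#' Multilayer cylindrical index stack
#'
#' @param radii interface radii in micrometers, strictly increasing.
#' @param indices layer refractive indices inner to outer; one more entry
#'   than `radii` (the last layer is unbounded).
#' @return An object of class `layer_stack`.
#' @export
#' @examples
#' layer_stack(c(0.4, 0.5714), c(1.38, 1.44, 1.34))
layer_stack <- function(radii, indices) {
  stopifnot(is.numeric(radii), is.numeric(indices))
  if (length(indices) != length(radii) + 1)
    stop("need exactly one more layer index than interface radius")
  if (any(radii <= 0) || is.unsorted(radii, strictly = TRUE))
    stop("interface radii must be positive and strictly increasing")
  structure(list(radii = radii, indices = indices), class = "layer_stack")
}

#' Three-layer stack of a nerve fiber
#'
#' @param spec a [fiber_spec()]; the stack describes the straight,
#'   unperturbed fiber (imperfections are handled by beam propagation).
#' @return A [layer_stack()] with layers axon, myelin, fluid.
#' @export
nerve_stack <- function(spec) {
  stopifnot(inherits(spec, "fiber_spec"))
  cst <- spec$constants
  if (spec$t_myelin <= 0)      # unmyelinated limit: axon in fluid
    return(layer_stack(spec$r_axon, c(cst$n_axon, cst$n_fluid)))
  layer_stack(c(spec$r_axon, spec$r_axon + spec$t_myelin),
              c(cst$n_axon, cst$n_myelin, cst$n_fluid))
}

# Cylinder-function values and radial derivatives.  kind "osc" uses J/Y with
# argument kr, kind "evan" uses I/K with argument gr; derivative is with
# respect to r (chain-rule factor kappa included by the caller).
bessel_j_d <- function(l, x)
  if (l == 0) -besselJ(x, 1) else 0.5 * (besselJ(x, l - 1) - besselJ(x, l + 1))
bessel_y_d <- function(l, x)
  if (l == 0) -besselY(x, 1) else 0.5 * (besselY(x, l - 1) - besselY(x, l + 1))
bessel_i_d <- function(l, x)
  if (l == 0) besselI(x, 1) else 0.5 * (besselI(x, l - 1) + besselI(x, l + 1))
bessel_k_d <- function(l, x)
  if (l == 0) -besselK(x, 1) else -0.5 * (besselK(x, l - 1) + besselK(x, l + 1))

# Basis (F, G) of the radial equation in one layer, evaluated at radius r.
# Returns value and d/dr for both solutions.  For the regular (innermost)
# layer only F is used: J_l (oscillatory) or I_l (evanescent).
layer_basis <- function(l, kappa, r, oscillatory) {
  x <- kappa * r
  if (oscillatory) {
    list(F = besselJ(x, l), dF = kappa * bessel_j_d(l, x),
         G = besselY(x, l), dG = kappa * bessel_y_d(l, x))
  } else {
    list(F = besselI(x, l), dF = kappa * bessel_i_d(l, x),
         G = besselK(x, l), dG = kappa * bessel_k_d(l, x))
  }
}

# Transverse wavenumber magnitude in a layer.
layer_kappa <- function(k0, n_layer, n_eff) k0 * sqrt(abs(n_layer^2 - n_eff^2))

# March (u, u') from the regular inner solution across all interior
# interfaces; returns the field and derivative just inside the outer
# interface plus per-layer coefficients (for profile reconstruction).
march_layers <- function(n_eff, lambda, l, stack) {
  k0 <- 2 * pi / lambda
  nr <- length(stack$radii)
  coef <- vector("list", nr + 1)
  osc1 <- stack$indices[1] > n_eff
  kap1 <- layer_kappa(k0, stack$indices[1], n_eff)
  coef[[1]] <- list(A = 1, B = 0, kappa = kap1, osc = osc1)
  b <- layer_basis(l, kap1, stack$radii[1], osc1)
  u <- b$F; du <- b$dF
  if (nr >= 2) {
    for (j in 2:nr) {
      oscj <- stack$indices[j] > n_eff
      kapj <- layer_kappa(k0, stack$indices[j], n_eff)
      rin <- stack$radii[j - 1]
      bin <- layer_basis(l, kapj, rin, oscj)
      # analytic Wronskian of the basis pair: 2/(pi r) for J/Y, -1/r for I/K
      W <- if (oscj) 2 / (pi * rin) else -1 / rin
      ab <- c((u * bin$dG - du * bin$G) / W,
              (du * bin$F - u * bin$dF) / W)
      coef[[j]] <- list(A = ab[1], B = ab[2], kappa = kapj, osc = oscj)
      bout <- layer_basis(l, kapj, stack$radii[j], oscj)
      u <- ab[1] * bout$F + ab[2] * bout$G
      du <- ab[1] * bout$dF + ab[2] * bout$dG
    }
  }
  list(u = u, du = du, coef = coef, k0 = k0)
}

#' Dispersion residual of the scalar multilayer fiber
#'
#' Zero exactly at scalar-mode effective indices.  The field is marched from
#' the regular inner solution across every interface; the residual is the
#' Wronskian-type mismatch with the decaying `K_l` solution of the unbounded
#' outer medium, normalized so its sign is continuous across the bound-mode
#' search window `(n_fluid, n_myelin)`.
#'
#' @param n_eff trial effective indices (vectorized).
#' @param lambda wavelength in micrometers.
#' @param l azimuthal order (non-negative integer).
#' @param stack a [layer_stack()].
#' @return Normalized residuals, one per `n_eff`.
#' @export
dispersion_residual <- function(n_eff, lambda, l, stack) {
  stopifnot(inherits(stack, "layer_stack"), lambda > 0, l >= 0)
  n_out <- stack$indices[length(stack$indices)]
  n_max <- max(stack$indices)
  if (any(n_eff <= n_out) || any(n_eff >= n_max))
    stop("n_eff must lie inside the bound-mode window (n_outer, n_max)")
  vapply(n_eff, function(ne) {
    m <- march_layers(ne, lambda, l, stack)
    rlast <- stack$radii[length(stack$radii)]
    gam <- layer_kappa(m$k0, n_out, ne)
    K <- besselK(gam * rlast, l)
    dK <- gam * bessel_k_d(l, gam * rlast)
    res <- m$du * K - m$u * dK
    res / (sqrt(m$u^2 + m$du^2) * sqrt(K^2 + dK^2))
  }, numeric(1))
}

# Radial field profile from marched layer coefficients; r vectorized.
profile_eval <- function(r, n_eff, lambda, l, stack) {
  m <- march_layers(n_eff, lambda, l, stack)
  nr <- length(stack$radii)
  rlast <- stack$radii[nr]
  gam <- layer_kappa(m$k0, stack$indices[nr + 1], n_eff)
  # outer coefficient scales K_l to match the marched field at r_last
  Kl <- besselK(gam * rlast, l)
  cK <- if (Kl > 0) m$u / Kl else 0
  out <- numeric(length(r))
  lo <- 0
  for (j in seq_len(nr)) {
    sel <- r >= lo & r < stack$radii[j]
    if (any(sel)) {
      cf <- m$coef[[j]]
      b <- layer_basis(l, cf$kappa, r[sel], cf$osc)
      out[sel] <- cf$A * b$F + cf$B * b$G
    }
    lo <- stack$radii[j]
  }
  sel <- r >= rlast
  if (any(sel)) out[sel] <- cK * besselK(gam * r[sel], l)
  out
}

#' Classify a mode by its effective index
#'
#' The guidance regime is set by where `n_eff` falls relative to the three
#' media: `myelin_TIR` modes (`n_axon < n_eff < n_myelin`) are confined to
#' the sheath by total internal reflection at both myelin boundaries;
#' `axon_regime` (`n_fluid < n_eff < n_axon`) is the anti-resonant window in
#' which the sheath acts as a Fabry-Perot reflector around the axon;
#' anything at or below `n_fluid` is unbound (`sub_fluid_leaky`).
#'
#' @param n_eff effective index (> 0).
#' @param constants an [optical_constants()] object.
#' @return One of `"myelin_TIR"`, `"axon_regime"`, `"sub_fluid_leaky"`.
#' @export
#' @examples
#' classify(1.40, optical_constants())   # myelin_TIR
classify <- function(n_eff, constants = optical_constants()) {
  stopifnot(inherits(constants, "optical_constants"), all(n_eff > 0))
  if (any(n_eff >= constants$n_myelin))
    stop("no bound mode can have n_eff >= n_myelin")
  ifelse(n_eff > constants$n_axon, "myelin_TIR",
         ifelse(n_eff > constants$n_fluid, "axon_regime", "sub_fluid_leaky"))
}

#' Power confinement fractions of a radial profile
#'
#' Fractions of `|field|^2 r dr` power inside the axon, the myelin annulus
#' and the outer fluid (to infinity, using the analytic `K_l` tail).
#'
#' @param n_eff,lambda,l mode parameters (see [find_modes()]).
#' @param stack a [layer_stack()].
#' @return Named numeric vector `c(f_axon, f_myelin, f_fluid)` summing to 1.
#' @export
confinement <- function(n_eff, lambda, l, stack) {
  stopifnot(inherits(stack, "layer_stack"))
  f <- function(r) profile_eval(r, n_eff, lambda, l, stack)^2 * r
  nr <- length(stack$radii)
  bounds <- c(0, stack$radii)
  parts <- vapply(seq_len(nr), function(j)
    stats::integrate(f, bounds[j], bounds[j + 1],
                     rel.tol = 1e-9, subdivisions = 400L)$value,
    numeric(1))
  # outer tail: K_l decays exponentially; integrate to where it is negligible
  gam <- layer_kappa(2 * pi / lambda, stack$indices[nr + 1], n_eff)
  rmax <- stack$radii[nr] + 40 / gam
  tail <- stats::integrate(f, stack$radii[nr], rmax,
                           rel.tol = 1e-9, subdivisions = 400L)$value
  tot <- sum(parts) + tail
  if (!is.finite(tot) || tot <= 0) stop("non-normalizable mode profile")
  out <- c(parts, tail) / tot
  if (nr == 2) names(out) <- c("f_axon", "f_myelin", "f_fluid")
  else names(out) <- c(paste0("f_layer", seq_len(nr)), "f_outer")
  out
}

#' Find scalar guided modes of a multilayer fiber
#'
#' Scans the bound-mode window `(n_outer, n_max)` on a regular `n_eff` grid
#' for sign changes of [dispersion_residual()], refines each bracket with
#' bisection/Brent to machine tolerance, and keeps roots whose refined
#' residual is below `1e-9`.  Each mode is classified and its confinement
#' fractions computed.
#'
#' @param lambda wavelength in micrometers (> 0).
#' @param stack a [layer_stack()].
#' @param l_max largest azimuthal order scanned (default 5).
#' @param scan_step `n_eff` scan-grid spacing (default 1e-4).
#' @param constants optical constants used for classification; defaults to
#'   the standard nerve media.
#' @return A data frame sorted by decreasing `n_eff`, one row per mode:
#'   `lambda_um, l, n_eff, family, f_axon, f_myelin, f_fluid` (confinement
#'   columns for three-layer stacks).  Zero rows is a valid result.
#' @export
#' @examples
#' \donttest{
#' find_modes(0.74, nerve_stack(fiber_spec()), l_max = 2)
#' }
find_modes <- function(lambda, stack, l_max = 5, scan_step = 1e-4,
                       constants = optical_constants()) {
  stopifnot(lambda > 0, inherits(stack, "layer_stack"))
  n_out <- stack$indices[length(stack$indices)]
  n_max <- max(stack$indices)
  eps <- 1e-9
  grid <- seq(n_out + scan_step / 2, n_max - scan_step / 2, by = scan_step)
  # keep the grid clear of interior layer indices where the basis switches
  for (ni in stack$indices) grid <- grid[abs(grid - ni) > 1e-7]
  rows <- list()
  for (l in 0:l_max) {
    res <- dispersion_residual(grid, lambda, l, stack)
    sgn <- sign(res)
    idx <- which(sgn[-1] * sgn[-length(sgn)] < 0)
    for (i in idx) {
      root <- tryCatch(
        stats::uniroot(function(ne) dispersion_residual(ne, lambda, l, stack),
                       lower = grid[i], upper = grid[i + 1],
                       tol = 1e-13)$root,
        error = function(e) NA_real_)
      if (is.na(root)) next
      if (abs(dispersion_residual(root, lambda, l, stack)) > 1e-9) next
      if (root <= n_out + eps || root >= n_max - eps) next
      fam <- if (length(stack$indices) == 3)
        classify(root, constants) else NA_character_
      conf <- tryCatch(confinement(root, lambda, l, stack),
                       error = function(e) rep(NA_real_, length(stack$indices)))
      rows[[length(rows) + 1]] <-
        c(list(lambda_um = lambda, l = l, n_eff = root, family = fam),
          as.list(conf))
    }
  }
  if (!length(rows)) {
    out <- data.frame(lambda_um = numeric(0), l = integer(0),
                      n_eff = numeric(0), family = character(0))
    return(out)
  }
  out <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  out <- out[!duplicated(round(out$n_eff, 8) + 1e4 * out$l), , drop = FALSE]
  out <- out[order(-out$n_eff), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Radial field profile of one mode
#'
#' @param r radii in micrometers (vector).
#' @param n_eff effective index of the mode (a root of
#'   [dispersion_residual()]).
#' @param lambda wavelength in micrometers.
#' @param l azimuthal order.
#' @param stack a [layer_stack()].
#' @return Scalar field samples, normalized to peak magnitude 1.
#' @export
mode_profile <- function(r, n_eff, lambda, l, stack) {
  u <- profile_eval(r, n_eff, lambda, l, stack)
  m <- max(abs(u))
  if (m > 0) u / m else u
}

#' Cutoff wavelength of a mode family and order
#'
#' Longest wavelength at which [find_modes()] still returns at least one
#' mode of the requested azimuthal order (and, optionally, family), located
#' by bisection over `lambda_range`.
#'
#' @param stack a [layer_stack()].
#' @param l azimuthal order.
#' @param family optional family filter (`"myelin_TIR"` etc.); `NULL`
#'   accepts any bound mode.
#' @param mode_index require at least this many modes of the order/family
#'   (default 1: the fundamental; 2 finds the second-mode cutoff).
#' @param lambda_range search interval in micrometers (default 0.1 to 2).
#' @param tol bisection tolerance in micrometers (default 1e-4).
#' @param constants optical constants for classification.
#' @return Cutoff wavelength in micrometers, or `NA` with a warning when no
#'   mode exists anywhere in the range.
#' @export
cutoff_wavelength <- function(stack, l, family = NULL, mode_index = 1,
                              lambda_range = c(0.1, 2), tol = 1e-4,
                              constants = optical_constants()) {
  has_mode <- function(lam) {
    m <- find_modes(lam, stack, l_max = l, constants = constants)
    m <- m[m$l == l, , drop = FALSE]
    if (!is.null(family) && nrow(m)) m <- m[m$family == family, , drop = FALSE]
    nrow(m) >= mode_index
  }
  lo <- lambda_range[1]; hi <- lambda_range[2]
  if (!has_mode(lo)) {
    warning("no mode of the requested order/family anywhere in the range")
    return(NA_real_)
  }
  if (has_mode(hi)) return(hi)   # no cutoff inside the range
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (has_mode(mid)) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
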