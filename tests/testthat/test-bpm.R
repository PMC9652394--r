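test_that("launch fields are unit power and correctly localized", {
  s <- fiber_spec()
  g <- grid_spec(extent = 4, dx = 4 / 128, dz = 0.05)
  fa <- make_launch(s, g, 0.473, launch_spec("axon"))
  expect_equal(field_power(fa), 1, tolerance = 1e-12)
  masks <- port_masks(s, g, z = 0)
  # default axon waist r/sqrt(2): analytic in-disc fraction 1 - exp(-4)
  expect_gte(port_power(fa, masks$axon), 0.9)
  expect_equal(port_power(fa, masks$axon), 1 - exp(-4), tolerance = 0.02)
  fm <- make_launch(s, g, 0.473, launch_spec("myelin"))
  expect_equal(field_power(fm), 1, tolerance = 1e-12)
  # ring intensity peaks at the mid-annulus radius
  row <- Mod(fm$u[, g$ny %/% 2 + 1])^2
  r_peak <- abs(g$x[which.max(row)])
  expect_equal(r_peak, s$r_axon + s$t_myelin / 2, tolerance = g$dx)
  expect_error(make_launch(s, g, 0.473, launch_spec("axon", waist = 5)),
               "window")
  expect_warning(make_launch(s, g, 1.2, launch_spec("axon")), "band")
})

test_that("free-space step reproduces the closed-form Gaussian diffraction law", {
  s <- fiber_spec()   # only used to build the field container
  g <- grid_spec(extent = 5.12, dx = 0.02, dz = 0.05)
  w0 <- 0.6; lam <- 0.5; n <- 1.34
  xm <- matrix(g$x, g$nx, g$ny); ym <- matrix(g$y, g$nx, g$ny, byrow = TRUE)
  f <- make_launch(s, g, lam, launch_spec("axon", waist = w0))
  # uniform fluid: 40 steps of 0.05 um
  for (k in 1:40) f <- bpm_step(f, n, 0.05, n_ref = n)
  expect_equal(f$z, 2)
  rho2 <- xm^2 + ym^2
  I <- Mod(f$u)^2
  w_meas <- sqrt(2 * sum(I * rho2) / sum(I))
  w_ref <- w0 * sqrt(1 + (lam * 2 / (pi * w0^2 * n))^2)
  expect_equal(w_meas, w_ref, tolerance = 0.005 * w_ref)
  # unitary propagation: no power lost without an absorber
  expect_equal(field_power(f), 1, tolerance = 1e-9)
})

test_that("a zero-length step is the identity and sampling violations error", {
  s <- fiber_spec()
  g <- grid_spec(extent = 4, dx = 4 / 128, dz = 0.05)
  f <- make_launch(s, g, 0.473, launch_spec("axon"))
  f0 <- bpm_step(f, 1.34, 0)
  expect_identical(f0$u, f$u)
  g_bad <- grid_spec(extent = 4, dx = 0.3, dz = 0.05)
  fb <- make_launch(s, g_bad, 0.473, launch_spec("axon"))
  expect_error(bpm_step(fb, 1.44, 0.05), "anti-alias")
})

test_that("step-size refinement converges over a fixed distance", {
  s <- fiber_spec(length_um = 2)
  g1 <- grid_spec(extent = 4, dx = 4 / 128, dz = 0.025)
  g2 <- grid_spec(extent = 4, dx = 4 / 128, dz = 0.0125)
  r1 <- propagate(s, g1, 0.5, launch_spec("myelin"))
  r2 <- propagate(s, g2, 0.5, launch_spec("myelin"))
  expect_lt(abs(r1$T_total - r2$T_total), 1e-3)
  expect_lt(abs(r1$T_myelin - r2$T_myelin), 1e-3)
})

test_that("port masks partition the window and port_power respects it", {
  s <- fiber_spec()
  g <- grid_spec(extent = 4, dx = 4 / 128, dz = 0.05)
  masks <- port_masks(s, g)
  expect_false(any(masks$axon & masks$myelin))
  f <- make_launch(s, g, 0.473, launch_spec("myelin"))
  full <- matrix(TRUE, g$nx, g$ny)
  expect_equal(port_power(f, full), field_power(f))
  expect_equal(port_power(f, !full), 0)
  rest <- full & !masks$axon & !masks$myelin
  expect_equal(port_power(f, masks$axon) + port_power(f, masks$myelin) +
                 port_power(f, rest), field_power(f), tolerance = 1e-12)
  expect_error(port_power(f, matrix(TRUE, 2, 2)), "mismatch")
  # node at the measurement plane empties the myelin port
  sn <- fiber_spec(node = TRUE, node_center = 27)
  mn <- port_masks(sn, g, z = 27)
  expect_false(any(mn$myelin))
})

test_that("energy is conserved: exit power plus absorbed equals the launch", {
  s <- fiber_spec()
  g <- default_grid("coarse")
  r <- cached("prop473", propagate(s, g, 0.473, launch_spec("myelin"),
                                   keep_field = FALSE))
  expect_equal(r$T_total + r$absorbed, 1, tolerance = 0.01)
  expect_lte(r$T_axon + r$T_myelin, r$T_total + 1e-12)
  expect_lte(r$T_total, 1 + 1e-9)
})

test_that("straight-fiber propagation is invariant under axial reversal", {
  s <- fiber_spec(length_um = 5, node = TRUE, node_center = 2.5)
  g <- grid_spec(extent = 4, dx = 4 / 128, dz = 0.05)
  fwd <- propagate(s, g, 0.473, launch_spec("myelin"), keep_field = FALSE)
  rev <- propagate(s, g, 0.473, launch_spec("myelin"), keep_field = FALSE,
                   reverse = TRUE)
  expect_equal(fwd$T_axon, rev$T_axon, tolerance = 1e-6)
  expect_equal(fwd$T_myelin, rev$T_myelin, tolerance = 1e-6)
  expect_equal(fwd$T_total, rev$T_total, tolerance = 1e-6)
})

test_that("an eigenmode of a conventional high-index core propagates invariantly", {
  # sanity inversion: core index above cladding (ordinary step fiber);
  # the solver's fundamental, fed to the BPM, must transport unchanged
  a <- 0.3; n_co <- 1.44; n_cl <- 1.34; lam <- 0.5
  st <- layer_stack(a, c(n_co, n_cl))
  m <- find_modes(lam, st, l_max = 0)
  expect_gte(nrow(m), 1)
  g <- grid_spec(extent = 4, dx = 4 / 256, dz = 0.05)
  xm <- matrix(g$x, g$nx, g$ny); ym <- matrix(g$y, g$nx, g$ny, byrow = TRUE)
  rho <- sqrt(xm^2 + ym^2)
  u <- matrix(mode_profile(as.vector(rho), m$n_eff[1], lam, 0, st),
              g$nx, g$ny) + 0i
  u <- u / sqrt(sum(Mod(u)^2) * g$dx * g$dy)
  f <- structure(list(u = u, lambda_um = lam, grid = g, z = 0),
                 class = "bpm_field")
  nmat <- matrix(ifelse(rho < a, n_co, n_cl), g$nx, g$ny)
  core <- rho < a
  p0 <- sum(Mod(u[core])^2) * g$dx * g$dy
  for (k in 1:100) f <- bpm_step(f, nmat, 0.05, n_ref = m$n_eff[1])
  p1 <- sum(Mod(f$u[core])^2) * g$dx * g$dy
  expect_equal(field_power(f), 1, tolerance = 1e-9)       # unitary
  expect_gt(p1 / p0, 0.99)                                 # shape preserved
  expect_lt(abs(p1 - p0) / p0, 0.01)
})

test_that("adding the node never increases myelin-port transmission", {
  g <- default_grid("coarse")
  s0 <- fiber_spec()
  s1 <- fiber_spec(node = TRUE)
  for (nm in c(300, 500, 700, 900)) {
    t0 <- cached(paste0("norm_my_", nm),
                 propagate(s0, g, nm / 1000, launch_spec("myelin"),
                           keep_field = FALSE))$T_myelin
    t1 <- propagate(s1, g, nm / 1000, launch_spec("myelin"),
                    keep_field = FALSE)$T_myelin
    expect_lte(t1, t0 + 1e-9)
  }
})

test_that("halving the grid steps moves port transmissions by under 2 points", {
  s <- fiber_spec()
  base <- propagate(s, grid_spec(extent = 4, dx = 4 / 256, dz = 0.05),
                    0.473, launch_spec("myelin"), keep_field = FALSE)
  half_dz <- propagate(s, grid_spec(extent = 4, dx = 4 / 256, dz = 0.025),
                       0.473, launch_spec("myelin"), keep_field = FALSE)
  half_dx <- propagate(s, grid_spec(extent = 4, dx = 4 / 512, dz = 0.05),
                       0.473, launch_spec("myelin"), keep_field = FALSE)
  for (ch in c("T_axon", "T_myelin", "T_total")) {
    expect_lt(abs(base[[ch]] - half_dz[[ch]]), 0.02)
    expect_lt(abs(base[[ch]] - half_dx[[ch]]), 0.02)
  }
})
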