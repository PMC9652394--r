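# Synthetic spectra helper: wrap plain columns in the spectrum class.
fake_spectrum <- function(wl, ax, my) {
  out <- data.frame(wavelength_nm = wl, T_axon = ax, T_myelin = my,
                    T_total = pmin(ax + my, 1))
  class(out) <- c("transmission_spectrum", "data.frame")
  out
}

test_that("crossing of two synthetic lines is located exactly", {
  wl <- seq(300, 900, by = 25)
  a <- fake_spectrum(wl, wl / 900, 0 * wl)
  b <- fake_spectrum(wl, 1 - wl / 900, 0 * wl)
  expect_equal(as.numeric(crossing_wavelength(a, b, "axon")), 450)
  # identical spectra -> not-found signal
  expect_warning(x <- crossing_wavelength(a, a, "axon"), "do not cross")
  expect_true(is.na(x))
  # crossing forced exactly at a grid point is returned exactly
  cr0 <- crossing_wavelength(fake_spectrum(wl, wl / 900, 0 * wl),
                             fake_spectrum(wl, rep(600 / 900, length(wl)),
                                           0 * wl), "axon")
  expect_identical(as.numeric(cr0), 600)
  # step-function crossing interpolates linearly between grid points
  ax <- rep(0.5, length(wl)); ax[wl >= 500] <- 0.2
  my <- rep(0.3, length(wl))
  cr <- crossing_wavelength(fake_spectrum(wl, ax, my),
                            fake_spectrum(wl, my, ax), "axon")
  expect_equal(as.numeric(cr), 475 + 25 * 0.2 / 0.3)
  # all crossings are reported
  osc <- fake_spectrum(wl, 0.5 + 0.3 * sin(wl / 50), rep(0.5, length(wl)))
  flat <- fake_spectrum(wl, rep(0.5, length(wl)), rep(0.5, length(wl)))
  expect_gt(length(attr(crossing_wavelength(osc, flat, "axon"),
                        "all_crossings")), 1)
  expect_error(crossing_wavelength(a, fake_spectrum(wl + 5, ax, my), "axon"),
               "share")
})

test_that("band edge finds the axon/myelin crossing inside one spectrum", {
  wl <- seq(300, 900, by = 25)
  sp <- fake_spectrum(wl, 1 - wl / 900, wl / 900)
  expect_equal(as.numeric(band_edge(sp)), 450)
  expect_warning(be <- band_edge(fake_spectrum(wl, wl, wl + 1)), "cross")
  expect_true(is.na(be))
})

test_that("ratio tables have unit reference rows and the benchmark columns", {
  wl <- seq(300, 900, by = 25)
  spectra <- list(a = fake_spectrum(wl, wl / 900, 0.2 + 0 * wl),
                  b = fake_spectrum(wl, 2 * wl / 900, 0.1 + 0 * wl))
  rt <- ratio_table(spectra, reference = "a", channel = "axon")
  expect_named(rt, c("config", "nm300", "nm473", "nm540", "nm900"))
  expect_equal(unlist(rt[rt$config == "a", -1], use.names = FALSE),
               rep(1, 4))
  expect_equal(unlist(rt[rt$config == "b", -1], use.names = FALSE),
               rep(2, 4), tolerance = 1e-12)
  expect_true(all(unlist(rt[, -1]) > 0))
})

test_that("g-ratio sweep runs end to end on a reduced problem", {
  g <- grid_spec(extent = 4, dx = 4 / 128, dz = 0.1)
  res <- suppressWarnings(run_gratio_sweep("myelin", grid = g,
                          lambda_nm = c(300, 473, 540, 900),
                          base = list(length_um = 2)))
  expect_s3_class(res, "sweep_result")
  expect_named(res$spectra, c("g0.60", "g0.70", "g0.78"))
  # all spectra share one wavelength grid and lie in [0, 1]
  for (sp in res$spectra) {
    expect_equal(sp$wavelength_nm, c(300, 473, 540, 900))
    expect_true(all(sp$T_axon >= 0 & sp$T_axon <= 1))
    expect_true(all(sp$T_myelin >= 0 & sp$T_myelin <= 1))
    expect_true(all(sp$T_axon + sp$T_myelin <= sp$T_total + 1e-9))
  }
  expect_equal(nrow(res$ratios), 3)
  expect_equal(unlist(res$ratios[res$ratios$config == "g0.78", -1],
                      use.names = FALSE), rep(1, 4))
})

test_that("imperfection sweep covers normal, bend and variation, with node", {
  g <- grid_spec(extent = 4, dx = 4 / 128, dz = 0.1)
  res <- suppressWarnings(
    run_imperfection_sweep("myelin", with_node = TRUE, grid = g,
                           lambda_nm = c(300, 600),
                           base = list(length_um = 2)))
  expect_named(res$spectra, c("normal", "bend", "variation"))
  expect_equal(unlist(res$ratios[res$ratios$config == "normal", -1],
                      use.names = FALSE), rep(1, 4))
  # the node geometry really removes the sheath inside the node interval
  sn <- fiber_spec(length_um = 2, node = TRUE)
  ni <- node_interval(sn)
  zin <- mean(ni)
  rm <- sn$r_axon + sn$t_myelin / 2
  expect_equal(index_at(rm, 0, zin, sn), sn$constants$n_fluid)
})

test_that("written outputs round-trip and the manifest records the config", {
  g <- grid_spec(extent = 4, dx = 4 / 128, dz = 0.1)
  res <- suppressWarnings(
    run_gratio_sweep("myelin", grid = g, lambda_nm = c(300, 600),
                     g_ratios = c(0.7, 0.78), base = list(length_um = 2)))
  dir <- file.path(tempdir(), "nervearrow-out")
  files <- write_outputs(res, dir, specs = list(g0.70 = fiber_spec(length_um = 2)))
  expect_true(all(file.exists(files)))
  sp <- utils::read.csv(file.path(dir, "spectrum_g0.70.csv"))
  expect_equal(sp$T_myelin, res$spectra$g0.70$T_myelin, tolerance = 1e-12)
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(man$site, "myelin")
  expect_true(all(c("r_axon", "g_ratio", "length_um", "bend", "node") %in%
                    names(man$specs$g0.70)))
  # determinism: a rerun writes byte-identical spectra
  dir2 <- file.path(tempdir(), "nervearrow-out2")
  res2 <- suppressWarnings(
    run_gratio_sweep("myelin", grid = g, lambda_nm = c(300, 600),
                     g_ratios = c(0.7, 0.78), base = list(length_um = 2)))
  write_outputs(res2, dir2)
  expect_identical(readLines(file.path(dir, "spectrum_g0.70.csv")),
                   readLines(file.path(dir2, "spectrum_g0.70.csv")))
  unlink(c(dir, dir2), recursive = TRUE)
})

test_that("myelin- and axon-port shares of surviving power are complementary", {
  sp <- cached("sp_norm_my",
               transmission_spectrum(fiber_spec(), coarse_grid(), "myelin",
                                     coarse_wl()))
  expect_true(all(sp$T_axon >= 0 & sp$T_myelin >= 0 & sp$T_total <= 1))
  share_ax <- sp$T_axon / sp$T_total
  share_my <- sp$T_myelin / sp$T_total
  expect_lt(stats::cor(share_ax, share_my), 0)
})
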