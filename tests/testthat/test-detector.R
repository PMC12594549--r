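test_that("sampling a uniform field returns the constant at every diode", {
  g <- dose_grid(matrix(42, 61, 61), spacing = c(1, 1))
  for (fp in list(c(0, 0), c(7, 3))) {
    m <- sample_dose(g, detector_layout(pitch = 10, extent = 40, footprint = fp),
                     quiet = TRUE)
    expect_equal(m$dose, rep(42, nrow(m)))
  }
})

test_that("a symmetric footprint on a linear ramp reads the centre dose", {
  ax <- seq(-30, 30)
  g <- dose_grid(outer(0.8 * ax, 0.5 * ax, `+`) + 60, spacing = c(1, 1))
  m <- sample_dose(g, detector_layout(pitch = 10, extent = 40,
                                      footprint = c(7, 3)), quiet = TRUE)
  expect_equal(m$dose, 0.8 * m$pos_si + 0.5 * m$pos_rl + 60, tolerance = 1e-12)
})

test_that("footprint averaging matches a dense-quadrature oracle within 0.2%", {
  # fine grid so that bilinear error is negligible against the 0.2% band
  ax <- seq(-20, 20, by = 0.25)
  g <- dose_grid(outer(ax, ax, function(s, r) analytic_field(s, r)),
                 spacing = c(0.25, 0.25))
  lay <- detector_layout(pitch = 5, extent = 20, footprint = c(7, 3))
  m <- sample_dose(g, lay, quiet = TRUE)
  oracle <- mapply(brute_footprint_mean, m$pos_si, m$pos_rl,
                   MoreArgs = list(footprint = c(7, 3)))
  expect_lt(max(abs(m$dose - oracle)), 0.2)   # 0.2% of Dmax = 100
})

test_that("point-detector sampling is equivariant under field translation", {
  g <- generate_single_field()
  lay <- detector_layout(pitch = 10, extent = 60, footprint = c(0, 0))
  d <- c(3.2, -1.7)
  m_shift <- sample_dose(g, lay, shift = d, quiet = TRUE)
  g_trans <- dose_grid(g$values, spacing = g$spacing, origin = g$origin - d)
  m_trans <- sample_dose(g_trans, lay, shift = c(0, 0), quiet = TRUE)
  expect_equal(m_shift$dose, m_trans$dose, tolerance = 1e-12)
  expect_equal(m_shift$pos_si, m_trans$pos_si + d[1])
})

test_that("the elongated footprint attenuates an SI gradient more than an RL one", {
  # same sigmoid edge, oriented along each axis in turn
  ax <- seq(-30, 30)
  edge <- function(x) 100 * pnorm(-x / 2)
  g_si <- dose_grid(matrix(edge(ax), 61, 61, byrow = FALSE), spacing = c(1, 1))
  g_rl <- dose_grid(matrix(edge(ax), 61, 61, byrow = TRUE), spacing = c(1, 1))
  lay <- detector_layout(pitch = 10, extent = 10, footprint = c(7, 3))
  off <- c(2, 0)   # probe 2 mm off the edge, where attenuation is visible
  m_si <- sample_dose(g_si, lay, shift = off, quiet = TRUE)
  m_rl <- sample_dose(g_rl, lay, shift = rev(off), quiet = TRUE)
  err_si <- abs(m_si$dose - edge(2))
  err_rl <- abs(m_rl$dose - edge(2))
  expect_gt(err_si, err_rl)
  # square footprint: the directional difference collapses
  lay_sq <- detector_layout(pitch = 10, extent = 10, footprint = c(5, 5))
  m_si_sq <- sample_dose(g_si, lay_sq, shift = off, quiet = TRUE)
  m_rl_sq <- sample_dose(g_rl, lay_sq, shift = rev(off), quiet = TRUE)
  expect_equal(m_si_sq$dose, m_rl_sq$dose, tolerance = 1e-9)
})

test_that("noise is reproducible under a fixed seed and leaves RNG state alone", {
  g <- generate_single_field()
  lay <- detector_layout()
  m1 <- sample_dose(g, lay, noise = noise_model(0.01, seed = 5), quiet = TRUE)
  m2 <- sample_dose(g, lay, noise = noise_model(0.01, seed = 5), quiet = TRUE)
  m3 <- sample_dose(g, lay, noise = noise_model(0.01, seed = 6), quiet = TRUE)
  expect_identical(m1$dose, m2$dose)
  expect_false(isTRUE(all.equal(m1$dose, m3$dose)))
  set.seed(99); before <- runif(3)
  set.seed(99); invisible(sample_dose(g, lay, noise = noise_model(0.01, seed = 5),
                                      quiet = TRUE))
  expect_identical(runif(3), before)
})

test_that("diodes whose footprint leaves the grid are dropped and counted", {
  g <- generate_single_field()   # +-50 mm extent
  lay <- detector_layout(pitch = 10, extent = 200, footprint = c(7, 3))
  expect_message(m <- sample_dose(g, lay), "dropped")
  expect_equal(attr(m, "meta")$dropped, 21^2 - 9^2)  # only |pos| <= 40 survives
  expect_true(all(abs(m$pos_si) <= 40 + 1e-9))
  expect_error(sample_dose(dose_grid(matrix(1, 11, 11)), lay, shift = c(500, 0),
                           quiet = TRUE), "empty|no detectors")
})

test_that("film sampling at matching pitch reproduces node values exactly", {
  g <- generate_single_field()
  m <- sample_film(g)
  ax <- grid_axes(g)
  expect_equal(nrow(m), length(ax$si) * length(ax$rl))
  expect_equal(m$dose[m$pos_si == 0 & m$pos_rl == 0], dose_at(g, 0, 0))
  i <- match(m$pos_si, ax$si); j <- match(m$pos_rl, ax$rl)
  expect_equal(m$dose, g$values[cbind(i, j)])
})

test_that("film profile error is below the coarse array's on the single field", {
  g <- generate_single_field()
  film <- sample_film(g)
  arr <- sample_dose(g, detector_layout(footprint = c(0.8, 0.8)), quiet = TRUE)
  r_film <- compute_rmse(extract_profile(g, film, axis = "SI", at = "grid"))
  r_arr <- compute_rmse(extract_profile(g, arr, axis = "SI", at = "grid"))
  expect_lt(r_film$rmse, r_arr$rmse)
})

test_that("measurement invariants are enforced", {
  expect_error(measurement(c(0, 0.005), c(0, 0), c(1, 2)), "unique")
  expect_error(measurement(0, 0, -1), ">= 0")
  expect_error(measurement(numeric(0), numeric(0), numeric(0)), "empty")
})
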