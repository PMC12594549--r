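test_that("profile RMSE matches hand arithmetic and its invariances", {
  prof <- data.frame(position = 1:3, d_ref = c(100, 50, 0),
                     d_meas = c(98, 52, 1))
  r <- compute_rmse(prof)
  expect_equal(r$rmse, sqrt(3))
  expect_equal(r$n, 3)
  # identical columns give zero
  expect_equal(compute_rmse(data.frame(position = 1:4, d_ref = 4:1,
                                       d_meas = 4:1))$rmse, 0)
  # permutation invariance
  perm <- prof[c(3, 1, 2), ]
  expect_equal(compute_rmse(perm)$rmse, r$rmse)
  # the printed n-1 summation limit, on request
  r2 <- compute_rmse(prof, drop_last = TRUE)
  expect_equal(r2$n, 2)
  expect_equal(r2$rmse, sqrt((4 + 4) / 2))
})

test_that("profile extraction selects the line points and pairs the reference", {
  g <- generate_single_field()
  film <- sample_film(g)
  prof <- extract_profile(g, film, axis = "SI", line_position_mm = 0)
  expect_s3_class(prof, "dose_profile")
  expect_equal(nrow(prof), length(grid_axes(g)$si))
  expect_true(all(diff(prof$position) > 0))
  expect_equal(prof$d_ref, prof$d_meas, tolerance = 1e-12)
  # doses are percent of the grid maximum
  expect_equal(max(prof$d_ref), 100)

  # a native 10 mm sampling sees at most 3 in-field points on the central axis
  arr <- sample_dose(g, detector_layout(footprint = c(0, 0)), quiet = TRUE)
  parr <- extract_profile(g, arr, axis = "SI")
  expect_lte(sum(parr$d_meas >= 10), 3)
  expect_gte(sum(parr$d_meas >= 10), 1)

  # no points near the requested line
  expect_error(extract_profile(g, arr, axis = "SI", line_position_mm = 3),
               "fewer than 2")
})

test_that("grid-resampled profiles penalise undersampling of the penumbra", {
  g <- generate_single_field()
  arr <- sample_dose(g, detector_layout(footprint = c(0, 0)), quiet = TRUE)
  sparse <- compute_rmse(extract_profile(g, arr, axis = "SI", at = "grid"))
  at_meas <- compute_rmse(extract_profile(g, arr, axis = "SI"))
  expect_equal(at_meas$rmse, 0, tolerance = 1e-9)  # same grid, point samples
  expect_gt(sparse$rmse, 3)                        # missed gradient shows up
})

test_that("perfect agreement gives gamma 0 everywhere at every tolerance", {
  g <- generate_single_field()
  film <- sample_film(g)
  for (tl in paper_tolerances) {
    res <- gamma_index(g, film, gamma_params(tl[1], tl[2], threshold = 10))
    expect_equal(max(res$gamma), 0)
    expect_equal(pass_rate(res), 100)
  }
})

test_that("a 3% hot point on a flat field sits exactly on the gamma boundary", {
  g <- dose_grid(matrix(100, 21, 21), spacing = c(1, 1))
  m <- measurement(0, 0, 103)
  res <- gamma_index(g, m, gamma_params(3, 3, threshold = 10))
  expect_equal(res$gamma, 1)
  expect_true(res$pass)
})

test_that("gamma is monotone under loosening of either tolerance", {
  set.seed(21)
  g <- random_smooth_grid()
  sel <- which(g$values >= 15, arr.ind = TRUE)
  sel <- sel[sample(nrow(sel), 25), ]
  ax <- grid_axes(g)
  keep <- abs(ax$si[sel[, 1]]) <= 9 & abs(ax$rl[sel[, 2]]) <= 9
  sel <- sel[keep, ]
  m <- measurement(ax$si[sel[, 1]], ax$rl[sel[, 2]],
                   g$values[sel] * (1 + runif(nrow(sel), -0.05, 0.05)))
  g33 <- gamma_index(g, m, gamma_params(3, 3))$gamma
  g32 <- gamma_index(g, m, gamma_params(3, 2))$gamma
  g22 <- gamma_index(g, m, gamma_params(2, 2))$gamma
  g31 <- gamma_index(g, m, gamma_params(3, 1))$gamma
  expect_true(all(g33 <= g32 + 1e-9))   # looser dta lowers gamma
  expect_true(all(g32 <= g31 + 1e-9))
  expect_true(all(g32 <= g22 + 1e-9))   # looser dose_diff lowers gamma
})

test_that("gamma reduces to the pure dose difference on a flat reference", {
  g <- dose_grid(matrix(80, 31, 31), spacing = c(1, 1))
  doses <- c(80, 81.2, 78.5, 83)
  m <- measurement(c(0, 2, -3, 1), c(0, 1, 2, -4), doses)
  for (dta in c(1, 3)) {
    res <- gamma_index(g, m, gamma_params(3, dta, threshold = 10))
    expect_equal(res$gamma, abs(res$dose - 80) / (0.03 * 80), tolerance = 1e-12)
  }
})

test_that("gamma is bounded by, and approaches, the pure DTA measure", {
  # steep 1D ramp: dose matches the reference exactly 1.5 mm away
  ax <- seq(-20, 20)
  slope <- 10
  g <- dose_grid(matrix(250 + slope * ax, 41, 41, byrow = FALSE),
                 spacing = c(1, 1))
  m <- measurement(0, 0, 265)   # reference here is 250 -> DTA = 1.5 mm
  res <- gamma_index(g, m, gamma_params(3, 3, threshold = 10))
  d <- 1.5; dta <- 3; dD <- 0.03 * max(g$values)
  expect_lte(res$gamma, d / dta + 1e-9)           # gamma <= DTA / dta
  expect_lte(res$gamma, 15 / dD + 1e-9)           # gamma <= dose diff / dD
  # closed form for a linear profile: the quadratic in the search distance x
  # minimises at gamma = d * sqrt(a b / (a + b)), a = 1/dta^2, b = (s/dD)^2
  a <- 1 / dta^2; b <- (slope / dD)^2
  expect_equal(res$gamma, d * sqrt(a * b / (a + b)), tolerance = 1e-3)
})

test_that("gamma in global mode is invariant under joint dose rescaling", {
  set.seed(31)
  g <- random_smooth_grid(30)
  m <- measurement(c(0, 2, -1), c(1, -2, 0),
                   dose_at(g, c(0, 2, -1), c(1, -2, 0)) * c(1.02, 0.97, 1.01))
  scale <- 3.7
  g2 <- dose_grid(g$values * scale, spacing = g$spacing, origin = g$origin)
  m2 <- measurement(m$pos_si, m$pos_rl, m$dose * scale)
  p <- gamma_params(3, 2, threshold = 10)
  expect_equal(gamma_index(g2, m2, p)$gamma, gamma_index(g, m, p)$gamma,
               tolerance = 1e-9)
  r1 <- compute_rmse(extract_profile(g, sample_film(g), axis = "SI"))
  r2 <- compute_rmse(extract_profile(g2, sample_film(g2), axis = "SI"))
  expect_equal(r1$rmse, r2$rmse, tolerance = 1e-9)
})

test_that("gamma refuses an all-below-threshold measurement, naming the threshold", {
  g <- generate_single_field()
  m <- measurement(c(40, 45), c(40, 45), c(1, 1))
  expect_error(gamma_index(g, m, gamma_params(3, 3, threshold = 10)), "10")
})

test_that("pass-rate tables aggregate replicates correctly", {
  g <- generate_single_field()
  lay <- detector_layout(footprint = c(0.8, 0.8))
  one_rep <- function(seed) {
    m <- sample_dose(g, lay, noise = noise_model(0.01, seed = seed),
                     quiet = TRUE)
    setNames(lapply(paper_tolerances, function(tl)
      gamma_index(g, m, gamma_params(tl[1], tl[2]))),
      vapply(paper_tolerances, function(tl)
        sprintf("%g%%/%gmm", tl[1], tl[2]), character(1)))
  }
  single <- pass_rate_table(one_rep(1))
  expect_equal(single$pass_rate_sd, rep(0, 4))
  expect_equal(single$n_replicates, rep(1, 4))
  reps <- lapply(1:3, one_rep)
  tab <- pass_rate_table(reps)
  for (i in seq_len(nrow(tab))) {
    prs <- vapply(reps, function(r) pass_rate(r[[tab$tolerance[i]]]), numeric(1))
    expect_gte(tab$pass_rate_mean[i], min(prs))
    expect_lte(tab$pass_rate_mean[i], max(prs))
  }
  identical3 <- pass_rate_table(list(reps[[1]], reps[[1]], reps[[1]]))
  expect_equal(identical3$pass_rate_sd, rep(0, 4))
  expect_equal(identical3$pass_rate_mean, single$pass_rate_mean)
})
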