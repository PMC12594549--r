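# Shared fixtures and independent oracles used across the test files.

# analytic dose of a single erf-edge field (independent of the package's
# generator internals)
analytic_field <- function(si, rl, center = c(0, 0), diameter = 10,
                           sigma = 2, dmax = 100, bg = 0.01) {
  r <- sqrt((si - center[1])^2 + (rl - center[2])^2)
  bg * dmax + (1 - bg) * dmax * pnorm((diameter / 2 - r) / sigma)
}

# random smooth positive dose field on an n x n 1 mm grid, max scaled to 100
random_smooth_grid <- function(n = 40, n_bumps = 3) {
  si <- seq_len(n) - 1
  vals <- matrix(2, n, n)
  for (b in seq_len(n_bumps)) {
    ctr <- runif(2, 0.15 * n, 0.85 * n)
    sg <- runif(1, 4, 12)
    amp <- runif(1, 30, 100)
    vals <- vals + amp * exp(-outer((si - ctr[1])^2, (si - ctr[2])^2, `+`) /
                               (2 * sg^2))
  }
  vals <- vals / max(vals) * 100
  off <- -(n - 1) / 2
  dose_grid(vals, spacing = c(1, 1), origin = c(off, off))
}

# dense bilinear upsampling of a grid by separable 1D linear interpolation
# (stats::approx row-wise then column-wise) -- an independent route to the
# same mathematical surface as the package's bilinear lookup
upsample_dense <- function(grid, step = 0.05) {
  d <- dim(grid$values)
  si <- grid$origin[1] + (seq_len(d[1]) - 1) * grid$spacing[1]
  rl <- grid$origin[2] + (seq_len(d[2]) - 1) * grid$spacing[2]
  fsi <- seq(si[1], si[length(si)], by = step)
  frl <- seq(rl[1], rl[length(rl)], by = step)
  half <- t(apply(grid$values, 1, function(row)
    approx(rl, row, xout = frl)$y))
  dense <- apply(half, 2, function(col) approx(si, col, xout = fsi)$y)
  list(values = dense, si = fsi, rl = frl, step = step)
}

# exhaustive brute-force gamma at a fixed search step over the full search
# radius; evaluation positions must lie on the dense lattice (snap positions
# with snap_to_lattice below). Global normalization.
brute_gamma <- function(grid, pos_si, pos_rl, dose, dose_diff, dta,
                        step = 0.05, radius_factor = 3, dense = NULL) {
  if (is.null(dense)) dense <- upsample_dense(grid, step)
  DD <- dose_diff / 100 * max(grid$values)
  R <- radius_factor * dta
  k <- floor(R / step + 1e-9)
  dist2 <- outer((-k:k)^2, (-k:k)^2, `+`) * step^2
  mask <- dist2 <= R^2 + 1e-9
  vapply(seq_along(dose), function(p) {
    ci <- round((pos_si[p] - dense$si[1]) / step) + 1L
    cj <- round((pos_rl[p] - dense$rl[1]) / step) + 1L
    stopifnot(ci - k >= 1, ci + k <= length(dense$si),
              cj - k >= 1, cj + k <= length(dense$rl))
    W <- dense$values[(ci - k):(ci + k), (cj - k):(cj + k)]
    sqrt(min((dist2 / dta^2 + (W - dose[p])^2 / DD^2)[mask]))
  }, numeric(1))
}

snap_to_lattice <- function(x, step = 0.05) round(x / step) * step

# brute-force footprint box average of the analytic field: midpoint rule at
# 0.05 mm sub-steps (equal-weight endpoint sampling would bias the mean)
brute_footprint_mean <- function(center_si, center_rl, footprint,
                                 step = 0.05, ...) {
  mids <- function(w) {
    n <- max(1, round(w / step))
    (seq_len(n) - (n + 1) / 2) * (w / n)
  }
  qq <- expand.grid(u = mids(footprint[1]), v = mids(footprint[2]))
  mean(analytic_field(center_si + qq$u, center_rl + qq$v, ...))
}

# the four clinical gamma tolerances (dose_diff %, dta mm)
paper_tolerances <- list(c(3, 3), c(3, 2), c(2, 2), c(3, 1))
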