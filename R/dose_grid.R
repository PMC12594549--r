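#' Dense 2D reference dose grid
#'
#' Container for a planar reference ("TPS") dose distribution on a regular
#' grid. Axis 1 is superior--inferior (SI, positive = superior), axis 2 is
#' right--left (RL, positive = right); all coordinates are millimetres
#' relative to the isocenter. Rows of `values` run along SI, columns along RL.
#'
#' @param values numeric matrix of non-negative doses, rows = SI, cols = RL.
#' @param spacing grid step in mm, length-2 `c(si, rl)` (a scalar is recycled).
#' @param origin position in mm of `values[1, 1]` relative to the isocenter.
#' @param unit dose unit tag, `"percent"` (of the reference maximum) or `"Gy"`.
#'   Metadata only: all metrics renormalise to percent of the grid maximum.
#' @param meta optional list of provenance metadata.
#' @return An object of class `dose_grid`.
#' @seealso [generate_single_field()], [generate_simt()], [dose_at()]
#' @export
dose_grid <- function(values, spacing = c(1, 1), origin = NULL,
                      unit = c("percent", "Gy"), meta = list()) {
  unit <- match.arg(unit)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (any(!is.finite(values)) || any(values < 0))
    stop("dose values must be finite and >= 0")
  spacing <- rep_len(as.numeric(spacing), 2L)
  if (any(spacing <= 0)) stop("`spacing` must be > 0 on both axes")
  if (is.null(origin)) {
    # centre the grid on the isocenter
    origin <- -spacing * (dim(values) - 1L) / 2
  }
  origin <- rep_len(as.numeric(origin), 2L)
  g <- structure(
    list(values = values, spacing = spacing, origin = origin,
         unit = unit, max = max(values), meta = meta),
    class = "dose_grid")
  ext <- grid_extent(g)
  if (0 < ext$si[1] || 0 > ext$si[2] || 0 < ext$rl[1] || 0 > ext$rl[2])
    stop("isocenter (0, 0) must lie inside the grid extent")
  g
}

#' Grid node coordinates
#'
#' @param grid a [dose_grid()].
#' @return list with numeric vectors `si` and `rl` of node positions (mm).
#' @export
grid_axes <- function(grid) {
  stopifnot(inherits(grid, "dose_grid"))
  d <- dim(grid$values)
  list(si = grid$origin[1] + (seq_len(d[1]) - 1) * grid$spacing[1],
       rl = grid$origin[2] + (seq_len(d[2]) - 1) * grid$spacing[2])
}

#' Physical extent of a dose grid
#'
#' @param grid a [dose_grid()].
#' @return list with ranges `si` and `rl` in mm.
#' @export
grid_extent <- function(grid) {
  ax <- grid_axes(grid)
  list(si = range(ax$si), rl = range(ax$rl))
}

#' Field geometry for synthetic dose generation
#'
#' Describes one or more circular targets with an error-function penumbra.
#' The radial dose model for a single target of radius R is
#' `D(r) = background * dose_max + (1 - background) * dose_max * pnorm((R - r) / sigma)`,
#' which places the 50% dose level exactly at the field edge `r = R`.
#'
#' @param centers target centre(s), a length-2 vector `c(si, rl)` in mm or a
#'   list of such vectors.
#' @param target_diameter target diameter in mm (> 0).
#' @param penumbra_sigma penumbra width parameter sigma in mm (> 0); the
#'   20--80% penumbra is about `1.68 * sigma`.
#' @param dose_max central-axis dose in grid units.
#' @param background out-of-field dose as a fraction of `dose_max`, in
#'   `[0, 0.05]`.
#' @return An object of class `field_spec`.
#' @export
field_spec <- function(centers = c(0, 0), target_diameter = 10,
                       penumbra_sigma = 2, dose_max = 100,
                       background = 0.01) {
  if (!is.list(centers)) centers <- list(centers)
  centers <- lapply(centers, function(p) {
    p <- as.numeric(p)
    if (length(p) != 2L || any(!is.finite(p)))
      stop("each centre must be a finite length-2 c(si, rl) vector")
    p
  })
  if (target_diameter <= 0) stop("`target_diameter` must be > 0")
  if (penumbra_sigma <= 0) stop("`penumbra_sigma` must be > 0")
  if (background < 0 || background > 0.05)
    stop("`background` must lie in [0, 0.05]")
  structure(list(centers = centers, target_diameter = target_diameter,
                 penumbra_sigma = penumbra_sigma, dose_max = dose_max,
                 background = background),
            class = "field_spec")
}

# analytic single-target dose at radial distance r (vectorised)
field_dose_radial <- function(spec, r) {
  R <- spec$target_diameter / 2
  spec$background * spec$dose_max +
    (1 - spec$background) * spec$dose_max *
      stats::pnorm((R - r) / spec$penumbra_sigma)
}

# analytic multi-target dose at positions (si, rl); sum over targets with the
# background counted once per target (pointwise sum, no renormalisation)
field_dose_at <- function(spec, si, rl) {
  d <- 0
  for (ct in spec$centers)
    d <- d + field_dose_radial(spec, sqrt((si - ct[1])^2 + (rl - ct[2])^2))
  d
}

check_field_extent <- function(spec, extent, margin = 30) {
  R <- spec$target_diameter / 2
  for (ct in spec$centers) {
    need <- abs(ct) + R + margin
    if (extent[1] / 2 < need[1] || extent[2] / 2 < need[2])
      stop(sprintf(
        "grid extent (%g x %g mm) too small: target at (%g, %g) needs a %g mm margin",
        extent[1], extent[2], ct[1], ct[2], margin))
  }
}

#' Generate a single-field SRS-like reference dose distribution
#'
#' Builds the steep-gradient planar dose of a single static field on a small
#' circular target: a radially symmetric flat-top profile with an
#' error-function penumbra (see [field_spec()]). Emulates a single-field
#' irradiation plan for a 1 cm target computed on a 1 mm grid.
#'
#' @param spec a [field_spec()] with exactly one centre.
#' @param extent_mm physical extent in mm per axis, `c(si, rl)` (scalar
#'   recycled); must cover the target plus a 3 cm margin.
#' @param spacing_mm grid step in mm per axis, default 1.
#' @return A [dose_grid()] in percent units (when `dose_max = 100`).
#' @examples
#' g <- generate_single_field()
#' dose_at(g, 0, 0)    # ~ 99.4 (flat top)
#' dose_at(g, 5, 0)    # ~ 50 (field edge)
#' @export
generate_single_field <- function(spec = field_spec(),
                                  extent_mm = c(100, 100),
                                  spacing_mm = c(1, 1)) {
  stopifnot(inherits(spec, "field_spec"))
  if (length(spec$centers) != 1L)
    stop("`spec` must contain a single target centre")
  extent_mm <- rep_len(as.numeric(extent_mm), 2L)
  spacing_mm <- rep_len(as.numeric(spacing_mm), 2L)
  if (any(spacing_mm <= 0)) stop("`spacing_mm` must be > 0")
  check_field_extent(spec, extent_mm)
  si <- seq(-extent_mm[1] / 2, extent_mm[1] / 2, by = spacing_mm[1])
  rl <- seq(-extent_mm[2] / 2, extent_mm[2] / 2, by = spacing_mm[2])
  ct <- spec$centers[[1]]
  r <- sqrt(outer((si - ct[1])^2, (rl - ct[2])^2, `+`))
  vals <- field_dose_radial(spec, r)
  dose_grid(vals, spacing = spacing_mm, origin = c(si[1], rl[1]),
            unit = if (spec$dose_max == 100) "percent" else "Gy",
            meta = list(scenario = "single_field", spec = spec))
}

#' Generate a single-isocenter two-target (SIMT) reference distribution
#'
#' Pointwise sum of single-field profiles for each target, without
#' renormalisation. The default geometry places two 1 cm targets offset from
#' the isocenter by +/- 60 mm along the superior--inferior axis, emulating a
#' single-isocenter multiple-target SRS plan for two brain metastases.
#'
#' @param spec a [field_spec()]; defaults to two centres at `(+-60, 0)` mm.
#' @param extent_mm physical extent in mm per axis, default `c(240, 120)`.
#' @param spacing_mm grid step in mm, default 1.
#' @return A [dose_grid()]. If the targets overlap (separation smaller than
#'   `diameter + 6 * sigma`) a warning flag is recorded in `meta$overlap`.
#' @export
generate_simt <- function(spec = field_spec(centers = list(c(60, 0), c(-60, 0))),
                          extent_mm = c(240, 120),
                          spacing_mm = c(1, 1)) {
  stopifnot(inherits(spec, "field_spec"))
  if (length(spec$centers) == 1L)
    return(generate_single_field(spec, extent_mm, spacing_mm))
  extent_mm <- rep_len(as.numeric(extent_mm), 2L)
  spacing_mm <- rep_len(as.numeric(spacing_mm), 2L)
  if (any(spacing_mm <= 0)) stop("`spacing_mm` must be > 0")
  check_field_extent(spec, extent_mm)
  si <- seq(-extent_mm[1] / 2, extent_mm[1] / 2, by = spacing_mm[1])
  rl <- seq(-extent_mm[2] / 2, extent_mm[2] / 2, by = spacing_mm[2])
  vals <- 0
  for (ct in spec$centers) {
    r <- sqrt(outer((si - ct[1])^2, (rl - ct[2])^2, `+`))
    vals <- vals + field_dose_radial(spec, r)
  }
  overlap <- FALSE
  n <- length(spec$centers)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sep <- sqrt(sum((spec$centers[[i]] - spec$centers[[j]])^2))
    if (sep < spec$target_diameter + 6 * spec$penumbra_sigma) overlap <- TRUE
  }
  if (overlap) warning("targets overlap: separation < diameter + 6 * sigma")
  dose_grid(vals, spacing = spacing_mm, origin = c(si[1], rl[1]),
            unit = if (spec$dose_max == 100) "percent" else "Gy",
            meta = list(scenario = "simt", spec = spec, overlap = overlap))
}

#' Bilinear dose lookup
#'
#' Interpolates the dose at arbitrary in-grid positions from the four
#' surrounding nodes. Exact at grid nodes; no extrapolation -- positions
#' outside the grid extent are an error.
#'
#' @param grid a [dose_grid()].
#' @param si,rl numeric vectors of positions in mm (recycled to a common
#'   length).
#' @return Numeric vector of interpolated doses.
#' @export
dose_at <- function(grid, si, rl) {
  stopifnot(inherits(grid, "dose_grid"))
  n <- max(length(si), length(rl))
  si <- rep_len(as.numeric(si), n)
  rl <- rep_len(as.numeric(rl), n)
  d <- dim(grid$values)
  fi <- (si - grid$origin[1]) / grid$spacing[1] + 1
  fj <- (rl - grid$origin[2]) / grid$spacing[2] + 1
  eps <- 1e-9
  if (any(fi < 1 - eps | fi > d[1] + eps | fj < 1 - eps | fj > d[2] + eps))
    stop("position outside grid extent (no extrapolation)")
  fi <- pmin(pmax(fi, 1), d[1])
  fj <- pmin(pmax(fj, 1), d[2])
  i0 <- pmin(floor(fi), d[1] - 1L); u <- fi - i0
  j0 <- pmin(floor(fj), d[2] - 1L); v <- fj - j0
  V <- grid$values
  (1 - u) * (1 - v) * V[cbind(i0, j0)] +
    u       * (1 - v) * V[cbind(i0 + 1, j0)] +
    (1 - u) * v       * V[cbind(i0, j0 + 1)] +
    u       * v       * V[cbind(i0 + 1, j0 + 1)]
}

#' @export
print.dose_grid <- function(x, ...) {
  d <- dim(x$values)
  ext <- grid_extent(x)
  cat(sprintf("<dose_grid> %d x %d nodes (SI x RL), spacing %g x %g mm\n",
              d[1], d[2], x$spacing[1], x$spacing[2]))
  cat(sprintf("  SI extent [%g, %g] mm, RL extent [%g, %g] mm\n",
              ext$si[1], ext$si[2], ext$rl[1], ext$rl[2]))
  cat(sprintf("  max dose %.4g %s%s\n", x$max, x$unit,
              if (!is.null(x$meta$scenario))
                paste0(", scenario: ", x$meta$scenario) else ""))
  invisible(x)
}

#' @export
plot.dose_grid <- function(x, contours = c(10, 50, 90), ...) {
  ax <- grid_axes(x)
  graphics::image(ax$rl, ax$si, t(x$values),
                  col = grDevices::hcl.colors(64, "viridis"),
                  xlab = "RL position (mm)", ylab = "SI position (mm)", ...)
  if (length(contours))
    graphics::contour(ax$rl, ax$si, t(x$values),
                      levels = contours / 100 * x$max, add = TRUE,
                      col = "white")
  invisible(x)
}
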