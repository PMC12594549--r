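#' Diode-array or film detector layout
#'
#' Describes a rectangular grid of detectors centred on the isocenter. The
#' default emulates a general-purpose diode array with 10 mm pitch and the
#' 0.8 x 0.8 mm^2 active area of its silicon diodes; `film_layout()` is the
#' fine-grid radiochromic-film stand-in (1 mm pitch, point samples). The
#' array's true diagonal diode pattern is simplified to a rectangular grid at
#' the nominal pitch.
#'
#' The `footprint` is the aperture over which each reading averages the dose.
#' Besides the small active area, the diode *units* of such arrays are
#' elongated along SI (7 x 3 mm^2 package); passing `footprint = c(7, 3)`
#' averages over that whole envelope, the limiting partial-volume model used
#' to study how couch-shift direction interacts with detector anisotropy.
#'
#' @param pitch detector spacing in mm per axis `c(si, rl)`; scalar recycled.
#' @param extent physical extent covered by the array in mm per axis,
#'   default 200 x 200; detector positions are the multiples of the pitch
#'   within `+- extent/2`.
#' @param footprint averaging-aperture dimensions in mm `c(si, rl)`;
#'   `c(0, 0)` is an ideal point detector, `c(7, 3)` the full diode-unit
#'   envelope.
#' @param mode `"array"` or `"film"`.
#' @return An object of class `detector_layout`.
#' @export
detector_layout <- function(pitch = c(10, 10), extent = c(200, 200),
                            footprint = c(0.8, 0.8),
                            mode = c("array", "film")) {
  mode <- match.arg(mode)
  pitch <- rep_len(as.numeric(pitch), 2L)
  extent <- rep_len(as.numeric(extent), 2L)
  footprint <- rep_len(as.numeric(footprint), 2L)
  if (any(pitch <= 0)) stop("`pitch` must be > 0")
  if (any(extent <= 0)) stop("`extent` must be > 0")
  if (any(footprint < 0)) stop("`footprint` must be >= 0 (0 = point detector)")
  structure(list(pitch = pitch, extent = extent, footprint = footprint,
                 mode = mode),
            class = "detector_layout")
}

#' @rdname detector_layout
#' @export
film_layout <- function(extent = c(200, 200), pitch = c(1, 1)) {
  detector_layout(pitch = pitch, extent = extent, footprint = c(0, 0),
                  mode = "film")
}

# nominal detector positions along one axis: multiples of the pitch in
# [-extent/2, extent/2]
layout_positions <- function(layout) {
  k <- floor(layout$extent / 2 / layout$pitch)
  list(si = seq(-k[1], k[1]) * layout$pitch[1],
       rl = seq(-k[2], k[2]) * layout$pitch[2])
}

#' Measurement noise model
#'
#' Multiplicative Gaussian reading noise: each sample is scaled by
#' `1 + rnorm(1, 0, relative_sd)`. With a non-NULL seed the draw is
#' reproducible and does not disturb the caller's RNG state. Repeat-to-repeat
#' variability of array and film readings motivates the stochastic model; the
#' default magnitude (0.5%) is a configurable stand-in.
#'
#' @param relative_sd relative standard deviation (fraction), >= 0.
#' @param seed integer seed, or NULL to use the current RNG stream.
#' @param shift_error_sd optional couch-positioning error: each commanded
#'   shift is perturbed by `rnorm(1, 0, shift_error_sd)` mm when sampling,
#'   while recorded coordinates keep the commanded value. Default 0 (off).
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(relative_sd = 0.005, seed = NULL, shift_error_sd = 0) {
  if (relative_sd < 0) stop("`relative_sd` must be >= 0")
  if (shift_error_sd < 0) stop("`shift_error_sd` must be >= 0")
  structure(list(relative_sd = relative_sd, seed = seed,
                 shift_error_sd = shift_error_sd),
            class = "noise_model")
}

# evaluate fn() under a local RNG seeded with `seed`, restoring global state
with_local_seed <- function(seed, fn) {
  if (is.null(seed)) return(fn())
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Sparse detector measurement
#'
#' A set of (position, dose) samples in the beam frame, possibly merged from
#' several couch-shifted acquisitions. Positions must be unique within
#' 0.01 mm and doses non-negative.
#'
#' @param pos_si,pos_rl sample positions in mm.
#' @param dose sample doses (same unit as the source grid).
#' @param meta list of acquisition metadata (layout, shift, seed, ...).
#' @return A data frame of class `measurement` with columns `pos_si`,
#'   `pos_rl`, `dose`, ordered by SI then RL position.
#' @export
measurement <- function(pos_si, pos_rl, dose, meta = list()) {
  n <- length(dose)
  if (length(pos_si) != n || length(pos_rl) != n)
    stop("`pos_si`, `pos_rl`, `dose` must have equal length")
  if (n == 0L) stop("empty measurement")
  if (any(!is.finite(dose)) || any(dose < 0))
    stop("doses must be finite and >= 0")
  key <- paste(round(pos_si / 0.01), round(pos_rl / 0.01))
  if (anyDuplicated(key))
    stop("measurement positions must be unique within 0.01 mm")
  ord <- order(pos_si, pos_rl)
  df <- data.frame(pos_si = as.numeric(pos_si)[ord],
                   pos_rl = as.numeric(pos_rl)[ord],
                   dose = as.numeric(dose)[ord])
  structure(df, meta = meta, class = c("measurement", "data.frame"))
}

# midpoint quadrature offsets spanning a footprint dimension at <= `step` mm
quad_offsets <- function(width, step = 0.5) {
  if (width <= 0) return(0)
  n <- max(1L, ceiling(width / step))
  ((seq_len(n)) - (n + 1) / 2) * (width / n)
}

#' Sample a dose grid with a detector under a couch shift
#'
#' Simulates one acquisition: each detector nominally at position `x` reads
#' the field at `x + shift` (sign convention: a couch translation that
#' displaces the detector by `+d` in the beam frame assigns the diode
#' nominally at `x` the coordinate `x + d`; recorded sample positions include
#' the shift). The reading is the mean reference dose over the active
#' footprint, computed by regular midpoint sub-sampling at steps of at most
#' `quad_step` mm (a single centre point for point detectors), then scaled by
#' the multiplicative noise factor. Detectors whose shifted footprint falls
#' outside the grid extent are dropped and counted in the metadata.
#'
#' @param grid a [dose_grid()].
#' @param layout a [detector_layout()].
#' @param shift couch shift in mm, `c(si, rl)`.
#' @param noise a [noise_model()], or NULL for a noiseless reading.
#' @param quad_step maximum footprint sub-sampling step in mm.
#' @param quiet suppress the dropped-detector message.
#' @return A [measurement()]; metadata records the layout, applied shift,
#'   noise seed and dropped-detector count.
#' @export
sample_dose <- function(grid, layout, shift = c(0, 0), noise = NULL,
                        quad_step = 0.5, quiet = FALSE) {
  stopifnot(inherits(grid, "dose_grid"), inherits(layout, "detector_layout"))
  shift <- rep_len(as.numeric(shift), 2L)
  if (quad_step <= 0) stop("`quad_step` must be > 0")
  nom <- layout_positions(layout)
  pos <- expand.grid(si = nom$si, rl = nom$rl, KEEP.OUT.ATTRS = FALSE)

  shift_eff <- shift
  noise_fn <- NULL
  if (!is.null(noise)) {
    stopifnot(inherits(noise, "noise_model"))
    draws <- with_local_seed(noise$seed, function() {
      list(eps = stats::rnorm(nrow(pos), 0, noise$relative_sd),
           shift_err = if (noise$shift_error_sd > 0)
             stats::rnorm(2, 0, noise$shift_error_sd) else c(0, 0))
    })
    shift_eff <- shift + draws$shift_err
  }

  # recorded coordinates use the commanded shift; the field is read at the
  # effective (possibly error-perturbed) shift
  rec_si <- pos$si + shift[1]
  rec_rl <- pos$rl + shift[2]
  eff_si <- pos$si + shift_eff[1]
  eff_rl <- pos$rl + shift_eff[2]

  ext <- grid_extent(grid)
  half <- layout$footprint / 2
  keep <- eff_si - half[1] >= ext$si[1] & eff_si + half[1] <= ext$si[2] &
          eff_rl - half[2] >= ext$rl[1] & eff_rl + half[2] <= ext$rl[2]
  dropped <- sum(!keep)
  if (dropped > 0 && !quiet)
    message(sprintf("sample_dose: dropped %d detector(s) outside the grid extent",
                    dropped))
  if (!any(keep)) stop("no detectors inside the grid extent: empty measurement")

  qs <- quad_offsets(layout$footprint[1], quad_step)
  qr <- quad_offsets(layout$footprint[2], quad_step)
  qq <- expand.grid(ds = qs, dr = qr, KEEP.OUT.ATTRS = FALSE)
  nk <- sum(keep); nq <- nrow(qq)
  all_si <- rep(eff_si[keep], times = nq) + rep(qq$ds, each = nk)
  all_rl <- rep(eff_rl[keep], times = nq) + rep(qq$dr, each = nk)
  doses <- rowMeans(matrix(dose_at(grid, all_si, all_rl), nrow = nk))

  if (!is.null(noise)) doses <- doses * (1 + draws$eps[keep])
  doses <- pmax(doses, 0)

  measurement(rec_si[keep], rec_rl[keep], doses,
              meta = list(mode = layout$mode,
                          pitch = layout$pitch,
                          footprint = layout$footprint,
                          shift = shift,
                          noise_sd = if (is.null(noise)) 0 else noise$relative_sd,
                          seed = if (is.null(noise)) NA else
                            (if (is.null(noise$seed)) NA else noise$seed),
                          dropped = dropped))
}

#' Sample a dose grid with the film stand-in
#'
#' Convenience wrapper around [sample_dose()] with a film-mode layout: 1 mm
#' pitch, point footprint, extent matched to the grid.
#'
#' @param grid a [dose_grid()].
#' @param noise a [noise_model()] for the film reading, or NULL.
#' @param pitch film sampling pitch in mm, default 1.
#' @param quiet suppress the dropped-detector message.
#' @return A [measurement()].
#' @export
sample_film <- function(grid, noise = NULL, pitch = c(1, 1), quiet = FALSE) {
  ext <- grid_extent(grid)
  lay <- film_layout(extent = c(min(-2 * ext$si[1], 2 * ext$si[2]),
                                min(-2 * ext$rl[1], 2 * ext$rl[2])),
                     pitch = pitch)
  sample_dose(grid, lay, shift = c(0, 0), noise = noise, quiet = quiet)
}

#' @export
print.measurement <- function(x, ...) {
  meta <- attr(x, "meta")
  cat(sprintf("<measurement> %d points", nrow(x)))
  if (!is.null(meta$mode)) cat(sprintf(", mode %s", meta$mode))
  if (!is.null(meta$shift) && is.numeric(meta$shift))
    cat(sprintf(", shift (%g, %g) mm", meta$shift[1], meta$shift[2]))
  if (!is.null(meta$merged_spacing))
    cat(sprintf(", merged %s spacing %g mm", meta$axis, meta$merged_spacing))
  cat(sprintf("\n  SI range [%g, %g] mm, RL range [%g, %g] mm, dose range [%.3g, %.3g]\n",
              min(x$pos_si), max(x$pos_si), min(x$pos_rl), max(x$pos_rl),
              min(x$dose), max(x$dose)))
  invisible(x)
}

#' @export
plot.measurement <- function(x, ...) {
  sc <- 0.2 + 0.8 * x$dose / max(x$dose)
  graphics::plot(x$pos_rl, x$pos_si, cex = 2 * sc,
                 col = grDevices::hcl.colors(64, "viridis")[pmax(1, ceiling(64 * sc))],
                 pch = 16, xlab = "RL position (mm)", ylab = "SI position (mm)", ...)
  invisible(x)
}
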