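#' Plan a couch-shift schedule for a target virtual spacing
#'
#' Computes the couch offsets needed to synthesise a virtual detector spacing
#' of `target_spacing_mm` from an array with native pitch `native_pitch_mm`
#' along one axis. The offsets are the distinct residues of the target
#' lattice modulo the native pitch, in increasing order and starting at 0
#' (the isocenter acquisition). When the target spacing divides the pitch the
#' schedule is `{0, t, 2t, ..., pitch - t}` with `pitch / t` acquisitions;
#' non-divisor spacings that still generate a uniform lattice (e.g. 4 or 3 mm
#' from a 10 mm pitch) use more offsets, and the merge keeps only the samples
#' that land on the target lattice.
#'
#' @param native_pitch_mm native detector pitch along the shift axis, mm.
#' @param target_spacing_mm desired virtual spacing, mm; must be positive,
#'   at most the pitch, and commensurable with it.
#' @param axis shift axis, `"SI"` or `"RL"`.
#' @return An object of class `shift_schedule` with fields `axis`, `offsets`
#'   (mm, first = 0), `native_pitch`, `target_spacing`.
#' @examples
#' plan_shifts(10, 5, "SI")   # offsets 0, 5
#' plan_shifts(10, 1, "SI")   # offsets 0..9 (10 acquisitions)
#' plan_shifts(10, 4, "SI")   # offsets 0, 2, 4, 6, 8
#' @export
plan_shifts <- function(native_pitch_mm, target_spacing_mm,
                        axis = c("SI", "RL")) {
  axis <- match.arg(axis)
  p <- as.numeric(native_pitch_mm); t <- as.numeric(target_spacing_mm)
  if (!is.finite(p) || p <= 0) stop("`native_pitch_mm` must be > 0")
  if (!is.finite(t) || t <= 0 || t > p)
    stop(sprintf(
      "`target_spacing_mm` must lie in (0, %g]; e.g. %s are valid for a %g mm pitch",
      p, paste(signif(p / seq_len(10), 3), collapse = ", "), p))
  # residues k*t mod p for k = 0, 1, ... until the cycle closes
  offsets <- 0
  k <- 1L
  repeat {
    r <- (k * t) %% p
    if (min(abs(c(r, r - p))) < 1e-9) break
    if (any(abs(offsets - r) < 1e-9)) break
    offsets <- c(offsets, r)
    k <- k + 1L
    if (k > 1000L)
      stop(sprintf(
        "`target_spacing_mm` = %g is not commensurable with the %g mm pitch; valid spacings include %s",
        t, p, paste(signif(p / seq_len(10), 3), collapse = ", ")))
  }
  structure(list(axis = axis, offsets = sort(offsets),
                 native_pitch = p, target_spacing = t),
            class = "shift_schedule")
}

#' @export
print.shift_schedule <- function(x, ...) {
  cat(sprintf("<shift_schedule> %s axis: %g mm pitch -> %g mm virtual spacing\n",
              x$axis, x$native_pitch, x$target_spacing))
  cat(sprintf("  %d acquisition(s), couch offsets (mm): %s\n",
              length(x$offsets), paste(format(x$offsets), collapse = ", ")))
  invisible(x)
}

shift_axis_index <- function(axis) if (axis == "SI") 1L else 2L

#' Merge couch-shifted acquisitions into a virtual fine-pitch measurement
#'
#' Takes one [measurement()] per schedule offset (identified by the recorded
#' shift in each measurement's metadata) and combines them on the virtual
#' grid: sample coordinates already include the couch shift, and only samples
#' whose along-axis coordinate lies on the target-spacing lattice are
#' assigned (for divisor spacings that is every sample). Points coinciding
#' within 0.01 mm are averaged with a warning. The result is independent of
#' the order of `measurements`.
#'
#' @param measurements list of [measurement()] objects, one per offset.
#' @param schedule the [plan_shifts()] schedule they realise.
#' @return A merged [measurement()] whose metadata records the schedule,
#'   per-acquisition point counts, and any off-lattice or coincident points.
#' @export
merge_measurements <- function(measurements, schedule) {
  stopifnot(inherits(schedule, "shift_schedule"))
  if (inherits(measurements, "measurement")) measurements <- list(measurements)
  if (!length(measurements) || !all(vapply(measurements, inherits,
                                           logical(1), "measurement")))
    stop("`measurements` must be a list of measurement objects")
  ai <- shift_axis_index(schedule$axis)
  oi <- 3L - ai

  shifts <- lapply(measurements, function(m) {
    s <- attr(m, "meta")$shift
    if (is.null(s)) stop("measurement has no recorded shift in its metadata")
    as.numeric(s)
  })
  off_axis <- vapply(shifts, `[`, numeric(1), oi)
  if (any(abs(off_axis) > 1e-9))
    stop(sprintf("mixed axes: measurement shifted along %s does not match a %s schedule",
                 if (ai == 1L) "RL" else "SI", schedule$axis))
  along <- vapply(shifts, `[`, numeric(1), ai)
  idx <- vapply(along, function(a) {
    j <- which(abs(schedule$offsets - a) < 1e-9)
    if (length(j) != 1L)
      stop(sprintf("recorded shift %g mm does not match any schedule offset (%s)",
                   a, paste(format(schedule$offsets), collapse = ", ")))
    j
  }, integer(1))
  if (anyDuplicated(idx))
    stop("duplicate offsets: more than one measurement for the same couch shift")
  if (length(idx) != length(schedule$offsets))
    stop(sprintf("missing offsets: schedule needs %d acquisitions, got %d",
                 length(schedule$offsets), length(measurements)))

  t <- schedule$target_spacing
  pieces <- lapply(measurements, function(m) {
    co <- if (ai == 1L) m$pos_si else m$pos_rl
    # half the 0.01 mm coincidence tolerance, so near-coincident points are
    # assigned to the lattice and then averaged rather than silently dropped
    on_lattice <- abs(co - t * round(co / t)) < 0.005
    as.data.frame(m)[on_lattice, , drop = FALSE]
  })
  n_off_lattice <- sum(vapply(measurements, nrow, integer(1))) -
    sum(vapply(pieces, nrow, integer(1)))
  if (n_off_lattice > 0)
    message(sprintf("merge: %d sample(s) off the %g mm lattice discarded",
                    n_off_lattice, t))
  all_pts <- do.call(rbind, pieces)
  if (!nrow(all_pts)) stop("merge produced an empty measurement")

  # average coincident points (within 0.01 mm)
  key <- paste(round(all_pts$pos_si / 0.01), round(all_pts$pos_rl / 0.01))
  n_coincident <- 0L
  if (anyDuplicated(key)) {
    n_coincident <- nrow(all_pts) - length(unique(key))
    warning(sprintf("merge: %d coincident point(s) averaged", n_coincident))
    agg <- stats::aggregate(all_pts[c("pos_si", "pos_rl", "dose")],
                            by = list(key = key), FUN = mean)
    all_pts <- agg[c("pos_si", "pos_rl", "dose")]
  }

  measurement(all_pts$pos_si, all_pts$pos_rl, all_pts$dose,
              meta = list(mode = attr(measurements[[1]], "meta")$mode,
                          footprint = attr(measurements[[1]], "meta")$footprint,
                          axis = schedule$axis,
                          merged_spacing = t,
                          offsets = schedule$offsets,
                          n_acquisitions = length(measurements),
                          n_off_lattice = n_off_lattice,
                          n_coincident = n_coincident))
}
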