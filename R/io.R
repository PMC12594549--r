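#' Write a dose grid to the plain-text grid format
#'
#' Format: four header lines -- `nx ny` (columns = RL, rows = SI),
#' `spacing_si spacing_rl`, `origin_si origin_rl`, `unit` -- followed by
#' `ny` rows of `nx` whitespace-separated values. Values are written with 6
#' significant digits, so write/read round-trips are lossless at that
#' precision.
#'
#' @param grid a [dose_grid()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dose_grid <- function(grid, path) {
  stopifnot(inherits(grid, "dose_grid"))
  d <- dim(grid$values)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste(d[2], d[1]),
    paste(format(grid$spacing[1], digits = 9), format(grid$spacing[2], digits = 9)),
    paste(format(grid$origin[1], digits = 9), format(grid$origin[2], digits = 9)),
    grid$unit), con)
  rows <- apply(grid$values, 1, function(r)
    paste(formatC(r, format = "g", digits = 6), collapse = " "))
  writeLines(rows, con)
  invisible(path)
}

parse_num_line <- function(lines, i, n_expected, what) {
  if (length(lines) < i)
    stop(sprintf("line %d: expected %s, got end of file", i, what))
  x <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
  if (length(x) != n_expected || any(is.na(x)))
    stop(sprintf("line %d: expected %s (%d numeric values)", i, what, n_expected))
  x
}

#' Read a dose grid from the plain-text grid format
#'
#' @param path file written by [write_dose_grid()].
#' @return A [dose_grid()].
#' @export
read_dose_grid <- function(path) {
  lines <- readLines(path)
  hdr <- parse_num_line(lines, 1, 2, "header `nx ny`")
  nx <- as.integer(hdr[1]); ny <- as.integer(hdr[2])
  spacing <- parse_num_line(lines, 2, 2, "`spacing_si spacing_rl`")
  origin <- parse_num_line(lines, 3, 2, "`origin_si origin_rl`")
  if (length(lines) < 4) stop("line 4: expected unit")
  unit <- trimws(lines[4])
  if (!unit %in% c("percent", "Gy"))
    stop(sprintf("line 4: unknown unit '%s'", unit))
  if (length(lines) < 4 + ny)
    stop(sprintf("line %d: expected %d data rows, file has %d",
                 length(lines) + 1, ny, length(lines) - 4))
  vals <- matrix(0, ny, nx)
  for (i in seq_len(ny))
    vals[i, ] <- parse_num_line(lines, 4 + i, nx, sprintf("data row %d", i))
  dose_grid(vals, spacing = spacing, origin = origin, unit = unit)
}

#' Write a measurement to CSV
#'
#' Columns `pos_si_mm,pos_rl_mm,dose`, one row per sample. Acquisition
#' metadata (applied shift, noise seed, layout summary, dropped-diode count)
#' is written to a key-value sidecar `<path>.meta` unless `sidecar = FALSE`.
#'
#' @param meas a [measurement()].
#' @param path output CSV path.
#' @param sidecar write the metadata sidecar file?
#' @return `path`, invisibly.
#' @export
write_measurement <- function(meas, path, sidecar = TRUE) {
  stopifnot(inherits(meas, "measurement"))
  df <- as.data.frame(meas)[, c("pos_si", "pos_rl", "dose")]
  names(df) <- c("pos_si_mm", "pos_rl_mm", "dose")
  utils::write.csv(format(df, digits = 6, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  meta <- attr(meas, "meta")
  if (sidecar && length(meta)) {
    kv <- vapply(names(meta), function(k) {
      v <- meta[[k]]
      if (is.list(v)) v <- unlist(v)
      paste0(k, ": ", paste(format(v), collapse = " "))
    }, character(1))
    writeLines(kv, paste0(path, ".meta"))
  }
  invisible(path)
}

#' Read a measurement from CSV
#'
#' @param path CSV written by [write_measurement()]. A sidecar `<path>.meta`,
#'   if present, is parsed back into the measurement metadata (`shift`,
#'   `noise_sd`, `seed` as numerics; other keys as character).
#' @return A [measurement()].
#' @export
read_measurement <- function(path) {
  df <- utils::read.csv(path)
  need <- c("pos_si_mm", "pos_rl_mm", "dose")
  if (!all(need %in% names(df)))
    stop("line 1: measurement CSV header must be `pos_si_mm,pos_rl_mm,dose`")
  meta <- list()
  side <- paste0(path, ".meta")
  if (file.exists(side)) {
    for (ln in readLines(side)) {
      kv <- regmatches(ln, regexec("^([^:]+): ?(.*)$", ln))[[1]]
      if (length(kv) == 3) {
        val <- kv[3]
        num <- suppressWarnings(as.numeric(strsplit(val, "\\s+")[[1]]))
        meta[[trimws(kv[2])]] <- if (!anyNA(num)) num else val
      }
    }
  }
  measurement(df$pos_si_mm, df$pos_rl_mm, df$dose, meta = meta)
}

#' Write a shift schedule to a key-value text file
#'
#' @param schedule a [plan_shifts()] schedule.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "shift_schedule"))
  writeLines(c(
    paste("axis:", schedule$axis),
    paste("native_pitch_mm:", format(schedule$native_pitch)),
    paste("target_spacing_mm:", format(schedule$target_spacing)),
    paste("offsets_mm:", paste(format(schedule$offsets), collapse = " "))),
    path)
  invisible(path)
}

#' Read a shift schedule written by [write_schedule()]
#'
#' @param path schedule file path.
#' @return A `shift_schedule`.
#' @export
read_schedule <- function(path) {
  lines <- readLines(path)
  get <- function(key, line) {
    if (length(lines) < line || !startsWith(lines[line], paste0(key, ":")))
      stop(sprintf("line %d: expected `%s:`", line, key))
    trimws(sub(paste0("^", key, ":"), "", lines[line]))
  }
  axis <- get("axis", 1)
  pitch <- as.numeric(get("native_pitch_mm", 2))
  spacing <- as.numeric(get("target_spacing_mm", 3))
  offsets <- as.numeric(strsplit(get("offsets_mm", 4), "\\s+")[[1]])
  sched <- plan_shifts(pitch, spacing, axis)
  if (!isTRUE(all.equal(sort(offsets), sched$offsets, tolerance = 1e-9)))
    stop("line 4: offsets are inconsistent with pitch and target spacing")
  sched
}
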