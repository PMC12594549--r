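#' Extract a paired reference/measurement dose profile
#'
#' Selects the measurement samples lying on a line parallel to one axis
#' (off-axis coordinate within `tolerance_mm` of `line_position_mm`) and
#' pairs them with the reference dose. Both dose columns are expressed in
#' percent of the reference grid's global maximum.
#'
#' Two pairings are supported. `at = "measurement"` pairs the reference,
#' interpolated with [dose_at()], at the sparse measurement positions.
#' `at = "grid"` compares profile *shapes*: the measured line doses are
#' linearly interpolated onto the reference grid's node positions along the
#' line (within the measured span) and paired with the reference there, so a
#' sparse measurement that misses the penumbra is penalised for the gradient
#' it cannot see. The shape comparison is what the spacing-vs-RMSE experiment
#' uses.
#'
#' @param grid reference [dose_grid()].
#' @param meas a [measurement()].
#' @param axis profile direction, `"SI"` or `"RL"`.
#' @param line_position_mm off-axis coordinate of the line, mm (default 0:
#'   the central axis).
#' @param tolerance_mm half-width of the selection band, mm.
#' @param at pairing positions: `"measurement"` or `"grid"` (see above).
#' @return A data frame of class `dose_profile` with columns `position`,
#'   `d_ref`, `d_meas` (percent of the reference maximum), positions strictly
#'   increasing.
#' @export
extract_profile <- function(grid, meas, axis = c("SI", "RL"),
                            line_position_mm = 0, tolerance_mm = 0.5,
                            at = c("measurement", "grid")) {
  axis <- match.arg(axis)
  at <- match.arg(at)
  stopifnot(inherits(grid, "dose_grid"), inherits(meas, "measurement"))
  along <- if (axis == "SI") meas$pos_si else meas$pos_rl
  off <- if (axis == "SI") meas$pos_rl else meas$pos_si
  sel <- abs(off - line_position_mm) <= tolerance_mm
  if (sum(sel) < 2L)
    stop(sprintf("fewer than 2 measurement points within %g mm of the %s line at %g mm",
                 tolerance_mm, axis, line_position_mm))
  p <- along[sel]; dm <- meas$dose[sel]; po <- off[sel]
  ord <- order(p)
  p <- p[ord]; dm <- dm[ord]; po <- po[ord]
  if (any(diff(p) <= 0)) stop("profile positions must be strictly increasing")
  to_pct <- 100 / grid$max
  if (at == "measurement") {
    d_ref <- if (axis == "SI") dose_at(grid, p, po) else dose_at(grid, po, p)
    out <- data.frame(position = p, d_ref = d_ref * to_pct,
                      d_meas = dm * to_pct)
  } else {
    ax <- grid_axes(grid)
    nodes <- if (axis == "SI") ax$si else ax$rl
    nodes <- nodes[nodes >= min(p) & nodes <= max(p)]
    dmi <- stats::approx(p, dm, xout = nodes)$y
    d_ref <- if (axis == "SI") dose_at(grid, nodes, line_position_mm)
             else dose_at(grid, line_position_mm, nodes)
    out <- data.frame(position = nodes, d_ref = d_ref * to_pct,
                      d_meas = dmi * to_pct)
  }
  structure(out, axis = axis, line_position = line_position_mm, at = at,
            class = c("dose_profile", "data.frame"))
}

#' Profile root-mean-square error
#'
#' `RMSE = sqrt(mean((d_ref - d_meas)^2))` over the paired profile doses, in
#' percent of the reference maximum. `drop_last = TRUE` excludes the final
#' pair from the sum (reproducing a published summation limit of n - 1); the
#' default uses all n pairs.
#'
#' @param profile a [extract_profile()] result (or any data frame with
#'   `d_ref` and `d_meas` columns).
#' @param drop_last exclude the last pair?
#' @return An object of class `rmse_result`: list with `rmse` (percent) and
#'   `n` (pairs used).
#' @export
compute_rmse <- function(profile, drop_last = FALSE) {
  stopifnot(is.data.frame(profile),
            all(c("d_ref", "d_meas") %in% names(profile)))
  n <- nrow(profile)
  if (n < 2L) stop("profile must contain at least 2 pairs")
  idx <- if (drop_last) seq_len(n - 1L) else seq_len(n)
  r <- sqrt(mean((profile$d_ref[idx] - profile$d_meas[idx])^2))
  structure(list(rmse = r, n = length(idx)), class = "rmse_result")
}

#' @export
print.rmse_result <- function(x, ...) {
  cat(sprintf("<rmse_result> RMSE = %.4f%% over %d pairs\n", x$rmse, x$n))
  invisible(x)
}

#' Gamma-analysis parameters
#'
#' @param dose_diff dose-difference criterion, percent.
#' @param dta distance-to-agreement criterion, mm.
#' @param threshold low-dose cutoff: points whose measured dose is below this
#'   percent of the reference global maximum are excluded.
#' @param normalization `"global"` (dose criterion anchored to the reference
#'   global maximum) or `"local"` (anchored to the reference dose at each
#'   evaluated point).
#' @param search_radius_factor spatial search radius as a multiple of `dta`.
#' @param ref_step reference sub-sampling step for the search, mm; default
#'   `min(0.05, dta / 10)`.
#' @return An object of class `gamma_params`.
#' @export
gamma_params <- function(dose_diff = 3, dta = 3, threshold = 10,
                         normalization = c("global", "local"),
                         search_radius_factor = 3, ref_step = NULL) {
  normalization <- match.arg(normalization)
  if (dose_diff <= 0) stop("`dose_diff` must be > 0")
  if (dta <= 0) stop("`dta` must be > 0")
  if (threshold < 0 || threshold >= 100) stop("`threshold` must be in [0, 100)")
  if (search_radius_factor <= 0) stop("`search_radius_factor` must be > 0")
  if (is.null(ref_step)) ref_step <- min(0.05, dta / 10)
  if (ref_step > dta / 10 + 1e-12)
    stop("`ref_step` must be <= dta / 10")
  structure(list(dose_diff = dose_diff, dta = dta, threshold = threshold,
                 normalization = normalization,
                 search_radius_factor = search_radius_factor,
                 ref_step = ref_step),
            class = "gamma_params")
}

# candidate search offsets within the radius, sorted by distance
gamma_offsets <- function(params) {
  s <- params$ref_step
  R <- params$search_radius_factor * params$dta
  k <- floor(R / s + 1e-9)
  o <- (-k:k) * s
  tab <- expand.grid(dsi = o, drl = o, KEEP.OUT.ATTRS = FALSE)
  dist <- sqrt(tab$dsi^2 + tab$drl^2)
  keep <- dist <= R + 1e-12
  ord <- order(dist[keep])
  list(dsi = tab$dsi[keep][ord], drl = tab$drl[keep][ord],
       dist = dist[keep][ord])
}

#' 2D gamma analysis of a measurement against a reference grid
#'
#' For each measurement point above the dose threshold, the gamma index is
#' the minimum over reference positions `r` within
#' `search_radius_factor * dta` of
#' `sqrt(|r - r_i|^2 / dta^2 + (D_ref(r) - D_e(i))^2 / dD^2)`,
#' where `dD` is `dose_diff`% of the reference global maximum (global
#' normalization) or of the reference dose at the point (local). The
#' reference is evaluated by bilinear interpolation on a sub-grid of step
#' `ref_step`; candidate positions outside the grid extent are excluded (no
#' extrapolation). A point passes when gamma <= 1.
#'
#' The search prunes candidates farther than `gamma(r_i) * dta`, which cannot
#' change the minimum because the distance term alone already exceeds the
#' incumbent there.
#'
#' @param grid reference [dose_grid()].
#' @param meas a [measurement()]; all points must lie inside the grid extent.
#' @param params a [gamma_params()].
#' @return An object of class `gamma_result`: data frame of evaluated points
#'   (`pos_si`, `pos_rl`, `dose`, `gamma`, `pass`) with attributes
#'   `pass_rate` (percent), `n_evaluated`, `n_pass`, `params`.
#' @export
gamma_index <- function(grid, meas, params = gamma_params()) {
  stopifnot(inherits(grid, "dose_grid"), inherits(meas, "measurement"),
            inherits(params, "gamma_params"))
  max_ref <- grid$max
  thr_abs <- params$threshold / 100 * max_ref
  sel <- meas$dose >= thr_abs
  if (!any(sel))
    stop(sprintf("no measurement points at or above the %g%% dose threshold",
                 params$threshold))
  pts <- as.data.frame(meas)[sel, , drop = FALSE]
  off <- gamma_offsets(params)
  ext <- grid_extent(grid)
  dta <- params$dta
  R <- params$search_radius_factor * dta

  d_ref_at_pt <- dose_at(grid, pts$pos_si, pts$pos_rl)
  dD <- if (params$normalization == "global")
    rep(params$dose_diff / 100 * max_ref, nrow(pts))
  else params$dose_diff / 100 * d_ref_at_pt

  gam <- numeric(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    De <- pts$dose[i]
    g0 <- abs(d_ref_at_pt[i] - De) / dD[i]
    cut <- min(R, g0 * dta)
    m <- findInterval(cut + 1e-12, off$dist)
    dsi <- off$dsi[seq_len(m)]; drl <- off$drl[seq_len(m)]
    csi <- pts$pos_si[i] + dsi; crl <- pts$pos_rl[i] + drl
    inside <- csi >= ext$si[1] & csi <= ext$si[2] &
              crl >= ext$rl[1] & crl <= ext$rl[2]
    dref <- dose_at(grid, csi[inside], crl[inside])
    g2 <- off$dist[seq_len(m)][inside]^2 / dta^2 + (dref - De)^2 / dD[i]^2
    gam[i] <- sqrt(min(g2, g0^2))
  }
  pass <- gam <= 1
  res <- data.frame(pos_si = pts$pos_si, pos_rl = pts$pos_rl,
                    dose = pts$dose, gamma = gam, pass = pass)
  structure(res, pass_rate = 100 * mean(pass), n_evaluated = nrow(res),
            n_pass = sum(pass), params = params,
            class = c("gamma_result", "data.frame"))
}

#' Gamma pass rate of a result
#'
#' @param x a [gamma_index()] result.
#' @return Pass rate in percent.
#' @export
pass_rate <- function(x) {
  stopifnot(inherits(x, "gamma_result"))
  attr(x, "pass_rate")
}

#' @export
print.gamma_result <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf("<gamma_result> %g%%/%g mm (%s, threshold %g%%): %d/%d pass (%.1f%%)\n",
              p$dose_diff, p$dta, p$normalization, p$threshold,
              attr(x, "n_pass"), attr(x, "n_evaluated"), attr(x, "pass_rate")))
  invisible(x)
}

#' Tabulate gamma pass rates across tolerances and replicates
#'
#' @param results either a named list of [gamma_index()] results (one
#'   replicate; names label the tolerances) or a list of such named lists
#'   (one element per replicate, identical names).
#' @return Data frame with one row per tolerance: `tolerance`, `n_replicates`,
#'   `n_evaluated` (mean), `pass_rate_mean`, `pass_rate_sd` (0 for a single
#'   replicate).
#' @export
pass_rate_table <- function(results) {
  single <- all(vapply(results, inherits, logical(1), "gamma_result"))
  reps <- if (single) list(results) else results
  tol <- names(reps[[1]])
  if (is.null(tol)) stop("gamma results must be named by tolerance")
  rows <- lapply(tol, function(tl) {
    pr <- vapply(reps, function(r) attr(r[[tl]], "pass_rate"), numeric(1))
    ne <- vapply(reps, function(r) attr(r[[tl]], "n_evaluated"), numeric(1))
    data.frame(tolerance = tl, n_replicates = length(pr),
               n_evaluated = mean(ne), pass_rate_mean = mean(pr),
               pass_rate_sd = if (length(pr) > 1) stats::sd(pr) else 0)
  })
  do.call(rbind, rows)
}
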