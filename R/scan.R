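# Condition scans: initial glucose:xylose ratio at fixed total substrate
# carbon, and oxygen transfer (kLa), scored by maximum 2,3-BDO productivity
# and final titer.

#' Maximum 2,3-BDO productivity of a trajectory
#'
#' The maximum over sampled times `t > 0` of `[BDO](t) / t` (mmol L^-1
#' h^-1) and the time at which it is attained (earliest in case of ties).
#'
#' @param traj a [simulate_batch()] trajectory.
#' @return list `value` (mmol L^-1 h^-1) and `time` (h).
#' @export
max_productivity <- function(traj) {
  s <- traj$states
  pos <- s$time_h > 0
  if (!any(pos)) stop_zf("trajectory has no positive-time samples", "zf_bad_trajectory")
  p <- s$bdo_mM[pos] / s$time_h[pos]
  i <- which(p >= max(p) - 1e-12)[1]  # earliest tie
  list(value = max(p), time = s$time_h[pos][i])
}

#' Initial glucose and xylose concentrations at a molar ratio and fixed carbon
#'
#' Solves `6 glc + 5 xyl = total_cmol` with `glc = r * xyl`.
#'
#' @param ratio molar glucose:xylose ratio `r`.
#' @param total_cmol total substrate carbon, mM carbon (default
#'   `6*443 + 5*245 = 3883`, the validation condition).
#' @return list `glc`, `xyl` in mM.
#' @export
sugars_at_ratio <- function(ratio, total_cmol = 3883) {
  if (ratio <= 0 || total_cmol <= 0) {
    stop_zf("ratio and total_cmol must be positive", "zf_bad_scan")
  }
  xyl <- total_cmol / (6 * ratio + 5)
  list(glc = ratio * xyl, xyl = xyl)
}

#' Scan initial glucose:xylose ratios at fixed total substrate carbon
#'
#' Simulates one batch per molar ratio with initial sugars from
#' [sugars_at_ratio()], holding everything else at the base configuration.
#'
#' @param ratios molar glucose:xylose ratios (> 0), e.g. `c(0.5, 1, 2, 4)`.
#' @param total_cmol total substrate carbon, mM carbon.
#' @param net,tk,ul,gas,init,t_end,dt,reuptake base configuration passed to
#'   [simulate_batch()]; `init` supplies everything but the sugars.
#' @return object of class `scan_result` (axis `"glc_xyl_ratio"`).
#' @export
sugar_ratio_scan <- function(ratios, total_cmol = 3883, net, tk,
                             ul = uptake_limits(), gas = gas_transfer(),
                             init = extracellular_state(),
                             t_end = 65, dt = 0.1, reuptake = TRUE) {
  trajs <- lapply(ratios, function(r) {
    sg <- sugars_at_ratio(r, total_cmol)
    ini <- init
    ini$glc <- sg$glc; ini$xyl <- sg$xyl
    simulate_batch(net, tk, ul, gas, ini, t_end = t_end, dt = dt,
                   reuptake = reuptake)
  })
  scan_result("glc_xyl_ratio", ratios, trajs)
}

#' Scan oxygen mass-transfer coefficients
#'
#' One batch per kLa value; reports both maximum productivity and final
#' titer so the productivity-versus-titer tension across aeration levels is
#' visible.
#'
#' @param kla_values kLa grid, h^-1 (>= 0), e.g. `c(10, 30, 60, 120)`.
#' @inheritParams sugar_ratio_scan
#' @return object of class `scan_result` (axis `"kla"`).
#' @export
kla_scan <- function(kla_values, net, tk, ul = uptake_limits(),
                     gas = gas_transfer(), init = extracellular_state(),
                     t_end = 65, dt = 0.1, reuptake = TRUE) {
  if (any(kla_values < 0)) stop_zf("kla values must be >= 0", "zf_bad_scan")
  trajs <- lapply(kla_values, function(k) {
    g <- gas
    g$kla <- k
    simulate_batch(net, tk, ul, g, init, t_end = t_end, dt = dt,
                   reuptake = reuptake)
  })
  scan_result("kla", kla_values, trajs)
}

scan_result <- function(axis, values, trajectories) {
  mp <- lapply(trajectories, max_productivity)
  structure(list(
    axis = axis, values = values, trajectories = trajectories,
    summary = data.frame(
      value = values,
      max_productivity = vapply(mp, `[[`, numeric(1), "value"),
      t_at_max = vapply(mp, `[[`, numeric(1), "time"),
      final_titer = vapply(trajectories, function(tr) {
        tr$states$bdo_mM[nrow(tr$states)]
      }, numeric(1))
    )
  ), class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf("Condition scan over %s (%d points)\n", x$axis,
              length(x$values)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
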