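#' Fit a conduction velocity vector over one electrode triangle
#'
#' Fits the plane `t = a*x + b*y + c` through three activation times at
#' three electrode positions. The gradient `g = (a, b)` in ms/mm points
#' toward later activation, i.e. along the propagation direction; local
#' speed is `1/|g|` (mm/ms = m/s) and direction is the orientation of `g`
#' in degrees (0 = +x, counter-clockwise).
#'
#' The fit is invalid when the electrodes are collinear (degenerate
#' geometry), when the time span across the vertices is below `min_dt_ms`
#' or the gradient is unresolvable (all times equal), or when the fitted
#' speed falls outside `speed_bounds` — triangles nearly parallel to the
#' wavefront otherwise yield unphysically high speeds.
#'
#' @param positions_mm 3 x 2 matrix of `(x, y)` electrode positions in mm.
#' @param times_ms Numeric length-3 activation times in ms.
#' @param speed_bounds Admissible speed range in m/s (default `c(0.1, 5)`).
#' @param min_dt_ms Minimum time span across the triangle (default 0.04 ms,
#'   one sample at 25 kHz).
#' @param min_area_mm2 Minimum triangle area (default 1e-6 mm^2).
#' @return List with `speed_mps`, `direction_deg`, `valid`, `reason`
#'   (`NA` when valid).
#' @examples
#' fit_triangle_velocity(rbind(c(0, 0), c(2.7, 0), c(0, 2.7)), c(0, 3, 0))
#' @export
fit_triangle_velocity <- function(positions_mm, times_ms,
                                  speed_bounds = c(0.1, 5),
                                  min_dt_ms = 0.04,
                                  min_area_mm2 = 1e-6) {
  positions_mm <- as.matrix(positions_mm)
  if (!identical(dim(positions_mm), c(3L, 2L)) || length(times_ms) != 3) {
    stop_invalid("need three (x, y) positions and three times")
  }
  invalid <- function(reason) list(speed_mps = NA_real_, direction_deg = NA_real_,
                                   valid = FALSE, reason = reason)
  # signed doubled area; zero means collinear electrodes
  a2 <- (positions_mm[2, 1] - positions_mm[1, 1]) * (positions_mm[3, 2] - positions_mm[1, 2]) -
        (positions_mm[3, 1] - positions_mm[1, 1]) * (positions_mm[2, 2] - positions_mm[1, 2])
  if (abs(a2) / 2 <= min_area_mm2) return(invalid("degenerate geometry"))
  if (diff(range(times_ms)) < min_dt_ms) return(invalid("unresolvable gradient"))
  A <- cbind(positions_mm, 1)
  coef <- solve(A, times_ms)
  g <- coef[1:2]  # ms/mm, points toward later activation
  gnorm <- sqrt(sum(g^2))
  if (gnorm <= .Machine$double.eps) return(invalid("unresolvable gradient"))
  speed <- 1 / gnorm
  if (speed < speed_bounds[1] || speed > speed_bounds[2]) {
    return(invalid("speed outside bounds"))
  }
  direction <- atan2(g[2], g[1]) * 180 / pi
  if (direction < 0) direction <- direction + 360
  list(speed_mps = speed, direction_deg = direction, valid = TRUE, reason = NA_character_)
}

#' Wave propagation velocity over an activation map
#'
#' Fits a conduction vector in every geometry triangle whose three vertices
#' have valid activation times, applies the validity filters of
#' [fit_triangle_velocity()], and summarizes the valid speeds into the wave
#' propagation velocity (WPV). The per-array summary is the arithmetic mean
#' by default; the median is available via `summary`.
#'
#' @param activation_map An [detect_activation_times()] result, or any
#'   data.frame with `channel_id`, `t_ms`, `valid`.
#' @param geometry The matching [make_geometry()] object.
#' @param speed_bounds,min_dt_ms Validity filters, see
#'   [fit_triangle_velocity()].
#' @param summary `"mean"` (default) or `"median"`.
#' @return A `conduction_field`: list with `triangles` (data.frame `v1, v2,
#'   v3, speed_mps, direction_deg, valid, reason`), `wpv_mps`, `sd_mps`,
#'   `n_valid`, `n_total`, `summary`.
#' @export
wave_propagation_velocity <- function(activation_map, geometry,
                                      speed_bounds = c(0.1, 5),
                                      min_dt_ms = 0.04,
                                      summary = c("mean", "median")) {
  summary <- match.arg(summary)
  tri <- geometry$triangles
  xy <- as.matrix(geometry$channels[, c("x_mm", "y_mm")])
  t_by_id <- activation_map$t_ms[match(geometry$channels$channel_id,
                                       activation_map$channel_id)]
  v_by_id <- activation_map$valid[match(geometry$channels$channel_id,
                                        activation_map$channel_id)]
  n_tri <- nrow(tri)
  out <- data.frame(v1 = tri[, 1], v2 = tri[, 2], v3 = tri[, 3],
                    speed_mps = NA_real_, direction_deg = NA_real_,
                    valid = FALSE, reason = NA_character_)
  for (k in seq_len(n_tri)) {
    idx <- chan_index(geometry, tri[k, ])
    if (!all(v_by_id[idx] %in% TRUE)) {
      out$reason[k] <- "invalid vertex channel"
      next
    }
    fit <- fit_triangle_velocity(xy[idx, , drop = FALSE], t_by_id[idx],
                                 speed_bounds = speed_bounds, min_dt_ms = min_dt_ms)
    out$speed_mps[k] <- fit$speed_mps
    out$direction_deg[k] <- fit$direction_deg
    out$valid[k] <- fit$valid
    out$reason[k] <- fit$reason
  }
  speeds <- out$speed_mps[out$valid]
  if (!length(speeds)) {
    stop_analysis("no valid conduction triangle: cannot estimate WPV (%s)",
                  paste(sprintf("%s: %d", names(table(out$reason)), table(out$reason)),
                        collapse = ", "))
  }
  wpv <- if (summary == "mean") mean(speeds) else stats::median(speeds)
  structure(list(triangles = out, wpv_mps = wpv,
                 sd_mps = if (length(speeds) > 1) stats::sd(speeds) else 0,
                 n_valid = length(speeds), n_total = n_tri, summary = summary),
            class = "conduction_field")
}

#' @export
print.conduction_field <- function(x, ...) {
  cat(sprintf("Conduction field: WPV (%s) = %.3f m/s (SD %.3f), %d/%d valid triangles\n",
              x$summary, x$wpv_mps, x$sd_mps, x$n_valid, x$n_total))
  invisible(x)
}

#' Phase map: per-site maximal neighbor activation delay
#'
#' For every channel with a valid activation time, the phase delay is the
#' largest absolute activation-time difference to its valid Moore
#' (8-connected) neighbors. Channels with no valid neighbor are excluded.
#' The delays feed the phase histogram and the conduction heterogeneity
#' index ([conduction_heterogeneity_index()]).
#'
#' @inheritParams wave_propagation_velocity
#' @return A data.frame `channel_id, delay_ms` of class `phase_map`.
#' @export
phase_map <- function(activation_map, geometry) {
  t_by_id <- activation_map$t_ms[match(geometry$channels$channel_id,
                                       activation_map$channel_id)]
  v_by_id <- activation_map$valid[match(geometry$channels$channel_id,
                                        activation_map$channel_id)]
  v_by_id[is.na(v_by_id)] <- FALSE
  ids <- geometry$channels$channel_id
  res_id <- integer(0); res_delay <- numeric(0)
  for (i in seq_along(ids)) {
    if (!v_by_id[i]) next
    nb <- chan_index(geometry, geometry$neighbors[[i]])
    nb <- nb[v_by_id[nb]]
    if (!length(nb)) next
    res_id <- c(res_id, ids[i])
    res_delay <- c(res_delay, max(abs(t_by_id[nb] - t_by_id[i])))
  }
  if (!length(res_id)) {
    stop_analysis("phase map is empty: no channel has a valid neighbor")
  }
  structure(data.frame(channel_id = res_id, delay_ms = res_delay),
            class = c("phase_map", "data.frame"))
}

#' Percentile with linear interpolation
#'
#' The percentile convention used throughout the package for P5/P50/P95:
#' linear interpolation of the empirical quantile function with endpoints
#' at the extreme order statistics (the `type = 7` convention). Changing
#' this convention changes CHI, so it is fixed and documented here.
#'
#' @param values Non-empty numeric vector.
#' @param p Percentile in `[0, 100]`.
#' @return The interpolated percentile.
#' @examples
#' percentile(1:5, 5)   # 1.2
#' percentile(1:5, 95)  # 4.8
#' @export
percentile <- function(values, p) {
  if (!length(values) || anyNA(values)) stop_invalid("values must be non-empty and NA-free")
  if (!is.numeric(p) || length(p) != 1 || is.na(p) || p < 0 || p > 100) {
    stop_invalid("p must lie in [0, 100]")
  }
  unname(stats::quantile(values, probs = p / 100, type = 7))
}

#' Conduction heterogeneity index
#'
#' `CHI = (P95 - P5) / P50` of the phase-map delays, a dimensionless
#' measure of conduction scattering: 0 for perfectly uniform propagation
#' (all delays equal), increasing with activation-time heterogeneity. CHI
#' is invariant under rescaling of all delays. Undefined when the median
#' delay is 0 (uniformly simultaneous neighbors).
#'
#' @param delays Numeric vector of phase delays in ms, or a [phase_map()]
#'   data.frame.
#' @return List with `p5`, `p50`, `p95` (ms) and `chi`.
#' @export
conduction_heterogeneity_index <- function(delays) {
  if (is.data.frame(delays)) delays <- delays$delay_ms
  if (!length(delays)) stop_invalid("empty delay vector")
  p5 <- percentile(delays, 5)
  p50 <- percentile(delays, 50)
  p95 <- percentile(delays, 95)
  if (p50 == 0) {
    stop_analysis("CHI undefined: median phase delay is 0")
  }
  list(p5 = p5, p50 = p50, p95 = p95, chi = (p95 - p5) / p50)
}

#' Serialize conduction results to CSV
#'
#' `write_conduction_csv` writes one row per triangle (vertices, speed,
#' direction, validity, rejection reason); the WPV summary record is
#' written by the pipeline alongside it. `write_phase_map_csv` writes
#' `channel_id, delay_ms`.
#'
#' @param field A `conduction_field`.
#' @param path File path.
#' @export
write_conduction_csv <- function(field, path) {
  utils::write.csv(field$triangles, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_conduction_csv
#' @param pm A `phase_map`.
#' @export
write_phase_map_csv <- function(pm, path) {
  utils::write.csv(as.data.frame(pm), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
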