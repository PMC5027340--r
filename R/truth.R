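#' Ground-truth activation times for simulated wavefronts
#'
#' Exact per-channel activation times for an idealized wavefront crossing the
#' array: `simulate_planar_truth` propagates a plane wave with constant speed
#' and direction, `simulate_focal_truth` spreads radially from a focal
#' origin. Because mm/ms and m/s are the same unit, a speed of 0.9 m/s moves
#' 0.9 mm per ms across the grid. These objects are the reference against
#' which the activation-mapping stages are validated.
#'
#' Planar: `t_i = t0 + (r_i . u) / speed`, with `r_i` the channel position in
#' mm and `u` the unit vector at `direction_deg` (0 deg = +x, 90 deg = +y,
#' counter-clockwise). Focal: `t_i = t0 + |r_i - origin| / speed`.
#'
#' @param geometry An [make_geometry()] object.
#' @param speed_mps Conduction speed in m/s; must be > 0.
#' @param direction_deg Propagation direction in degrees (planar only).
#' @param origin_mm Numeric length-2 `(x, y)` in mm (focal only).
#' @param t0_ms Activation onset offset in ms (time of the earliest possible
#'   activation reference; see formulas above).
#' @return An object of class `activation_truth`: list with `t_ms` (vector of
#'   per-channel times, ordered as `geometry$channels`), `kind`,
#'   `speed_mps`, and the wavefront parameters.
#' @examples
#' g <- make_geometry(4, 4, 2.7)
#' tr <- simulate_planar_truth(g, speed_mps = 0.9, direction_deg = 0)
#' diff(tr$t_ms[1:2])  # 3 ms between adjacent columns
#' @export
simulate_planar_truth <- function(geometry, speed_mps, direction_deg = 0, t0_ms = 0) {
  check_speed(speed_mps)
  th <- direction_deg * pi / 180
  u <- c(cos(th), sin(th))
  t_ms <- t0_ms + (geometry$channels$x_mm * u[1] + geometry$channels$y_mm * u[2]) / speed_mps
  # keep times non-negative relative to t0 by anchoring at the most upstream channel
  t_ms <- t_ms - min(t_ms) + t0_ms
  structure(list(t_ms = t_ms, kind = "planar", speed_mps = speed_mps,
                 direction_deg = direction_deg, t0_ms = t0_ms,
                 geometry = geometry),
            class = "activation_truth")
}

#' @rdname simulate_planar_truth
#' @export
simulate_focal_truth <- function(geometry, speed_mps, origin_mm, t0_ms = 0) {
  check_speed(speed_mps)
  if (!is.numeric(origin_mm) || length(origin_mm) != 2 || any(is.na(origin_mm))) {
    stop_invalid("origin_mm must be numeric (x, y) in mm")
  }
  d <- sqrt((geometry$channels$x_mm - origin_mm[1])^2 +
            (geometry$channels$y_mm - origin_mm[2])^2)
  structure(list(t_ms = t0_ms + d / speed_mps, kind = "focal",
                 speed_mps = speed_mps, origin_mm = origin_mm, t0_ms = t0_ms,
                 geometry = geometry),
            class = "activation_truth")
}

check_speed <- function(speed_mps) {
  if (!is.numeric(speed_mps) || length(speed_mps) != 1 || is.na(speed_mps) ||
      speed_mps <= 0) {
    stop_invalid("speed_mps must be a positive scalar (m/s)")
  }
  invisible(TRUE)
}

#' Convert a ground-truth wavefront to an activation map
#'
#' Wraps the exact truth times in the `activation_map` layout used by the
#' conduction stage, so mapping operations can be validated against
#' machine-precision inputs independently of signal synthesis and
#' detection.
#'
#' @param truth An `activation_truth`.
#' @param jitter_sd_ms Optional Gaussian activation-time jitter SD (ms);
#'   uses the current RNG state.
#' @return An `activation_map` data.frame (`channel_id, t_ms,
#'   slope_mv_per_ms, valid`), all channels valid.
#' @export
as_activation_map <- function(truth, jitter_sd_ms = 0) {
  t_ms <- truth$t_ms
  if (jitter_sd_ms > 0) t_ms <- t_ms + stats::rnorm(length(t_ms), 0, jitter_sd_ms)
  structure(data.frame(channel_id = truth$geometry$channels$channel_id,
                       t_ms = t_ms, slope_mv_per_ms = NA_real_, valid = TRUE),
            class = c("activation_map", "data.frame"),
            stimulus_time_ms = 0, sampling_rate_hz = NA_real_)
}

#' @export
print.activation_truth <- function(x, ...) {
  cat(sprintf("%s wavefront truth: %d channels, speed %.3g m/s, times %.2f..%.2f ms\n",
              x$kind, length(x$t_ms), x$speed_mps, min(x$t_ms), max(x$t_ms)))
  invisible(x)
}
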