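# k-step central difference of one channel, in mV/ms; NA at the edges.
# half_width = 1 sample for activation (sharp deflection); a wider step acts
# as a smoothed derivative for the slow repolarization wave.
discrete_derivative <- function(x, sampling_rate_hz, half_width = 1L) {
  n <- length(x)
  k <- as.integer(half_width)
  if (k < 1L || 2L * k >= n) stop_invalid("derivative half-width out of range")
  d <- rep(NA_real_, n)
  dt_ms <- 1000 / sampling_rate_hz
  idx <- (k + 1L):(n - k)
  d[idx] <- (x[idx + k] - x[idx - k]) / (2 * k * dt_ms)
  d
}

ms_to_sample <- function(t_ms, fs) as.integer(round(t_ms / 1000 * fs)) + 1L
sample_to_ms <- function(i, fs) (i - 1L) / fs * 1000

#' Detect local activation times from unipolar electrograms
#'
#' Local activation at each electrode is the time of the steepest negative
#' slope of the intrinsic deflection: per channel, the most negative
#' discrete derivative (central difference) within the search window after
#' the analyzed stimulus, excluding a post-stimulus blanking interval that
#' masks the pacing artifact. Channels whose peak negative-slope magnitude
#' falls below `min_slope_mv_per_ms` — by default 5x the channel's median
#' absolute derivative, a robust noise floor — are flagged invalid, as are
#' the geometry's bad channels. Ties resolve to the earliest sample.
#'
#' @param recording An [synthesize_recording()] object (or one read from
#'   disk with [read_recording()]).
#' @param stimulus_index Which stimulus of the pacing train to analyze
#'   (1-based; default 1 — one pacing train, one analyzed beat).
#' @param search_window_ms Length-2 window in ms relative to the stimulus;
#'   default `c(blanking_ms, cycle - blanking_ms)`, i.e. the full
#'   inter-stimulus interval minus blanking at both ends (the tail guard
#'   keeps the next stimulus artifact out of the window).
#' @param blanking_ms Post-stimulus blanking (default 5 ms).
#' @param min_slope_mv_per_ms Minimum |dV/dt| for a valid detection; `NULL`
#'   uses the per-channel robust default described above.
#' @return An `activation_map`: data.frame with `channel_id`, `t_ms`
#'   (activation time relative to the analyzed stimulus; NA when invalid),
#'   `slope_mv_per_ms`, `valid`; attributes carry the stimulus time and
#'   window.
#' @export
detect_activation_times <- function(recording, stimulus_index = 1L,
                                    search_window_ms = NULL,
                                    blanking_ms = 5,
                                    min_slope_mv_per_ms = NULL) {
  fs <- recording$sampling_rate_hz
  stims <- recording$stimulus_times_ms
  if (stimulus_index < 1L || stimulus_index > length(stims)) {
    stop_invalid("stimulus_index %d outside 1..%d", stimulus_index, length(stims))
  }
  stim <- stims[stimulus_index]
  if (is.null(search_window_ms)) {
    cycle <- if (stimulus_index < length(stims)) {
      stims[stimulus_index + 1L] - stim
    } else {
      ncol(recording$signal) / fs * 1000 - stim
    }
    # guard the tail end too: the next stimulus artifact has negative-slope
    # lobes a few ms before its centre
    search_window_ms <- c(blanking_ms, cycle - blanking_ms)
  }
  if (diff(search_window_ms) <= 0) stop_invalid("empty activation search window")
  search_window_ms[1] <- max(search_window_ms[1], blanking_ms)

  n_samp <- ncol(recording$signal)
  lo <- ms_to_sample(stim + search_window_ms[1], fs)
  hi <- min(ms_to_sample(stim + search_window_ms[2], fs), n_samp - 1L)
  lo <- max(lo, 2L)
  if (hi <= lo) stop_invalid("activation search window lies outside the recording")

  geom <- recording$geometry
  ids <- geom$channels$channel_id
  n_ch <- length(ids)
  t_ms <- rep(NA_real_, n_ch); slope <- rep(NA_real_, n_ch); valid <- logical(n_ch)
  for (i in seq_len(n_ch)) {
    if (ids[i] %in% geom$bad_channels) next
    d <- discrete_derivative(recording$signal[i, ], fs, 1L)
    win <- d[lo:hi]
    j <- which.min(win)          # earliest index on ties
    if (!length(j)) next
    peak <- win[j]
    thr <- if (is.null(min_slope_mv_per_ms)) {
      5 * stats::median(abs(d), na.rm = TRUE)
    } else min_slope_mv_per_ms
    if (!is.finite(peak) || peak >= 0 || abs(peak) < thr || abs(peak) == 0) next
    valid[i] <- TRUE
    t_ms[i] <- sample_to_ms(lo + j - 1L, fs) - stim
    slope[i] <- peak
  }
  if (!any(valid)) {
    warn_epimapr("activation map is empty: no channel passed the slope threshold")
  }
  structure(data.frame(channel_id = ids, t_ms = t_ms,
                       slope_mv_per_ms = slope, valid = valid),
            class = c("activation_map", "data.frame"),
            stimulus_time_ms = stim, search_window_ms = search_window_ms,
            blanking_ms = blanking_ms, sampling_rate_hz = fs)
}

#' Detect repolarization times from unipolar electrograms
#'
#' Repolarization at each electrode is the time of the steepest positive
#' slope of the repolarization (T) wave — the polarity-independent Wyatt
#' convention. The search window is expressed relative to each channel's
#' detected activation time; channels with invalid activation are invalid
#' here too. The derivative uses a wider central-difference step
#' (`deriv_halfwidth_ms`, default 5 ms) than activation detection: the
#' T-wave upstroke is one to two orders of magnitude slower than the
#' intrinsic deflection, and the wider step is a smoothed slope estimate
#' that is robust to acquisition noise while shifting the slow wave's
#' slope maximum by a negligible amount.
#'
#' @param recording The recording the activation map came from.
#' @param activation_map An [detect_activation_times()] result.
#' @param repol_window_ms Length-2 window in ms relative to activation
#'   (default `c(80, 400)`, bracketing ventricular action-potential
#'   durations at 120 bpm; use ~`c(40, 250)` for atria).
#' @param deriv_halfwidth_ms Central-difference half-step in ms.
#' @return A `repolarization_map` data.frame: `channel_id`, `t_ms` (relative
#'   to the analyzed stimulus), `slope_mv_per_ms`, `valid`.
#' @export
detect_repolarization_times <- function(recording, activation_map,
                                        repol_window_ms = c(80, 400),
                                        deriv_halfwidth_ms = 5) {
  if (diff(repol_window_ms) <= 0) stop_invalid("repolarization window start must precede its end")
  fs <- recording$sampling_rate_hz
  stim <- attr(activation_map, "stimulus_time_ms")
  k <- max(1L, as.integer(round(deriv_halfwidth_ms / 1000 * fs)))
  n_samp <- ncol(recording$signal)
  ids <- activation_map$channel_id
  n_ch <- length(ids)
  t_ms <- rep(NA_real_, n_ch); slope <- rep(NA_real_, n_ch); valid <- logical(n_ch)
  for (i in seq_len(n_ch)) {
    if (!activation_map$valid[i]) next
    act_abs <- stim + activation_map$t_ms[i]
    lo <- max(ms_to_sample(act_abs + repol_window_ms[1], fs), k + 1L)
    hi <- min(ms_to_sample(act_abs + repol_window_ms[2], fs), n_samp - k)
    if (hi <= lo) next
    d <- discrete_derivative(recording$signal[i, ], fs, k)
    win <- d[lo:hi]
    j <- which.max(win)
    if (!length(j) || !is.finite(win[j]) || win[j] <= 0) next
    valid[i] <- TRUE
    t_ms[i] <- sample_to_ms(lo + j - 1L, fs) - stim
    slope[i] <- win[j]
  }
  structure(data.frame(channel_id = ids, t_ms = t_ms,
                       slope_mv_per_ms = slope, valid = valid),
            class = c("repolarization_map", "data.frame"),
            stimulus_time_ms = stim, repol_window_ms = repol_window_ms,
            deriv_halfwidth_ms = deriv_halfwidth_ms)
}

#' Activation recovery intervals
#'
#' ARI — a surrogate for local action potential duration — is the time from
#' the steepest negative slope of the intrinsic deflection (activation) to
#' the steepest positive slope of the repolarization wave, per channel.
#' Channels valid in both maps but with non-positive ARI violate the
#' activation-before-repolarization ordering and are flagged invalid.
#'
#' @param activation_map,repolarization_map Maps from the same recording
#'   and analyzed beat.
#' @return An `ari_map`: data.frame `channel_id, ari_ms, valid` with
#'   attributes `mean_ms` and `sd_ms` over valid channels.
#' @export
compute_ari <- function(activation_map, repolarization_map) {
  if (!identical(activation_map$channel_id, repolarization_map$channel_id)) {
    stop_invalid("activation and repolarization maps cover different channels")
  }
  ari <- repolarization_map$t_ms - activation_map$t_ms
  valid <- activation_map$valid & repolarization_map$valid & !is.na(ari) & ari > 0
  n_bad_order <- sum(activation_map$valid & repolarization_map$valid &
                       !is.na(ari) & ari <= 0)
  if (n_bad_order > 0) {
    warn_epimapr("%d channel(s) with repolarization at or before activation flagged invalid",
                 n_bad_order)
  }
  ari[!valid] <- NA_real_
  vals <- ari[valid]
  structure(data.frame(channel_id = activation_map$channel_id,
                       ari_ms = ari, valid = valid),
            class = c("ari_map", "data.frame"),
            mean_ms = if (length(vals)) mean(vals) else NA_real_,
            sd_ms = if (length(vals) > 1) stats::sd(vals) else NA_real_,
            n_valid = length(vals))
}

#' Serialize a feature map to CSV
#'
#' Writes `channel_id, time_ms, slope, valid` (or `channel_id, ari_ms,
#' valid` for ARI maps).
#'
#' @param map An activation, repolarization or ARI map.
#' @param path File path.
#' @export
write_map_csv <- function(map, path) {
  utils::write.csv(as.data.frame(map), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
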