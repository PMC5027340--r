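# Independent brute-force oracles used across tests. These deliberately
# re-derive each quantity with naive loops, separate from the package's
# implementation path.

# naive k-step central difference scan: returns sample index of the extreme
# slope inside [lo, hi] (1-based sample indices), earliest tie wins
oracle_extreme_slope <- function(x, fs, lo, hi, k = 1L, mode = c("min", "max")) {
  mode <- match.arg(mode)
  dt_ms <- 1000 / fs
  best_i <- NA_integer_
  best_v <- if (mode == "min") Inf else -Inf
  for (i in max(lo, k + 1L):min(hi, length(x) - k)) {
    v <- (x[i + k] - x[i - k]) / (2 * k * dt_ms)
    if ((mode == "min" && v < best_v) || (mode == "max" && v > best_v)) {
      best_v <- v
      best_i <- i
    }
  }
  list(index = best_i, slope = best_v)
}

# naive neighbor-delay scan over a grid geometry
oracle_phase_delays <- function(t_ms, valid, geometry) {
  ids <- geometry$channels$channel_id
  out_id <- integer(0); out_d <- numeric(0)
  for (i in seq_along(ids)) {
    if (!valid[i]) next
    best <- -Inf
    for (nb in geometry$neighbors[[i]]) {
      j <- which(ids == nb)
      if (valid[j]) best <- max(best, abs(t_ms[j] - t_ms[i]))
    }
    if (is.finite(best)) {
      out_id <- c(out_id, ids[i]); out_d <- c(out_d, best)
    }
  }
  data.frame(channel_id = out_id, delay_ms = out_d)
}

# single-beat constructed channel: one biphasic deflection + one repol wave,
# sampled at fs, used to exercise the detectors with known extrema
make_beat_signal <- function(n_samp, fs, act_ms, ari_ms,
                             def_amp = 10, def_sigma = 1,
                             rep_amp = 4, rep_sigma = 8) {
  t <- (seq_len(n_samp) - 1) / fs * 1000
  dog <- function(tt, c0, s) { u <- (tt - c0) / s; u * exp(-u^2 / 2) }
  -def_amp * dog(t, act_ms, def_sigma) + rep_amp * dog(t, act_ms + ari_ms, rep_sigma)
}

# tiny default geometry + truth used by several files
tiny_setup <- function(rows = 4, cols = 4, pitch = 2.7, speed = 0.9, dir = 0) {
  g <- make_geometry(rows, cols, pitch)
  list(geometry = g, truth = simulate_planar_truth(g, speed, dir, t0_ms = 10))
}
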