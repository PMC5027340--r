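#' Default electrogram waveform parameters
#'
#' Shape parameters of the synthetic unipolar electrogram. The intrinsic
#' deflection is a derivative-of-Gaussian biphasic wave `-a * u * exp(-u^2/2)`
#' with `u = (t - t_act)/sigma`: its steepest *negative* slope falls exactly
#' at the programmed activation time with magnitude `a/sigma` mV/ms. The
#' repolarization wave is the mirrored shape `+b * u * exp(-u^2/2)` centred
#' at `t_act + ari`, so its steepest *positive* slope (`b/sigma_rep`) falls
#' exactly at activation + ARI. The pacing artifact is a large biphasic
#' spike at each stimulus whose amplitude decays exponentially with distance
#' from the bipolar stimulation corner.
#'
#' Noise is band-limited: white Gaussian noise convolved with a Gaussian
#' kernel (`noise_kernel_ms`) and rescaled to the requested SD, mimicking
#' the analog band-pass of an acquisition chain rather than white noise at
#' the full 25 kHz bandwidth.
#'
#' @param def_amp_mv Intrinsic-deflection amplitude scale (mV); peak-to-peak
#'   is about 1.21 x this value.
#' @param def_sigma_ms Intrinsic-deflection width (ms).
#' @param rep_amp_mv Repolarization-wave amplitude scale (mV).
#' @param rep_sigma_ms Repolarization-wave width (ms); slow compared to the
#'   deflection.
#' @param stim_amp_mv Stimulus-artifact amplitude at the stimulation site (mV).
#' @param stim_sigma_ms Stimulus-artifact width (ms).
#' @param stim_decay_mm Exponential spatial decay length of the artifact (mm).
#' @param noise_kernel_ms Gaussian smoothing SD applied to the noise (ms).
#' @return Named list of waveform parameters.
#' @export
waveform_params <- function(def_amp_mv = 10, def_sigma_ms = 1,
                            rep_amp_mv = 4, rep_sigma_ms = 8,
                            stim_amp_mv = 20, stim_sigma_ms = 0.5,
                            stim_decay_mm = 5, noise_kernel_ms = 0.5) {
  p <- list(def_amp_mv = def_amp_mv, def_sigma_ms = def_sigma_ms,
            rep_amp_mv = rep_amp_mv, rep_sigma_ms = rep_sigma_ms,
            stim_amp_mv = stim_amp_mv, stim_sigma_ms = stim_sigma_ms,
            stim_decay_mm = stim_decay_mm, noise_kernel_ms = noise_kernel_ms)
  if (any(!vapply(p, function(x) is.numeric(x) && length(x) == 1 && x > 0, TRUE))) {
    stop_invalid("all waveform parameters must be positive scalars")
  }
  p
}

# biphasic derivative-of-Gaussian: u * exp(-u^2/2)
dog_wave <- function(t_ms, centre_ms, sigma_ms) {
  u <- (t_ms - centre_ms) / sigma_ms
  u * exp(-u^2 / 2)
}

#' Synthesize a multichannel unipolar electrogram recording
#'
#' Renders a ground-truth wavefront ([simulate_planar_truth()] /
#' [simulate_focal_truth()]) into a channels x samples signal matrix:
#' pacing-train stimulus artifacts, one intrinsic deflection per beat at
#' `stimulus + t_i`, a repolarization wave at `stimulus + t_i + ari_ms`,
#' band-limited Gaussian noise, and (by default) 12-bit quantization over
#' +/- `range_mv`. With the default +/-20 mV range the quantization step is
#' 40/4096 mV, an exact binary fraction, so quantized samples are exactly
#' representable in 32-bit floats and the binary file dialect round-trips
#' bit-identically.
#'
#' @param truth An `activation_truth`; its `t_ms` are per-beat activation
#'   times relative to each stimulus.
#' @param params Waveform shape parameters, see [waveform_params()].
#' @param ari_ms Programmed activation recovery interval (ms, > 0).
#' @param noise_sd_mv Noise SD in mV (>= 0).
#' @param seed Integer seed; the signal is a pure function of
#'   (arguments, seed).
#' @param sampling_rate_hz Sampling rate (default 25000).
#' @param duration_s Recording length in seconds (default 2).
#' @param stimulus_times_ms Pacing train stimulus times; default a 120 bpm
#'   train starting at 100 ms (500 ms cycle length).
#' @param quantization_bits ADC resolution; `NA` disables quantization.
#' @param range_mv Half-range of the ADC in mV.
#' @return An object of class `mea_recording`: list with `signal`
#'   (channels x samples matrix, mV), `sampling_rate_hz`, `stimulus_times_ms`,
#'   `geometry`, `ari_ms`, `quantization_bits`, `range_mv`, `seed`, `units`.
#' @export
synthesize_recording <- function(truth, params = waveform_params(),
                                 ari_ms = 180, noise_sd_mv = 0.05,
                                 seed = 1L,
                                 sampling_rate_hz = 25000,
                                 duration_s = 2,
                                 stimulus_times_ms = NULL,
                                 quantization_bits = 12L,
                                 range_mv = 20) {
  if (!inherits(truth, "activation_truth")) stop_invalid("truth must be an activation_truth")
  if (!is.numeric(ari_ms) || length(ari_ms) != 1 || is.na(ari_ms) || ari_ms <= 0) {
    stop_invalid("ari_ms must be a positive scalar (ms)")
  }
  if (!is.numeric(noise_sd_mv) || noise_sd_mv < 0) stop_invalid("noise_sd_mv must be >= 0")
  if (sampling_rate_hz <= 0) stop_invalid("sampling_rate_hz must be > 0")
  geometry <- truth$geometry
  duration_ms <- duration_s * 1000
  if (is.null(stimulus_times_ms)) {
    cycle_ms <- 500  # 120 bpm
    stimulus_times_ms <- seq(100, duration_ms - cycle_ms + 100, by = cycle_ms)
  }
  # every programmed event (repolarization tail included) must fit the window
  last_event <- max(stimulus_times_ms) + max(truth$t_ms) + ari_ms + 5 * params$rep_sigma_ms
  if (last_event > duration_ms || min(stimulus_times_ms) < 0) {
    stop_invalid("programmed events extend beyond the recording (%0.1f > %0.1f ms)",
                 last_event, duration_ms)
  }

  n_ch <- nrow(geometry$channels)
  n_samp <- as.integer(round(duration_s * sampling_rate_hz))
  t_axis <- (seq_len(n_samp) - 1L) / sampling_rate_hz * 1000  # ms

  # distance of each channel to the bipolar stimulation site (closest pole)
  stim_xy <- geometry$channels[chan_index(geometry, geometry$stim_channels), c("x_mm", "y_mm")]
  d_stim <- apply(as.matrix(stim_xy), 1, function(p) {
    sqrt((geometry$channels$x_mm - p[1])^2 + (geometry$channels$y_mm - p[2])^2)
  })
  d_stim <- apply(d_stim, 1, min)

  signal <- matrix(0, nrow = n_ch, ncol = n_samp)
  for (i in seq_len(n_ch)) {
    s <- numeric(n_samp)
    for (st in stimulus_times_ms) {
      act <- st + truth$t_ms[i]
      s <- s - params$def_amp_mv * dog_wave(t_axis, act, params$def_sigma_ms)
      s <- s + params$rep_amp_mv * dog_wave(t_axis, act + ari_ms, params$rep_sigma_ms)
      s <- s + params$stim_amp_mv * exp(-d_stim[i] / params$stim_decay_mm) *
        dog_wave(t_axis, st, params$stim_sigma_ms)
    }
    signal[i, ] <- s
  }

  if (noise_sd_mv > 0) {
    set.seed(as.integer(seed))
    kern_sd_samp <- params$noise_kernel_ms * sampling_rate_hz / 1000
    half <- max(1L, as.integer(ceiling(4 * kern_sd_samp)))
    kern <- stats::dnorm(seq(-half, half), sd = kern_sd_samp)
    kern <- kern / sqrt(sum(kern^2))  # unit L2 norm preserves the white-noise SD
    for (i in seq_len(n_ch)) {
      w <- stats::rnorm(n_samp + 2L * half, sd = noise_sd_mv)
      sm <- stats::filter(w, kern, method = "convolution", sides = 2)
      signal[i, ] <- signal[i, ] + as.numeric(sm[(half + 1L):(half + n_samp)])
    }
  }

  if (!is.na(quantization_bits)) {
    signal <- quantize_signal(signal, quantization_bits, range_mv)
  }

  structure(list(signal = signal, sampling_rate_hz = sampling_rate_hz,
                 stimulus_times_ms = stimulus_times_ms, geometry = geometry,
                 ari_ms = ari_ms, noise_sd_mv = noise_sd_mv,
                 quantization_bits = quantization_bits, range_mv = range_mv,
                 seed = as.integer(seed), units = "mV"),
            class = "mea_recording")
}

# Midrise-free uniform quantizer: round to the 2^bits-level lattice over
# [-range, +range) and clip; LSB = 2*range / 2^bits.
quantize_signal <- function(signal, bits, range_mv) {
  lsb <- 2 * range_mv / 2^bits
  k <- pmin(pmax(round(signal / lsb), -2^(bits - 1)), 2^(bits - 1) - 1)
  k * lsb
}

#' @export
print.mea_recording <- function(x, ...) {
  cat(sprintf("MEA recording: %d channels x %d samples @ %g kHz (%.2f s), %s\n",
              nrow(x$signal), ncol(x$signal), x$sampling_rate_hz / 1000,
              ncol(x$signal) / x$sampling_rate_hz,
              if (is.na(x$quantization_bits)) "unquantized"
              else sprintf("%d-bit over +/-%g mV", x$quantization_bits, x$range_mv)))
  cat(sprintf("  stimuli at %s ms\n", toString(x$stimulus_times_ms)))
  invisible(x)
}
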