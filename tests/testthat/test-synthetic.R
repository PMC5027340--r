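# synthetic_data module: wavefront truths, recording synthesis, cohort

test_that("planar truth matches the closed-form times and symmetries", {
  g <- make_geometry(4, 4, 2.7)
  tr <- simulate_planar_truth(g, 0.9, 0, t0_ms = 0)
  # channel at the upstream origin activates at t0
  expect_equal(tr$t_ms[1], 0)
  # adjacent columns differ by pitch / speed = 3 ms
  by_col <- tr$t_ms[g$channels$row == 0]
  expect_equal(diff(by_col), rep(3, 3))
  # direction 90 deg: all channels in one row share identical times
  tr90 <- simulate_planar_truth(g, 0.9, 90, t0_ms = 5)
  for (r in 0:3) {
    expect_equal(diff(tr90$t_ms[g$channels$row == r]), rep(0, 3))
  }
})

test_that("planar truth is exact and translation-invariant in t0", {
  g <- make_geometry(5, 6, 2.1)
  for (case in 1:20) {
    sp <- 0.3 + 1.7 * ((case * 7) %% 20) / 20
    dir <- (case * 37) %% 360
    a <- simulate_planar_truth(g, sp, dir, t0_ms = 0)
    b <- simulate_planar_truth(g, sp, dir, t0_ms = 12.5)
    expect_equal(b$t_ms, a$t_ms + 12.5, tolerance = 1e-12)
    # exact plane: projecting positions onto the direction reproduces times
    u <- c(cos(dir * pi / 180), sin(dir * pi / 180))
    proj <- (g$channels$x_mm * u[1] + g$channels$y_mm * u[2]) / sp
    expect_equal(a$t_ms, proj - min(proj), tolerance = 1e-12)
  }
})

test_that("focal truth is radial with equal times at equidistant channels", {
  g <- make_geometry(5, 5, 2.7)
  centre <- c(2 * 2.7, 2 * 2.7)
  tr <- simulate_focal_truth(g, 1.0, centre, t0_ms = 4)
  i_centre <- which(g$channels$x_mm == centre[1] & g$channels$y_mm == centre[2])
  expect_equal(tr$t_ms[i_centre], 4)
  # 2.7 mm neighbor at 1.0 m/s activates t0 + 2.7 ms
  i_nb <- which(g$channels$row == 2 & g$channels$col == 3)
  expect_equal(tr$t_ms[i_nb], 4 + 2.7)
  # mirror-symmetric channels about the origin have equal times
  i_a <- which(g$channels$row == 0 & g$channels$col == 0)
  i_b <- which(g$channels$row == 4 & g$channels$col == 4)
  expect_equal(tr$t_ms[i_a], tr$t_ms[i_b])
})

test_that("invalid wavefront parameters are rejected", {
  g <- make_geometry(3, 3, 2.7)
  expect_error(simulate_planar_truth(g, 0, 0), class = "epimapr_invalid_parameter")
  expect_error(simulate_planar_truth(g, -1, 0), class = "epimapr_invalid_parameter")
  expect_error(simulate_focal_truth(g, 1.0, c(1, 2, 3)), class = "epimapr_invalid_parameter")
})

test_that("recording synthesis is deterministic and places slope extrema on the programmed samples", {
  s <- tiny_setup()
  r1 <- synthesize_recording(s$truth, ari_ms = 180, noise_sd_mv = 0.1, seed = 42,
                             duration_s = 1)
  r2 <- synthesize_recording(s$truth, ari_ms = 180, noise_sd_mv = 0.1, seed = 42,
                             duration_s = 1)
  expect_identical(r1$signal, r2$signal)

  # noiseless, unquantized: each channel's steepest negative slope sample is
  # the programmed activation sample (brute-force discrete-derivative scan)
  r0 <- synthesize_recording(s$truth, ari_ms = 180, noise_sd_mv = 0, seed = 1,
                             duration_s = 1, quantization_bits = NA)
  fs <- r0$sampling_rate_hz
  stim <- r0$stimulus_times_ms[1]
  for (i in c(1, 5, 16)) {
    sc <- oracle_extreme_slope(r0$signal[i, ], fs,
                               lo = round((stim + 5) / 1000 * fs),
                               hi = round((stim + 480) / 1000 * fs), mode = "min")
    act_sample <- round((stim + s$truth$t_ms[i]) / 1000 * fs) + 1
    expect_lte(abs(sc$index - act_sample), 1)
  }
})

test_that("quantized samples lie on the 12-bit lattice and survive float32", {
  s <- tiny_setup()
  r <- synthesize_recording(s$truth, ari_ms = 150, noise_sd_mv = 0.1, seed = 3,
                            duration_s = 1)
  lsb <- 2 * r$range_mv / 2^r$quantization_bits
  k <- r$signal / lsb
  expect_equal(k, round(k), tolerance = 1e-12)
  expect_lte(max(abs(r$signal)), r$range_mv)
  # lattice values are exactly representable as float32
  expect_identical(r$signal, matrix(readBin(writeBin(as.numeric(r$signal), raw(),
                                                     size = 4L),
                                            "numeric", n = length(r$signal), size = 4L),
                                    nrow = nrow(r$signal)))
})

test_that("synthesis rejects impossible event programs", {
  s <- tiny_setup()
  expect_error(synthesize_recording(s$truth, ari_ms = 0), class = "epimapr_invalid_parameter")
  expect_error(synthesize_recording(s$truth, ari_ms = -5), class = "epimapr_invalid_parameter")
  # repolarization would land beyond the recording
  expect_error(synthesize_recording(s$truth, ari_ms = 600, duration_s = 0.5,
                                    stimulus_times_ms = 100),
               class = "epimapr_invalid_parameter")
})

test_that("cohort generation is deterministic and matches configured means at n = 500", {
  p <- cohort_params(n_control = 500, n_angii = 500)
  c1 <- generate_cohort(p, seed = 11)
  c2 <- generate_cohort(p, seed = 11)
  expect_identical(c1$endpoints, c2$endpoints)
  expect_identical(c1$map, c2$map)

  # 16 simultaneous mean checks: 3 SE per comparison keeps the joint test
  # from false-failing while still catching any systematic bias
  for (g in c("control", "angii")) {
    for (nm in c("map_mmhg", "lv_mass_g", "ef_pct", "sv_ml")) {
      pars <- p$endpoints[[nm]][g, ]
      sub <- c1$endpoints[c1$endpoints$group == g, ]
      se_b <- pars["base_sd"] / sqrt(500)
      expect_lt(abs(mean(sub[[paste0(nm, "_baseline")]]) - pars["base_mean"]),
                3 * se_b)
      se_f <- sqrt(pars["base_sd"]^2 + pars["delta_sd"]^2) / sqrt(500)
      expect_lt(abs(mean(sub[[paste0(nm, "_followup")]]) -
                      (pars["base_mean"] + pars["delta_mean"])), 3 * se_f)
    }
  }
})

test_that("zero effect and zero noise gives follow-up identical to baseline", {
  ep <- list(map_mmhg = rbind(control = c(90, 5, 0, 0), angii = c(90, 5, 0, 0)))
  p <- cohort_params(n_control = 4, n_angii = 4, endpoints = ep,
                     map_meas_sd_mmhg = 0)
  co <- generate_cohort(p, seed = 2)
  expect_identical(co$endpoints$map_mmhg_followup, co$endpoints$map_mmhg_baseline)
  # and the weekly trajectory stays flat at the baseline value
  one <- co$map[co$map$animal_id == co$endpoints$animal_id[1], ]
  expect_equal(one$map_mmhg, rep(one$map_mmhg[1], nrow(one)))
})

test_that("invalid cohort parameters are rejected", {
  expect_error(cohort_params(n_control = 0), class = "epimapr_invalid_parameter")
  expect_error(cohort_params(endpoints = list(
    map_mmhg = rbind(control = c(90, -1, 0, 0), angii = c(90, 5, 0, 0)))),
    class = "epimapr_invalid_parameter")
})
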