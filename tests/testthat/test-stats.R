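# endpoint_stats module

test_that("group summaries use the n-1 SD and reject degenerate input", {
  s <- summarize_group(c(1, 2, 3))
  expect_equal(s, list(n = 3L, mean = 2, sd = 1))
  expect_equal(summarize_group(rep(4.2, 6))$sd, 0)
  expect_error(summarize_group(numeric(0)), class = "epimapr_invalid_parameter")
  expect_error(summarize_group(5), class = "epimapr_invalid_parameter")

  set.seed(12)
  draws <- rnorm(200, 87.4, 5.3)
  expect_lt(abs(summarize_group(draws)$mean - 87.4), 2 * 5.3 / sqrt(200))
})

test_that("percent change reproduces the published effect sizes", {
  expect_equal(percent_change(111.2, 131.5)$display, 18.3)
  expect_equal(percent_change(11.86, 17.27)$display, 45.6)
  expect_equal(percent_change(5, 5)$percent, 0)
  expect_error(percent_change(0, 10), class = "epimapr_invalid_parameter")
  # percent and mean difference stay consistent
  pc <- percent_change(109.8, 109.6)
  expect_equal(109.8 * pc$percent / 100, 109.6 - 109.8, tolerance = 1e-12)
})

test_that("unpaired Student's t matches hand computation and the reference oracle", {
  r <- students_t_unpaired(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$t, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(r$df, 4)
  expect_equal(r$p, 2 * pt(-abs(r$t), 4))

  same <- students_t_unpaired(c(2, 2, 2), c(2, 2, 2))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  set.seed(3)
  for (i in 1:25) {
    a <- rnorm(sample(3:12, 1), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(3:12, 1), mean = runif(1, -1, 1))
    mine <- students_t_unpaired(a, b)
    ref <- t.test(a, b, var.equal = TRUE)
    expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(mine$df, unname(ref$parameter))
    expect_equal(mine$p, ref$p.value, tolerance = 1e-6)
    welch <- students_t_unpaired(a, b, var_equal = FALSE)
    refw <- t.test(a, b)
    expect_equal(welch$p, refw$p.value, tolerance = 1e-6)
  }
  expect_error(students_t_unpaired(1, c(1, 2)), class = "epimapr_invalid_parameter")
})

test_that("paired Student's t matches hand computation, antisymmetry and the oracle", {
  r <- students_t_paired(c(1, 2, 3), c(2, 4, 3))
  expect_equal(r$t, sqrt(3), tolerance = 1e-12)
  expect_equal(r$df, 2)
  expect_equal(r$p, 2 * pt(-sqrt(3), 2), tolerance = 1e-12)

  expect_equal(students_t_paired(c(1, 2), c(1, 2)),
               list(t = 0, df = 1, p = 1, p_floor = FALSE))
  # zero-variance nonzero differences: flagged floor, not a bogus finite p
  fl <- students_t_paired(c(1, 2, 3), c(2, 3, 4))
  expect_true(fl$p_floor)
  expect_equal(fl$p, 0)

  set.seed(4)
  for (i in 1:25) {
    n <- sample(3:15, 1)
    pre <- rnorm(n); post <- pre + rnorm(n, 0.3)
    mine <- students_t_paired(pre, post)
    flip <- students_t_paired(post, pre)
    expect_equal(flip$t, -mine$t)
    expect_equal(flip$p, mine$p)
    ref <- t.test(post, pre, paired = TRUE)
    expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-6)
  }
  expect_error(students_t_paired(1:3, 1:4), class = "epimapr_invalid_parameter")
})

test_that("MAP trajectory summary finds the plateau week", {
  co <- generate_cohort(cohort_params(), seed = 20)
  traj <- map_trajectory_summary(co)
  plateau <- attr(traj, "plateau_week")
  expect_equal(unname(plateau["angii"]), 3)
  # control stays flat: plateau at the first observed week
  expect_equal(unname(plateau["control"]), 0)
  expect_true(all(c("group", "week", "n", "mean_mmhg", "sd_mmhg") %in% names(traj)))
  expect_error(map_trajectory_summary(co, plateau_fraction = 0),
               class = "epimapr_invalid_parameter")

  # constant trajectories plateau immediately
  ep <- list(map_mmhg = rbind(control = c(90, 2, 0, 0), angii = c(95, 2, 0, 0)))
  co0 <- generate_cohort(cohort_params(endpoints = ep, map_meas_sd_mmhg = 0), seed = 1)
  expect_true(all(attr(map_trajectory_summary(co0), "plateau_week") == 0))
})

test_that("control group drift stays within 2 SE of baseline under the null", {
  ep <- list(map_mmhg = rbind(control = c(89.4, 3.7, 0, 0), angii = c(87.4, 5.3, 24.4, 4.4)))
  co <- generate_cohort(cohort_params(n_control = 400, n_angii = 2, endpoints = ep),
                        seed = 8)
  ctrl <- co$endpoints[co$endpoints$group == "control", ]
  se <- sd(ctrl$map_mmhg_baseline) / sqrt(nrow(ctrl))
  expect_lt(abs(mean(ctrl$map_mmhg_followup) - mean(ctrl$map_mmhg_baseline)), 2 * se)
})

test_that("endpoint report covers paired, between-group and postmortem comparisons", {
  co <- generate_cohort(cohort_params(), seed = 6)
  rep <- endpoint_report(co)
  expect_s3_class(rep, "endpoint_report")
  expect_true(all(rep$p >= 0 & rep$p <= 1))
  # every paired endpoint is reported for both groups plus one between-group row
  for (nm in c("map_mmhg", "lv_mass_g", "ef_pct", "sv_ml")) {
    sub <- rep[rep$endpoint == nm, ]
    expect_equal(sum(sub$comparison == "paired_within_group"), 2)
    expect_equal(sum(sub$comparison == "unpaired_between_groups_followup"), 1)
  }
  expect_true(all(c("lv_wall_mm", "septum_mm") %in% rep$endpoint))
  # star coding honors the 0.05/0.01/0.001 thresholds
  expect_true(all(rep$stars[!is.na(rep$p) & rep$p <= 0.001] == "***"))
  expect_true(all(rep$stars[rep$p > 0.05] == ""))

  # single-group cohort: between-group rows are skipped, within-group kept
  co1 <- co
  co1$endpoints <- co1$endpoints[co1$endpoints$group == "angii", ]
  rep1 <- endpoint_report(co1)
  expect_false(any(grepl("between", rep1$comparison)))
  expect_true(any(rep1$comparison == "paired_within_group"))
})

test_that("type-I error of both tests is near nominal under the null (vectorized MC)", {
  set.seed(99)
  n_rep <- 4000
  # unpaired: two groups of 8 standard normals
  a <- matrix(rnorm(8 * n_rep), nrow = 8)
  b <- matrix(rnorm(8 * n_rep), nrow = 8)
  p_un <- vapply(seq_len(n_rep), function(j) students_t_unpaired(a[, j], b[, j])$p, 0)
  rate <- mean(p_un < 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / n_rep))
  # paired: 9 paired differences under the null
  pre <- matrix(rnorm(9 * n_rep), nrow = 9)
  post <- pre + matrix(rnorm(9 * n_rep), nrow = 9)
  p_pa <- vapply(seq_len(n_rep), function(j) students_t_paired(pre[, j], post[, j])$p, 0)
  expect_lt(abs(mean(p_pa < 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / n_rep))
})
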