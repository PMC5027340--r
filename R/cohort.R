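#' Parameters of the synthetic hypertension cohort
#'
#' Defaults reproduce the published 8-week angiotensin-II sheep cohort:
#' treated group n = 9, control n = 7, with baseline mean +/- SD and
#' within-animal change (delta) models for each endpoint. Mean arterial
#' pressure (MAP) is generated weekly (weeks 0..8, week 0 = baseline):
#' the treated group rises along a normalized logistic reaching ~95% of its
#' plateau at week 3, the control group stays flat apart from its small
#' drift. Follow-up values are `baseline + delta`, with
#' `delta ~ N(delta_mean, delta_sd)` per animal, so zero effect sizes and
#' zero SDs give follow-up == baseline exactly.
#'
#' Endpoint defaults (baseline mean, baseline SD, delta mean, delta SD):
#' MAP control (89.4, 3.7, +1.1, 3.0) vs treated (87.4, 5.3, +24.4, 4.4)
#' mmHg; LV mass (109.8, 19.9, -0.2, 8.52) vs (111.2, 12.6, +20.33, 13.16)
#' g — the change SDs are the published per-animal change SDs; EF
#' (45.4, 8.8, +4.2, 7.0) vs (49.4, 10.4, -6.5, 7.0) %; stroke volume
#' (55.6, 6.7, -4.4, 8.0) vs (51.8, 12.8, -8.0, 8.0) mL; weight
#' (73.5, 5.4, +1.6, 2.5) vs (78.8, 4.5, -1.0, 2.5) kg; creatinine
#' (1.0, 0.1, +0.1, 0.08) vs (0.9, 0.1, 0.0, 0.08) mg/dL. Postmortem wall
#' thickness is a single follow-up draw: LV wall 12.14 +/- 1.57 (control)
#' vs 18.82 +/- 4.6 mm, septum 11.86 +/- 1.57 vs 17.27 +/- 2.24 mm.
#'
#' @param n_control,n_angii Animals per group (>= 1).
#' @param endpoints Named list of per-endpoint parameter matrices; rows
#'   `control`/`angii`, columns `base_mean, base_sd, delta_mean, delta_sd`.
#'   Override individual entries to change the stated world.
#' @param postmortem Named list (`lv_wall_mm`, `septum_mm`) of 2 x 2 matrices
#'   (rows control/angii, columns mean, sd).
#' @param map_weeks Weeks at which MAP is recorded (default 0:8).
#' @param map_meas_sd_mmhg Weekly MAP measurement noise SD (mmHg); small
#'   because each printed value is itself an average of five consecutive
#'   cuff readings.
#' @param logistic_k,logistic_mid Shape of the treated-group MAP rise; the
#'   defaults put 95% of the plateau at week 3.
#' @return A `cohort_params` list.
#' @export
cohort_params <- function(n_control = 7, n_angii = 9,
                          endpoints = NULL, postmortem = NULL,
                          map_weeks = 0:8, map_meas_sd_mmhg = 2.0,
                          logistic_k = log(19) / 1.5, logistic_mid = 1.5) {
  ep_default <- function(cb, ca) {
    m <- rbind(control = cb, angii = ca)
    colnames(m) <- c("base_mean", "base_sd", "delta_mean", "delta_sd")
    m
  }
  ep <- list(
    map_mmhg   = ep_default(c(89.4, 3.7, 1.1, 3.0),   c(87.4, 5.3, 24.4, 4.4)),
    lv_mass_g  = ep_default(c(109.8, 19.9, -0.2, 8.52), c(111.2, 12.6, 20.33, 13.16)),
    ef_pct     = ep_default(c(45.4, 8.8, 4.2, 7.0),   c(49.4, 10.4, -6.5, 7.0)),
    sv_ml      = ep_default(c(55.6, 6.7, -4.4, 8.0),  c(51.8, 12.8, -8.0, 8.0)),
    weight_kg  = ep_default(c(73.5, 5.4, 1.6, 2.5),   c(78.8, 4.5, -1.0, 2.5)),
    creatinine_mg_dl = ep_default(c(1.0, 0.1, 0.1, 0.08), c(0.9, 0.1, 0.0, 0.08))
  )
  if (!is.null(endpoints)) {
    endpoints <- lapply(endpoints, function(m) {
      m <- as.matrix(m)
      if (ncol(m) != 4 || nrow(m) != 2) {
        stop_invalid("endpoint override must be a 2 x 4 matrix (control/angii rows)")
      }
      colnames(m) <- c("base_mean", "base_sd", "delta_mean", "delta_sd")
      if (is.null(rownames(m))) rownames(m) <- c("control", "angii")
      m
    })
    ep[names(endpoints)] <- endpoints
  }
  pm <- list(
    lv_wall_mm = rbind(control = c(12.14, 1.57), angii = c(18.82, 4.6)),
    septum_mm  = rbind(control = c(11.86, 1.57), angii = c(17.27, 2.24))
  )
  if (!is.null(postmortem)) pm[names(postmortem)] <- postmortem

  if (n_control < 1 || n_angii < 1) stop_invalid("group sizes must be >= 1")
  for (nm in names(ep)) {
    if (any(ep[[nm]][, c("base_sd", "delta_sd")] < 0)) {
      stop_invalid("negative SD in endpoint %s", nm)
    }
  }
  if (any(vapply(pm, function(m) any(m[, 2] < 0), TRUE))) {
    stop_invalid("negative SD in postmortem parameters")
  }
  structure(list(n = c(control = n_control, angii = n_angii),
                 endpoints = ep, postmortem = pm, map_weeks = map_weeks,
                 map_meas_sd_mmhg = map_meas_sd_mmhg,
                 logistic_k = logistic_k, logistic_mid = logistic_mid),
            class = "cohort_params")
}

# normalized logistic rise: 0 at week 0, -> 1 at late weeks
logistic_rise <- function(week, k, mid) {
  s <- function(w) 1 / (1 + exp(-k * (w - mid)))
  (s(week) - s(0)) / (1 - s(0))
}

#' Generate a synthetic study cohort
#'
#' Draws per-animal endpoint trajectories from the normal models described
#' in [cohort_params()]. All randomness flows from `seed`; identical seeds
#' give identical tables.
#'
#' @param params A [cohort_params()] object.
#' @param seed Integer seed.
#' @return An object of class `cohort`: list with `endpoints` (wide
#'   data.frame: one row per animal, baseline/follow-up columns per paired
#'   endpoint plus postmortem columns) and `map` (long data.frame:
#'   `animal_id, group, week, map_mmhg`), plus the generating `params` and
#'   `seed`.
#' @export
generate_cohort <- function(params = cohort_params(), seed = 1L) {
  if (!inherits(params, "cohort_params")) stop_invalid("params must come from cohort_params()")
  set.seed(as.integer(seed))
  groups <- names(params$n)
  ep_rows <- list()
  map_rows <- list()
  for (g in groups) {
    n <- params$n[[g]]
    ids <- sprintf("%s_%02d", g, seq_len(n))
    row <- data.frame(animal_id = ids, group = g, stringsAsFactors = FALSE)
    for (nm in names(params$endpoints)) {
      p <- params$endpoints[[nm]][g, ]
      base <- stats::rnorm(n, p["base_mean"], p["base_sd"])
      delta <- if (p["delta_sd"] == 0 && p["delta_mean"] == 0) {
        numeric(n)  # exact zero effect: follow-up identical to baseline
      } else {
        stats::rnorm(n, p["delta_mean"], p["delta_sd"])
      }
      row[[paste0(nm, "_baseline")]] <- base
      row[[paste0(nm, "_followup")]] <- base + delta
      if (nm == "map_mmhg") {
        rise <- logistic_rise(params$map_weeks, params$logistic_k, params$logistic_mid)
        for (a in seq_len(n)) {
          noise <- if (params$map_meas_sd_mmhg > 0) {
            stats::rnorm(length(params$map_weeks), 0, params$map_meas_sd_mmhg)
          } else numeric(length(params$map_weeks))
          map_rows[[length(map_rows) + 1L]] <- data.frame(
            animal_id = ids[a], group = g, week = params$map_weeks,
            map_mmhg = base[a] + delta[a] * rise + noise,
            stringsAsFactors = FALSE)
        }
      }
    }
    for (nm in names(params$postmortem)) {
      p <- params$postmortem[[nm]][g, ]
      row[[nm]] <- stats::rnorm(n, p[1], p[2])
    }
    ep_rows[[g]] <- row
  }
  structure(list(endpoints = do.call(rbind, ep_rows),
                 map = do.call(rbind, map_rows),
                 params = params, seed = as.integer(seed)),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  tab <- table(x$endpoints$group)
  cat(sprintf("Synthetic cohort: %s animals (%s), weeks %s\n",
              nrow(x$endpoints),
              paste(sprintf("%s n=%d", names(tab), tab), collapse = ", "),
              paste(range(x$map$week), collapse = "..")))
  invisible(x)
}

#' Write / read a cohort as CSV
#'
#' One row per animal and week: `animal_id, group, week, map_mmhg` followed
#' by the wide endpoint columns (repeated on every week row of the animal).
#'
#' @param cohort A `cohort`.
#' @param path File path.
#' @return `read_cohort_csv` returns a `cohort` (without generator params).
#' @export
write_cohort_csv <- function(cohort, path) {
  wide <- cohort$endpoints
  merged <- merge(cohort$map, wide, by = c("animal_id", "group"), sort = FALSE)
  merged <- merged[order(merged$animal_id, merged$week), ]
  utils::write.csv(format(merged, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop_format("cohort file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "group", "week", "map_mmhg")
  if (!all(need %in% names(df))) {
    stop_format("cohort CSV missing columns: %s", toString(setdiff(need, names(df))))
  }
  map <- df[, need]
  wide_cols <- setdiff(names(df), c("week", "map_mmhg"))
  wide <- unique(df[, wide_cols])
  if (anyDuplicated(wide$animal_id)) {
    stop_format("inconsistent wide endpoint values across weeks for one animal")
  }
  structure(list(endpoints = wide, map = map, params = NULL, seed = NA_integer_),
            class = "cohort")
}
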