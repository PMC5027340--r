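#' Group summary: n, mean, sample SD
#'
#' Endpoints are reported as mean +/- standard deviation with the n-1
#' denominator. A single observation has no SD and is an error rather than
#' a silent 0.
#'
#' @param values Numeric vector, n >= 2.
#' @return List `n, mean, sd`.
#' @export
summarize_group <- function(values) {
  values <- values[!is.na(values)]
  if (!length(values)) stop_invalid("empty input: nothing to summarize")
  if (length(values) == 1) stop_invalid("n = 1: standard deviation undefined")
  list(n = length(values), mean = mean(values), sd = stats::sd(values))
}

#' Percent change between baseline and follow-up means
#'
#' `100 * (followup - baseline) / baseline`. Both the unrounded value and
#' the one-decimal display value are returned; tables print the rounded
#' one, machine outputs keep the unrounded one.
#'
#' @param baseline_mean,followup_mean Group means; baseline must be nonzero.
#' @return List `percent` (unrounded) and `display` (rounded to 1 decimal).
#' @examples
#' percent_change(111.2, 131.5)$display  # 18.3
#' @export
percent_change <- function(baseline_mean, followup_mean) {
  if (!is.numeric(baseline_mean) || baseline_mean == 0) {
    stop_invalid("baseline mean must be nonzero")
  }
  pct <- 100 * (followup_mean - baseline_mean) / baseline_mean
  list(percent = pct, display = round(pct, 1))
}

#' Student's t-tests (pooled-variance unpaired, and paired)
#'
#' `students_t_unpaired` is the classical pooled-variance Student's t with
#' `df = n_a + n_b - 2` (not Welch; the study design assumes equal
#' variances and names Student's test — Welch is available via
#' `var_equal = FALSE` and the choice is recorded in the result).
#' `students_t_paired` tests the within-animal differences with
#' `df = n - 1`. Both return two-sided p-values. Degenerate inputs are
#' handled explicitly: identical constant groups give `t = 0, p = 1`;
#' zero-variance nonzero paired differences cannot yield a finite t and are
#' reported as `p = 0` with `p_floor = TRUE`.
#'
#' @param a,b Numeric vectors (unpaired), each n >= 2.
#' @param var_equal Pooled variance (TRUE, default) or Welch.
#' @return List `t, df, p` (plus `variant` for unpaired, `p_floor` for
#'   paired).
#' @examples
#' students_t_unpaired(c(1, 2, 3), c(4, 5, 6))  # t = -3.674, df = 4
#' @export
students_t_unpaired <- function(a, b, var_equal = TRUE) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) stop_invalid("both groups need n >= 2")
  na <- length(a); nb <- length(b)
  d <- mean(a) - mean(b)
  if (var_equal) {
    sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  } else {
    va <- stats::var(a) / na; vb <- stats::var(b) / nb
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
  }
  if (se == 0) {
    # both groups constant: equal means -> t = 0, p = 1; unequal -> p floor
    if (d == 0) return(list(t = 0, df = df, p = 1, variant = if (var_equal) "student" else "welch"))
    return(list(t = sign(d) * Inf, df = df, p = 0,
                variant = if (var_equal) "student" else "welch"))
  }
  t <- d / se
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df),
       variant = if (var_equal) "student" else "welch")
}

#' @rdname students_t_unpaired
#' @param pre,post Paired numeric vectors of equal length, n >= 2.
#' @export
students_t_paired <- function(pre, post) {
  if (length(pre) != length(post)) stop_invalid("paired vectors differ in length")
  keep <- !(is.na(pre) | is.na(post))
  pre <- pre[keep]; post <- post[keep]
  if (length(pre) < 2) stop_invalid("paired test needs n >= 2 complete pairs")
  d <- post - pre
  n <- length(d)
  sd_d <- stats::sd(d)
  if (sd_d == 0) {
    if (mean(d) == 0) return(list(t = 0, df = n - 1, p = 1, p_floor = FALSE))
    return(list(t = sign(mean(d)) * Inf, df = n - 1, p = 0, p_floor = TRUE))
  }
  t <- mean(d) / (sd_d / sqrt(n))
  list(t = t, df = n - 1, p = 2 * stats::pt(-abs(t), n - 1), p_floor = FALSE)
}

star_code <- function(p) {
  if (is.na(p)) return("")
  if (p <= 0.001) return("***")
  if (p <= 0.01) return("**")
  if (p <= 0.05) return("*")
  ""
}

#' Weekly MAP trajectory summary and plateau detection
#'
#' Computes weekly group means +/- SD of mean arterial pressure and the
#' plateau week per group: the first week whose group mean reaches
#' `plateau_fraction` (default 0.95) of the mean over the final four
#' observed weeks. Missing weeks are omitted, never interpolated; a week
#' missing for a whole group is dropped with a warning.
#'
#' @param cohort A [generate_cohort()] object (or one read from CSV).
#' @param plateau_fraction Fraction of the late-plateau level that defines
#'   arrival, in `(0, 1]`.
#' @return Data.frame `group, week, n, mean_mmhg, sd_mmhg` with attribute
#'   `plateau_week` (named numeric, one entry per group).
#' @export
map_trajectory_summary <- function(cohort, plateau_fraction = 0.95) {
  if (plateau_fraction <= 0 || plateau_fraction > 1) {
    stop_invalid("plateau_fraction must lie in (0, 1]")
  }
  map <- cohort$map
  map <- map[!is.na(map$map_mmhg), ]
  if (!nrow(map)) stop_invalid("no MAP observations")
  out <- do.call(rbind, lapply(split(map, map[c("group", "week")], drop = TRUE),
    function(d) data.frame(group = d$group[1], week = d$week[1], n = nrow(d),
                           mean_mmhg = mean(d$map_mmhg),
                           sd_mmhg = if (nrow(d) > 1) stats::sd(d$map_mmhg) else NA_real_)))
  out <- out[order(out$group, out$week), ]
  rownames(out) <- NULL
  plateau <- sapply(split(out, out$group), function(d) {
    d <- d[order(d$week), ]
    late <- utils::tail(d$mean_mmhg, 4)
    target <- plateau_fraction * mean(late)
    w <- d$week[d$mean_mmhg >= target]
    if (length(w)) min(w) else NA_real_
  })
  attr(out, "plateau_week") <- plateau
  out
}

# paired endpoints present in a cohort's wide table
paired_endpoints <- function(endpoints) {
  base_cols <- grep("_baseline$", names(endpoints), value = TRUE)
  nm <- sub("_baseline$", "", base_cols)
  nm[paste0(nm, "_followup") %in% names(endpoints)]
}

#' Full endpoint comparison report
#'
#' Reproduces the study-style endpoint analysis on a cohort table. For
#' every paired endpoint (baseline and follow-up measured in the same
#' animals): within-group paired Student's t-tests, group means +/- SD,
#' mean differences and percent changes; plus the unpaired between-group
#' Student's t-test at follow-up. Postmortem single-timepoint endpoints
#' (wall thicknesses) get the between-group comparison only. P-values are
#' unadjusted (no multiple-testing correction, by design) and star-coded
#' at 0.05 / 0.01 / 0.001. An endpoint absent for a whole group is skipped
#' with a logged reason.
#'
#' @param cohort A [generate_cohort()] object or one from
#'   [read_cohort_csv()].
#' @param var_equal Passed to [students_t_unpaired()].
#' @return Data.frame of class `endpoint_report`, one row per comparison:
#'   `endpoint, comparison, group, n, baseline_mean, baseline_sd,
#'   followup_mean, followup_sd, mean_diff, pct_change, t, df, p, stars`.
#' @export
endpoint_report <- function(cohort, var_equal = TRUE) {
  ep <- cohort$endpoints
  groups <- sort(unique(ep$group))  # deterministic regardless of row order
  rows <- list()
  add <- function(...) rows[[length(rows) + 1L]] <<- data.frame(..., stringsAsFactors = FALSE)

  for (nm in paired_endpoints(ep)) {
    bcol <- paste0(nm, "_baseline"); fcol <- paste0(nm, "_followup")
    for (g in groups) {
      sub <- ep[ep$group == g, ]
      b <- sub[[bcol]]; f <- sub[[fcol]]
      if (all(is.na(b)) || all(is.na(f)) || sum(!is.na(b) & !is.na(f)) < 2) {
        log_msg("WARN", "endpoint %s skipped for group %s: insufficient paired data", nm, g)
        next
      }
      tt <- students_t_paired(b, f)
      sb <- summarize_group(b); sf <- summarize_group(f)
      add(endpoint = nm, comparison = "paired_within_group", group = g,
          n = sb$n, baseline_mean = sb$mean, baseline_sd = sb$sd,
          followup_mean = sf$mean, followup_sd = sf$sd,
          mean_diff = sf$mean - sb$mean,
          pct_change = percent_change(sb$mean, sf$mean)$percent,
          t = tt$t, df = tt$df, p = tt$p, stars = star_code(tt$p))
    }
    if (length(groups) >= 2) {
      ga <- ep[[fcol]][ep$group == groups[1]]
      gb <- ep[[fcol]][ep$group == groups[2]]
      if (sum(!is.na(ga)) >= 2 && sum(!is.na(gb)) >= 2) {
        tt <- students_t_unpaired(ga, gb, var_equal = var_equal)
        sa <- summarize_group(ga); sb2 <- summarize_group(gb)
        add(endpoint = nm, comparison = "unpaired_between_groups_followup",
            group = paste(groups[1], "vs", groups[2]),
            n = sa$n + sb2$n, baseline_mean = NA_real_, baseline_sd = NA_real_,
            followup_mean = NA_real_, followup_sd = NA_real_,
            mean_diff = sa$mean - sb2$mean,
            pct_change = NA_real_,
            t = tt$t, df = tt$df, p = tt$p, stars = star_code(tt$p))
      }
    } else {
      log_msg("INFO", "single-group cohort: between-group comparison skipped for %s", nm)
    }
  }

  for (nm in intersect(c("lv_wall_mm", "septum_mm"), names(ep))) {
    if (length(groups) < 2) break
    ga <- ep[[nm]][ep$group == groups[1]]
    gb <- ep[[nm]][ep$group == groups[2]]
    if (sum(!is.na(ga)) < 2 || sum(!is.na(gb)) < 2) {
      log_msg("WARN", "postmortem endpoint %s skipped: insufficient data", nm)
      next
    }
    tt <- students_t_unpaired(ga, gb, var_equal = var_equal)
    sa <- summarize_group(ga); sb2 <- summarize_group(gb)
    add(endpoint = nm, comparison = "unpaired_between_groups",
        group = paste(groups[1], "vs", groups[2]),
        n = sa$n + sb2$n,
        baseline_mean = sa$mean, baseline_sd = sa$sd,
        followup_mean = sb2$mean, followup_sd = sb2$sd,
        mean_diff = sb2$mean - sa$mean,
        pct_change = percent_change(sa$mean, sb2$mean)$percent,
        t = tt$t, df = tt$df, p = tt$p, stars = star_code(tt$p))
  }

  if (!length(rows)) stop_analysis("no endpoint could be analyzed")
  res <- do.call(rbind, rows)
  class(res) <- c("endpoint_report", "data.frame")
  attr(res, "pairing") <- "baseline-vs-follow-up treated as paired within group"
  attr(res, "p_adjustment") <- "none (unadjusted)"
  attr(res, "t_variant") <- if (var_equal) "student_pooled" else "welch"
  res
}

#' Write an endpoint report as TSV and JSON
#'
#' @param report An [endpoint_report()].
#' @param tsv_path,json_path Output paths (`NULL` to skip one format).
#' @export
write_endpoint_report <- function(report, tsv_path = NULL, json_path = NULL) {
  if (!is.null(tsv_path)) {
    utils::write.table(as.data.frame(report), tsv_path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  if (!is.null(json_path)) {
    meta <- list(pairing = attr(report, "pairing"),
                 p_adjustment = attr(report, "p_adjustment"),
                 t_variant = attr(report, "t_variant"))
    jsonlite::write_json(list(metadata = meta, records = as.data.frame(report)),
                         json_path, auto_unbox = TRUE, digits = NA, na = "null",
                         pretty = TRUE)
  }
  invisible(report)
}
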