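#' Construct a per-fly activity trace
#'
#' Minute-binned beam-crossing counts for one fly, with the light schedule
#' and optional genotype/sex labels.  Trace length must be a whole number of
#' days (1440-minute blocks); with `pad = TRUE` a partial final day is
#' dropped.
#'
#' @param fly_id identifier.
#' @param counts non-negative integer counts, one per minute, starting at
#'   midnight of day 1.
#' @param lights_on,lights_off schedule in minutes after midnight
#'   (defaults 480 and 1200: lights on 08:00, off 20:00).
#' @param genotype,sex optional labels.
#' @param pad drop a trailing partial day instead of erroring.
#' @return A list of class `activity_trace`.
#' @export
activity_trace <- function(fly_id, counts, lights_on = 480, lights_off = 1200,
                           genotype = NA, sex = NA, pad = FALSE) {
  counts <- as.numeric(counts)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop_field("counts", "must be non-negative integers")
  if (length(counts) %% 1440L != 0L) {
    if (pad) counts <- counts[seq_len(1440L * (length(counts) %/% 1440L))]
    else stop_field("counts", "length must be a multiple of 1440 minutes")
  }
  if (!length(counts)) stop_field("counts", "trace shorter than one day")
  assert_scalar_num(lights_on, "lights_on", lower = 0, upper = 1440)
  assert_scalar_num(lights_off, "lights_off", lower = 0, upper = 1440)
  structure(list(fly_id = as.character(fly_id), counts = as.integer(counts),
                 schedule = list(lights_on = lights_on,
                                 lights_off = lights_off),
                 genotype = genotype, sex = sex),
            class = "activity_trace")
}

#' @export
print.activity_trace <- function(x, ...) {
  cat(sprintf("activity_trace %s: %d days, %d total beam crossings\n",
              x$fly_id, length(x$counts) / 1440L, sum(x$counts)))
  invisible(x)
}

daily_totals <- function(trace) {
  colSums(matrix(trace$counts, nrow = 1440L))
}

#' Remove dead flies from a set of traces
#'
#' A fly is considered dead when any full day of its recording has strictly
#' fewer than `min_daily` beam crossings.
#'
#' @param traces list of `activity_trace` objects.
#' @param min_daily daily count threshold (default 50; strict `<`).
#' @return A list: `kept` (traces), `removed` (fly ids).
#' @export
filter_dead <- function(traces, min_daily = 50) {
  dead <- vapply(traces, function(tr) any(daily_totals(tr) < min_daily),
                 logical(1))
  list(kept = traces[!dead],
       removed = vapply(traces[dead], function(tr) tr$fly_id, character(1),
                        USE.NAMES = FALSE))
}

# maximal runs of >= min_run consecutive zero minutes; returns start/length
zero_runs <- function(counts, min_run = 5L) {
  r <- rle(counts == 0)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sel <- r$values & r$lengths >= min_run
  data.frame(start = starts[sel], length = r$lengths[sel])
}

#' Detect sleep from an activity trace
#'
#' Any maximal run of at least 5 consecutive zero-count minutes is a sleep
#' bout; minutes inside such runs are sleep minutes.  Day/night sleep is
#' split by the light schedule, with a bout spanning a transition split at
#' the boundary.
#'
#' @param trace an `activity_trace`.
#' @param min_run minimum inactivity run length in minutes (default 5).
#' @return A list of class `sleep_summary`: `fly_id`, `total_sleep_min`,
#'   `day_sleep_min`, `night_sleep_min`, `bout_count`, `mean_bout_min`
#'   (`NA` when no bouts).
#' @export
detect_sleep <- function(trace, min_run = 5L) {
  stopifnot(inherits(trace, "activity_trace"))
  runs <- zero_runs(trace$counts, min_run)
  asleep <- rep(FALSE, length(trace$counts))
  for (i in seq_len(nrow(runs)))
    asleep[seq.int(runs$start[i], length.out = runs$length[i])] <- TRUE
  minute_of_day <- (seq_along(trace$counts) - 1L) %% 1440L
  is_day <- minute_of_day >= trace$schedule$lights_on &
    minute_of_day < trace$schedule$lights_off
  structure(list(fly_id = trace$fly_id,
                 total_sleep_min = sum(asleep),
                 day_sleep_min = sum(asleep & is_day),
                 night_sleep_min = sum(asleep & !is_day),
                 bout_count = nrow(runs),
                 mean_bout_min = if (nrow(runs)) mean(runs$length) else NA_real_),
            class = "sleep_summary")
}

#' Chi-square (Sokolove-Bushell) periodogram
#'
#' For each candidate period P (on a grid in hours, evaluated at minute
#' resolution), the trace is folded into P bins over the K complete cycles
#' it contains (a partial final cycle is dropped) and the statistic
#' \deqn{Q_P = K \sum_h (M_h - M)^2 / s^2}
#' is computed, where `M_h` are the bin means, `M` the grand mean and `s^2`
#' the overall variance of the points used.  Under the null of no rhythm,
#' `Q_P` is approximately chi-square with P - 1 degrees of freedom; the
#' significance line is the corresponding upper-`alpha` quantile.  The peak
#' period is the grid period maximizing `Q_P` among periods reaching the
#' significance line, and a trace is called rhythmic when the best
#' `Q_P / Q_sig` ratio is at least 1.
#'
#' @param trace an `activity_trace`.
#' @param range_h period testing range in hours (default 18-30).
#' @param step_h grid resolution in hours (default 0.2).
#' @param alpha significance level for the chi-square line (default 0.05).
#' @return A list of class `periodogram_result`: `fly_id`, `periods_h`,
#'   `Qp`, `Qp_sig`, `peak_period_h` (`NA` when no period is significant),
#'   `rhythmicity_ratio` (max Qp/Qp_sig), `rhythmic`.
#' @export
chisq_periodogram <- function(trace, range_h = c(18, 30), step_h = 0.2,
                              alpha = 0.05) {
  stopifnot(inherits(trace, "activity_trace"))
  periods_h <- seq(range_h[1], range_h[2], by = step_h)
  periods_min <- round(periods_h * 60)
  n <- length(trace$counts)
  if (n < 2 * max(periods_min))
    stop_field("trace", sprintf(
      "trace too short: need >= %d minutes (2 x the longest test period)",
      2 * max(periods_min)))
  x <- as.numeric(trace$counts)
  qp <- vapply(periods_min, function(P) {
    K <- n %/% P
    used <- x[seq_len(K * P)]
    m <- mean(used)
    s2 <- mean((used - m)^2)
    if (s2 == 0) return(0)
    bins <- rowMeans(matrix(used, nrow = P))
    K * sum((bins - m)^2) / s2
  }, numeric(1))
  qsig <- qchisq(1 - alpha, df = periods_min - 1)
  ratio <- qp / qsig
  sig <- which(qp >= qsig)
  peak <- if (length(sig)) periods_h[sig[which.max(qp[sig])]] else NA_real_
  structure(list(fly_id = trace$fly_id, periods_h = periods_h, Qp = qp,
                 Qp_sig = qsig, peak_period_h = peak,
                 rhythmicity_ratio = max(ratio),
                 rhythmic = max(ratio) >= 1),
            class = "periodogram_result")
}

#' Per-group activity, sleep and period summaries
#'
#' Aggregates per-fly summaries by grouping keys (typically genotype and
#' sex).  Flies failing the rhythmicity criterion are excluded from the
#' period statistics and counted.
#'
#' @param flies data.frame with one row per fly: grouping columns plus any
#'   of `activity` (e.g. mean daily counts), `total_sleep_min`, `period_h`,
#'   `rhythmic` (logical; defaults to TRUE when absent).
#' @param group_keys character vector of grouping column names.
#' @return data.frame with one row per group: `n_flies`, mean/median/sd of
#'   each present measure, `n_rhythmic`, `n_arrhythmic_excluded`, and period
#'   statistics over rhythmic flies only.
#' @export
group_summaries <- function(flies, group_keys = c("genotype", "sex")) {
  stopifnot(all(group_keys %in% names(flies)))
  if (!nrow(flies)) stop_field("flies", "no flies to summarize")
  key <- interaction(flies[group_keys], drop = TRUE, lex.order = TRUE)
  rows <- lapply(split(flies, key), function(d) {
    out <- d[1, group_keys, drop = FALSE]
    out$n_flies <- nrow(d)
    for (m in intersect(c("activity", "total_sleep_min", "day_sleep_min",
                          "night_sleep_min"), names(d))) {
      out[[paste0(m, "_mean")]] <- mean(d[[m]])
      out[[paste0(m, "_median")]] <- median(d[[m]])
      out[[paste0(m, "_sd")]] <- sd(d[[m]])
    }
    rhythmic <- if (!is.null(d$rhythmic)) d$rhythmic else rep(TRUE, nrow(d))
    out$n_rhythmic <- sum(rhythmic)
    out$n_arrhythmic_excluded <- sum(!rhythmic)
    if (!is.null(d$period_h)) {
      p <- d$period_h[rhythmic]
      out$period_mean <- if (length(p)) mean(p) else NA_real_
      out$period_median <- if (length(p)) median(p) else NA_real_
      out$period_sd <- if (length(p) > 1) sd(p) else NA_real_
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Trim acclimation days from a trace
#'
#' @param trace an `activity_trace`.
#' @param drop_days full days removed from the start (e.g. 5 acclimation
#'   days of a light-dark assay); a `day_range` of the form `c(first, last)`
#'   may be given instead to take a day window (1-based, inclusive).
#' @param day_range optional inclusive day window.
#' @return The trimmed `activity_trace`.
#' @export
trim_days <- function(trace, drop_days = 0, day_range = NULL) {
  stopifnot(inherits(trace, "activity_trace"))
  n_days <- length(trace$counts) %/% 1440L
  if (is.null(day_range)) day_range <- c(drop_days + 1L, n_days)
  if (day_range[1] < 1 || day_range[2] > n_days || day_range[1] > day_range[2])
    stop_field("day_range", sprintf("must lie within 1..%d", n_days))
  idx <- seq.int((day_range[1] - 1L) * 1440L + 1L, day_range[2] * 1440L)
  activity_trace(trace$fly_id, trace$counts[idx],
                 lights_on = trace$schedule$lights_on,
                 lights_off = trace$schedule$lights_off,
                 genotype = trace$genotype, sex = trace$sex)
}
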