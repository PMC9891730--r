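test_that("dead-fly filtering uses a strict daily threshold", {
  mk <- function(id, day_totals) {
    counts <- unlist(lapply(day_totals, function(tt) {
      x <- integer(1440)
      if (tt > 0) x[seq_len(tt)] <- 1L
      x
    }))
    activity_trace(id, counts)
  }
  traces <- list(mk("a", c(100, 49)), mk("b", c(50, 50)), mk("c", c(300, 300)))
  flt <- filter_dead(traces)
  expect_equal(flt$removed, "a")
  expect_setequal(vapply(flt$kept, `[[`, "", "fly_id"), c("b", "c"))
})

test_that("sleep detection follows the 5-minute rule on hand cases", {
  pad <- function(x) activity_trace("f", c(x, rep(1L, 1440 - length(x))))
  s1 <- detect_sleep(pad(c(1, 0, 0, 0, 0, 0, 1)))
  expect_equal(s1$total_sleep_min, 5)
  expect_equal(s1$bout_count, 1)
  s2 <- detect_sleep(pad(c(1, 0, 0, 0, 0, 1)))
  expect_equal(s2$total_sleep_min, 0)
  expect_equal(s2$bout_count, 0)
  s3 <- detect_sleep(activity_trace("f", integer(1440)))
  expect_equal(s3$total_sleep_min, 1440)
  expect_equal(s3$bout_count, 1)
  expect_equal(s3$mean_bout_min, 1440)
})

test_that("sleep detection equals the brute-force window scan on random traces", {
  set.seed(110)
  for (i in 1:200) {
    counts <- rbinom(1440, 1, runif(1, 0.1, 0.9))
    tr <- activity_trace("f", counts)
    got <- detect_sleep(tr)
    want <- naive_sleep(counts)
    expect_equal(got$total_sleep_min, want$total)
    expect_equal(got$bout_count, want$bouts)
    if (want$bouts > 0) expect_gte(got$mean_bout_min, 5)
  }
})

test_that("day and night sleep split at the light transitions", {
  counts <- rep(1L, 1440)
  # a bout spanning lights-off (minute 1200): 1190..1209 inclusive
  counts[1191:1210] <- 0L
  s <- detect_sleep(activity_trace("f", counts))
  expect_equal(s$total_sleep_min, 20)
  expect_equal(s$day_sleep_min, 10)
  expect_equal(s$night_sleep_min, 10)
  expect_equal(s$day_sleep_min + s$night_sleep_min, s$total_sleep_min)
})

test_that("periodogram recovers planted periods and rejects flat traces", {
  sq <- activity_trace("sq", rep(c(rep(10L, 720), rep(0L, 720)), 10))
  pg <- chisq_periodogram(sq)
  expect_equal(pg$peak_period_h, 24)
  expect_true(pg$rhythmic)
  expect_equal(pg$periods_h, seq(18, 30, by = 0.2))
  # scale invariance of the peak
  sq3 <- activity_trace("sq3", 3L * sq$counts)
  expect_equal(chisq_periodogram(sq3)$peak_period_h, 24)
  # constant nonzero activity is arrhythmic
  ct <- chisq_periodogram(activity_trace("c", rep(3L, 14400)))
  expect_false(ct$rhythmic)
  # too-short trace errors with the minimum
  expect_error(chisq_periodogram(activity_trace("s", rep(1L, 1440))),
               "too short")
})

test_that("noisy planted periods are recovered within one grid step", {
  hits <- vapply(1:20, function(s) {
    tr <- simulate_activity(sim_activity_spec(n_flies = 1, n_days = 10,
                                              period_h = 22.8, amplitude = 1,
                                              baseline_rate = 2,
                                              seed = 300 + s))[[1]]
    abs(chisq_periodogram(tr)$peak_period_h - 22.8) <= 0.2 + 1e-9
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("group summaries aggregate periods over rhythmic flies only", {
  flies <- data.frame(genotype = "exp", sex = c("male", "male", "male"),
                      period_h = c(22.8, 23.0, 30),
                      rhythmic = c(TRUE, TRUE, FALSE),
                      activity = c(100, 120, 10))
  g <- group_summaries(flies)
  expect_equal(g$period_mean, 22.9)
  expect_equal(g$n_arrhythmic_excluded, 1)
  expect_equal(g$n_flies, 3)
  expect_equal(g$activity_mean, mean(c(100, 120, 10)))
  expect_error(group_summaries(flies[0, ]), "no flies")
})

test_that("activity CSV and monitor files round-trip into traces", {
  spec <- sim_activity_spec(n_flies = 3, n_days = 2, seed = 7)
  traces <- simulate_activity(spec)
  dir <- withr::local_tempdir()
  csv <- file.path(dir, "act.csv"); sch <- file.path(dir, "sched.json")
  write_activity_csv(traces, csv, sch)
  back <- read_activity_csv(csv, sch)
  expect_equal(lapply(back, `[[`, "counts"),
               lapply(traces, `[[`, "counts")[names(back)])
  expect_equal(back[[1]]$schedule$lights_on, 480)
  # monitor-style file: 10 meta columns then 32 channels
  n_min <- 2 * 1440
  chan <- matrix(rpois(n_min * 32, 1), n_min, 32)
  meta <- matrix("x", n_min, 10)
  write.table(cbind(meta, chan), file.path(dir, "Monitor1.txt"),
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  mon <- read_dam_monitor(file.path(dir, "Monitor1.txt"))
  expect_length(mon, 32)
  expect_equal(mon[[5]]$counts, chan[, 5])
  # day trimming
  tr <- trim_days(mon[[1]], drop_days = 1)
  expect_length(tr$counts, 1440)
  expect_equal(tr$counts, mon[[1]]$counts[1441:2880])
})
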