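test_that("cleansing normalizes verbose sex codes, drops the rest, and is idempotent", {
  df <- data.frame(patient_id = sprintf("P%d", 1:6),
                   sex = c("men", "women", "M", "F", "", "unicorn"))
  res <- cleanse(df)
  expect_equal(res$table$sex, c("M", "F", "M", "F"))
  expect_equal(res$report$dropped_missing_sex, 1L)
  expect_equal(res$report$dropped_unknown_sex, 1L)
  again <- cleanse(res$table)
  expect_identical(as.data.frame(again$table), as.data.frame(res$table))
})

test_that("cleansing drop counts match a brute-force scan", {
  set.seed(4)
  df <- random_event_table(100)
  df$sex[sample.int(100, 7)] <- ""
  res <- cleanse(df)
  expect_equal(nrow(res$table), 93L)
  expect_equal(res$report$dropped_missing_sex, sum(df$sex == ""))
})

test_that("deduplication keeps the last-loaded row per key and matches the oracle", {
  clean <- data.frame(patient_id = c("A", "B"), visit_date = "2024-01-01",
                      dx_code = c("J06.9", "K29.7"), visit_type = "outpatient")
  expect_identical(as.data.frame(deduplicate(clean)), clean)

  dup <- data.frame(patient_id = "A", visit_date = "2024-01-01", dx_code = "J06.9",
                    visit_type = c("outpatient", "inpatient"))
  kept <- deduplicate(dup)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$visit_type, "inpatient")

  for (s in 1:5) {
    set.seed(s)
    df <- random_event_table(1000, n_patients = 12, n_codes = 4, n_days = 20)
    expect_identical(as.data.frame(deduplicate(df)), brute_dedup(df))
  }
})

test_that("episode segmentation handles the canonical hand-worked cases", {
  one <- data.frame(patient_id = "P1", visit_date = "2024-03-05",
                    department = "IM", is_primary = TRUE)
  ep <- segment_episodes(one)
  expect_equal(nrow(ep), 1L)
  expect_equal(ep$duration_days, 0L)
  expect_equal(ep$event_count, 1L)

  # days 0, 10, 200 in one department with gap 30 -> {0,10} and {200}
  gaps <- data.frame(patient_id = "P1",
                     visit_date = format(as.Date("2024-01-01") + c(0, 10, 200), "%Y-%m-%d"),
                     department = "IM", is_primary = FALSE)
  ep <- segment_episodes(gaps, gap_days = 30)
  expect_equal(nrow(ep), 2L)
  expect_equal(sort(ep$event_count), c(1L, 2L))
  expect_equal(sort(ep$duration_days), c(0L, 10L))

  # department change on consecutive days: A,A,B -> two episodes
  dep <- data.frame(patient_id = "P1",
                    visit_date = format(as.Date("2024-01-01") + 0:2, "%Y-%m-%d"),
                    department = c("A", "A", "B"), is_primary = c(FALSE, TRUE, FALSE))
  ep <- segment_episodes(dep, gap_days = 30)
  expect_equal(nrow(ep), 2L)
  expect_equal(ep$event_count[ep$department == "A"], 2L)
  expect_true(ep$has_primary_dx[ep$department == "A"])
  expect_false(ep$has_primary_dx[ep$department == "B"])

  expect_error(segment_episodes(one, gap_days = 0), "positive")
})

test_that("episodes partition each patient's events and match the walk oracle", {
  for (s in 1:6) {
    set.seed(s)
    df <- brute_dedup(random_event_table(200, n_patients = 6, n_days = 300))
    ep <- segment_episodes(df, gap_days = 30)
    # partition: per-patient event counts are conserved
    got <- tapply(ep$event_count, ep$patient_id, sum)
    want <- table(df$patient_id)
    expect_equal(as.integer(got[names(want)]), as.integer(want))
    # full summary equality against the event-walk oracle
    oracle <- brute_episodes(df, gap_days = 30)
    a <- ep[order(ep$patient_id, ep$start_date, ep$department), ]
    b <- oracle[order(oracle$patient_id, oracle$start_date, oracle$department), ]
    expect_equal(a$event_count, b$event_count)
    expect_equal(a$duration_days, b$duration_days)
    expect_equal(a$has_primary_dx, b$has_primary_dx)
  }
})

test_that("rolling features agree with hand counts and the pairwise oracle", {
  one <- data.frame(patient_id = "P1", visit_date = "2024-05-01", dx_code = "J06.9")
  rf <- rolling_features(one)
  expect_equal(rf$roll_dx_count, 1L)
  expect_equal(rf$roll_code_diversity, 1L)

  # events at days 0, 50, 100 with distinct codes: at day 100 the window
  # [11, 100] holds days 50 and 100
  tri <- data.frame(patient_id = "P1",
                    visit_date = format(as.Date("2024-01-01") + c(0, 50, 100), "%Y-%m-%d"),
                    dx_code = c("A01.1", "B02.2", "C03.3"))
  rf <- rolling_features(tri, window_days = 90)
  expect_equal(rf$roll_dx_count, c(1L, 2L, 2L))
  expect_equal(rf$roll_code_diversity, c(1L, 2L, 2L))

  expect_error(rolling_features(one, window_days = -1), "positive")

  for (s in 1:4) {
    set.seed(s)
    df <- brute_dedup(random_event_table(500, n_patients = 10, n_days = 250))
    rf <- rolling_features(df, window_days = 90)
    oracle <- brute_rolling(as.data.frame(rf)[, c("patient_id", "visit_date", "dx_code")],
                            window_days = 90)
    expect_equal(rf$roll_dx_count, oracle$cnt)
    expect_equal(rf$roll_code_diversity, oracle$div)
    expect_true(all(rf$roll_code_diversity <= rf$roll_dx_count))
    expect_true(all(rf$roll_code_diversity >= 1))
  }
})

test_that("monthly aggregates match the quantile oracle and skip empty months", {
  single <- data.frame(patient_id = "P1", visit_date = "2024-03-07",
                       dx_code = "J06.9", is_primary = TRUE)
  ma <- monthly_aggregates(single)
  expect_equal(ma$patient_count, 1L)
  expect_equal(ma$p50, 1)
  expect_equal(ma$p90, 1)

  # per-patient counts {1, 1, 2, 4}: p50/p90 by sort-and-interpolate
  df <- data.frame(
    patient_id = c("A", "B", "C", "C", "D", "D", "D", "D"),
    visit_date = sprintf("2024-06-%02d", c(1, 2, 3, 4, 5, 6, 7, 8)),
    dx_code = sprintf("C%02d.0", 1:8), is_primary = FALSE
  )
  ma <- monthly_aggregates(df)
  counts <- sort(c(1, 1, 2, 4))
  interp <- function(q) {
    h <- (length(counts) - 1) * q + 1
    lo <- floor(h)
    counts[lo] + (h - lo) * (counts[min(lo + 1, length(counts))] - counts[lo])
  }
  expect_equal(ma$p50, interp(0.5))
  expect_equal(ma$p90, interp(0.9))
  expect_equal(ma$distinct_code_count, 8)

  # a gap between months never produces zero-filled rows
  gap <- data.frame(patient_id = "P1",
                    visit_date = c("2024-01-15", "2024-04-15"),
                    dx_code = "J06.9", is_primary = FALSE)
  expect_equal(monthly_aggregates(gap)$month, c("2024-01", "2024-04"))
})

test_that("target extraction respects exact codes and prefix ranges", {
  df <- data.frame(
    patient_id = c("A", "A", "B", "C", "D"),
    visit_date = sprintf("2024-02-%02d", 1:5),
    dx_code = c("E11.9", "E15", "I10.9", "I10.0", "M48.06"),
    is_primary = FALSE
  )
  out <- extract_targets(df, c(hypertension = "I10.9", diabetes = "E10-E14",
                               spine = "M48.06"))
  expect_equal(out$diabetes$patient_id, "A")
  expect_equal(out$diabetes$event_count, 1L)  # E15 is outside the range
  expect_equal(out$hypertension$patient_id, "B")  # I10.0 is not I10.9
  expect_equal(out$spine$patient_id, "D")
  expect_equal(out$hypertension$first_date, "2024-02-03")
  expect_error(extract_targets(df, c("E14-E10")), "lower bound")
})
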