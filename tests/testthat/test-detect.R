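test_that("gap tolerance controls episode splitting", {
  cfg <- detection_config()
  one <- segment_episodes(mk_ir(c(0, 10), "A", "B"), cfg)
  expect_equal(nrow(one), 1)
  expect_equal(one$duration_min, (10 + cfg$ir_tick_s) / 60)
  two <- segment_episodes(mk_ir(c(0, 120), "A", "B"), cfg)
  expect_equal(nrow(two), 2)
  merged <- segment_episodes(mk_ir(c(0, 60), "A", "B"), cfg) # gap == tolerance
  expect_equal(nrow(merged), 1)
})

test_that("self-observations are skipped with a warning", {
  ir <- mk_ir(c(0, 10, 20), c("A", "A", "A"), c("B", "A", "B"))
  expect_warning(eps <- segment_episodes(ir), "self-observation")
  expect_equal(nrow(eps), 1)
  expect_equal(eps$n_detections, 2)
})

test_that("segmentation equals the brute-force oracle on random streams", {
  set.seed(42)
  badges <- sprintf("b%02d", 1:6)
  for (rep in 1:3) {
    n <- 500
    ir <- mk_ir(sort(sample(0:5000, n, replace = TRUE)),
                sample(badges, n, replace = TRUE),
                sample(badges, n, replace = TRUE))
    ir <- ir[ir$observer_badge != ir$observed_badge, ]
    got <- segment_episodes(ir, detection_config())
    want <- bf_segment(ir, 60, 10)
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$badge_a, want$badge_a)
    expect_equal(as.numeric(got$start), want$start)
    expect_equal(as.numeric(got$end), want$end)
    expect_equal(got$n_detections, want$n)
  }
})

test_that("outputs are invariant to swapping observer and observed", {
  set.seed(7)
  ir <- mk_ir(sort(sample(0:2000, 200, replace = TRUE)),
              sample(c("A", "B", "C"), 200, replace = TRUE),
              sample(c("A", "B", "C"), 200, replace = TRUE))
  ir <- ir[ir$observer_badge != ir$observed_badge, ]
  swapped <- data.frame(timestamp = ir$timestamp,
                        observer_badge = ir$observed_badge,
                        observed_badge = ir$observer_badge)
  expect_equal(segment_episodes(ir), segment_episodes(swapped))
})

test_that("motion means average samples inside the episode window", {
  eps <- segment_episodes(mk_ir(c(0, 60, 110), "A", "B"))  # [0, 120) seconds
  accel <- mk_accel(c(10, 70, 130, 50), c("A", "A", "A", "B"),
                    c(2.0, 3.0, 9.0, 1.5))
  got <- attach_motion(eps, accel)
  expect_equal(got$motion_a_hz, 2.5)   # the 130 s sample is outside [0,120)
  expect_equal(got$motion_b_hz, 1.5)
  expect_false(got$motion_missing_a)
})

test_that("participants without samples get mean zero and a flag", {
  eps <- segment_episodes(mk_ir(c(0, 60), "A", "B"))
  got <- attach_motion(eps, mk_accel(10, "A", 2.2))
  expect_equal(got$motion_b_hz, 0)
  expect_true(got$motion_missing_b)
  expect_false(got$motion_missing_a)
})

test_that("motion means match brute-force filtering on random streams", {
  set.seed(13)
  ir <- mk_ir(sort(sample(0:3000, 300, replace = TRUE)),
              sample(c("A", "B", "C", "D"), 300, replace = TRUE),
              sample(c("A", "B", "C", "D"), 300, replace = TRUE))
  ir <- ir[ir$observer_badge != ir$observed_badge, ]
  accel <- mk_accel(sample(0:3200, 400, replace = TRUE),
                    sample(c("A", "B", "C", "D"), 400, replace = TRUE),
                    round(runif(400, 0, 4), 2))
  accel <- accel[order(accel$timestamp), ]
  eps <- attach_motion(segment_episodes(ir), accel)
  for (i in seq_len(nrow(eps))) {
    for (side in c("a", "b")) {
      badge <- eps[[paste0("badge_", side)]][i]
      sel <- accel$badge_id == badge &
        accel$timestamp >= eps$start[i] & accel$timestamp < eps$end[i]
      want <- if (any(sel)) mean(accel$motion_hz[sel]) else 0
      expect_equal(eps[[paste0("motion_", side, "_hz")]][i], want)
    }
  }
})

test_that("the active rule applies strict duration and motion gates", {
  t0 <- as.POSIXct("2019-10-01", tz = "UTC")
  eps <- data.frame(
    badge_a = "A", badge_b = "B",
    start = t0, end = t0 + c(90, 90, 45, 60, 90) ,
    duration_min = c(1.5, 1.5, 0.75, 1.0, 1.5),
    n_detections = 5L,
    motion_a_hz = c(2.5, 1.5, 3.0, 3.0, 2.0),
    motion_b_hz = c(1.0, 1.9, 3.0, 3.0, 2.0))
  act <- classify_active(eps, detection_config(), keep_all = TRUE)
  expect_equal(act$active, c(TRUE, FALSE, FALSE, FALSE, FALSE))
  # motion rules: either uses the max, both the min, mean the average
  expect_equal(classify_active(eps, detection_config(motion_rule = "both"),
                               keep_all = TRUE)$active[1], FALSE)
  eps2 <- eps[1, ]; eps2$motion_b_hz <- 2.1
  expect_equal(classify_active(eps2, detection_config(motion_rule = "both"),
                               keep_all = TRUE)$active, TRUE)
})

test_that("raising either gate never adds interactions", {
  set.seed(99)
  t0 <- as.POSIXct("2019-10-01", tz = "UTC")
  eps <- data.frame(
    badge_a = "A", badge_b = sprintf("B%02d", 1:60),
    start = t0, end = t0 + runif(60, 30, 300),
    motion_a_hz = runif(60, 0, 4), motion_b_hz = runif(60, 0, 4))
  eps$duration_min <- as.numeric(eps$end - eps$start, units = "mins")
  base <- classify_active(eps, detection_config())
  stricter_motion <- classify_active(eps, detection_config(motion_threshold_hz = 2.8))
  stricter_dur <- classify_active(eps, detection_config(min_duration_min = 2.5))
  key <- function(x) paste(x$badge_a, x$badge_b)
  expect_true(all(key(stricter_motion) %in% key(base)))
  expect_true(all(key(stricter_dur) %in% key(base)))
})

test_that("intensity series conserves minutes and bins by overlap", {
  t0 <- as.POSIXct("2019-10-01", tz = "UTC")
  win <- c(t0, t0 + 86400)
  none <- intensity_series(mk_interactions(character(0), character(0),
                                           numeric(0), numeric(0)),
                           60, window = win)
  expect_equal(sum(none$pair_minutes), 0)
  expect_equal(nrow(none), 24)

  one <- intensity_series(mk_interactions("A", "B", 600, 10), 60, window = win)
  expect_equal(one$pair_minutes[1], 10)
  expect_equal(sum(one$pair_minutes), 10)

  straddle <- intensity_series(mk_interactions("A", "B", 3480, 4), 60,
                               window = win)
  expect_equal(straddle$pair_minutes[1:2], c(2, 2))

  set.seed(31)
  rand <- mk_interactions(rep("A", 80), sprintf("B%02d", 1:80),
                          runif(80, 0, 86000), runif(80, 0.5, 40))
  rand$end <- pmin(rand$end, win[2])
  rand$duration_min <- as.numeric(rand$end - rand$start, units = "mins")
  ser <- intensity_series(rand, 30, window = win)
  expect_equal(sum(ser$pair_minutes), sum(rand$duration_min),
               tolerance = 1e-9)
  expect_error(intensity_series(rand, 7, window = win), "divide 1440")
})

test_that("daily profile averages across days and finds circular peaks", {
  t0 <- as.POSIXct("2019-10-01", tz = "UTC")
  win <- c(t0, t0 + 2 * 86400)
  ints <- mk_interactions(rep("A", 4), rep("B", 4),
                          c(0, 86400, 8 * 3600, 16 * 3600 + 86400),
                          c(10, 20, 6, 8))
  ser <- intensity_series(ints, 60, window = win)
  prof <- daily_profile(ser)
  expect_equal(length(prof), 24)
  expect_equal(unname(prof[1]), 15)  # (10 + 20) / 2 days
  expect_equal(unname(prof[9]), 3)
  expect_equal(count_daily_peaks(prof), 3)
  expect_equal(count_daily_peaks(c(5, 1, 1)), 1)
  expect_equal(count_daily_peaks(rep(2, 24)), 0)
})
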