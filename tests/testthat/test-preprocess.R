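test_that("quality control passes clean sessions untouched", {
  s <- flat_session(duration = 300)
  qc <- quality_control(s)
  expect_equal(qc$discard_fraction, 0)
  expect_true(all(unlist(qc$session$valid)))
})

test_that("an implausible HR invalidates its second across all channels", {
  s <- flat_session(duration = 300)
  s$channels$HR[101] <- 300  # second index 100 (0-based)
  qc <- quality_control(s)
  expect_equal(qc$discard_fraction, 1 / 300)
  expect_false(qc$session$valid$HR[101])
  expect_false(all(qc$session$valid$EDA[100 * 4 + 1:4]))
  expect_false(all(qc$session$valid$BVP[100 * 64 + 1:64]))
  expect_false(all(qc$session$valid$ACC[100 * 32 + 1:32]))
  # no dilation for the HR rule
  expect_true(qc$session$valid$HR[100])
  expect_true(qc$session$valid$HR[102])
})

test_that("EDA violations dilate by 5 seconds on both sides", {
  s <- flat_session(duration = 300)
  s$channels$EDA[100 * 4 + 1] <- 0.01  # second 100
  qc <- quality_control(s)
  expect_equal(qc$discard_fraction, 11 / 300)  # [95, 105]
  bad_secs <- which(!qc$session$valid$HR) - 1L
  expect_equal(bad_secs, 95:105)
})

test_that("EDA slope rule catches abrupt jumps within plausible range", {
  s <- flat_session(duration = 60, eda = 2)
  s$channels$EDA[50] <- 2 + 5  # +5 uS in 0.25 s = 20 uS/s
  qc <- quality_control(s)
  expect_gt(qc$discard_fraction, 0)
})

test_that("unknown rules are rejected", {
  rules <- qc_rules()
  rules$bvp_range <- c(-5, 5)
  expect_error(quality_control(flat_session(60), rules), "unknown")
})

test_that("segmentation tiles regions with non-overlapping windows", {
  s <- flat_session(duration = 1800)
  segs <- segment_session(s, 16, c(0, 1800))
  expect_equal(n_segments(segs), 112)  # floor(1800 / 16)
  expect_equal(segs$manifest$offset, 16 * (0:111))
  # exhaustive non-overlap in wall time
  ends <- segs$manifest$offset + 16
  expect_true(all(segs$manifest$offset[-1] >= ends[-length(ends)]))
  # block lengths at native rates
  expect_equal(dim(segs$channels$ACC)[2], 512)
  expect_equal(ncol(segs$channels$BVP), 1024)
  expect_equal(ncol(segs$channels$EDA), 64)
  expect_equal(ncol(segs$channels$HR), 16)
  expect_equal(ncol(segs$channels$TEMP), 16)
  # a 5-hour region at tau = 16 gives 1125 windows
  expect_equal(floor(5 * 3600 / 16), 1125)
  expect_equal(n_segments(segment_session(s, 3600, c(0, 1800))), 0)
})

test_that("windows covering an invalid second are dropped, others kept", {
  s <- flat_session(duration = 320)
  s$channels$HR[161] <- 300  # second 160 -> window index 11 ([160,176))
  qc <- quality_control(s)
  segs <- segment_session(qc$session, 16, c(0, 320))
  expect_equal(n_segments(segs), 19)
  expect_false(11 %in% segs$manifest$window_index)
  # conservation: kept + dropped window time equals the tiled region
  expect_equal(n_segments(segs) * 16 + 1 * 16, 20 * 16)
})

test_that("segment values match the raw arrays", {
  s <- flat_session(duration = 64)
  s$channels$EDA <- seq_len(64 * 4) / 100
  segs <- segment_session(s, 16, c(0, 64))
  expect_equal(segs$channels$EDA[2, ], s$channels$EDA[65:128])
})

test_that("close/far partition yields aligned 30-minute intervals", {
  p48 <- close_far_partition(48 * 3600)
  expect_equal(length(p48$far), 86)  # (48 - 5) * 2
  expect_equal(p48$close, c(0, 5 * 3600))
  expect_equal(p48$far[[1]], c(5 * 3600, 5.5 * 3600))
  expect_equal(length(close_far_partition(5 * 3600)$far), 0)
  expect_equal(length(close_far_partition(6 * 3600)$far), 2)
  # partial trailing interval discarded
  expect_equal(length(close_far_partition(6.4 * 3600)$far), 2)
})

test_that("splits are stratified, sized at 70-15-15 and deterministic", {
  cfg <- synth_config(n_subjects = 3, session_rate = 1, duration_h = 0.12,
                      drift_mag = 0, seed = 41)
  dat <- render_cohort_segments(cfg, split_seed = 7)
  segs <- dat$segs
  split <- dat$split
  n <- n_segments(segs)
  expect_equal(sort(c(split$train, split$val, split$test)), seq_len(n))
  expect_equal(length(split$train) / n, 0.70, tolerance = 0.03)
  expect_equal(length(split$val) / n, 0.15, tolerance = 0.03)
  split2 <- make_splits(segs, seed = 7)
  expect_identical(split, split2)
  # every session appears in the training split (critic needs them)
  expect_setequal(unique(segs$manifest$session_id[split$train]),
                  unique(segs$manifest$session_id))
  # per-item training rank frequencies normalized
  expect_true(all(abs(vapply(split$rank_freqs, sum, 0) - 1) < 1e-12))
  expect_error(make_splits(subset_segments(segs, 1:2), seed = 1), "at least 3")
})

test_that("subject-level splits keep subjects disjoint", {
  cfg <- synth_config(n_subjects = 6, session_rate = 1, duration_h = 0.05,
                      drift_mag = 0, seed = 43)
  dat <- render_cohort_segments(cfg)
  split <- make_splits(dat$segs, seed = 3, by = "subject")
  sub <- function(ix) unique(dat$segs$manifest$subject_id[ix])
  expect_length(intersect(sub(split$train), sub(split$test)), 0)
  expect_length(intersect(sub(split$train), sub(split$val)), 0)
})

test_that("severity-bin resampling matches the stated proportionality rule", {
  mk_split <- function(bins) {
    structure(list(train = seq_along(bins), val = integer(0),
                   test = integer(0), rank_freqs = list(),
                   bin_label = bins), class = "dataset_split")
  }
  bins <- c(rep("HDRS:mild", 100), rep("YMRS:severe", 10))
  ros <- resample_training(mk_split(bins), "ROS", seed = 1)
  expect_equal(sum(bins[ros$idx] == "HDRS:mild"), 100)
  expect_equal(sum(bins[ros$idx] == "YMRS:severe"), 100)
  expect_equal(unique(ros$weights[bins[ros$idx] == "HDRS:mild"]), 1)
  expect_equal(unique(ros$weights[bins[ros$idx] == "YMRS:severe"]), 0.1)
  rus <- resample_training(mk_split(bins), "RUS", seed = 1)
  expect_equal(sum(bins[rus$idx] == "HDRS:mild"), 10)
  expect_equal(unique(rus$weights[bins[rus$idx] == "HDRS:mild"]), 10)
  expect_equal(unique(rus$weights[bins[rus$idx] == "YMRS:severe"]), 1)
  # balanced bins: identity sizes, unit weights
  bal <- resample_training(mk_split(rep(c("a", "b"), each = 20)), "ROS",
                           seed = 2)
  expect_equal(length(bal$idx), 40)
  expect_true(all(bal$weights == 1))
})

test_that("resampling weights keep each bin's expected loss invariant", {
  set.seed(8)
  bins <- sample(c("remission", "HDRS:mild", "YMRS:severe"), 200, TRUE,
                 prob = c(0.7, 0.2, 0.1))
  loss <- runif(200)  # toy per-segment losses
  split <- structure(list(train = 1:200, val = integer(0),
                          test = integer(0), rank_freqs = list(),
                          bin_label = bins), class = "dataset_split")
  for (strat in c("ROS", "RUS")) {
    # E over resampling draws of the weighted bin loss equals the original
    sums <- replicate(200, {
      rs <- resample_training(split, strat, seed = sample.int(1e6, 1))
      vapply(unique(bins), function(b)
        sum((loss[rs$idx] * rs$weights)[bins[rs$idx] == b]), 0)
    })
    orig <- vapply(unique(bins), function(b) sum(loss[bins == b]), 0)
    expect_equal(rowMeans(sums), orig, tolerance = 0.1)
  }
})

test_that("the resampling label collapses to the more severe component", {
  sch <- build_schemas()
  mk <- function(h_items, y_items) {
    v <- setNames(rep(0L, 28), combined_items()$id)
    v[names(h_items)] <- h_items; v[names(y_items)] <- y_items
    v
  }
  expect_equal(derive_resample_label(mk(c(), c())), "remission")
  expect_equal(derive_resample_label(mk(c(H1 = 4, H2 = 4, H3 = 2), c())),
               "HDRS:mild")  # total 10
  expect_equal(derive_resample_label(
    mk(c(H1 = 4, H2 = 4, H3 = 2), c(Y5 = 8, Y6 = 8, Y8 = 4))),
    "YMRS:severe")  # YMRS 20 beats HDRS mild
})
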