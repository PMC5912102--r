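test_that("the feature inventory has the fixed 34/64/53/56 block structure", {
  nms <- feature_names()
  expect_length(nms, 207)
  expect_false(anyDuplicated(nms) > 0)
  blocks <- attr(nms, "blocks")
  expect_equal(lengths(blocks), c(raw = 34, heatmap = 64, event = 53,
                                  ngram = 56))
  # blocks partition 0..206 (1-based: 1..207) in concatenation order
  expect_equal(unname(sort(unlist(blocks))), 1:207)
})

test_that("raw gaze statistics match hand computations", {
  rec <- make_recording(rep(0.3, 20), y = 0.7)
  f <- raw_gaze_features(rec$samples)
  expect_equal(unname(f[c("raw_x_min", "raw_x_max", "raw_x_mean")]),
               rep(0.3, 3))
  expect_equal(unname(f["raw_y_median"]), 0.7)
  expect_equal(unname(f[c("raw_x_std", "raw_x_range", "raw_speed_mean",
                          "raw_speed_max", "raw_xy_corr")]),
               rep(0, 5))
  expect_equal(unname(f["raw_valid_fraction"]), 1)

  # x alternating 0/1 at 60 Hz: range 1, mean sample speed 60 range/s
  rec2 <- make_recording(rep(c(0, 1), 10))
  f2 <- raw_gaze_features(rec2$samples)
  expect_equal(unname(f2["raw_x_range"]), 1)
  expect_equal(unname(f2["raw_speed_mean"]), 60)
  expect_length(f2, 34)
  expect_true(all(is.finite(f2)))
})

test_that("heatmap features follow the top-left row-major convention", {
  # all points identical: degenerate interval puts all mass in cell 0
  rec <- make_recording(rep(0.5, 30))
  h <- heatmap_features(rec$samples)
  expect_equal(unname(h[1]), 1)
  expect_equal(sum(h), 1)

  # two distinct points: the 2.5-97.5% interval excludes both -> uniform
  rec2 <- make_recording(c(0.2, 0.8))
  h2 <- heatmap_features(rec2$samples)
  expect_equal(unname(h2), rep(1 / 64, 64))

  # a point near the top-right lands in cell 7 of the top row
  x <- c(rep(0.1, 50), rep(0.9, 50))
  y <- rep(0.1, 100)
  h3 <- heatmap_features(make_recording(x, y = y)$samples)
  expect_gt(h3["heatmap_07"], 0)
  expect_gt(h3["heatmap_00"], 0)
  expect_equal(sum(h3), 1)

  # normalisation holds on random windows
  for (seed in 1:5) {
    set.seed(seed)
    hr <- heatmap_features(make_recording(runif(200), y = runif(200))$samples)
    expect_equal(sum(hr), 1)
    expect_true(all(hr >= 0))
  }
})

test_that("heatmap features are shift-invariant, raw location stats shift", {
  set.seed(7)
  x <- runif(100, 0.2, 0.5); y <- runif(100, 0.2, 0.5)
  a <- make_recording(x, y = y)$samples
  b <- make_recording(x + 0.3, y = y + 0.3)$samples
  expect_equal(heatmap_features(a), heatmap_features(b))
  fa <- raw_gaze_features(a); fb <- raw_gaze_features(b)
  expect_equal(unname(fb["raw_x_mean"] - fa["raw_x_mean"]), 0.3)
  expect_equal(fa["raw_x_std"], fb["raw_x_std"])
  expect_equal(fa["raw_speed_mean"], fb["raw_speed_mean"])
})

test_that("event statistics follow the empty-set and single-event rules", {
  fx1 <- data.frame(start = 1, end = 1.2, x = 0.5, y = 0.5,
                    dispersion = 0.01, pupil_mean = 3, pupil_var = 0.02,
                    erroneous_share = 0)
  none <- fx1[0, ]
  sc0 <- data.frame(start = numeric(0), end = numeric(0),
                    amplitude = numeric(0), direction = numeric(0),
                    peak_velocity = numeric(0), erroneous_share = numeric(0))
  bl0 <- data.frame(start = numeric(0), end = numeric(0))
  samples <- make_recording(rep(0.5, 300))$samples
  f <- event_features(fx1, sc0, bl0, samples, size = 5)
  expect_equal(unname(f["fix_count"]), 1)
  expect_equal(unname(f[c("fix_dur_min", "fix_dur_max", "fix_dur_mean")]),
               rep(0.2, 3))
  expect_equal(unname(f["fix_dur_std"]), 0)
  expect_equal(unname(f["fix_rate"]), 1 / 5)
  # all 6 blink features zero with no blinks
  expect_equal(unname(f[c("blink_count", "blink_rate_per_min",
                          "blink_dur_min", "blink_dur_max", "blink_dur_mean",
                          "blink_dur_std")]), rep(0, 6))
  # empty saccade set: zero counts and zero direction histogram
  expect_equal(unname(f["sacc_count"]), 0)
  expect_equal(unname(f[sprintf("sacc_dir_hist_%d", 0:7)]), rep(0, 8))
  expect_length(f, 53)
})

test_that("event statistics agree with the generator's ground truth", {
  rec <- generate_recording(oculomotor_params(loss_fraction = 0),
                            duration = 30, rate = 60, seed = 13)
  ev <- detect_events(rec)
  fx <- ev$fixations[(ev$fixations$start + ev$fixations$end) / 2 < 15, ]
  f <- event_features(fx, ev$saccades[0, ], ev$blinks[0, ],
                      rec$samples[rec$samples$t < 15, ], size = 15)
  expect_equal(unname(f["fix_count"]), nrow(fx))
  expect_equal(unname(f["fix_dur_mean"]), mean(fx$end - fx$start))
  expect_equal(unname(f["fix_disp_median"]), median(fx$dispersion))
  expect_equal(unname(f["fix_pupil_mean_mean"]), mean(fx$pupil_mean))
})

test_that("n-gram features match hand enumerations", {
  cfg <- ngram_config()
  # three small upward saccades: bigrams all identical
  up_small <- data.frame(start = c(1, 2, 3), end = c(1.05, 2.05, 3.05),
                         amplitude = 0.05, direction = pi / 2,
                         peak_velocity = 3, erroneous_share = 0)
  f <- ngram_features(up_small[0, ], up_small, cfg)
  expect_equal(unname(f[c("ngramA_n2_distinct", "ngramA_n2_max",
                          "ngramA_n2_min", "ngramA_n2_mean",
                          "ngramA_n2_var")]),
               c(1, 2, 2, 2, 0))
  # the single bigram is (up-small, up-small) = symbol 4 twice: index 4*16+4
  expect_equal(unname(f["ngramA_n2_most_idx"]), 4 * 16 + 4)

  # empty saccade sequence: zeros with indices -1 for every A feature
  f0 <- ngram_features(up_small[0, ], up_small[0, ], cfg)
  for (n in 1:4) {
    expect_equal(unname(f0[sprintf("ngramA_n%d_distinct", n)]), 0)
    expect_equal(unname(f0[sprintf("ngramA_n%d_most_idx", n)]), -1)
    expect_equal(unname(f0[sprintf("ngramA_n%d_least_idx", n)]), -1)
  }

  # "long saccade up, short fixation, short saccade up" is exactly one
  # B-encoding 3-gram
  sacs <- data.frame(start = c(1, 3), end = c(1.06, 3.06),
                     amplitude = c(0.3, 0.05), direction = pi / 2,
                     peak_velocity = 4, erroneous_share = 0)
  fixs <- data.frame(start = 2, end = 2.2, x = 0.5, y = 0.5,
                     dispersion = 0.01, pupil_mean = 3, pupil_var = 0,
                     erroneous_share = 0)
  fb <- ngram_features(fixs, sacs, cfg)
  expect_equal(unname(fb["ngramB_n3_distinct"]), 1)
  expect_equal(unname(fb["ngramB_n3_max"]), 1)
  # symbols: large-up = 2*2+1 = 5, short fixation = 16, small-up = 4
  expect_equal(unname(fb["ngramB_n3_most_idx"]), 5 * 18^2 + 16 * 18 + 4)
})

test_that("the full vector is deterministic, finite and context-tagged", {
  rec <- generate_recording(oculomotor_params(), duration = 60, rate = 60,
                            seed = 17)
  ev <- detect_events(rec)
  v1 <- extract_feature_vector(rec, ev, 7.5, 15)
  v2 <- extract_feature_vector(rec, ev, 7.5, 15)
  expect_identical(v1, v2)
  expect_length(v1, 207)
  expect_identical(names(v1), as.character(feature_names()))
  fs <- extract_features(rec, ev, 15)
  expect_equal(ncol(fs$X), 207)
  expect_true(all(is.finite(fs$X)))
  expect_true(all(fs$meta$context %in% c("way1", "shop", "way2")))
  expect_equal(fs$meta$mid, fs$meta$start + 7.5)
})

test_that("features stay finite across many random synthetic windows", {
  total <- 0
  for (seed in 41:44) {
    rec <- generate_recording(oculomotor_params(loss_fraction = 0.3),
                              duration = 120, rate = 60, seed = seed)
    fs <- extract_features(rec, detect_events(rec), 10)
    expect_true(all(is.finite(fs$X)))
    total <- total + nrow(fs$X)
  }
  expect_gt(total, 60)
})
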