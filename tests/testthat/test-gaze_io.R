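test_that("gaze CSV parsing handles complete rows, missing pupil, and errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("t,x,y,pupil",
               "0,0.1,0.2,3.1",
               "0.0167,0.5,0.5,",
               "0.0333,0.9,0.8,2.9"), path)
  rec <- read_gaze_recording(path, participant_id = "a")
  expect_equal(nrow(rec$samples), 3)
  expect_equal(rec$samples$x, c(0.1, 0.5, 0.9))
  expect_true(is.na(rec$samples$pupil[2]))
  expect_false(anyNA(rec$samples$pupil[c(1, 3)]))
  # whole recording covered by a single default context
  expect_equal(nrow(rec$contexts), 1)

  writeLines(c("t,x,y,pupil", "0,0.1,0.2,3.1", "0,0.5,0.5,3.0"), path)
  expect_error(read_gaze_recording(path), "non-monotonic timestamps")
  writeLines(c("t,x,pupil", "0,0.1,3.1"), path)
  expect_error(read_gaze_recording(path), "missing required column")
})

test_that("written recordings round-trip exactly, contexts included", {
  set.seed(42)
  n <- 50
  samples <- data.frame(t = cumsum(runif(n, 0.02, 0.03)),
                        x = runif(n, -0.3, 1.3), y = runif(n, -0.3, 1.3),
                        pupil = ifelse(runif(n) < 0.2, NA, runif(n, 2, 6)))
  ctx <- data.frame(label = c("way1", "shop", "way2"),
                    start = c(0, 0.3, 0.6), end = c(0.3, 0.6, 0.9))
  rec <- gaze_recording("rt", samples, contexts = ctx)
  gp <- withr::local_tempfile(fileext = ".csv")
  cp <- withr::local_tempfile(fileext = ".csv")
  write_gaze_recording(rec, gp, cp)
  back <- read_gaze_recording(gp, cp, participant_id = "rt")
  expect_identical(back$samples$t, rec$samples$t)
  expect_identical(back$samples$x, rec$samples$x)
  expect_identical(back$samples$y, rec$samples$y)
  expect_identical(back$samples$pupil, rec$samples$pupil)
  expect_identical(back$contexts$label, ctx$label)
})

test_that("erroneous marking follows the 150%-range rule and is idempotent", {
  samples <- data.frame(t = (0:5) / 60,
                        x = c(0.5, 1.30, -0.26, 1.25, -0.25, 0.2),
                        y = c(0.5, 0.5, 0.5, 0.5, 0.5, 1.30),
                        pupil = c(3.1, 3.1, 3.1, 3.1, NA, 3.1))
  rec <- mark_erroneous_samples(gaze_recording("m", samples))
  # interior point valid; beyond 1.25 or below -0.25 on either axis, or
  # absent pupil, erroneous; the boundary itself is still valid
  expect_identical(rec$samples$valid, c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE))
  twice <- mark_erroneous_samples(rec)
  expect_identical(twice$samples, rec$samples)
  expect_equal(nrow(rec$samples), nrow(samples))
})

test_that("participant screening applies the exclusion rules and reports all", {
  good <- make_recording(x = rep(c(0.4, 0.41, 0.42), 40),
                         y = rep(c(0.5, 0.51, 0.52), 40), id = "good")
  n <- 100
  set.seed(1)
  bad_pupil <- make_recording(x = runif(n, 0.3, 0.7), y = runif(n, 0.3, 0.7),
                              pupil = c(rep(NA, 60), rep(3, 40)), id = "erro")
  const <- make_recording(x = c(rep(0.5, 48), runif(72, 0.1, 0.9)),
                          y = runif(120, 0.1, 0.9), id = "const")
  res <- screen_participants(list(good, bad_pupil, const))
  rep_df <- res$reports
  expect_equal(nrow(rep_df), 3)
  expect_false(rep_df$excluded[rep_df$participant_id == "good"])
  expect_equal(rep_df$reason[rep_df$participant_id == "erro"], "erroneous>0.5")
  expect_equal(rep_df$reason[rep_df$participant_id == "const"], "constant-gaze")
  expect_equal(vapply(list(good, bad_pupil, const), erroneous_fraction,
                      numeric(1)),
               rep_df$erroneous_fraction)
  # erroneous fraction is exactly the mean of the negated validity flag
  expect_identical(rep_df$erroneous_fraction[2],
                   mean(!bad_pupil$samples$valid))
  expect_equal(length(res$retained), 1)
  expect_error(screen_participants(list()), "empty cohort")
})
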