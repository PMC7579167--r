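test_that("identical seeds reproduce campaigns byte-identically", {
  cfg <- scenario_config(seed = 42, n_participants = 2, n_stressors = 4,
                         walk_duration_s = 400)
  c1 <- generate_campaign(cfg)
  c2 <- generate_campaign(cfg)
  expect_identical(c1, c2)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_campaign(c1, d1); write_campaign(c2, d2)
  for (f in list.files(d1, recursive = TRUE)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
  c3 <- generate_campaign(scenario_config(seed = 43, n_participants = 2,
                                          n_stressors = 4,
                                          walk_duration_s = 400))
  expect_false(identical(c1$participants[[1]]$physio$gsr,
                         c3$participants[[1]]$physio$gsr))
})

test_that("noise-free planted events satisfy all three rule clauses by construction", {
  cfg <- scenario_config(seed = 5, n_stressors = 6, walk_duration_s = 700,
                         event_probability = 1, gsr_noise_sd_us = 0,
                         st_noise_sd_degc = 0)
  p <- generate_campaign(cfg)$participants[[1]]
  fs <- p$physio$fs
  for (k in seq_len(nrow(p$truth))) {
    i <- round(as.numeric(p$truth$onset_time[k] - p$physio$start_time,
                          units = "secs") * fs) + 1
    rise <- p$physio$gsr[i:(i + 5 * fs)]
    expect_true(all(diff(rise) >= 0))                        # clause (a)
    slope <- (rise[length(rise)] - rise[1]) / 5
    expect_gte(atan(slope) * 180 / pi, 10)                   # clause (b)
    win <- p$physio$st[(i + 3 * fs):(i + 13 * fs)]
    expect_lt(min(win), win[1])                              # clause (c): drop
    expect_gt(win[length(win)], min(win))                    # and recovery
  }
})

test_that("seed 42, five certain passages, zero noise: closed loop with the detector", {
  cfg <- scenario_config(seed = 42, n_stressors = 5, walk_duration_s = 600,
                         event_probability = 1, gsr_noise_sd_us = 0,
                         st_noise_sd_degc = 0)
  p <- generate_campaign(cfg)$participants[[1]]
  expect_equal(nrow(p$truth), 5)
  ev <- detect_mos(preprocess_trace(p$physio))
  m <- evaluate_detection(ev, p$truth$onset_time)
  expect_equal(m$precision, 1)
  expect_equal(m$recall, 1)
})

test_that("zero event probability gives baseline-only traces and no detections", {
  cfg <- scenario_config(seed = 6, n_stressors = 5, walk_duration_s = 500,
                         event_probability = 0)
  p <- generate_campaign(cfg)$participants[[1]]
  expect_equal(nrow(p$truth), 0)
  ev <- detect_mos(preprocess_trace(p$physio))
  expect_equal(nrow(ev), 0)
})

test_that("reduction_factor thins planted events exactly in the annotations", {
  mk <- function(seed, f) {
    generate_campaign(scenario_config(seed = seed, n_stressors = 10,
                                      walk_duration_s = 1000,
                                      event_probability = 1,
                                      reduction_factor = f))
  }
  pre <- mk(1, 1); post <- mk(2, 0.8)
  n_pre <- nrow(pre$participants[[1]]$truth)
  n_post <- nrow(post$participants[[1]]$truth)
  expect_equal(n_post / n_pre, 0.8)
})

test_that("a route shorter than the walk is a configuration error", {
  short_route <- cbind(c(13.040, 13.041), c(47.800, 47.800))  # ~75 m
  cfg <- scenario_config(seed = 1, walk_duration_s = 600, route = short_route)
  expect_error(generate_campaign(cfg), "route too short")
})

test_that("synthetic diaries use the closed vocabularies and carry locations", {
  cfg <- scenario_config(seed = 12, n_stressors = 8, walk_duration_s = 900,
                         diary_report_probability = 1)
  p <- generate_campaign(cfg)$participants[[1]]
  expect_gt(nrow(p$diary), 0)
  expect_true(all(p$diary$emotion %in% diary_emotions))
  expect_true(all(p$diary$trigger %in% diary_triggers))
  expect_true(all(diary_valence(p$diary$emotion) == "negative"))
  expect_true(all(!p$diary$needs_georef))
  expect_true(all(p$diary$intensity >= 1 & p$diary$intensity <= 5))
})

test_that("written campaigns round-trip through the package readers", {
  cfg <- scenario_config(seed = 33, n_stressors = 3, walk_duration_s = 400,
                         diary_report_probability = 1)
  cp <- generate_campaign(cfg)
  d <- withr::local_tempdir()
  write_campaign(cp, d)
  pd <- file.path(d, "P01")
  tr <- read_physio(pd, "e4", participant_id = "P01")
  p <- cp$participants[[1]]
  expect_equal(tr$gsr, p$physio$gsr, tolerance = 1e-6)
  expect_equal(as.numeric(tr$start_time), as.numeric(p$physio$start_time))
  tk <- read_track(file.path(pd, "track.gpx"))
  expect_equal(length(tk$time), length(p$track$time))
  expect_equal(tk$lon, p$track$lon, tolerance = 1e-7)
  if (nrow(p$diary) > 0) {
    dd <- read_diary(file.path(pd, "diary.csv"))
    expect_equal(dd$emotion, p$diary$emotion)
  }
})
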