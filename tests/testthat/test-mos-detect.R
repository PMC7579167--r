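test_that("flat signals yield no detections", {
  ft <- fake_filtered(rep(0, 481), rep(33, 481))   # 120 s at 4 Hz
  expect_equal(nrow(detect_mos(ft)), 0)
})

test_that("the canonical planted template fires exactly once at its onset", {
  # phasic GSR rises 0 -> 1 uS over t = 10..15 s (0.2 uS/s, 11.3 deg);
  # ST flat at 33 until a local max at 13.5 s, falling to 32.8 by 20 s
  tp <- template_series()
  ft <- fake_filtered(tp$g, tp$s)
  ev <- detect_mos(ft)
  expect_equal(nrow(ev), 1)
  onset_s <- as.numeric(ev$onset_time) - as.numeric(ft$start_time)
  # the sliding rule first fires half a second before the plant: the flat
  # samples ahead of the ramp do not violate non-decrease and the 5 s net
  # change already clears 10 degrees at t = 9.5
  expect_lte(abs(onset_s - 10), 0.5)
  expect_equal(ev$gsr_slope_deg, atan(0.2) * 180 / pi, tolerance = 1e-6)
  expect_equal(ev$gsr_delta_us, 1, tolerance = 1e-9)
  # rule invariants on the reported event
  expect_lt(as.numeric(ev$onset_time), as.numeric(ev$window_end_time))
  expect_lt(as.numeric(ev$st_max_time), as.numeric(ev$st_min_time))
  expect_gte(as.numeric(ev$st_max_time),
             as.numeric(ev$onset_time) + 3 - 1e-9)

  # agreement with the independent straight-line reference implementation
  ref <- ref_detect_onsets(tp$g, tp$s, fs = 4)
  expect_equal(onset_s, ref)
})

test_that("a rise below the 10-degree slope threshold does not fire", {
  tp <- template_series(rise_to = 0.5)   # 0.1 uS/s -> 5.7 deg
  ft <- fake_filtered(tp$g, tp$s)
  expect_equal(nrow(detect_mos(ft)), 0)
  expect_length(ref_detect_onsets(tp$g, tp$s, fs = 4), 0)
})

test_that("a GSR rise without the delayed ST drop does not fire", {
  tp <- template_series()
  ft <- fake_filtered(tp$g, rep(33, length(tp$s)))   # ST never drops
  expect_equal(nrow(detect_mos(ft)), 0)
})

test_that("vectorized detector matches the reference on random multi-event traces", {
  set.seed(11)
  fs <- 4
  for (r in 1:5) {
    n <- 1201
    g <- rep(0, n); s <- rep(33, n)
    onsets <- sort(sample(seq(40, 1100, by = 4), 4)) / fs
    for (o in onsets) {
      i <- o * fs + 1
      ramp <- seq(0, 1.2, length.out = 21)
      g[i:(i + 20)] <- pmax(g[i:(i + 20)], ramp)
      g[(i + 21):min(i + 60, n)] <- 1.2 * exp(-(1:length((i + 21):min(i + 60, n))) / 16)
      j <- i + 12
      s[j:(j + 20)] <- s[j:(j + 20)] - seq(0, 0.3, length.out = 21)
      s[(j + 21):min(j + 60, n)] <- 32.7
    }
    ft <- fake_filtered(g, s, fs)
    ev <- detect_mos(ft)
    got <- as.numeric(ev$onset_time) - as.numeric(ft$start_time)
    ref <- ref_detect_onsets(g, s, fs)
    expect_equal(sort(got), sort(ref), tolerance = 1e-9)
  }
})

test_that("detections shift exactly with a shifted trace (equivariance)", {
  tp <- template_series(duration_s = 120)
  k <- 37                                   # shift by 37 samples = 9.25 s
  g2 <- c(rep(0, k), tp$g)[seq_along(tp$g)]
  s2 <- c(rep(33, k), tp$s)[seq_along(tp$s)]
  e1 <- detect_mos(fake_filtered(tp$g, tp$s))
  e2 <- detect_mos(fake_filtered(g2, s2))
  expect_equal(nrow(e2), nrow(e1))
  expect_equal(as.numeric(e2$onset_time) - as.numeric(e1$onset_time),
               k / 4, tolerance = 1e-9)
})

test_that("raising the slope threshold never adds detections", {
  set.seed(21)
  cp <- generate_campaign(scenario_config(seed = 21, n_stressors = 10,
                                          walk_duration_s = 800,
                                          event_probability = 1))
  ft <- preprocess_trace(cp$participants[[1]]$physio)
  counts <- vapply(c(5, 10, 15, 25, 45), function(th) {
    nrow(detect_mos(ft, mos_rule_config(min_slope_deg = th)))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("firings within the refractory window merge into one event", {
  # two 5 s rises back to back: sliding onsets fire repeatedly but
  # describe one physiological episode
  fs <- 4
  t <- seq(0, 60, by = 1 / fs)
  g <- pmin(pmax(t - 10, 0) * 0.25, 2.5)     # one long 10 s rise
  s <- rep(33, length(t))
  s[t > 14 & t <= 20] <- 33 - (t[t > 14 & t <= 20] - 14) * 0.05
  s[t > 20] <- 32.7
  ev <- detect_mos(fake_filtered(g, s, fs))
  expect_equal(nrow(ev), 1)
})

test_that("contract and length errors are raised", {
  tr <- physio_trace("P01", 0, 4, rep(0, 481), rep(33, 481))
  expect_error(detect_mos(tr), "filtered")
  tp <- template_series(duration_s = 12)
  expect_error(detect_mos(fake_filtered(tp$g, tp$s)), "too short")
})

test_that("evaluate_detection implements greedy one-to-one matching", {
  r <- evaluate_detection(c(10, 60), c(10, 60))
  expect_equal(c(r$precision, r$recall), c(1, 1))
  r <- evaluate_detection(c(10), c(10, 60))
  expect_equal(c(r$precision, r$recall), c(1, 0.5))
  r <- evaluate_detection(c(10, 12), c(10))
  expect_equal(c(r$precision, r$recall), c(0.5, 1))
  r <- evaluate_detection(numeric(0), c(10))
  expect_equal(c(r$precision, r$recall), c(1, 0))
})
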