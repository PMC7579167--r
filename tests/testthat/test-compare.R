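mk_events <- function(n, lon = 13.04, lat = 47.8, jitter = 2e-4) {
  set.seed(n + 1000)
  data.frame(lon = lon + runif(n, -jitter, jitter),
             lat = lat + runif(n, -jitter, jitter))
}

test_that("difference map: identical fields cancel; lone sensor cell is positive", {
  spec <- structure(list(zone = 33L, hemisphere = "N", cell_size_m = 25,
                         x0 = 353200, y0 = 5295900, nx = 4, ny = 4),
                    class = "grid_spec")
  base <- data.frame(x = rep(c(353210, 353240), each = 50),
                     y = rep(5295910, 100), layer = "meas")
  both <- rbind(base,
                data.frame(x = c(353210, 353240), y = rep(5295910, 2),
                           layer = "mos"),
                data.frame(x = c(353210, 353240), y = rep(5295910, 2),
                           layer = "diary_neg"))
  g <- rasterize(both, spec)
  d <- difference_map(g, g)
  expect_true(all(d$diff == 0))

  sensor_only <- rasterize(rbind(base, data.frame(
    x = c(353210, 353210, 353240), y = rep(5295910, 3), layer = "mos")), spec)
  diary_empty <- rasterize(base, spec)
  d2 <- difference_map(sensor_only, diary_empty)
  expect_gt(d2$diff[d2$cx == 1][1], 0)
})

test_that("difference map reproduces the hand-computed two-cell case", {
  spec <- structure(list(zone = 33L, hemisphere = "N", cell_size_m = 25,
                         x0 = 353200, y0 = 5295900, nx = 2, ny = 1),
                    class = "grid_spec")
  meas <- data.frame(x = rep(c(353210, 353235), each = 100),
                     y = 5295910, layer = "meas")
  # sensor rates {0.02, 0.04}; diary rates {0.04, 0.02}
  sensor <- rasterize(rbind(meas, data.frame(
    x = c(rep(353210, 2), rep(353235, 4)), y = 5295910, layer = "mos")), spec)
  diary <- rasterize(rbind(meas, data.frame(
    x = c(rep(353210, 4), rep(353235, 2)), y = 5295910,
    layer = "diary_neg")), spec)
  d <- difference_map(sensor, diary)
  expect_equal(d$diff[order(d$cx)], c(-1, 1))
})

test_that("percent change mirrors the headline pre-post arithmetic", {
  pre <- list(events = mk_events(100), exposure_s = 3600)
  post <- list(events = mk_events(80), exposure_s = 3600)
  cmp <- compare_campaigns(pre, post)
  expect_equal(cmp$change_pct[cmp$zone == "overall"], -20)
})

test_that("per-zone counts reproduce the printed reductions to 1 dp", {
  # zone A: 103 -> 90 (-12.6%); zone B: 58 -> 43 (-25.9%)
  zoneA <- cbind(c(13.03, 13.05, 13.05, 13.03, 13.03),
                 c(47.79, 47.79, 47.81, 47.81, 47.79))
  zoneB <- zoneA; zoneB[, 1] <- zoneB[, 1] + 0.1
  pre <- list(events = rbind(mk_events(103),
                             mk_events(58, lon = 13.14)),
              exposure_s = 7200)
  post <- list(events = rbind(mk_events(90),
                              mk_events(43, lon = 13.14)),
               exposure_s = 7200)
  cmp <- compare_campaigns(pre, post,
                           zones = list(city = zoneA, out_of_town = zoneB))
  expect_equal(round(cmp$change_pct[cmp$zone == "city"], 1), -12.6)
  expect_equal(round(cmp$change_pct[cmp$zone == "out_of_town"], 1), -25.9)
})

test_that("exposure-rate mode normalizes by measurement time", {
  pre <- list(events = mk_events(50), exposure_s = 3600)
  post <- list(events = mk_events(50), exposure_s = 7200)
  cmp <- compare_campaigns(pre, post, mode = "exposure_rate")
  expect_equal(cmp$change_pct[cmp$zone == "overall"], -50)
  raw <- compare_campaigns(pre, post, mode = "raw_counts")
  expect_equal(raw$change_pct[raw$zone == "overall"], 0)
})

test_that("a zero pre-campaign statistic is an explicit error", {
  pre <- list(events = mk_events(0), exposure_s = 3600)
  post <- list(events = mk_events(10), exposure_s = 3600)
  expect_error(compare_campaigns(pre, post), "undefined")
})
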