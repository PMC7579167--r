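# a small grid spec in projected coordinates for convention tests
mk_spec <- function(nx = 4, ny = 4, s = 25) {
  structure(list(zone = 33L, hemisphere = "N", cell_size_m = s,
                 x0 = 353200, y0 = 5295900, nx = nx, ny = ny),
            class = "grid_spec")
}

pts_xy <- function(x, y, layer) {
  data.frame(x = x, y = y, layer = layer, stringsAsFactors = FALSE)
}

test_that("rasterize counts per layer and standardizes to a rate", {
  spec <- mk_spec()
  pts <- rbind(pts_xy(rep(353210, 100), rep(5295910, 100), "meas"),
               pts_xy(rep(353212, 2), rep(5295912, 2), "mos"))
  g <- rasterize(pts, spec)
  expect_equal(sum(g$meas), 100)
  expect_equal(sum(g$mos), 2)
  r <- stressmapr:::grid_rates(g, "mos", min_support = 10)
  expect_equal(nrow(r), 1)
  expect_equal(r$rate, 0.02)
})

test_that("an empty point set gives an all-zero grid", {
  g <- rasterize(data.frame(x = numeric(0), y = numeric(0)), mk_spec())
  expect_equal(sum(g$meas) + sum(g$mos), 0)
})

test_that("half-open cell membership assigns edge points right/top", {
  spec <- mk_spec()
  # exactly on the boundary between cells (1,1) and (2,1)
  g <- rasterize(pts_xy(353200 + 25, 5295910, "meas"), spec)
  expect_equal(g$meas[2, 1], 1L)
  expect_equal(g$meas[1, 1], 0L)
  # on the top edge between (1,1) and (1,2)
  g2 <- rasterize(pts_xy(353210, 5295900 + 25, "meas"), spec)
  expect_equal(g2$meas[1, 2], 1L)
})

test_that("counts are conserved through rasterization, overflow included", {
  set.seed(14)
  spec <- mk_spec()
  for (r in 1:10) {
    n <- sample(50:200, 1)
    pts <- pts_xy(353200 + runif(n, -40, 140), 5295900 + runif(n, -40, 140),
                  sample(c("meas", "mos"), n, replace = TRUE))
    g <- suppressWarnings(rasterize(pts, spec))
    expect_equal(sum(g$meas) + sum(g$mos) + sum(g$overflow), n)
  }
})

test_that("Gi* matches the brute-force double-loop oracle on random grids", {
  set.seed(15)
  worst <- 0
  for (r in 1:50) {
    x <- rnorm(64, sd = runif(1, 0.5, 3))
    co <- as.matrix(expand.grid(x = 1:8, y = 1:8)) * 25
    W <- distance_band_weights(co, runif(1, 25, 120))
    worst <- max(worst, max(abs(gi_star_z(x, W) - oracle_gi_star(x, W))))
  }
  expect_lt(worst, 1e-9)
})

test_that("degenerate fields follow the S = 0 and sign conventions", {
  co <- as.matrix(expand.grid(1:3, 1:3)) * 25
  expect_equal(gi_star_z(rep(7, 9), distance_band_weights(co, 50)),
               rep(0, 9))
  x <- rep(0, 9); x[5] <- 9
  W <- distance_band_weights(co, 25)         # rook + self band
  z <- gi_star_z(x, W)
  expect_gt(z[5], 0)
  expect_lt(z[1], 0)
  expect_equal(z, oracle_gi_star(x, W), tolerance = 1e-12)
})

test_that("permuting cells permutes z-scores under permuted weights", {
  set.seed(16)
  x <- rnorm(30)
  co <- cbind(runif(30, 0, 200), runif(30, 0, 200))
  W <- distance_band_weights(co, 60)
  z <- gi_star_z(x, W)
  p <- sample(30)
  expect_equal(gi_star_z(x[p], W[p, p]), z[p], tolerance = 1e-12)
})

test_that("z-score classification uses the standard two-sided thresholds", {
  expect_equal(classify_z(c(2.0, -1.7, 0, 2.6, -2.58, 1.645, -1.96)),
               c("hot95", "cold90", "neutral", "hot99", "cold99",
                 "hot90", "cold95"))
})

test_that("weights are symmetric, binary and self-inclusive", {
  set.seed(17)
  co <- cbind(runif(15, 0, 100), runif(15, 0, 100))
  W <- distance_band_weights(co, 40)
  expect_true(all(W %in% c(0, 1)))
  expect_equal(W, t(W))
  expect_equal(diag(W), rep(1, 15))
})

test_that("gi_star on a grid reproduces gi_star_z on its included cells", {
  spec <- mk_spec(3, 3)
  set.seed(18)
  pts <- do.call(rbind, lapply(1:9, function(k) {
    cx <- (k - 1) %% 3; cy <- (k - 1) %/% 3
    n_meas <- 50
    n_mos <- sample(0:5, 1)
    rbind(pts_xy(rep(353200 + cx * 25 + 12, n_meas),
                 rep(5295900 + cy * 25 + 12, n_meas),
                 rep("meas", n_meas)),
          pts_xy(rep(353200 + cx * 25 + 12, n_mos),
                 rep(5295900 + cy * 25 + 12, n_mos),
                 rep("mos", n_mos)))
  }))
  g <- rasterize(pts, spec)
  res <- gi_star(g, min_support = 10)
  expect_equal(nrow(res), 9)
  W <- distance_band_weights(res[, c("x", "y")], 50)
  expect_equal(res$z, gi_star_z(res$rate, W), tolerance = 1e-12)
  expect_error(gi_star(g, min_support = 1000), "included cells")
})

test_that("hotspot GeoJSON export writes valid classified polygons", {
  spec <- mk_spec(3, 3)
  pts <- rbind(pts_xy(rep(353210, 60), rep(5295910, 60), "meas"),
               pts_xy(rep(353240, 60), rep(5295910, 60), "meas"),
               pts_xy(rep(353212, 3), rep(5295912, 3), "mos"))
  res <- gi_star(rasterize(pts, spec), min_support = 10)
  f <- withr::local_tempfile(fileext = ".geojson")
  write_hotspots_geojson(res, f)
  gj <- jsonlite::read_json(f)
  expect_equal(gj$type, "FeatureCollection")
  expect_length(gj$features, 2)
  ring <- gj$features[[1]]$geometry$coordinates[[1]]
  expect_length(ring, 5)                      # closed square
  expect_equal(unlist(ring[[1]]), unlist(ring[[5]]))
  lon <- unlist(ring)[c(TRUE, FALSE)]
  expect_true(all(lon > 12 & lon < 14))       # back in WGS84 degrees
})
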