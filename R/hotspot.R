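#' Metric analysis grid specification
#'
#' Stress rates are aggregated on a square grid in a metric CRS (a UTM zone
#' auto-selected from the data centroid by default). The grid origin is
#' snapped down to a multiple of the cell size so that cell boundaries are
#' reproducible across runs and campaigns covering the same area. Cell
#' membership is half-open: \[x0 + c*s, x0 + (c+1)*s) in both axes, so a
#' point exactly on a shared edge belongs to the cell on its right/top.
#'
#' @param lon,lat Point coordinates (degrees) whose extent the grid covers.
#' @param cell_size_m Cell edge length in metres (default 25, a city-block
#'   sub-scale).
#' @param pad_cells Extra cells added around the data extent.
#' @param zone,hemisphere UTM zone override (default: from the centroid).
#' @return An object of class `grid_spec` with the zone, cell size, snapped
#'   origin `x0`, `y0`, and dimensions `nx`, `ny`.
#' @export
grid_spec <- function(lon, lat, cell_size_m = 25, pad_cells = 1,
                      zone = NULL, hemisphere = NULL) {
  stopifnot(cell_size_m > 0, length(lon) >= 1, length(lon) == length(lat))
  if (is.null(zone) || is.null(hemisphere)) {
    z <- utm_zone(mean(lon, na.rm = TRUE), mean(lat, na.rm = TRUE))
    if (is.null(zone)) zone <- z$zone
    if (is.null(hemisphere)) hemisphere <- z$hemisphere
  }
  p <- project_utm(lon, lat, zone, hemisphere)
  s <- cell_size_m
  x0 <- (floor(min(p$x, na.rm = TRUE) / s) - pad_cells) * s
  y0 <- (floor(min(p$y, na.rm = TRUE) / s) - pad_cells) * s
  nx <- ceiling((max(p$x, na.rm = TRUE) - x0) / s) + pad_cells
  ny <- ceiling((max(p$y, na.rm = TRUE) - y0) / s) + pad_cells
  structure(list(zone = zone, hemisphere = hemisphere,
                 cell_size_m = s, x0 = x0, y0 = y0,
                 nx = as.integer(nx), ny = as.integer(ny)),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> UTM %d%s, %g m cells, %d x %d, origin (%g, %g)\n",
              x$zone, x$hemisphere, x$cell_size_m, x$nx, x$ny, x$x0, x$y0))
  invisible(x)
}

project_points <- function(df, spec) {
  if (all(c("x", "y") %in% names(df))) {
    df[, c("x", "y")]
  } else {
    project_utm(df$lon, df$lat, spec$zone, spec$hemisphere)
  }
}

#' Aggregate located points to the grid
#'
#' Counts points per cell into named layers. The canonical layers are
#' `meas` (georeferenced sensor samples — the denominator of the
#' standardized rate), `mos` (detected moments of stress), `diary_neg` and
#' `diary_pos` (negative/positive-valence diary entries). Counts are
#' conserved: every input point lands in exactly one cell or, if outside
#' the grid extent, in the overflow tally reported via
#' `attr(grid, "overflow")` (with a warning).
#'
#' @param points Data frame with `lon`/`lat` (or projected `x`/`y`) and
#'   optionally a `layer` column; rows with missing coordinates are counted
#'   as overflow.
#' @param spec A [grid_spec].
#' @param layer Default layer for points without a `layer` column.
#' @return An object of class `hotspot_grid`: the spec plus one `nx * ny`
#'   count matrix per layer.
#' @export
rasterize <- function(points, spec, layer = "meas") {
  stopifnot(inherits(spec, "grid_spec"))
  layers <- c("meas", "mos", "diary_neg", "diary_pos")
  counts <- lapply(layers, function(l) matrix(0L, spec$nx, spec$ny))
  names(counts) <- layers
  overflow <- stats::setNames(rep(0L, length(layers)), layers)
  if (nrow(points) > 0) {
    lay <- if ("layer" %in% names(points)) as.character(points$layer)
           else rep(layer, nrow(points))
    bad_lay <- setdiff(unique(lay), layers)
    if (length(bad_lay) > 0) {
      stop(sprintf("unknown layer(s): %s", paste(bad_lay, collapse = ", ")),
           call. = FALSE)
    }
    xy <- project_points(points, spec)
    s <- spec$cell_size_m
    cx <- floor((xy$x - spec$x0) / s) + 1L
    cy <- floor((xy$y - spec$y0) / s) + 1L
    inside <- !is.na(cx) & !is.na(cy) &
      cx >= 1L & cx <= spec$nx & cy >= 1L & cy <= spec$ny
    for (l in layers) {
      sel <- lay == l
      tab <- table(factor(cx[sel & inside], levels = seq_len(spec$nx)),
                   factor(cy[sel & inside], levels = seq_len(spec$ny)))
      counts[[l]] <- counts[[l]] + unclass(tab)
      overflow[[l]] <- overflow[[l]] + sum(sel & !inside)
    }
    if (sum(overflow) > 0) {
      warning(sprintf("%d point(s) outside the grid extent counted as overflow",
                      sum(overflow)), call. = FALSE)
    }
  }
  structure(c(list(spec = spec), counts, list(overflow = overflow)),
            class = "hotspot_grid")
}

#' Merge count grids sharing one spec
#'
#' @param ... `hotspot_grid` objects on identical specs.
#' @return A `hotspot_grid` with summed layers.
#' @export
merge_grids <- function(...) {
  gs <- list(...)
  g <- gs[[1]]
  for (h in gs[-1]) {
    stopifnot(identical(g$spec, h$spec))
    for (l in c("meas", "mos", "diary_neg", "diary_pos")) {
      g[[l]] <- g[[l]] + h[[l]]
    }
    g$overflow <- g$overflow + h$overflow
  }
  g
}

#' @export
print.hotspot_grid <- function(x, ...) {
  cat(sprintf("<hotspot_grid> %d x %d cells (%g m), counts: meas %d, mos %d, diary -%d/+%d\n",
              x$spec$nx, x$spec$ny, x$spec$cell_size_m,
              sum(x$meas), sum(x$mos), sum(x$diary_neg), sum(x$diary_pos)))
  if (sum(x$overflow) > 0) {
    cat(sprintf("  overflow: %d point(s) outside extent\n", sum(x$overflow)))
  }
  invisible(x)
}

# per-cell standardized rate for included cells; numerator layer over the
# measurement count (rates from near-empty cells are unstable, hence the
# minimum-support gate)
grid_rates <- function(grid, numerator = "mos", min_support = 10) {
  inc <- which(grid$meas >= min_support & grid$meas > 0)
  if (length(inc) == 0L) {
    return(data.frame(cell = integer(0), cx = integer(0), cy = integer(0),
                      x = numeric(0), y = numeric(0), rate = numeric(0)))
  }
  cx <- ((inc - 1L) %% grid$spec$nx) + 1L
  cy <- ((inc - 1L) %/% grid$spec$nx) + 1L
  s <- grid$spec$cell_size_m
  data.frame(cell = inc, cx = cx, cy = cy,
             x = grid$spec$x0 + (cx - 0.5) * s,
             y = grid$spec$y0 + (cy - 0.5) * s,
             n_meas = grid$meas[inc],
             n_num = grid[[numerator]][inc],
             rate = grid[[numerator]][inc] / grid$meas[inc])
}

#' Fixed-distance-band spatial weights
#'
#' Binary weights between cell centroids: `w_ij = 1` when the centroid
#' distance is at most `d_m`, self-inclusive (`w_ii = 1`, the "star" in
#' Gi*), symmetric by construction.
#'
#' @param coords Two-column matrix/data.frame of centroid coordinates (m).
#' @param d_m Band distance in metres.
#' @return An `n x n` 0/1 matrix.
#' @export
distance_band_weights <- function(coords, d_m) {
  coords <- as.matrix(coords)
  d <- as.matrix(stats::dist(coords))
  W <- (d <= d_m) * 1
  dimnames(W) <- NULL
  W
}

#' Getis--Ord Gi* z-scores for a value vector and weight matrix
#'
#' Standard Gi* statistic: for each location i,
#' \deqn{z_i = \frac{\sum_j w_{ij} x_j - \bar{X} \sum_j w_{ij}}
#'   {S \sqrt{[n \sum_j w_{ij}^2 - (\sum_j w_{ij})^2] / (n - 1)}}}
#' with \eqn{\bar{X}} the global mean and
#' \eqn{S = \sqrt{\sum_j x_j^2 / n - \bar{X}^2}}. A degenerate field
#' (S = 0, all values equal) yields z = 0 everywhere by convention, as does
#' a location whose denominator vanishes (its neighborhood is the whole
#' study area).
#'
#' @param x Numeric value vector (length >= 2).
#' @param W Weight matrix (`n x n`), typically from
#'   [distance_band_weights()].
#' @return Numeric vector of z-scores.
#' @export
gi_star_z <- function(x, W) {
  n <- length(x)
  if (n < 2L) stop("Gi* needs at least 2 included cells", call. = FALSE)
  W <- as.matrix(W)
  stopifnot(nrow(W) == n, ncol(W) == n)
  xbar <- mean(x)
  S <- sqrt(max(sum(x^2) / n - xbar^2, 0))
  Wi <- rowSums(W)
  num <- as.numeric(W %*% x) - xbar * Wi
  den <- S * sqrt(pmax(n * rowSums(W^2) - Wi^2, 0) / (n - 1))
  z <- ifelse(den > 0, num / den, 0)
  if (S == 0) z[] <- 0
  unname(z)
}

#' Hot/cold classification of Gi* z-scores
#'
#' Two-sided normal thresholds: |z| >= 2.576, 1.96, 1.645 mark the 99%,
#' 95% and 90% confidence classes; positive z are hot spots (stress
#' accumulation), negative z cold spots (low-stress areas).
#'
#' @param z Numeric z-scores.
#' @return Character vector in `{hot99, hot95, hot90, neutral, cold90,
#'   cold95, cold99}`.
#' @export
classify_z <- function(z) {
  cls <- rep("neutral", length(z))
  cls[z >= 1.645] <- "hot90"
  cls[z >= 1.96] <- "hot95"
  cls[z >= 2.576] <- "hot99"
  cls[z <= -1.645] <- "cold90"
  cls[z <= -1.96] <- "cold95"
  cls[z <= -2.576] <- "cold99"
  cls
}

#' Hot-spot analysis of a count grid
#'
#' Computes the standardized stress rate per included cell (numerator layer
#' over measurement count, cells below `min_support` excluded), builds
#' fixed-distance-band self-inclusive weights (default band: twice the cell
#' size), and evaluates the Getis--Ord Gi* z-score and hot/cold class.
#'
#' @param grid A [rasterize()]d `hotspot_grid`.
#' @param numerator Count layer standardized by `meas` (default `"mos"`).
#' @param min_support Minimum sensor samples per cell (default 10).
#' @param d_m Weight band distance in metres (default `2 * cell_size_m`).
#' @return An object of class `gi_star_result`: data frame of included
#'   cells (`cx`, `cy`, centroid `x`/`y`, counts, `rate`, `z`, `class`)
#'   with global statistics (`n`, `xbar`, `S`) as attributes.
#' @export
gi_star <- function(grid, numerator = "mos", min_support = 10, d_m = NULL) {
  stopifnot(inherits(grid, "hotspot_grid"))
  if (is.null(d_m)) d_m <- 2 * grid$spec$cell_size_m
  cells <- grid_rates(grid, numerator, min_support)
  if (nrow(cells) < 2L) {
    stop(sprintf("Gi* needs >= 2 included cells (got %d at min_support = %g)",
                 nrow(cells), min_support), call. = FALSE)
  }
  W <- distance_band_weights(cells[, c("x", "y")], d_m)
  cells$z <- gi_star_z(cells$rate, W)
  cells$class <- classify_z(cells$z)
  attr(cells, "n") <- nrow(cells)
  attr(cells, "xbar") <- mean(cells$rate)
  attr(cells, "S") <- sqrt(max(mean(cells$rate^2) - mean(cells$rate)^2, 0))
  attr(cells, "spec") <- grid$spec
  attr(cells, "d_m") <- d_m
  class(cells) <- c("gi_star_result", "data.frame")
  cells
}

#' Export classified cells as GeoJSON polygons
#'
#' Writes one polygon feature per included cell (corners unprojected back
#' to WGS84 lon/lat) with the rate, z-score and hot/cold class as
#' properties. Output is deterministic for a given result.
#'
#' @param result A [gi_star()] result.
#' @param path Output `.geojson` path.
#' @return Invisibly, `path`.
#' @export
write_hotspots_geojson <- function(result, path) {
  spec <- attr(result, "spec")
  s <- spec$cell_size_m
  feats <- lapply(seq_len(nrow(result)), function(r) {
    xl <- spec$x0 + (result$cx[r] - 1) * s
    yb <- spec$y0 + (result$cy[r] - 1) * s
    cx <- c(xl, xl + s, xl + s, xl, xl)
    cy <- c(yb, yb, yb + s, yb + s, yb)
    ll <- unproject_utm(cx, cy, spec$zone, spec$hemisphere)
    ring <- lapply(seq_len(5), function(k) c(ll$lon[k], ll$lat[k]))
    list(type = "Feature",
         geometry = list(type = "Polygon", coordinates = list(ring)),
         properties = list(cx = result$cx[r], cy = result$cy[r],
                           n_meas = result$n_meas[r], n_num = result$n_num[r],
                           rate = result$rate[r], z = result$z[r],
                           class = result$class[r]))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA, pretty = FALSE)
  invisible(path)
}

#' Sensor-versus-diary difference map
#'
#' Compares where the wearable sensors and the diary reports place stress:
#' both rate fields are min--max normalized over their own included cells
#' (a constant field normalizes to 0), cells present on only one side are
#' treated as 0 on the missing side, and the signed difference
#' (sensor − diary) is returned per cell. Positive values mark cells where
#' the sensors see relatively more stress than participants report.
#'
#' @param sensor_grid,diary_grid `hotspot_grid`s on the same [grid_spec].
#' @param sensor_layer,diary_layer Numerator layers (defaults `"mos"` and
#'   `"diary_neg"`).
#' @param min_support Minimum sensor samples per included cell.
#' @return Data frame with `cx`, `cy`, `sensor_norm`, `diary_norm`, `diff`.
#' @export
difference_map <- function(sensor_grid, diary_grid, sensor_layer = "mos",
                           diary_layer = "diary_neg", min_support = 10) {
  stopifnot(identical(sensor_grid$spec, diary_grid$spec))
  norm01 <- function(v) {
    rng <- range(v)
    if (diff(rng) == 0) rep(0, length(v)) else (v - rng[1]) / diff(rng)
  }
  a <- grid_rates(sensor_grid, sensor_layer, min_support)
  b <- grid_rates(diary_grid, diary_layer, min_support)
  a$norm <- if (nrow(a)) norm01(a$rate) else numeric(0)
  b$norm <- if (nrow(b)) norm01(b$rate) else numeric(0)
  cells <- sort(union(a$cell, b$cell))
  nx <- sensor_grid$spec$nx
  out <- data.frame(
    cell = cells,
    cx = ((cells - 1L) %% nx) + 1L,
    cy = ((cells - 1L) %/% nx) + 1L)
  out$sensor_norm <- a$norm[match(cells, a$cell)]
  out$diary_norm <- b$norm[match(cells, b$cell)]
  out$sensor_norm[is.na(out$sensor_norm)] <- 0
  out$diary_norm[is.na(out$diary_norm)] <- 0
  out$diff <- out$sensor_norm - out$diary_norm
  out
}

# even-odd ray casting; poly is a closed or open ring, 2 columns
point_in_polygon <- function(px, py, poly) {
  poly <- as.matrix(poly)
  n <- nrow(poly)
  if (all(poly[1, ] == poly[n, ])) { poly <- poly[-n, , drop = FALSE]; n <- n - 1L }
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

count_in_zones <- function(xy, zones) {
  if (is.null(zones)) return(stats::setNames(numeric(0), character(0)))
  vapply(zones, function(poly) {
    sum(point_in_polygon(xy$x, xy$y, poly))
  }, numeric(1))
}

#' Pre-post campaign comparison
#'
#' Compares stress-point totals between two campaigns (e.g. before and
#' after an infrastructure change), overall and per zone, as the percent
#' change `(post - pre) / pre * 100`. In `exposure_rate` mode each count is
#' first divided by its campaign's exposure (measurement-seconds), so
#' unequal campaign durations or participant numbers do not masquerade as
#' stress changes.
#'
#' @param pre,post Either a `list(events = <located points data frame>,
#'   exposure_s = <number>)` or a `hotspot_grid` (counts taken from the
#'   `mos` and `meas` layers; grid exposure is the sample count).
#' @param mode `"raw_counts"` or `"exposure_rate"`.
#' @param zones Optional named list of polygons (two-column lon/lat
#'   matrices) evaluated in addition to the overall extent.
#' @return Data frame of class `campaign_comparison` with one row per zone
#'   (plus `"overall"`): counts, the compared statistic, and `change_pct`.
#' @export
compare_campaigns <- function(pre, post,
                              mode = c("raw_counts", "exposure_rate"),
                              zones = NULL) {
  mode <- match.arg(mode)
  ref_zone <- if (inherits(pre, "hotspot_grid")) {
    list(zone = pre$spec$zone, hemisphere = pre$spec$hemisphere)
  } else NULL
  unpack <- function(obj) {
    if (inherits(obj, "hotspot_grid")) {
      cells <- grid_rates(obj, "mos", min_support = 0)
      list(xy = cells[rep(seq_len(nrow(cells)), cells$n_num),
                      c("x", "y"), drop = FALSE],
           total = sum(obj$mos), exposure = sum(obj$meas))
    } else {
      ev <- obj$events
      if (all(c("x", "y") %in% names(ev))) {
        xy <- ev[, c("x", "y")]
      } else {
        loc <- !is.na(ev$lon) & !is.na(ev$lat)
        if (is.null(ref_zone)) {
          ref_zone <<- utm_zone(mean(ev$lon[loc]), mean(ev$lat[loc]))
        }
        xy <- project_utm(ev$lon[loc], ev$lat[loc],
                          ref_zone$zone, ref_zone$hemisphere)
      }
      list(xy = xy, total = nrow(xy), exposure = obj$exposure_s)
    }
  }
  a <- unpack(pre); b <- unpack(post)
  if (!is.null(zones)) {
    zones <- lapply(zones, function(poly) {
      poly <- as.matrix(poly)
      if (max(abs(poly[, 1])) <= 180 && max(abs(poly[, 2])) <= 90 &&
          !is.null(ref_zone)) {
        p <- project_utm(poly[, 1], poly[, 2],
                         ref_zone$zone, ref_zone$hemisphere)
        cbind(p$x, p$y)
      } else poly
    })
  }
  n_pre <- c(overall = a$total, count_in_zones(a$xy, zones))
  n_post <- c(overall = b$total, count_in_zones(b$xy, zones))
  stat_pre <- if (mode == "exposure_rate") n_pre / a$exposure else n_pre
  stat_post <- if (mode == "exposure_rate") n_post / b$exposure else n_post
  if (any(stat_pre == 0)) {
    stop(sprintf("percent change undefined: pre-campaign statistic is zero in zone(s) %s",
                 paste(names(stat_pre)[stat_pre == 0], collapse = ", ")),
         call. = FALSE)
  }
  out <- data.frame(zone = names(n_pre),
                    n_pre = as.numeric(n_pre), n_post = as.numeric(n_post),
                    stat_pre = as.numeric(stat_pre),
                    stat_post = as.numeric(stat_post),
                    change_pct = as.numeric((stat_post - stat_pre) /
                                              stat_pre * 100),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("campaign_comparison", "data.frame")
  out
}

#' @export
print.campaign_comparison <- function(x, ...) {
  cat("<campaign_comparison>\n")
  for (r in seq_len(nrow(x))) {
    cat(sprintf("  %-12s pre %g  post %g  change %+.1f%%\n",
                x$zone[r], x$stat_pre[r], x$stat_post[r], x$change_pct[r]))
  }
  invisible(x)
}
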