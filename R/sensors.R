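#' Sensor models
#'
#' Construct the three sensor models used to sample synthetic canopy scenes
#' into point clouds. Point densities default to the study values (789, 269
#' and 9 points/cm2 for UAV-SfM, pole-camera SfM and hand-held LiDAR); a
#' `scale` factor applied at sampling time reduces all densities
#' proportionally, preserving their ratio.
#'
#' The SfM model samples the canopy *upper envelope* (tallest blade tip
#' within `envelope_radius`) minus a reconstruction depth: photogrammetry of
#' swaying grass under-resolves leaf tips, so points sit a height-proportional
#' sway depth (`depth_frac` +/- a spatially varying `depth_frac_sd`) plus an
#' exponential sag tail (`tail_frac`) below the envelope. Vertical noise is a
#' spatially correlated field with marginal sd `vertical_jitter_sd` (SfM
#' error is a coherent surface undulation, not white noise). With probability
#' `ground_visible_fraction` (a (pre, post) pair: tall canopy hides the
#' ground before harvest, stubble mostly hides it after) the point is the
#' local ground instead. Setting depth, tail and jitter to zero makes the
#' sampler return the exact envelope.
#'
#' The LiDAR model shoots beams with a finite footprint: within each beam's
#' interception window (footprint inflated by `leaf_reach`) a leaf cover
#' fraction is computed from the local blade area (scaled by `path_factor`
#' for the oblique beam path); with that probability the return is the leaf
#' surface — the *window-mean* tip elevation, the smooth surface that
#' averaging `n_revisits` evaluations of a swaying canopy reconstructs,
#' minus an exponential `penetration_depth` for beams reflecting off lower
#' leaf material — otherwise the beam passes between the leaves and returns
#' the ground. Revisit averaging shrinks the effective ranging noise to
#' `vertical_jitter_sd / sqrt(n_revisits)`. `cover` forces a constant cover
#' fraction (useful for controlled experiments).
#'
#' @param density Points per cm2 at scale 1.
#' @param vertical_jitter_sd Marginal sd of vertical noise (m). For LiDAR
#'   this is the per-evaluation ranging noise before revisit averaging.
#' @param ground_visible_fraction Probability that an SfM point is ground,
#'   as a single value or a (pre-harvest, post-harvest) pair.
#' @param envelope_radius Smoothing radius of the SfM canopy envelope (m).
#' @param depth_frac,depth_frac_sd,depth_correlation_length Mean sway-depth
#'   fraction of local canopy height, its spatial sd, and the correlation
#'   length (m) of the spatial variation.
#' @param tail_frac Mean of the per-point exponential sag tail, as a
#'   fraction of local canopy height.
#' @param jitter_correlation_length Correlation length (m) of the vertical
#'   noise field.
#' @param footprint_xy Beam footprint diameters (m) along x and y.
#' @param n_revisits Number of repeat evaluations averaged per leaf return.
#' @param path_factor Multiplier on leaf area for the oblique beam path.
#' @param leaf_reach How far (m) beyond its base a leaning blade can
#'   intercept a beam; inflates the footprint into the effective
#'   interception window used for both cover and the leaf-return surface.
#' @param penetration_depth Mean of the exponential first-return depth (m)
#'   below the leaf surface: beams entering canopy gaps reflect off lower
#'   leaf material, which drags the per-cell minimum (and, less, the mean)
#'   downward while leaving the per-cell maximum nearly untouched.
#' @param cover Optional constant cover fraction in `[0, 1]` overriding the
#'   scene-derived cover.
#' @param tag Sensor name used to label clouds.
#' @return A `sensor_model` object.
#' @name sensor_models
NULL

#' @rdname sensor_models
#' @export
sensor_sfm <- function(density = 789, vertical_jitter_sd = 0.015,
                       ground_visible_fraction = c(0, 0.1),
                       envelope_radius = 0.025,
                       depth_frac = 0.12, depth_frac_sd = 0.04,
                       depth_correlation_length = 0.3,
                       tail_frac = 0.10,
                       jitter_correlation_length = 0.04,
                       tag = "sfm") {
  stopifnot_scalar_num(density, "density", positive = TRUE)
  stopifnot_scalar_num(vertical_jitter_sd, "vertical_jitter_sd", nonneg = TRUE)
  if (any(ground_visible_fraction < 0 | ground_visible_fraction > 1)) {
    stop("`ground_visible_fraction` must lie in [0, 1]", call. = FALSE)
  }
  if (length(ground_visible_fraction) == 1L) {
    ground_visible_fraction <- rep(ground_visible_fraction, 2L)
  }
  structure(
    list(
      kind = "sfm", tag = tag, density = density,
      vertical_jitter_sd = vertical_jitter_sd,
      ground_visible_fraction = ground_visible_fraction,
      envelope_radius = envelope_radius,
      depth_frac = depth_frac, depth_frac_sd = depth_frac_sd,
      depth_correlation_length = depth_correlation_length,
      tail_frac = tail_frac,
      jitter_correlation_length = jitter_correlation_length
    ),
    class = "sensor_model"
  )
}

#' @rdname sensor_models
#' @export
sensor_lidar <- function(density = 9, vertical_jitter_sd = 0.0045,
                         n_revisits = 5L,
                         footprint_xy = c(0.0318, 0.0200),
                         path_factor = 1.5, leaf_reach = 0.03,
                         penetration_depth = 0.02,
                         cover = NULL, tag = "lidar") {
  stopifnot_scalar_num(density, "density", positive = TRUE)
  stopifnot_scalar_num(vertical_jitter_sd, "vertical_jitter_sd", nonneg = TRUE)
  if (n_revisits < 1) stop("`n_revisits` must be >= 1", call. = FALSE)
  if (!is.null(cover)) {
    stopifnot_scalar_num(cover, "cover", nonneg = TRUE)
    if (cover > 1) stop("`cover` must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(
      kind = "lidar", tag = tag, density = density,
      vertical_jitter_sd = vertical_jitter_sd,
      n_revisits = as.integer(n_revisits),
      footprint_xy = footprint_xy, path_factor = path_factor,
      leaf_reach = leaf_reach, penetration_depth = penetration_depth,
      cover = cover
    ),
    class = "sensor_model"
  )
}

#' @rdname sensor_models
#' @export
sensor_uav_sfm <- function() {
  sensor_sfm(density = 789, vertical_jitter_sd = 0.015, tag = "uav_sfm")
}

#' @rdname sensor_models
#' @export
sensor_pole_sfm <- function() {
  sensor_sfm(density = 269, vertical_jitter_sd = 0.008, tag = "pole_sfm")
}

#' @rdname sensor_models
#' @export
sensor_hand_lidar <- function() sensor_lidar(tag = "lidar")

#' @export
print.sensor_model <- function(x, ...) {
  cat(sprintf("<sensor_model> %s (%s), %.0f pts/cm2\n", x$tag, x$kind,
              x$density))
  invisible(x)
}

# ---- canopy surface rasters used by the samplers -------------------------

# Max blade-tip elevation within an elliptical neighbourhood, on an
# auxiliary grid; cells with no blade in reach fall back to the ground.
envelope_grid <- function(scene, radius_x, radius_y = radius_x, res = 0.005) {
  ext <- layout_extent(scene$layout)
  nx <- max(1L, as.integer(ceiling((ext["xmax"] - ext["xmin"]) / res)))
  ny <- max(1L, as.integer(ceiling((ext["ymax"] - ext["ymin"]) / res)))
  m <- matrix(-Inf, nrow = ny, ncol = nx)
  blades <- scene$blades
  if (nrow(blades) > 0) {
    gz <- ground_height(scene$ground, blades$x, blades$y)
    zt <- gz + blades$tip_height
    jx <- pmin(pmax(floor((blades$x - ext["xmin"]) / res), 0), nx - 1L)
    iy <- pmin(pmax(floor((blades$y - ext["ymin"]) / res), 0), ny - 1L)
    dt <- data.table::data.table(i = as.integer(iy), j = as.integer(jx), z = zt)
    agg <- dt[, .(z = max(z)), by = c("i", "j")]
    m[cbind(agg$i + 1L, agg$j + 1L)] <- agg$z
  }
  rx <- max(0L, as.integer(round(radius_x / res)))
  ry <- max(0L, as.integer(round(radius_y / res)))
  m <- dilate_max(m, rx, ry, res, radius_x, radius_y)
  # empty neighbourhoods: canopy absent, surface falls to ground
  if (any(!is.finite(m))) {
    centers_x <- ext["xmin"] + (seq_len(nx) - 0.5) * res
    centers_y <- ext["ymin"] + (seq_len(ny) - 0.5) * res
    miss <- which(!is.finite(m), arr.ind = TRUE)
    m[miss] <- ground_height(scene$ground,
                             centers_x[miss[, 2]], centers_y[miss[, 1]])
  }
  list(values = m, x0 = unname(ext["xmin"]), y0 = unname(ext["ymin"]),
       res = res, nx = nx, ny = ny)
}

# grey-scale dilation by an elliptical structuring element (shift + pmax)
dilate_max <- function(m, rx, ry, res, radius_x, radius_y) {
  if (rx == 0 && ry == 0) return(m)
  ny <- nrow(m); nx <- ncol(m)
  big <- matrix(-Inf, ny + 2 * ry, nx + 2 * rx)
  big[ry + seq_len(ny), rx + seq_len(nx)] <- m
  out <- matrix(-Inf, ny, nx)
  for (dy in -ry:ry) {
    for (dx in -rx:rx) {
      if ((dx * res / max(radius_x, res / 2))^2 +
          (dy * res / max(radius_y, res / 2))^2 > 1 + 1e-9) next
      out <- pmax(out, big[ry + dy + seq_len(ny), rx + dx + seq_len(nx)])
    }
  }
  out
}

grid_lookup <- function(g, x, y) {
  j <- pmin(pmax(floor((x - g$x0) / g$res), 0), g$nx - 1L)
  i <- pmin(pmax(floor((y - g$y0) / g$res), 0), g$ny - 1L)
  g$values[cbind(as.integer(i) + 1L, as.integer(j) + 1L)]
}

box_sum <- function(m, rx, ry) {
  ny0 <- nrow(m); nx0 <- ncol(m)
  big <- matrix(0, ny0 + 2 * ry, nx0 + 2 * rx)
  big[ry + seq_len(ny0), rx + seq_len(nx0)] <- m
  s <- matrix(0, ny0, nx0)
  for (dy in -ry:ry) {
    for (dx in -rx:rx) {
      s <- s + big[ry + dy + seq_len(ny0), rx + dx + seq_len(nx0)]
    }
  }
  s
}

# Per-beam statistics of the interception window (footprint inflated by
# leaf_reach), on an auxiliary grid: leaf area index (blade width x blade
# length ~ tip height, per unit ground area), giving the cover fraction
# 1 - exp(-path_factor * lai), and the window-mean leaf-tip elevation — the
# smooth surface that revisit averaging reconstructs.
lidar_window_stats <- function(scene, sensor, res = 0.01) {
  half <- interception_half_widths(sensor)
  ext <- layout_extent(scene$layout)
  nx <- max(1L, as.integer(ceiling((ext["xmax"] - ext["xmin"]) / res)))
  ny <- max(1L, as.integer(ceiling((ext["ymax"] - ext["ymin"]) / res)))
  area_m <- cnt_m <- tip_m <- matrix(0, nrow = ny, ncol = nx)
  blades <- scene$blades
  if (nrow(blades) > 0) {
    gz <- ground_height(scene$ground, blades$x, blades$y)
    jx <- pmin(pmax(floor((blades$x - ext["xmin"]) / res), 0), nx - 1L)
    iy <- pmin(pmax(floor((blades$y - ext["ymin"]) / res), 0), ny - 1L)
    dt <- data.table::data.table(
      i = as.integer(iy), j = as.integer(jx),
      a = blades$width * blades$tip_height, zt = gz + blades$tip_height
    )
    agg <- dt[, .(a = sum(a), zt = sum(zt), n = .N), by = c("i", "j")]
    idx <- cbind(agg$i + 1L, agg$j + 1L)
    area_m[idx] <- agg$a
    tip_m[idx] <- agg$zt
    cnt_m[idx] <- agg$n
  }
  rx <- max(1L, as.integer(round(half[1] / res)))
  ry <- max(1L, as.integer(round(half[2] / res)))
  s_area <- box_sum(area_m, rx, ry)
  s_tip <- box_sum(tip_m, rx, ry)
  s_cnt <- box_sum(cnt_m, rx, ry)
  lai <- s_area / ((2 * rx + 1) * (2 * ry + 1) * res^2)
  mean_tip <- ifelse(s_cnt > 0, s_tip / pmax(s_cnt, 1), -Inf)
  base <- list(x0 = unname(ext["xmin"]), y0 = unname(ext["ymin"]),
               res = res, nx = nx, ny = ny)
  list(
    cover = c(base, list(values = 1 - exp(-sensor$path_factor * lai))),
    surface = c(base, list(values = mean_tip))
  )
}

# ---- samplers -------------------------------------------------------------

#' Sample a canopy scene into a point cloud
#'
#' `sample_cloud()` dispatches on the sensor kind; `sample_sfm()` and
#' `sample_lidar()` are the two concrete samplers. The realized point count
#' is `round(density * scale * plot area in cm2)`.
#'
#' @param scene A `canopy_scene`.
#' @param sensor A [sensor_sfm()] or [sensor_lidar()] model.
#' @param scale Density scale factor (1 = full study density).
#' @param seed Integer seed; pre- and post-harvest clouds from the same seed
#'   use distinct substreams.
#' @return A `point_cloud`: a tibble with `x`, `y`, `z` in metres and
#'   attributes `sensor_tag` and `epoch`.
#' @export
sample_cloud <- function(scene, sensor, scale = 1, seed = 1L) {
  stopifnot(inherits(sensor, "sensor_model"))
  switch(sensor$kind,
    sfm = sample_sfm(scene, sensor, scale, seed),
    lidar = sample_lidar(scene, sensor, scale, seed),
    stop("unknown sensor kind: ", sensor$kind)
  )
}

epoch_seed <- function(seed, stream, state) {
  s <- substream_seed(seed, stream)
  as.integer((as.numeric(s) + (state == "post_harvest") * 104729) %% 2147483647)
}

new_point_cloud <- function(x, y, z, sensor_tag, epoch) {
  out <- tibble(x = x, y = y, z = z)
  attr(out, "sensor_tag") <- sensor_tag
  attr(out, "epoch") <- epoch
  class(out) <- c("point_cloud", class(out))
  out
}

#' @rdname sample_cloud
#' @export
sample_sfm <- function(scene, sensor, scale = 1, seed = 1L) {
  stopifnot(inherits(scene, "canopy_scene"), inherits(sensor, "sensor_model"))
  if (sensor$kind != "sfm") stop("sample_sfm() needs an sfm sensor",
                                 call. = FALSE)
  area_cm2 <- (scene$layout$n_per_side * scene$layout$subplot_side * 100)^2
  n <- round(sensor$density * scale * area_cm2)
  ext <- layout_extent(scene$layout)
  env <- envelope_grid(scene, sensor$envelope_radius)
  gvf <- sensor$ground_visible_fraction[
    if (scene$state == "post_harvest") 2L else 1L
  ]
  sd_j <- sensor$vertical_jitter_sd
  need_fields <- sd_j > 0 || sensor$depth_frac_sd > 0
  s <- epoch_seed(seed, "sfm", scene$state)
  jf <- df <- NULL
  if (need_fields) {
    jf <- gaussian_field(ext[c("xmin", "xmax")], ext[c("ymin", "ymax")],
                         corr_len = sensor$jitter_correlation_length,
                         seed = epoch_seed(seed, "jitter", scene$state))
    df <- gaussian_field(ext[c("xmin", "xmax")], ext[c("ymin", "ymax")],
                         corr_len = sensor$depth_correlation_length,
                         seed = epoch_seed(seed, "sfm_depth", scene$state))
  }
  with_seed(s, {
    x <- runif(n, ext["xmin"], ext["xmax"])
    y <- runif(n, ext["ymin"], ext["ymax"])
    g <- ground_height(scene$ground, x, y)
    e <- grid_lookup(env, x, y)
    h_env <- pmax(e - g, 0)
    dfrac <- sensor$depth_frac
    if (!is.null(df) && sensor$depth_frac_sd > 0) {
      dfrac <- pmax(dfrac + sensor$depth_frac_sd * field_at(df, x, y), 0)
    }
    depth <- h_env * dfrac
    if (sensor$tail_frac > 0) {
      depth <- depth + rexp(n) * (sensor$tail_frac * h_env)
    }
    z <- pmax(e - depth, g)
    if (sd_j > 0) {
      z <- z + sd_j * (sqrt(0.9) * field_at(jf, x, y) +
                         sqrt(0.1) * rnorm(n))
    }
    if (gvf > 0) {
      is_ground <- runif(n) < gvf
      z[is_ground] <- g[is_ground]
    }
    new_point_cloud(x, y, z, sensor$tag, scene$state)
  })
}

#' @rdname sample_cloud
#' @export
sample_lidar <- function(scene, sensor, scale = 1, seed = 1L) {
  stopifnot(inherits(scene, "canopy_scene"), inherits(sensor, "sensor_model"))
  if (sensor$kind != "lidar") stop("sample_lidar() needs a lidar sensor",
                                   call. = FALSE)
  area_cm2 <- (scene$layout$n_per_side * scene$layout$subplot_side * 100)^2
  n <- round(sensor$density * scale * area_cm2)
  ext <- layout_extent(scene$layout)
  stats <- if (nrow(scene$blades) > 0) lidar_window_stats(scene, sensor)
  with_seed(epoch_seed(seed, "lidar", scene$state), {
    x <- runif(n, ext["xmin"], ext["xmax"])
    y <- runif(n, ext["ymin"], ext["ymax"])
    g <- ground_height(scene$ground, x, y)
    cov <- if (!is.null(sensor$cover)) {
      rep(sensor$cover, n)
    } else if (is.null(stats)) {
      rep(0, n)
    } else {
      grid_lookup(stats$cover, x, y)
    }
    hit_leaf <- runif(n) < cov
    sd_eff <- sensor$vertical_jitter_sd / sqrt(sensor$n_revisits)
    z <- g
    if (any(hit_leaf)) {
      zl <- if (is.null(stats)) g else grid_lookup(stats$surface, x, y)
      zl[!is.finite(zl)] <- g[!is.finite(zl)]   # no blade in reach
      if (sensor$penetration_depth > 0) {
        # first-return depth: beams entering canopy gaps reflect off lower
        # leaf material before reaching the window-mean surface
        zl <- zl - rexp(n) * sensor$penetration_depth
      }
      z[hit_leaf] <- pmax(zl, g)[hit_leaf]
    }
    if (sd_eff > 0) z <- z + rnorm(n, 0, sd_eff)
    new_point_cloud(x, y, z, sensor$tag, scene$state)
  })
}

interception_half_widths <- function(sensor) {
  reach <- sensor$leaf_reach %||% 0
  c(sensor$footprint_xy[1] / 2 + reach, sensor$footprint_xy[2] / 2 + reach)
}
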