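# Fixture builders and independent oracles shared across test files.

# a small 1 x 1 subplot layout (0.5 m plot) for cheap sensor tests
small_layout <- function(subplots = 1L, subplot_side = 0.5, crop = 0.3) {
  make_layout(plot_side = subplots * subplot_side, n_per_side = subplots,
              subplot_side = subplot_side, crop_side = crop)
}

flat_ground <- function(layout) generate_ground(layout, relief_sd = 0)

# a perfectly uniform canopy: flat ground, every tip at `height_mm`
constant_scene <- function(layout = small_layout(), height_mm = 400,
                           blades_per_m2 = 20000, seed = 1L) {
  generate_canopy(flat_ground(layout), layout,
                  subplot_mean_heights = height_mm, height_cv = 0,
                  blades_per_m2 = blades_per_m2, seed = seed)
}

# a noise-free SfM sensor: pure canopy-envelope sampler
ideal_sfm <- function(density = 100, gvf = 0) {
  sensor_sfm(density = density, vertical_jitter_sd = 0,
             ground_visible_fraction = gvf, depth_frac = 0,
             depth_frac_sd = 0, tail_frac = 0)
}

# a noise-free LiDAR with forced cover
ideal_lidar <- function(density = 100, cover = NULL) {
  sensor_lidar(density = density, vertical_jitter_sd = 0,
               penetration_depth = 0, cover = cover)
}

random_cloud <- function(n, extent = c(0, 1, 0, 1), zlim = c(0, 0.6),
                         seed = 1L) {
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    code
  }
  withr_seed({
    tibble::tibble(
      x = runif(n, extent[1], extent[2]),
      y = runif(n, extent[3], extent[4]),
      z = runif(n, zlim[1], zlim[2])
    )
  })
}

# independent rasterizer oracle: an explicit per-point loop
brute_force_dsm <- function(cloud, grid, aggregator) {
  acc <- vector("list", grid$n_rows * grid$n_cols)
  for (k in seq_len(nrow(cloud))) {
    j <- floor((cloud$x[k] - grid$origin_xy[1]) / grid$cell_size)
    i <- floor((cloud$y[k] - grid$origin_xy[2]) / grid$cell_size)
    if (i < 0 || i >= grid$n_rows || j < 0 || j >= grid$n_cols) next
    idx <- i * grid$n_cols + j + 1
    acc[[idx]] <- c(acc[[idx]], cloud$z[k])
  }
  f <- switch(aggregator, max = max, mean = mean, min = min)
  m <- matrix(NA_real_, grid$n_rows, grid$n_cols)
  for (i in seq_len(grid$n_rows)) {
    for (j in seq_len(grid$n_cols)) {
      vals <- acc[[(i - 1) * grid$n_cols + j]]
      if (!is.null(vals)) m[i, j] <- f(vals)
    }
  }
  m
}

# independent crop-membership oracle for subplot summaries
brute_force_subplot_mean <- function(raster, layout) {
  lt <- tidy(layout)
  cells <- tidy(raster)
  out <- numeric(0)
  ids <- integer(0)
  for (k in seq_len(nrow(lt))) {
    sel <- cells$x >= lt$crop_xmin[k] & cells$x < lt$crop_xmax[k] &
      cells$y >= lt$crop_ymin[k] & cells$y < lt$crop_ymax[k]
    if (any(sel)) {
      ids <- c(ids, lt$subplot_id[k])
      out <- c(out, mean(cells$estimate_mm[sel]))
    }
  }
  tibble::tibble(subplot_id = ids, estimate_mm = out)
}

# a deterministic two-cell DSM from explicit per-cell values (metres)
tiny_dsm <- function(values, aggregator, cell_size = 0.1) {
  grid <- make_grid(c(0, cell_size * length(values), 0, cell_size), cell_size)
  d <- rasterize(tibble::tibble(x = numeric(), y = numeric(), z = numeric()),
                 grid, aggregator)
  d$values[1, ] <- values
  d
}
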