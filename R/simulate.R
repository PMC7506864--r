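#' Simulate one complete measurement campaign
#'
#' Builds a plot (ground + canopy), measures the ruler truth, samples every
#' sensor before harvest, harvests to stubble, and samples every sensor
#' again — the full field sequence — returning everything downstream stages
#' need.
#'
#' Subplot mean heights, unless supplied, are drawn once per scene from a
#' lognormal with mean `mean_height_mm` and between-subplot coefficient of
#' variation `between_subplot_cv` (real swards vary plot-to-plot far more
#' than within a 0.5 m subplot).
#'
#' @param sensors Named list of [sensor_models]. Defaults to the three
#'   study sensors.
#' @param layout A [make_layout()] geometry.
#' @param scale Density scale factor passed to the samplers.
#' @param seed Integer seed controlling every random stage.
#' @param mean_height_mm,between_subplot_cv Distribution of subplot mean
#'   heights (mm).
#' @param subplot_mean_heights_mm Optional explicit per-subplot means,
#'   overriding the draw.
#' @param height_cv,blades_per_m2,leaf_width,relief_sd,stubble_height,n_probes
#'   Passed to the scene generators (see [generate_canopy()],
#'   [generate_ground()], [harvest()], [ruler_truth()]).
#' @return A list with `scene_before`, `scene_after`, `truth`, `clouds`
#'   (per sensor: list(before, after)), and `layout`.
#' @export
simulate_study <- function(sensors = default_sensors(),
                           layout = make_layout(), scale = 0.01, seed = 1L,
                           mean_height_mm = 400, between_subplot_cv = 0.25,
                           subplot_mean_heights_mm = NULL,
                           height_cv = 0.08, blades_per_m2 = 1500,
                           leaf_width = 0.010, relief_sd = 0.010,
                           stubble_height = 0.030, n_probes = 5L) {
  n_sub <- layout$n_per_side^2
  if (is.null(subplot_mean_heights_mm)) {
    sigma <- sqrt(log(1 + between_subplot_cv^2))
    subplot_mean_heights_mm <- with_seed(
      substream_seed(seed, "subplot_means"),
      rlnorm(n_sub, log(mean_height_mm) - sigma^2 / 2, sigma)
    )
  }
  ground <- generate_ground(layout, relief_sd = relief_sd, seed = seed)
  scene <- generate_canopy(
    ground, layout, subplot_mean_heights = subplot_mean_heights_mm,
    height_cv = height_cv, blades_per_m2 = blades_per_m2,
    leaf_width = leaf_width, seed = seed
  )
  truth <- ruler_truth(scene, n_probes = n_probes, seed = seed)
  scene_after <- harvest(scene, stubble_height)
  clouds <- purrr::map(sensors, function(sen) {
    list(
      before = sample_cloud(scene, sen, scale = scale, seed = seed),
      after = sample_cloud(scene_after, sen, scale = scale, seed = seed)
    )
  })
  list(scene_before = scene, scene_after = scene_after, truth = truth,
       clouds = clouds, layout = layout)
}

#' The three study sensor models
#' @return Named list: `uav_sfm`, `pole_sfm`, `lidar`.
#' @export
default_sensors <- function() {
  list(uav_sfm = sensor_uav_sfm(), pole_sfm = sensor_pole_sfm(),
       lidar = sensor_hand_lidar())
}

#' Replicated method x resolution x sensor evaluation
#'
#' Simulates `n_replicates` independent scenes, runs the full sweep on each,
#' and returns the pooled per-subplot table with a `replicate` column.
#' Qualitative conclusions (which method wins, where the LiDAR optimum sits)
#' are drawn from replicate means, not single scenes.
#'
#' @inheritParams simulate_study
#' @param n_replicates Number of independent scenes.
#' @param cell_sizes_mm,methods Passed to [run_sweep()].
#' @param ... Passed on to [simulate_study()].
#' @return A `sweep_table` with a `replicate` column.
#' @export
run_replicates <- function(n_replicates = 5L, sensors = default_sensors(),
                           layout = make_layout(), scale = 0.1, seed = 1L,
                           cell_sizes_mm = c(5, 10, 20, 30, 40, 50, 100),
                           methods = names(height_methods()), ...) {
  purrr::map_dfr(seq_len(n_replicates), function(r) {
    rep_seed <- as.integer(
      (as.numeric(substream_seed(seed, "replicate")) + r * 7919) %% 2147483647
    )
    sim <- simulate_study(sensors = sensors, layout = layout, scale = scale,
                          seed = rep_seed, ...)
    run_sweep(sim$clouds, layout, sim$truth, methods = methods,
              cell_sizes_mm = cell_sizes_mm) |>
      mutate(replicate = r)
  })
}

#' Replicate-mean MAE per configuration
#'
#' @param sweep A [run_replicates()] table.
#' @return One row per (sensor, method, cell_size_mm) with `mean_mae_mm`
#'   (mean over replicate MAEs), `sd_mae_mm` and `n_replicates`.
#' @export
replicate_mean_mae <- function(sweep) {
  sweep |>
    as_tibble() |>
    group_by(.data$sensor, .data$method, .data$cell_size_mm,
             .data$replicate) |>
    summarise(mae_mm = mean(.data$abs_error_mm), .groups = "drop") |>
    group_by(.data$sensor, .data$method, .data$cell_size_mm) |>
    summarise(
      mean_mae_mm = mean(.data$mae_mm),
      sd_mae_mm = sd(.data$mae_mm),
      n_replicates = dplyr::n(),
      .groups = "drop"
    )
}
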