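#' Generate the ground surface of a synthetic plot
#'
#' Produces a smooth, almost-flat random elevation field (mean ~0) emulating
#' a levelled grassland site. Elevations are a stationary Gaussian random
#' field with marginal standard deviation `relief_sd` and correlation length
#' `correlation_length`, deterministic for a given seed.
#'
#' @param layout A [make_layout()] object; the field covers its extent.
#' @param relief_sd Standard deviation of ground elevation (m). `0` gives a
#'   perfectly flat plot.
#' @param correlation_length Spatial correlation length of the relief (m).
#' @param seed Integer seed.
#' @return A `ground_model`; evaluate it with [ground_height()].
#' @export
generate_ground <- function(layout, relief_sd = 0.010,
                            correlation_length = 1.0, seed = 1L) {
  stopifnot(inherits(layout, "subplot_layout"))
  stopifnot_scalar_num(relief_sd, "relief_sd", nonneg = TRUE)
  stopifnot_scalar_num(correlation_length, "correlation_length",
                       positive = TRUE)
  ext <- layout_extent(layout)
  field <- NULL
  if (relief_sd > 0) {
    field <- gaussian_field(
      xlim = ext[c("xmin", "xmax")], ylim = ext[c("ymin", "ymax")],
      corr_len = correlation_length, seed = substream_seed(seed, "ground")
    )
  }
  structure(
    list(
      relief_sd = relief_sd, correlation_length = correlation_length,
      seed = seed, field = field
    ),
    class = "ground_model"
  )
}

#' Ground elevation at given coordinates
#'
#' @param ground A [generate_ground()] model.
#' @param x,y Coordinates (m).
#' @return Elevations in metres.
#' @export
ground_height <- function(ground, x, y) {
  stopifnot(inherits(ground, "ground_model"))
  if (is.null(ground$field)) return(rep(0, length(x)))
  ground$relief_sd * field_at(ground$field, x, y)
}

#' Populate a plot with grass blades
#'
#' Blades are placed uniformly at random within each subplot. Tip heights
#' (above local ground) are marginally lognormal with the requested subplot
#' mean and coefficient of variation; spatial coherence of sward height is
#' induced through a Gaussian-copula random field (correlation length
#' `height_correlation_length`, nugget fraction `height_nugget`), so
#' neighbouring blades have similar heights while each subplot keeps its
#' stated mean exactly in expectation.
#'
#' @param ground A [generate_ground()] model.
#' @param layout A [make_layout()] object.
#' @param subplot_mean_heights Mean tip height per subplot, in mm
#'   (one value per subplot, or one recycled value).
#' @param height_cv Within-subplot coefficient of variation of tip height.
#'   `0` makes every blade exactly the subplot mean.
#' @param blades_per_m2 Blade density (count per square metre).
#' @param leaf_width Blade width in metres (default the 10 mm leaf of an
#'   Italian ryegrass sward).
#' @param height_correlation_length,height_nugget Spatial structure of the
#'   height copula (m; fraction of variance that is independent per blade).
#' @param seed Integer seed.
#' @return A `canopy_scene` in the `pre_harvest` state; `tidy()` it for the
#'   blade table.
#' @export
generate_canopy <- function(ground, layout, subplot_mean_heights = 400,
                            height_cv = 0.08, blades_per_m2 = 1500,
                            leaf_width = 0.010,
                            height_correlation_length = 0.15,
                            height_nugget = 0.2, seed = 1L) {
  stopifnot(inherits(ground, "ground_model"), inherits(layout, "subplot_layout"))
  stopifnot_scalar_num(height_cv, "height_cv", nonneg = TRUE)
  stopifnot_scalar_num(blades_per_m2, "blades_per_m2", positive = TRUE)
  stopifnot_scalar_num(leaf_width, "leaf_width", positive = TRUE)
  n_sub <- layout$n_per_side^2
  if (length(subplot_mean_heights) == 1L) {
    subplot_mean_heights <- rep(subplot_mean_heights, n_sub)
  }
  if (length(subplot_mean_heights) != n_sub) {
    stop("`subplot_mean_heights` must have one value per subplot (",
         n_sub, ")", call. = FALSE)
  }
  if (any(!is.finite(subplot_mean_heights) | subplot_mean_heights <= 0)) {
    stop("subplot mean heights must be positive", call. = FALSE)
  }

  subs <- tidy(layout)
  n_blades_sub <- round(blades_per_m2 * layout$subplot_side^2)

  blades <- with_seed(substream_seed(seed, "canopy"), {
    bx <- runif(n_blades_sub * n_sub)
    by <- runif(n_blades_sub * n_sub)
    sub_id <- rep(subs$subplot_id, each = n_blades_sub)
    x <- subs$xmin[sub_id] + bx * layout$subplot_side
    y <- subs$ymin[sub_id] + by * layout$subplot_side
    az <- runif(length(x), 0, 2 * pi)
    nug <- rnorm(length(x))
    tibble(subplot_id = sub_id, x = x, y = y, azimuth = az, nugget = nug)
  })

  sigma_log <- sqrt(log(1 + height_cv^2))
  if (height_cv > 0) {
    spat <- gaussian_field(
      xlim = range(subs$xmin, subs$xmax), ylim = range(subs$ymin, subs$ymax),
      corr_len = height_correlation_length,
      seed = substream_seed(seed, "depth")
    )
    zstd <- sqrt(1 - height_nugget) * field_at(spat, blades$x, blades$y) +
      sqrt(height_nugget) * blades$nugget
  } else {
    zstd <- rep(0, nrow(blades))
  }
  mu_log <- log(subplot_mean_heights[blades$subplot_id] / 1000) - sigma_log^2 / 2
  tip <- exp(mu_log + sigma_log * zstd)

  blades <- blades |>
    mutate(tip_height = tip, width = leaf_width) |>
    select("subplot_id", "x", "y", "tip_height", "width", "azimuth")

  structure(
    list(
      ground = ground, layout = layout, blades = blades,
      state = "pre_harvest", stubble_height = NA_real_,
      subplot_mean_heights = subplot_mean_heights,
      height_cv = height_cv, leaf_width = leaf_width, seed = seed
    ),
    class = "canopy_scene"
  )
}

#' @export
print.canopy_scene <- function(x, ...) {
  cat(sprintf(
    "<canopy_scene> %s, %d blades over %.2f m plot (mean tip %.0f mm)\n",
    x$state, nrow(x$blades), x$layout$plot_side,
    mean(x$blades$tip_height) * 1000
  ))
  invisible(x)
}

#' @describeIn generate_canopy Blade table (one row per blade; tip heights
#'   in metres above local ground).
#' @param x A `canopy_scene`.
#' @param ... Unused.
#' @export
tidy.canopy_scene <- function(x, ...) as_tibble(x$blades)

#' Harvest the canopy to a fixed stubble height
#'
#' Cuts every blade to `stubble_height` above the local ground (the study
#' harvested at 3 cm). Blade count and positions are unchanged; only tip
#' heights are reduced.
#'
#' @param scene A pre-harvest `canopy_scene`.
#' @param stubble_height Residual height in metres.
#' @return A new `canopy_scene` in the `post_harvest` state.
#' @export
harvest <- function(scene, stubble_height = 0.030) {
  stopifnot(inherits(scene, "canopy_scene"))
  if (scene$state != "pre_harvest") {
    stop("scene is already harvested", call. = FALSE)
  }
  stopifnot_scalar_num(stubble_height, "stubble_height", positive = TRUE)
  if (stubble_height >= min(scene$blades$tip_height)) {
    stop("`stubble_height` must be below the shortest blade tip", call. = FALSE)
  }
  out <- scene
  out$blades$tip_height <- rep(stubble_height, nrow(scene$blades))
  out$state <- "post_harvest"
  out$stubble_height <- stubble_height
  out
}

#' Ruler ground truth per subplot
#'
#' Emulates the field protocol: within each subplot, measure the height of
#' `n_probes` randomly chosen blades with a ruler and average them.
#'
#' @param scene A pre-harvest `canopy_scene`.
#' @param n_probes Number of probes per subplot (field protocol: 5).
#' @param seed Integer seed.
#' @return A tibble (class `truth_table`) with `subplot_id`, `height_mm`,
#'   `n_probes`.
#' @export
ruler_truth <- function(scene, n_probes = 5L, seed = 1L) {
  stopifnot(inherits(scene, "canopy_scene"))
  if (scene$state != "pre_harvest") {
    stop("ruler truth is measured before harvest", call. = FALSE)
  }
  if (n_probes < 1) stop("`n_probes` must be >= 1", call. = FALSE)
  blades <- scene$blades
  out <- with_seed(substream_seed(seed, "ruler"), {
    blades |>
      group_by(.data$subplot_id) |>
      summarise(
        height_mm = {
          tips <- .data$tip_height
          if (length(tips) < n_probes) {
            warning("subplot has fewer blades than probes; sampling with ",
                    "replacement", call. = FALSE)
            mean(sample(tips, n_probes, replace = TRUE)) * 1000
          } else if (n_probes >= length(tips)) {
            mean(tips) * 1000
          } else {
            mean(sample(tips, n_probes)) * 1000
          }
        },
        .groups = "drop"
      )
  })
  out$n_probes <- as.integer(n_probes)
  class(out) <- c("truth_table", class(out))
  out
}
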