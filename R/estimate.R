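#' The four per-cell height-selection methods
#'
#' Canopy height is estimated cellwise as (before-harvest DSM) minus
#' (after-harvest DSM). The four legal selection rules pair the per-cell
#' aggregators of the two epochs:
#'
#' * `maximum`: max before − max after
#' * `average`: mean before − mean after
#' * `minimum`: min before − min after
#' * `maximum_minimum`: max before − min after (leaf-tip surface minus
#'   ground surface — the study's most accurate rule)
#'
#' @param name One of the four method names above.
#' @return A `method_tag` with fields `name`, `aggregator_before`,
#'   `aggregator_after`.
#' @export
height_method <- function(name = c("maximum_minimum", "maximum", "average",
                                   "minimum")) {
  name <- match.arg(name)
  aggs <- switch(name,
    maximum = c("max", "max"),
    average = c("mean", "mean"),
    minimum = c("min", "min"),
    maximum_minimum = c("max", "min")
  )
  structure(
    list(name = name, aggregator_before = aggs[1], aggregator_after = aggs[2]),
    class = "method_tag"
  )
}

#' All four selection methods
#' @return A named list of [height_method()] tags.
#' @export
height_methods <- function() {
  nm <- c("maximum", "average", "minimum", "maximum_minimum")
  setNames(lapply(nm, height_method), nm)
}

#' Estimate canopy height by DSM differencing
#'
#' Computes the cellwise difference (before − after) in millimetres under a
#' selection method. The DSM aggregators must match the method's pair and
#' the grids must be identical. A cell is nodata if it is nodata in either
#' epoch. Negative estimates are retained (clipping would bias the methods
#' differently) and counted.
#'
#' @param dsm_before,dsm_after [rasterize()] outputs for the pre- and
#'   post-harvest clouds on the same grid.
#' @param method A [height_method()] tag or its name.
#' @return A `height_raster`: matrix of per-cell heights (mm), grid, method,
#'   and `n_negative` count. `tidy()` it for a cell-level tibble.
#' @export
estimate_height <- function(dsm_before, dsm_after, method = "maximum_minimum") {
  stopifnot(inherits(dsm_before, "dsm"), inherits(dsm_after, "dsm"))
  if (is.character(method)) method <- height_method(method)
  stopifnot(inherits(method, "method_tag"))
  if (!grids_identical(dsm_before$grid, dsm_after$grid)) {
    stop("before/after DSMs are on different grids", call. = FALSE)
  }
  if (dsm_before$aggregator != method$aggregator_before) {
    stop("method `", method$name, "` needs a ", method$aggregator_before,
         "-aggregated before-harvest DSM, got ", dsm_before$aggregator,
         call. = FALSE)
  }
  if (dsm_after$aggregator != method$aggregator_after) {
    stop("method `", method$name, "` needs a ", method$aggregator_after,
         "-aggregated after-harvest DSM, got ", dsm_after$aggregator,
         call. = FALSE)
  }
  vals <- (dsm_before$values - dsm_after$values) * 1000
  structure(
    list(values = vals, grid = dsm_before$grid, method = method,
         n_negative = sum(vals < 0, na.rm = TRUE)),
    class = "height_raster"
  )
}

#' @export
print.height_raster <- function(x, ...) {
  cat(sprintf(
    "<height_raster> %s method, %d x %d cells (%.0f mm), %d negative cells\n",
    x$method$name, x$grid$n_rows, x$grid$n_cols, x$grid$cell_size * 1000,
    x$n_negative
  ))
  invisible(x)
}

#' @describeIn estimate_height Cell-level tibble of estimates (mm).
#' @param x A `height_raster`.
#' @param ... Unused.
#' @export
tidy.height_raster <- function(x, ...) {
  g <- x$grid
  idx <- which(!is.na(x$values), arr.ind = TRUE)
  vals <- x$values[idx]
  tibble(
    row_i = idx[, 1] - 1L, col_j = idx[, 2] - 1L,
    x = g$origin_xy[1] + (idx[, 2] - 0.5) * g$cell_size,
    y = g$origin_xy[2] + (idx[, 1] - 0.5) * g$cell_size,
    estimate_mm = vals
  ) |>
    arrange(.data$row_i, .data$col_j)
}

#' Summarise a height raster per subplot over the center crop
#'
#' For each subplot, averages the unmasked cell estimates whose cell
#' *centers* fall inside the centered crop window (half-open membership on
#' the crop boundary). Subplots with no valid cell are excluded with a
#' warning.
#'
#' @param raster An [estimate_height()] result.
#' @param layout A [make_layout()] object covered by the raster grid.
#' @return A tibble with `subplot_id`, `estimate_mm`, `n_valid_cells`,
#'   `method`, `cell_size_mm`.
#' @export
subplot_summary <- function(raster, layout) {
  stopifnot(inherits(raster, "height_raster"),
            inherits(layout, "subplot_layout"))
  g <- raster$grid
  ext <- layout_extent(layout)
  if (g$origin_xy[1] > ext["xmin"] + 1e-9 || g$origin_xy[2] > ext["ymin"] + 1e-9 ||
      g$origin_xy[1] + g$n_cols * g$cell_size < ext["xmax"] - 1e-9 ||
      g$origin_xy[2] + g$n_rows * g$cell_size < ext["ymax"] - 1e-9) {
    stop("raster grid does not cover the layout extent", call. = FALSE)
  }
  cells <- tidy(raster)
  subs <- tidy(layout)
  margin_lo <- (layout$subplot_side - layout$crop_side) / 2
  # crop membership by cell center, half-open on the crop boundary
  sub_id <- subplot_index(layout, cells$x, cells$y)
  keep <- !is.na(sub_id)
  cells <- cells[keep, , drop = FALSE]
  sub_id <- sub_id[keep]
  lx <- cells$x - (subs$xmin[sub_id] + margin_lo)
  ly <- cells$y - (subs$ymin[sub_id] + margin_lo)
  in_crop <- lx >= 0 & lx < layout$crop_side & ly >= 0 & ly < layout$crop_side
  out <- tibble(subplot_id = sub_id[in_crop],
                estimate_mm = cells$estimate_mm[in_crop]) |>
    group_by(.data$subplot_id) |>
    summarise(estimate_mm = mean(.data$estimate_mm),
              n_valid_cells = dplyr::n(), .groups = "drop")
  missing <- setdiff(subs$subplot_id, out$subplot_id)
  if (length(missing) > 0) {
    warning(length(missing), " subplot(s) had no valid cell and were excluded",
            call. = FALSE)
  }
  out |>
    mutate(method = raster$method$name,
           cell_size_mm = g$cell_size * 1000) |>
    arrange(.data$subplot_id)
}
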