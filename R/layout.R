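#' Define the plot / subplot geometry
#'
#' A square field plot is subdivided into a regular grid of square subplots,
#' each carrying a centered square comparison window ("crop"). The defaults
#' reproduce the study geometry: a 2.5 m x 2.5 m plot split into 25 subplots
#' of 0.5 m, compared over the central 0.3 m square of each subplot (to avoid
#' contamination by grass lodging across subplot borders).
#'
#' Subplots are enumerated row-major from the minimum-x / minimum-y corner,
#' with half-open extents \eqn{[lo, hi)} in both axes.
#'
#' @param plot_side Side length of the square plot (m).
#' @param n_per_side Number of subplots along each side.
#' @param subplot_side Side length of one subplot (m).
#' @param crop_side Side length of the centered comparison window (m).
#' @param origin_xy Coordinates of the plot's minimum corner (m).
#' @return A `subplot_layout` object; `tidy()` it for a tibble with one row
#'   per subplot (id, row, col, subplot and crop window bounds, all metres).
#' @examples
#' layout <- make_layout()
#' tidy(layout)
#' @export
make_layout <- function(plot_side = 2.5, n_per_side = 5L, subplot_side = 0.5,
                        crop_side = 0.3, origin_xy = c(0, 0)) {
  stopifnot_scalar_num(plot_side, "plot_side", positive = TRUE)
  stopifnot_scalar_num(subplot_side, "subplot_side", positive = TRUE)
  stopifnot_scalar_num(crop_side, "crop_side", positive = TRUE)
  if (!is.numeric(n_per_side) || length(n_per_side) != 1L || n_per_side < 1 ||
      n_per_side != round(n_per_side)) {
    stop("`n_per_side` must be a positive whole number", call. = FALSE)
  }
  n_per_side <- as.integer(n_per_side)
  if (n_per_side * subplot_side > plot_side + 1e-9) {
    stop("subplots do not fit: n_per_side * subplot_side > plot_side",
         call. = FALSE)
  }
  if (crop_side > subplot_side + 1e-12) {
    stop("`crop_side` must not exceed `subplot_side`", call. = FALSE)
  }
  structure(
    list(
      origin_xy = as.numeric(origin_xy), plot_side = plot_side,
      n_per_side = n_per_side, subplot_side = subplot_side,
      crop_side = crop_side
    ),
    class = "subplot_layout"
  )
}

#' @export
print.subplot_layout <- function(x, ...) {
  cat(sprintf(
    "<subplot_layout> %.2f m plot, %d x %d subplots of %.2f m, %.2f m crop\n",
    x$plot_side, x$n_per_side, x$n_per_side, x$subplot_side, x$crop_side
  ))
  invisible(x)
}

#' @describeIn make_layout One row per subplot with its extents.
#' @param x A `subplot_layout`.
#' @param ... Unused.
#' @export
tidy.subplot_layout <- function(x, ...) {
  n <- x$n_per_side
  grid <- expand.grid(col_j = seq_len(n) - 1L, row_i = seq_len(n) - 1L)
  margin <- (x$subplot_side - x$crop_side) / 2
  tibble(
    subplot_id = grid$row_i * n + grid$col_j + 1L,
    row_i = grid$row_i,
    col_j = grid$col_j,
    xmin = x$origin_xy[1] + grid$col_j * x$subplot_side,
    ymin = x$origin_xy[2] + grid$row_i * x$subplot_side
  ) |>
    mutate(
      xmax = .data$xmin + x$subplot_side,
      ymax = .data$ymin + x$subplot_side,
      crop_xmin = .data$xmin + margin,
      crop_xmax = .data$xmax - margin,
      crop_ymin = .data$ymin + margin,
      crop_ymax = .data$ymax - margin
    ) |>
    arrange(.data$subplot_id)
}

layout_extent <- function(layout) {
  c(
    xmin = layout$origin_xy[1],
    xmax = layout$origin_xy[1] + layout$n_per_side * layout$subplot_side,
    ymin = layout$origin_xy[2],
    ymax = layout$origin_xy[2] + layout$n_per_side * layout$subplot_side
  )
}

# subplot index (1-based, row-major) for coordinates; NA outside the grid
subplot_index <- function(layout, x, y) {
  n <- layout$n_per_side
  j <- floor((x - layout$origin_xy[1]) / layout$subplot_side)
  i <- floor((y - layout$origin_xy[2]) / layout$subplot_side)
  ok <- i >= 0 & i < n & j >= 0 & j < n
  out <- rep(NA_integer_, length(x))
  out[ok] <- as.integer(i[ok] * n + j[ok] + 1L)
  out
}
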