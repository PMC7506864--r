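#' @keywords internal
"_PACKAGE"

#' @import rlang
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join bind_rows across n slice_min pull distinct
#' @importFrom stats rnorm runif rexp rlnorm sd cor aov TukeyHSD setNames
#' @importFrom utils head
NULL

.datatable.aware <- TRUE

# silence R CMD check notes for NSE column names used with data.table/dplyr
utils::globalVariables(c(
  ".", "..cols", "x", "y", "z", "cell", "ix", "iy", "mx", "mn", "av",
  "subplot_id", "row_i", "col_j", "estimate_mm", "truth_mm", "abs_error_mm",
  "cell_size_mm", "method", "sensor", "mae_mm", "sd_mm", "n_subplots",
  "n_valid_cells", "value", "tip_height", "col_x", "row_y", "height_mm",
  "replicate", "contrast", "adj_p", "significant", "group", "error_mm",
  "mean_mae_mm", "width", "azimuth"
))

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(old <- get0(".Random.seed", globalenv(), mode = "integer"))) {
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv()),
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

# Derive a reproducible sub-seed for a named random-number stream, so the
# ground, canopy and each sampler consume independent streams: changing the
# draws of one subsystem does not perturb the others.
substream_seed <- function(seed, stream) {
  offsets <- c(
    ground = 11L, canopy = 23L, subplot_means = 29L, ruler = 37L,
    sfm = 41L, lidar = 43L, jitter = 53L, depth = 59L, sfm_depth = 61L,
    replicate = 71L
  )
  off <- offsets[[stream]]
  if (is.null(off)) stop("unknown RNG stream: ", stream)
  as.integer((as.numeric(seed) * 1009 + off * 9973) %% 2147483647)
}

stopifnot_scalar_num <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop("`", name, "` must be a single finite number", call. = FALSE)
  }
  if (positive && x <= 0) stop("`", name, "` must be > 0", call. = FALSE)
  if (nonneg && x < 0) stop("`", name, "` must be >= 0", call. = FALSE)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
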