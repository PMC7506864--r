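#' Absolute-error statistics against ruler truth
#'
#' Joins subplot estimates to the truth table, computes per-subplot absolute
#' errors (mm), their mean (MAE) and the sample standard deviation of the
#' absolute errors — the "MAE +/- SD" convention of the study.
#'
#' @param estimates A [subplot_summary()] tibble.
#' @param truth A [ruler_truth()] table.
#' @return A list with `errors` (tibble: `subplot_id`, `estimate_mm`,
#'   `truth_mm`, `abs_error_mm`), `mae_mm` and `sd_mm`.
#' @export
absolute_error_stats <- function(estimates, truth) {
  if (!all(estimates$subplot_id %in% truth$subplot_id)) {
    stop("estimates contain subplots missing from the truth table",
         call. = FALSE)
  }
  errors <- estimates |>
    left_join(
      truth |> select("subplot_id", truth_mm = "height_mm"),
      by = "subplot_id"
    ) |>
    mutate(abs_error_mm = abs(.data$estimate_mm - .data$truth_mm)) |>
    select("subplot_id", "estimate_mm", "truth_mm", "abs_error_mm")
  list(
    errors = errors,
    mae_mm = mean(errors$abs_error_mm),
    sd_mm = if (nrow(errors) > 1) sd(errors$abs_error_mm) else NA_real_
  )
}

# all three aggregations of one cloud in a single grouping pass
rasterize_multi <- function(cloud, grid) {
  template <- rasterize(cloud[0, , drop = FALSE], grid, "max")
  out <- list(max = template, mean = template, min = template)
  out$mean$aggregator <- "mean"
  out$min$aggregator <- "min"
  if (nrow(cloud) == 0) return(out)
  jx <- floor((cloud$x - grid$origin_xy[1]) / grid$cell_size)
  iy <- floor((cloud$y - grid$origin_xy[2]) / grid$cell_size)
  ok <- jx >= 0 & jx < grid$n_cols & iy >= 0 & iy < grid$n_rows
  n_dropped <- sum(!ok)
  dt <- data.table::data.table(i = as.integer(iy[ok]), j = as.integer(jx[ok]),
                               z = cloud$z[ok])
  agg <- dt[, .(mx = max(z), av = mean(z), mn = min(z)), by = c("i", "j")]
  idx <- cbind(agg$i + 1L, agg$j + 1L)
  for (nm in names(out)) out[[nm]]$n_dropped <- as.integer(n_dropped)
  out$max$values[idx] <- agg$mx
  out$mean$values[idx] <- agg$av
  out$min$values[idx] <- agg$mn
  out
}

# rasterize a before/after cloud pair at one cell size with the three
# aggregators, returning the four method estimates summarised per subplot
estimate_pair_all_methods <- function(cloud_before, cloud_after, layout,
                                      cell_size, methods = height_methods()) {
  grid <- suppressMessages(make_grid(layout, cell_size))
  dsms_b <- rasterize_multi(cloud_before, grid)
  dsms_a <- rasterize_multi(cloud_after, grid)
  purrr::map_dfr(methods, function(m) {
    hr <- estimate_height(dsms_b[[m$aggregator_before]],
                          dsms_a[[m$aggregator_after]], m)
    suppressWarnings(subplot_summary(hr, layout))
  })
}

#' Sweep selection methods and DSM resolutions over sensors
#'
#' Runs the full factorial of selection methods x cell sizes for each
#' sensor's before/after cloud pair, scoring every combination against the
#' ruler truth.
#'
#' @param clouds A named list, one entry per sensor, each a list with
#'   elements `before` and `after` (point clouds).
#' @param layout The [make_layout()] geometry.
#' @param truth A [ruler_truth()] table.
#' @param methods Character vector of method names or a list of
#'   [height_method()] tags (default: all four).
#' @param cell_sizes_mm Cell sizes in mm (default the seven study sizes).
#' @return A `sweep_table` tibble: one row per (sensor, method, cell size,
#'   subplot) with `estimate_mm`, `truth_mm`, `abs_error_mm`,
#'   `n_valid_cells`. Summarise with [summarize_sweep()].
#' @export
run_sweep <- function(clouds, layout, truth,
                      methods = names(height_methods()),
                      cell_sizes_mm = c(5, 10, 20, 30, 40, 50, 100)) {
  if (is.character(methods)) {
    methods <- setNames(lapply(methods, height_method), methods)
  }
  if (any(cell_sizes_mm <= 0)) stop("cell sizes must be positive", call. = FALSE)
  if (is.null(names(clouds)) || any(names(clouds) == "")) {
    stop("`clouds` must be a named list (one entry per sensor)", call. = FALSE)
  }
  out <- purrr::imap_dfr(clouds, function(pair, sensor_name) {
    if (!all(c("before", "after") %in% names(pair))) {
      stop("sensor `", sensor_name, "` is missing a before or after cloud",
           call. = FALSE)
    }
    purrr::map_dfr(cell_sizes_mm, function(cs) {
      estimate_pair_all_methods(pair$before, pair$after, layout, cs / 1000,
                                methods) |>
        mutate(sensor = sensor_name)
    })
  })
  out <- out |>
    left_join(truth |> select("subplot_id", truth_mm = "height_mm"),
              by = "subplot_id") |>
    mutate(abs_error_mm = abs(.data$estimate_mm - .data$truth_mm)) |>
    select("sensor", "method", "cell_size_mm", "subplot_id", "estimate_mm",
           "truth_mm", "abs_error_mm", "n_valid_cells")
  class(out) <- c("sweep_table", class(out))
  out
}

#' Summarise a sweep into MAE +/- SD per configuration
#'
#' @param sweep A [run_sweep()] table (optionally with a `replicate`
#'   column; replicates are pooled into the per-subplot errors first).
#' @return A tibble with one row per (sensor, method, cell_size_mm):
#'   `mae_mm`, `sd_mm`, `n_subplots`.
#' @export
summarize_sweep <- function(sweep) {
  sweep |>
    as_tibble() |>
    group_by(.data$sensor, .data$method, .data$cell_size_mm) |>
    summarise(
      mae_mm = mean(.data$abs_error_mm),
      sd_mm = sd(.data$abs_error_mm),
      n_subplots = dplyr::n(),
      .groups = "drop"
    )
}

#' One-way ANOVA with Tukey HSD on labelled error groups
#'
#' @param errors A data frame with columns `group` (factor/character) and
#'   `error_mm` (per-subplot absolute errors).
#' @param alpha Significance level (the study used 0.01).
#' @return A list with `f_statistic`, `p_value`, and `tukey` (tibble:
#'   `contrast`, `diff_mm`, `lwr_mm`, `upr_mm`, `adj_p`, `significant`).
#'   Degenerate input (zero variance everywhere) reports `p_value = 1` with
#'   a warning.
#' @export
anova_tukey <- function(errors, alpha = 0.01) {
  stopifnot(all(c("group", "error_mm") %in% names(errors)))
  errors <- errors |> mutate(group = factor(.data$group))
  if (nlevels(errors$group) < 2) {
    stop("need at least two groups", call. = FALSE)
  }
  if (any(table(errors$group) < 2)) {
    stop("every group needs at least two observations", call. = FALSE)
  }
  if (isTRUE(all.equal(stats::var(errors$error_mm), 0)) ||
      stats::var(errors$error_mm) == 0) {
    warning("all observations identical; reporting p = 1", call. = FALSE)
    pairs <- utils::combn(levels(errors$group), 2,
                          FUN = function(p) paste(p[2], p[1], sep = "-"))
    return(list(
      f_statistic = NA_real_, p_value = 1,
      tukey = tibble(contrast = pairs, diff_mm = 0, lwr_mm = 0, upr_mm = 0,
                     adj_p = 1, significant = FALSE),
      alpha = alpha
    ))
  }
  fit <- aov(error_mm ~ group, data = errors)
  an <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)$group
  list(
    f_statistic = an[["F value"]][1],
    p_value = an[["Pr(>F)"]][1],
    tukey = tibble(
      contrast = rownames(tk),
      diff_mm = tk[, "diff"], lwr_mm = tk[, "lwr"], upr_mm = tk[, "upr"],
      adj_p = tk[, "p adj"],
      significant = tk[, "p adj"] < alpha
    ),
    alpha = alpha
  )
}

#' Pearson correlation between estimated and measured heights
#'
#' @param estimate_mm,truth_mm Equal-length numeric vectors (>= 3 values).
#' @return Pearson r, or `NA` with a warning if either input has zero
#'   variance.
#' @export
height_correlation <- function(estimate_mm, truth_mm) {
  if (length(estimate_mm) != length(truth_mm) || length(estimate_mm) < 3) {
    stop("need equal-length vectors of at least 3 values", call. = FALSE)
  }
  if (stats::var(estimate_mm) == 0 || stats::var(truth_mm) == 0) {
    warning("zero variance; correlation undefined", call. = FALSE)
    return(NA_real_)
  }
  cor(estimate_mm, truth_mm)
}

#' Compare sensors at their error-minimising settings
#'
#' For each sensor, selects the (method, cell size) with the lowest MAE
#' (ties go to the larger cell size — fewer empty cells), then compares the
#' per-subplot absolute errors across sensors at those settings with a
#' one-way ANOVA + Tukey HSD, and reports the Pearson correlation of
#' estimates vs truth per sensor.
#'
#' @param sweep A [run_sweep()] table covering at least two sensors.
#' @param alpha Significance level for the pairwise flags.
#' @return A `sensor_comparison` object. `glance()` gives one row per
#'   sensor (best method, cell size, MAE +/- SD, Pearson r); `tidy()` gives
#'   the Tukey pairs.
#' @export
compare_sensors <- function(sweep, alpha = 0.01) {
  smry <- summarize_sweep(sweep)
  if (length(unique(smry$sensor)) < 2) {
    stop("need complete sweeps for at least two sensors", call. = FALSE)
  }
  best <- smry |>
    group_by(.data$sensor) |>
    arrange(.data$mae_mm, dplyr::desc(.data$cell_size_mm), .by_group = TRUE) |>
    dplyr::slice(1) |>
    ungroup()
  at_best <- purrr::pmap_dfr(
    best |> select("sensor", "method", "cell_size_mm"),
    function(sensor, method, cell_size_mm) {
      sweep |>
        as_tibble() |>
        filter(.data$sensor == !!sensor, .data$method == !!method,
               .data$cell_size_mm == !!cell_size_mm)
    }
  )
  r_by_sensor <- at_best |>
    group_by(.data$sensor) |>
    summarise(pearson_r = height_correlation(.data$estimate_mm, .data$truth_mm),
              .groups = "drop")
  stats <- anova_tukey(
    at_best |> select(group = "sensor", error_mm = "abs_error_mm"),
    alpha = alpha
  )
  best <- best |> left_join(r_by_sensor, by = "sensor")
  structure(
    list(best = best, errors_at_best = at_best, anova = stats, alpha = alpha),
    class = "sensor_comparison"
  )
}

#' @export
print.sensor_comparison <- function(x, ...) {
  cat("<sensor_comparison>\n")
  b <- x$best
  for (k in seq_len(nrow(b))) {
    cat(sprintf(
      "  %-10s best: %-15s @ %3.0f mm  MAE %5.1f +/- %4.1f mm  r = %.3f\n",
      b$sensor[k], b$method[k], b$cell_size_mm[k], b$mae_mm[k], b$sd_mm[k],
      b$pearson_r[k]
    ))
  }
  cat(sprintf("  one-way ANOVA F = %.2f, p = %.3g\n",
              x$anova$f_statistic, x$anova$p_value))
  invisible(x)
}

#' @describeIn compare_sensors Tukey HSD pairs across sensors.
#' @param x A `sensor_comparison`.
#' @param ... Unused.
#' @export
tidy.sensor_comparison <- function(x, ...) x$anova$tukey

#' @describeIn compare_sensors Best settings and accuracy per sensor.
#' @export
glance.sensor_comparison <- function(x, ...) x$best
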