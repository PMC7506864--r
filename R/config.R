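#' Run configuration
#'
#' `default_config()` returns the full default configuration of the
#' pipeline as a named list (the study geometry, the three sensors at their
#' paper densities, the four methods, the seven cell sizes, density scale
#' 0.01). `read_config()` loads a YAML file and merges it over the
#' defaults, rejecting unknown keys; `validate_config()` checks any
#' configuration list.
#'
#' @param path Path to a YAML configuration file.
#' @param config A configuration list.
#' @return A validated configuration list (class `run_config`).
#' @export
default_config <- function() {
  structure(
    list(
      seed = 1L,
      scale = 0.01,
      layout = list(plot_side = 2.5, n_per_side = 5L, subplot_side = 0.5,
                    crop_side = 0.3),
      scene = list(mean_height_mm = 400, between_subplot_cv = 0.25,
                   height_cv = 0.08, blades_per_m2 = 1500,
                   leaf_width = 0.010, relief_sd = 0.010,
                   stubble_height = 0.030, n_probes = 5L),
      sensors = c("uav_sfm", "pole_sfm", "lidar"),
      methods = c("maximum", "average", "minimum", "maximum_minimum"),
      cell_sizes_mm = c(5, 10, 20, 30, 40, 50, 100),
      output = list(cloud_format = "csv", write_dsms = FALSE,
                    dsm_cell_size_mm = 20)
    ),
    class = "run_config"
  )
}

config_schema <- function() {
  list(
    seed = "numeric", scale = "numeric", layout = "list", scene = "list",
    sensors = "character", methods = "character", cell_sizes_mm = "numeric",
    output = "list"
  )
}

#' @rdname default_config
#' @export
validate_config <- function(config) {
  schema <- config_schema()
  unknown <- setdiff(names(config), names(schema))
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  base <- unclass(default_config())
  merged <- utils::modifyList(base, lapply(config, function(x) x))
  for (key in names(schema)) {
    ok <- switch(schema[[key]],
      numeric = is.numeric(merged[[key]]),
      character = is.character(merged[[key]]),
      list = is.list(merged[[key]])
    )
    if (!ok) stop("configuration key `", key, "` has the wrong type",
                  call. = FALSE)
  }
  for (section in c("layout", "scene", "output")) {
    bad <- setdiff(names(merged[[section]]), names(base[[section]]))
    if (length(bad) > 0) {
      stop("unknown key(s) in `", section, "`: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  known_sensors <- names(default_sensors())
  if (!all(merged$sensors %in% known_sensors)) {
    stop("unknown sensor(s): ",
         paste(setdiff(merged$sensors, known_sensors), collapse = ", "),
         call. = FALSE)
  }
  if (!all(merged$methods %in% names(height_methods()))) {
    stop("unknown method(s): ",
         paste(setdiff(merged$methods, names(height_methods())),
               collapse = ", "), call. = FALSE)
  }
  if (any(merged$cell_sizes_mm <= 0)) {
    stop("cell sizes must be positive", call. = FALSE)
  }
  if (merged$scale <= 0) stop("`scale` must be positive", call. = FALSE)
  structure(merged, class = "run_config")
}

#' @rdname default_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  validate_config(yaml::read_yaml(path))
}
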