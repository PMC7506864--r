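#' Read and write DSM rasters
#'
#' `write_dsm_asc()` / `read_dsm_asc()` use the ESRI ASCII grid format
#' (`NODATA_value -9999`, rows written north-to-south) and round-trip the
#' full grid geometry. `write_dsm_tif()` / `read_dsm_tif()` use a
#' single-band 32-bit float TIFF via the tiff package; coordinates live in
#' a local plot frame and a plain TIFF carries no geo-tags, so the reader
#' takes the grid geometry as arguments.
#'
#' @param dsm A [rasterize()] result (`read_dsm_asc()` also accepts a
#'   `height_raster` matrix for `write_dsm_asc()`).
#' @param path File path.
#' @return Readers return a `dsm` (aggregator `"unknown"` unless recorded);
#'   writers return `path` invisibly.
#' @name dsm_io
NULL

#' @rdname dsm_io
#' @export
write_dsm_asc <- function(dsm, path) {
  stopifnot(inherits(dsm, "dsm") || inherits(dsm, "height_raster"))
  g <- dsm$grid
  v <- dsm$values
  v[is.na(v)] <- -9999
  header <- c(
    paste("ncols", g$n_cols),
    paste("nrows", g$n_rows),
    paste("xllcorner", format(g$origin_xy[1], digits = 15)),
    paste("yllcorner", format(g$origin_xy[2], digits = 15)),
    paste("cellsize", format(g$cell_size, digits = 15)),
    "NODATA_value -9999"
  )
  # internal row 1 is the southernmost; ASCII grids list north first
  rows <- apply(v[rev(seq_len(g$n_rows)), , drop = FALSE], 1L,
                function(r) paste(format(r, digits = 10, trim = TRUE,
                                         scientific = FALSE),
                                  collapse = " "))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' @rdname dsm_io
#' @export
read_dsm_asc <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  kv <- strsplit(trimws(lines[1:6]), "\\s+")
  keys <- tolower(vapply(kv, `[[`, "", 1L))
  vals <- as.numeric(vapply(kv, `[[`, "", 2L))
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  if (!identical(keys, need)) {
    stop("malformed ESRI ASCII grid header: ", path, call. = FALSE)
  }
  h <- as.list(setNames(vals, keys))
  body <- scan(text = lines[-(1:6)], quiet = TRUE)
  if (length(body) != h$ncols * h$nrows) {
    stop("ESRI ASCII grid body has wrong cell count: ", path, call. = FALSE)
  }
  m <- matrix(body, nrow = h$nrows, ncol = h$ncols, byrow = TRUE)
  m[m == h$nodata_value] <- NA_real_
  m <- m[rev(seq_len(nrow(m))), , drop = FALSE]   # back to south-first rows
  grid <- make_grid(
    c(h$xllcorner, h$xllcorner + h$ncols * h$cellsize,
      h$yllcorner, h$yllcorner + h$nrows * h$cellsize),
    h$cellsize
  )
  structure(
    list(values = m, grid = grid, aggregator = "unknown", n_dropped = 0L,
         sensor_tag = NA_character_, epoch = NA_character_),
    class = "dsm"
  )
}

# TIFF samples must lie in [0, 1]; heights are stored with a fixed affine
# encoding covering -10..10 m at ~1.2e-6 m float32 resolution, nodata as 0
TIF_OFFSET <- 10
TIF_SPAN <- 20

#' @rdname dsm_io
#' @export
write_dsm_tif <- function(dsm, path) {
  stopifnot(inherits(dsm, "dsm"))
  g <- dsm$grid
  v <- dsm$values[rev(seq_len(g$n_rows)), , drop = FALSE]
  if (any(abs(v) >= TIF_OFFSET, na.rm = TRUE)) {
    stop("TIFF writer supports heights in (-10, 10) m only", call. = FALSE)
  }
  enc <- (v + TIF_OFFSET) / TIF_SPAN
  enc[is.na(enc)] <- 0
  tiff::writeTIFF(enc, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' @rdname dsm_io
#' @param cell_size,origin_xy,aggregator Grid geometry and aggregator tag
#'   for `read_dsm_tif()`; a plain TIFF stores only the sample values.
#' @export
read_dsm_tif <- function(path, cell_size = 1, origin_xy = c(0, 0),
                         aggregator = "unknown") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- tiff::readTIFF(path)
  m <- img * TIF_SPAN - TIF_OFFSET
  m[img == 0] <- NA_real_
  m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  grid <- make_grid(
    c(origin_xy[1], origin_xy[1] + ncol(m) * cell_size,
      origin_xy[2], origin_xy[2] + nrow(m) * cell_size),
    cell_size
  )
  structure(
    list(values = m, grid = grid, aggregator = aggregator, n_dropped = 0L,
         sensor_tag = NA_character_, epoch = NA_character_),
    class = "dsm"
  )
}
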