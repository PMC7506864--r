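#' Read and write point clouds
#'
#' Supported formats (inferred from the file extension unless `format` is
#' given): headered CSV with columns `x,y,z` in metres; PLY (binary
#' little-endian, double-precision vertex properties); LAS 1.2 point format
#' 0 (0.1 mm scale, zero offset). All coordinates are metres in a local
#' plot frame.
#'
#' @param cloud A point cloud (data frame with `x`, `y`, `z`).
#' @param path File path.
#' @param format `"csv"`, `"ply"` or `"las"`.
#' @return `read_point_cloud()` returns a `point_cloud` tibble;
#'   `write_point_cloud()` returns `path` invisibly.
#' @name point_cloud_io
NULL

cloud_format <- function(path, format = NULL) {
  if (!is.null(format)) return(match.arg(format, c("csv", "ply", "las")))
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("csv", "ply", "las")) {
    stop("cannot infer point-cloud format from extension `.", ext, "`",
         call. = FALSE)
  }
  ext
}

#' @rdname point_cloud_io
#' @export
write_point_cloud <- function(cloud, path, format = NULL) {
  format <- cloud_format(path, format)
  stopifnot(all(c("x", "y", "z") %in% names(cloud)))
  switch(format,
    csv = readr::write_csv(
      tibble(x = cloud$x, y = cloud$y, z = cloud$z), path, progress = FALSE
    ),
    ply = write_ply(cloud, path),
    las = write_las(cloud, path)
  )
  invisible(path)
}

#' @rdname point_cloud_io
#' @export
read_point_cloud <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  format <- cloud_format(path, format)
  switch(format,
    csv = read_cloud_csv(path),
    ply = read_ply(path),
    las = read_las(path)
  )
}

read_cloud_csv <- function(path) {
  header <- readLines(path, n = 1L)
  cols <- strsplit(header, ",")[[1]]
  if (!all(c("x", "y", "z") %in% trimws(cols))) {
    stop("CSV point cloud must have a header with columns x,y,z: ", path,
         call. = FALSE)
  }
  raw <- utils::read.csv(path, colClasses = "character")
  if (nrow(raw) == 0) {
    warning("empty point cloud file: ", path, call. = FALSE)
    return(new_point_cloud(numeric(), numeric(), numeric(), NA_character_,
                           NA_character_))
  }
  for (col in c("x", "y", "z")) {
    vals <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(!is.finite(vals))
    if (length(bad) > 0) {
      stop("malformed record in ", basename(path), ": non-numeric ", col,
           " on line ", bad[1] + 1L, call. = FALSE)  # +1 for the header line
    }
    raw[[col]] <- vals
  }
  new_point_cloud(raw$x, raw$y, raw$z, NA_character_, NA_character_)
}

# ---- PLY: binary little-endian, double x/y/z -----------------------------

write_ply <- function(cloud, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  header <- c(
    "ply",
    "format binary_little_endian 1.0",
    paste("element vertex", nrow(cloud)),
    "property double x",
    "property double y",
    "property double z",
    "end_header"
  )
  writeLines(header, con, sep = "\n")
  m <- rbind(cloud$x, cloud$y, cloud$z)
  writeBin(as.numeric(m), con, size = 8L, endian = "little")
  invisible(path)
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character()
  repeat {
    line <- read_bin_line(con)
    header <- c(header, line)
    if (identical(line, "end_header")) break
    if (length(header) > 100) stop("malformed PLY header: ", path,
                                   call. = FALSE)
  }
  if (!identical(header[1], "ply") ||
      !any(grepl("^format binary_little_endian", header))) {
    stop("not a binary little-endian PLY file: ", path, call. = FALSE)
  }
  n <- as.integer(sub("^element vertex ", "",
                      grep("^element vertex ", header, value = TRUE)[1]))
  props <- sub("^property double ", "", grep("^property", header, value = TRUE))
  if (!identical(props, c("x", "y", "z"))) {
    stop("PLY vertex properties must be double x, y, z: ", path, call. = FALSE)
  }
  vals <- readBin(con, numeric(), n = 3L * n, size = 8L, endian = "little")
  m <- matrix(vals, nrow = 3L)
  new_point_cloud(m[1, ], m[2, ], m[3, ], NA_character_, NA_character_)
}

read_bin_line <- function(con) {
  chars <- raw()
  repeat {
    b <- readBin(con, "raw", n = 1L)
    if (length(b) == 0 || b == as.raw(10L)) break
    chars <- c(chars, b)
  }
  rawToChar(chars)
}

# ---- LAS 1.2, point data record format 0 ---------------------------------

LAS_HEADER_SIZE <- 227L
LAS_SCALE <- 1e-4  # 0.1 mm quantisation

write_uint16 <- function(con, x) {
  writeBin(as.integer(x), con, size = 2L, endian = "little")
}

write_las <- function(cloud, path) {
  n <- nrow(cloud)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("LASF", con, nchars = 4L, eos = NULL)
  write_uint16(con, 0L)                     # file source id
  write_uint16(con, 0L)                     # global encoding
  writeBin(raw(16L), con)                   # project GUID
  writeBin(as.integer(c(1L, 2L)), con, size = 1L)  # version 1.2
  writeChar(formatC("canopyheight", width = 32L, flag = "-"), con,
            nchars = 32L, eos = NULL)       # system identifier
  writeChar(formatC("canopyheight", width = 32L, flag = "-"), con,
            nchars = 32L, eos = NULL)       # generating software
  write_uint16(con, 1L)                     # file creation day
  write_uint16(con, 2026L)                  # file creation year
  write_uint16(con, LAS_HEADER_SIZE)        # header size
  writeBin(LAS_HEADER_SIZE, con, size = 4L, endian = "little")  # data offset
  writeBin(0L, con, size = 4L, endian = "little")  # number of VLRs
  writeBin(as.integer(0L), con, size = 1L)  # point data format 0
  write_uint16(con, 20L)                    # point record length
  writeBin(as.integer(n), con, size = 4L, endian = "little")
  writeBin(integer(5L), con, size = 4L, endian = "little")  # points by return
  writeBin(rep(LAS_SCALE, 3L), con, size = 8L, endian = "little")  # scales
  writeBin(rep(0, 3L), con, size = 8L, endian = "little")          # offsets
  ranges <- function(v) if (n > 0) c(max(v), min(v)) else c(0, 0)
  writeBin(c(ranges(cloud$x), ranges(cloud$y), ranges(cloud$z)), con,
           size = 8L, endian = "little")
  # point records: x,y,z int32 + 8 bytes of zeroed attributes
  if (n > 0) {
    xi <- as.integer(round(cloud$x / LAS_SCALE))
    yi <- as.integer(round(cloud$y / LAS_SCALE))
    zi <- as.integer(round(cloud$z / LAS_SCALE))
    rec <- matrix(as.raw(0L), nrow = 20L, ncol = n)
    rec[1:4, ] <- matrix(writeBin(xi, raw(), size = 4L, endian = "little"),
                         nrow = 4L)
    rec[5:8, ] <- matrix(writeBin(yi, raw(), size = 4L, endian = "little"),
                         nrow = 4L)
    rec[9:12, ] <- matrix(writeBin(zi, raw(), size = 4L, endian = "little"),
                          nrow = 4L)
    writeBin(as.vector(rec), con)
  }
  invisible(path)
}

read_las <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  sig <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(sig, "LASF")) stop("not a LAS file: ", path, call. = FALSE)
  invisible(readBin(con, "raw", n = 20L))   # source id .. GUID
  ver <- readBin(con, integer(), n = 2L, size = 1L)
  if (ver[1] != 1L) stop("unsupported LAS version: ", path, call. = FALSE)
  invisible(readBin(con, "raw", n = 68L))   # sysid, software, dates
  header_size <- readBin(con, integer(), size = 2L, endian = "little",
                         signed = FALSE)
  offset <- readBin(con, integer(), size = 4L, endian = "little")
  invisible(readBin(con, integer(), size = 4L, endian = "little"))  # VLRs
  fmt <- readBin(con, integer(), size = 1L)
  rec_len <- readBin(con, integer(), size = 2L, endian = "little",
                     signed = FALSE)
  n <- readBin(con, integer(), size = 4L, endian = "little")
  invisible(readBin(con, integer(), n = 5L, size = 4L, endian = "little"))
  scales <- readBin(con, numeric(), n = 3L, size = 8L, endian = "little")
  offsets <- readBin(con, numeric(), n = 3L, size = 8L, endian = "little")
  if (fmt != 0L) stop("only LAS point format 0 is supported: ", path,
                      call. = FALSE)
  seek(con, offset)
  recs <- readBin(con, "raw", n = rec_len * n)
  if (length(recs) < rec_len * n) {
    stop("truncated LAS point data: ", path, call. = FALSE)
  }
  m <- matrix(recs, nrow = rec_len)
  int_of <- function(rows) {
    readBin(as.vector(m[rows, , drop = FALSE]), integer(), n = n, size = 4L,
            endian = "little")
  }
  new_point_cloud(
    int_of(1:4) * scales[1] + offsets[1],
    int_of(5:8) * scales[2] + offsets[2],
    int_of(9:12) * scales[3] + offsets[3],
    NA_character_, NA_character_
  )
}
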