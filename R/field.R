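# Smooth stationary Gaussian random fields on a regular grid, evaluated by
# bilinear interpolation. Used for the ground surface, the spatial component
# of blade tip heights, and the correlated part of SfM reconstruction noise.
#
# The field is white noise convolved with a separable Gaussian kernel
# (sd = corr_len on the ground), then re-standardised so the grid values have
# mean 0 and sd exactly 1 over the region of interest.

gaussian_field <- function(xlim, ylim, corr_len, seed, res = NULL) {
  stopifnot_scalar_num(corr_len, "corr_len", positive = TRUE)
  if (is.null(res)) res <- corr_len / 3
  res <- max(res, (diff(xlim) + diff(ylim)) / 2000)  # cap grid size
  pad <- 3 * corr_len
  x0 <- xlim[1] - pad; x1 <- xlim[2] + pad
  y0 <- ylim[1] - pad; y1 <- ylim[2] + pad
  nx <- ceiling((x1 - x0) / res) + 1L
  ny <- ceiling((y1 - y0) / res) + 1L

  sigma_cells <- corr_len / res
  half <- ceiling(3 * sigma_cells)
  k <- stats::dnorm(seq(-half, half), sd = sigma_cells)
  k <- k / sum(k)

  w <- with_seed(seed, matrix(rnorm(nx * ny), nrow = ny, ncol = nx))
  sm <- apply(w, 2L, function(col) smooth_1d(col, k))
  sm <- t(apply(sm, 1L, function(rw) smooth_1d(rw, k)))

  # standardise against the region of interest, not the padded border
  core_i <- which(y0 + pad <= y0 + (seq_len(ny) - 1L) * res &
                    y0 + (seq_len(ny) - 1L) * res <= y1 - pad)
  core_j <- which(x0 + pad <= x0 + (seq_len(nx) - 1L) * res &
                    x0 + (seq_len(nx) - 1L) * res <= x1 - pad)
  core <- sm[core_i, core_j]
  sm <- sm - mean(core)
  s <- stats::sd(core)
  if (s > 0) sm <- sm / s

  structure(
    list(values = sm, x0 = x0, y0 = y0, res = res, nx = nx, ny = ny),
    class = "ch_field"
  )
}

# circular-free 1D convolution with edge renormalisation
smooth_1d <- function(v, k) {
  half <- (length(k) - 1L) / 2L
  padded <- c(rep(v[1], half), v, rep(v[length(v)], half))
  out <- stats::filter(padded, k, sides = 2)
  as.numeric(out[(half + 1L):(half + length(v))])
}

# Bilinear interpolation of a ch_field at arbitrary coordinates.
field_at <- function(field, x, y) {
  fx <- (x - field$x0) / field$res
  fy <- (y - field$y0) / field$res
  i0 <- pmin(pmax(floor(fy), 0), field$ny - 2L)
  j0 <- pmin(pmax(floor(fx), 0), field$nx - 2L)
  tx <- pmin(pmax(fx - j0, 0), 1)
  ty <- pmin(pmax(fy - i0, 0), 1)
  v <- field$values
  idx <- function(i, j) v[cbind(i + 1L, j + 1L)]
  (1 - tx) * (1 - ty) * idx(i0, j0) +
    tx * (1 - ty) * idx(i0, j0 + 1L) +
    (1 - tx) * ty * idx(i0 + 1L, j0) +
    tx * ty * idx(i0 + 1L, j0 + 1L)
}
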