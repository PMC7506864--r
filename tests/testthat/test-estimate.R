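test_that("only the four legal aggregator pairings exist", {
  m <- height_methods()
  expect_named(m, c("maximum", "average", "minimum", "maximum_minimum"))
  pairs <- vapply(m, function(x) paste(x$aggregator_before, x$aggregator_after),
                  "")
  expect_equal(unname(pairs),
               c("max max", "mean mean", "min min", "max min"))
  expect_error(height_method("median"))
})

test_that("differencing reproduces the per-cell arithmetic in mm", {
  before_max <- tiny_dsm(c(0.500, 0.450), "max")
  after_min <- tiny_dsm(c(0.030, 0.040), "min")
  hr <- estimate_height(before_max, after_min, "maximum_minimum")
  expect_equal(hr$values[1, ], c(470, 410))

  # identical inputs give 0 everywhere for the same-aggregator methods
  for (m in c("maximum", "average", "minimum")) {
    agg <- height_method(m)$aggregator_before
    d <- tiny_dsm(c(0.2, 0.3), agg)
    expect_equal(estimate_height(d, d, m)$values[1, ], c(0, 0))
  }

  # negative estimates are retained and counted
  hr_neg <- estimate_height(tiny_dsm(c(0.1, 0.5), "max"),
                            tiny_dsm(c(0.2, 0.1), "min"), "maximum_minimum")
  expect_equal(hr_neg$values[1, ], c(-100, 400))
  expect_equal(hr_neg$n_negative, 1L)
})

test_that("grid or aggregator mismatches are refused, masks propagate", {
  b <- tiny_dsm(c(0.5, 0.4), "max")
  a_wrong_grid <- tiny_dsm(c(0.03, 0.03, 0.03), "min")
  expect_error(estimate_height(b, a_wrong_grid, "maximum_minimum"),
               "different grids")
  a_wrong_agg <- tiny_dsm(c(0.03, 0.03), "mean")
  expect_error(estimate_height(b, a_wrong_agg, "maximum_minimum"),
               "needs a min")
  expect_error(estimate_height(tiny_dsm(c(0.5, 0.4), "mean"),
                               tiny_dsm(c(0.03, 0.03), "min"),
                               "maximum_minimum"),
               "needs a max")

  a <- tiny_dsm(c(0.03, NA), "min")
  a$values[1, 2] <- NA
  hr <- estimate_height(b, a, "maximum_minimum")
  expect_true(is.na(hr$values[1, 2]))
  expect_equal(hr$values[1, 1], 470)
})

test_that("maximum_minimum dominates the other methods cellwise", {
  for (seed in 1:10) {
    before <- random_cloud(400, zlim = c(0.2, 0.6), seed = seed)
    after <- random_cloud(400, zlim = c(0, 0.05), seed = seed + 100)
    grid <- make_grid(c(0, 1, 0, 1), 0.1)
    dsm_b <- canopyheight:::rasterize_multi(before, grid)
    dsm_a <- canopyheight:::rasterize_multi(after, grid)
    mm <- estimate_height(dsm_b$max, dsm_a$min, "maximum_minimum")$values
    for (m in c("maximum", "average", "minimum")) {
      tag <- height_method(m)
      other <- estimate_height(dsm_b[[tag$aggregator_before]],
                               dsm_a[[tag$aggregator_after]], tag)$values
      ok <- !is.na(mm) & !is.na(other)
      expect_true(all(mm[ok] >= other[ok] - 1e-9))
    }
  }
})

test_that("subplot summaries average crop-window cell centers", {
  layout <- make_layout(2.5, 5, 0.5, 0.3)
  grid <- make_grid(layout, 0.1)
  uniform <- estimate_height(
    rasterize(tibble::tibble(x = 0.05, y = 0.05, z = 0.5), grid, "max"),
    rasterize(tibble::tibble(x = 0.05, y = 0.05, z = 0.03), grid, "min"),
    "maximum_minimum"
  )
  uniform$values[, ] <- 470
  s <- subplot_summary(uniform, layout)
  expect_equal(nrow(s), 25L)
  expect_equal(unique(s$estimate_mm), 470)
  # a 0.3 m crop on 0.1 m cells admits exactly 3 x 3 = 9 cell centers
  expect_equal(unique(s$n_valid_cells), 9L)

  # random raster: agrees with the brute-force crop-membership oracle
  set.seed(21)
  uniform$values[, ] <- rnorm(length(uniform$values), 400, 50)
  uniform$values[sample(length(uniform$values), 100)] <- NA
  got <- suppressWarnings(subplot_summary(uniform, layout))
  oracle <- brute_force_subplot_mean(uniform, layout)
  expect_equal(got$subplot_id, oracle$subplot_id)
  expect_equal(got$estimate_mm, oracle$estimate_mm)

  # subplots with no valid cell are excluded with a warning
  uniform$values[, ] <- NA
  uniform$values[3, 3] <- 470   # inside subplot 1's crop
  expect_warning(s2 <- subplot_summary(uniform, layout), "excluded")
  expect_equal(s2$subplot_id, 1L)

  small <- make_grid(c(0, 0.5, 0, 0.5), 0.1)
  hr_small <- uniform
  hr_small$grid <- small
  hr_small$values <- uniform$values[1:5, 1:5]
  expect_error(subplot_summary(hr_small, layout), "does not cover")
})
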