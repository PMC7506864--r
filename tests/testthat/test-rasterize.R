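test_that("grids tile the study extent at the seven cell sizes", {
  expect_equal(make_grid(c(0, 2.5, 0, 2.5), 0.1)$n_cols, 25L)
  expect_equal(make_grid(c(0, 2.5, 0, 2.5), 0.005)$n_rows, 500L)
  g1 <- make_grid(c(0, 0.1, 0, 0.1), 0.1)
  expect_equal(c(g1$n_rows, g1$n_cols), c(1L, 1L))
  # non-multiple extents expand to the next multiple, with a message
  expect_message(g <- make_grid(c(0, 2.5, 0, 2.5), 0.04), "expanded")
  expect_equal(g$n_cols, 63L)
  expect_error(make_grid(c(0, 1, 0, 1), 0), "> 0")
})

test_that("single- and two-point cells aggregate exactly", {
  grid <- make_grid(c(0, 0.3, 0, 0.3), 0.1)
  one <- tibble::tibble(x = 0.05, y = 0.05, z = 0.42)
  for (agg in c("max", "mean", "min")) {
    d <- rasterize(one, grid, agg)
    expect_equal(d$values[1, 1], 0.42)
    expect_equal(sum(!is.na(d$values)), 1L)
  }
  two <- tibble::tibble(x = c(0.05, 0.06), y = c(0.05, 0.04), z = c(0.1, 0.3))
  expect_equal(rasterize(two, grid, "max")$values[1, 1], 0.3)
  expect_equal(rasterize(two, grid, "mean")$values[1, 1], 0.2)
  expect_equal(rasterize(two, grid, "min")$values[1, 1], 0.1)
})

test_that("rasterize matches the brute-force per-point loop exactly", {
  cloud <- random_cloud(1000, seed = 13)
  for (cs in c(0.005, 0.02, 0.1)) {
    grid <- make_grid(c(0, 1, 0, 1), cs)
    multi <- canopyheight:::rasterize_multi(cloud, grid)
    for (agg in c("max", "mean", "min")) {
      expect_identical(rasterize(cloud, grid, agg)$values,
                       brute_force_dsm(cloud, grid, agg))
      # the fused three-way pass agrees with the single-aggregator path
      expect_equal(multi[[agg]]$values, rasterize(cloud, grid, agg)$values)
    }
  }
})

test_that("min <= mean <= max cellwise on random clouds", {
  for (seed in 1:5) {
    cloud <- random_cloud(500, seed = seed)
    grid <- make_grid(c(0, 1, 0, 1), 0.05)
    lo <- rasterize(cloud, grid, "min")$values
    mid <- rasterize(cloud, grid, "mean")$values
    hi <- rasterize(cloud, grid, "max")$values
    expect_identical(is.na(lo), is.na(hi))
    ok <- !is.na(lo)
    expect_true(all(lo[ok] <= mid[ok] + 1e-12))
    expect_true(all(mid[ok] <= hi[ok] + 1e-12))
  }
})

test_that("binning is half-open and out-of-grid points are dropped", {
  grid <- make_grid(c(0, 0.2, 0, 0.2), 0.1)
  cloud <- tibble::tibble(
    x = c(0.1, 0.0, 0.2, 0.1),    # 0.2 is on the outer edge -> dropped
    y = c(0.1, 0.0, 0.1, 0.2),
    z = 1:4 / 10
  )
  d <- rasterize(cloud, grid, "max")
  expect_equal(d$n_dropped, 2L)        # (0.2, .) and (., 0.2)
  expect_equal(d$values[2, 2], 0.1)    # boundary point went +x/+y
  expect_equal(d$values[1, 1], 0.2)

  # refining the grid never unmasks an empty region
  coarse <- rasterize(cloud, make_grid(c(0, 0.2, 0, 0.2), 0.2), "max")
  fine <- rasterize(cloud, make_grid(c(0, 0.2, 0, 0.2), 0.05), "max")
  expect_gte(sum(is.na(fine$values)) / length(fine$values),
             sum(is.na(coarse$values)) / length(coarse$values))

  # empty cloud: fully masked DSM, not an error
  empty <- rasterize(cloud[0, ], grid, "mean")
  expect_true(all(is.na(empty$values)))
})

test_that("point density is count over area", {
  cloud <- random_cloud(62500, seed = 3)
  expect_equal(point_density(cloud, 62500), 1.0)
  expect_equal(point_density(cloud[0, ], 100), 0)
  expect_error(point_density(cloud, 0), "> 0")
})
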