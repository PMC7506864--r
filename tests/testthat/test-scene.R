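test_that("ground relief is zero, reproducible, and has the stated sd", {
  layout <- make_layout(2.5, 5, 0.5, 0.3)
  flat <- generate_ground(layout, relief_sd = 0)
  set.seed(1)
  qx <- runif(100, 0, 2.5); qy <- runif(100, 0, 2.5)
  expect_equal(ground_height(flat, qx, qy), rep(0, 100))

  g1 <- generate_ground(layout, relief_sd = 0.01, seed = 11)
  g2 <- generate_ground(layout, relief_sd = 0.01, seed = 11)
  expect_identical(ground_height(g1, qx, qy), ground_height(g2, qx, qy))

  # empirical sd of the field within 20% of the requested relief_sd
  set.seed(2)
  qx <- runif(1e4, 0, 2.5); qy <- runif(1e4, 0, 2.5)
  z <- ground_height(g1, qx, qy)
  expect_lt(abs(sd(z) - 0.01) / 0.01, 0.2)
  expect_lt(abs(mean(z)), 0.005)

  expect_error(generate_ground(layout, relief_sd = -1), ">=")
})

test_that("canopy tips honour the requested mean, cv and leaf width", {
  layout <- make_layout(2.5, 5, 0.5, 0.3)
  ground <- generate_ground(layout, relief_sd = 0)

  # zero variance: every blade exactly at the subplot mean
  sc0 <- generate_canopy(ground, layout, subplot_mean_heights = 400,
                         height_cv = 0, blades_per_m2 = 100, seed = 3)
  expect_equal(unique(tidy(sc0)$tip_height), 0.4)
  expect_equal(unique(tidy(sc0)$width), 0.010)  # 10 mm study leaf width

  # ~1e4 blades: empirical mean within 2% of the 400 mm parameter
  sc <- generate_canopy(ground, layout, subplot_mean_heights = 400,
                        height_cv = 0.1, blades_per_m2 = 1600, seed = 4)
  expect_gt(nrow(tidy(sc)), 9000)
  expect_lt(abs(mean(tidy(sc)$tip_height) - 0.4) / 0.4, 0.02)

  # per-subplot means are honoured and the marginal stays lognormal-scale
  means <- seq(200, 680, length.out = 25)
  sc2 <- generate_canopy(ground, layout, subplot_mean_heights = means,
                         height_cv = 0.05, blades_per_m2 = 4000, seed = 5)
  by_sub <- tidy(sc2) |>
    dplyr::group_by(subplot_id) |>
    dplyr::summarise(m = mean(tip_height) * 1000)
  expect_lt(max(abs(by_sub$m - means) / means), 0.1)

  expect_error(
    generate_canopy(ground, layout, subplot_mean_heights = c(400, 300)),
    "one value per subplot"
  )
})

test_that("harvest cuts every blade to the stubble without moving bases", {
  sc <- constant_scene(height_mm = 500, blades_per_m2 = 400)
  post <- harvest(sc, 0.03)
  expect_equal(post$state, "post_harvest")
  expect_equal(unique(tidy(post)$tip_height), 0.03)
  expect_equal(nrow(tidy(post)), nrow(tidy(sc)))
  expect_identical(tidy(post)$x, tidy(sc)$x)
  expect_identical(tidy(post)$y, tidy(sc)$y)
  expect_equal(max(tidy(sc)$tip_height) - max(tidy(post)$tip_height), 0.47)

  expect_error(harvest(post, 0.03), "already harvested")
  expect_error(harvest(sc, 0.6), "below the shortest blade")
})

test_that("ruler truth averages probed blade tips per subplot", {
  layout <- make_layout(1.0, 2, 0.5, 0.3)
  sc <- generate_canopy(flat_ground(layout), layout,
                        subplot_mean_heights = 400, height_cv = 0,
                        blades_per_m2 = 200, seed = 6)
  tt <- ruler_truth(sc, n_probes = 5, seed = 1)
  expect_equal(nrow(tt), 4L)
  expect_equal(tt$height_mm, rep(400, 4))
  expect_equal(unique(tt$n_probes), 5L)

  # probing every blade reproduces the exact per-subplot mean
  scv <- generate_canopy(flat_ground(layout), layout,
                         subplot_mean_heights = 400, height_cv = 0.2,
                         blades_per_m2 = 200, seed = 7)
  exact <- tidy(scv) |>
    dplyr::group_by(subplot_id) |>
    dplyr::summarise(h = mean(tip_height) * 1000)
  n_per_sub <- min(table(tidy(scv)$subplot_id))   # 50 blades per subplot
  tt_all <- ruler_truth(scv, n_probes = n_per_sub, seed = 1)
  expect_equal(tt_all$height_mm, exact$h)

  # more probes than blades: sample with replacement, with a warning
  sparse <- generate_canopy(flat_ground(layout), layout,
                            subplot_mean_heights = 400, height_cv = 0,
                            blades_per_m2 = 8, seed = 8)
  expect_warning(ruler_truth(sparse, n_probes = 50, seed = 1), "replacement")

  expect_error(ruler_truth(harvest(scv, 0.03)), "before harvest")
})
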