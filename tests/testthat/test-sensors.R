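test_that("the noiseless SfM sampler returns the exact canopy envelope", {
  sc <- constant_scene(height_mm = 400, blades_per_m2 = 20000)
  cl <- sample_sfm(sc, ideal_sfm(density = 50, gvf = 0), seed = 9)
  expect_equal(unique(round(cl$z, 12)), 0.4)
  expect_equal(attr(cl, "epoch"), "pre_harvest")

  # ground_visible_fraction 1: every point is the local ground
  cl_g <- sample_sfm(sc, ideal_sfm(density = 50, gvf = 1), seed = 9)
  expect_equal(unique(cl_g$z), 0)

  expect_error(sample_sfm(sc, ideal_lidar()), "sfm sensor")
})

test_that("realized point counts match density x area within 1%", {
  layout <- small_layout()          # 0.5 m plot = 2500 cm2
  sc <- generate_canopy(flat_ground(layout), layout, 400, height_cv = 0,
                        blades_per_m2 = 500, seed = 2)
  for (sen in list(ideal_sfm(density = 40), ideal_lidar(density = 40))) {
    cl <- sample_cloud(sc, sen, scale = 1, seed = 3)
    expect_lt(abs(nrow(cl) - 40 * 2500) / (40 * 2500), 0.01)
  }
  # study densities survive the round trip through point_density
  cl9 <- sample_cloud(sc, sensor_hand_lidar(), scale = 1, seed = 4)
  expect_lt(abs(point_density(cl9, 2500) - 9), 0.09)
})

test_that("lidar returns ground on bare scenes and honours forced cover", {
  layout <- small_layout()
  bare <- generate_canopy(flat_ground(layout), layout, 400, height_cv = 0,
                          blades_per_m2 = 100, seed = 5)
  bare$blades <- bare$blades[0, ]
  cl <- sample_lidar(bare, ideal_lidar(density = 20), seed = 6)
  expect_equal(unique(cl$z), 0)

  # forced cover 0.5: ground-return fraction 0.5 +/- 0.01 over 1e5 beams
  sc <- constant_scene(height_mm = 400, blades_per_m2 = 2000)
  cl2 <- sample_lidar(sc, ideal_lidar(density = 40, cover = 0.5), seed = 7)
  expect_gt(nrow(cl2), 9e4)
  expect_lt(abs(mean(cl2$z < 0.2) - 0.5), 0.01)

  expect_error(sample_lidar(sc, ideal_sfm()), "lidar sensor")
})

test_that("identical seeds give bit-identical scenes and clouds", {
  run <- function() {
    sim <- simulate_study(sensors = list(lidar = sensor_hand_lidar(),
                                         uav = sensor_uav_sfm()),
                          layout = small_layout(2L), scale = 0.02, seed = 42)
    list(blades = tidy(sim$scene_before), truth = sim$truth,
         clouds = sim$clouds)
  }
  a <- run(); b <- run()
  expect_identical(a$blades, b$blades)
  expect_identical(a$truth, b$truth)
  expect_identical(a$clouds, b$clouds)
})

test_that("post-harvest lidar clouds contain ground returns where cover < 1", {
  layout <- small_layout(2L)
  sc <- generate_canopy(flat_ground(layout), layout, 400, height_cv = 0.1,
                        blades_per_m2 = 1500, seed = 10)
  post <- harvest(sc, 0.03)
  cl <- sample_lidar(post, sensor_hand_lidar(), scale = 0.5, seed = 11)
  frac_below_stubble <- mean(cl$z < 0.029)
  expect_gt(frac_below_stubble, 0.1)   # the laser passes between the leaves
  # and the pre-harvest canopy blocks almost every beam
  cl_pre <- sample_lidar(sc, sensor_hand_lidar(), scale = 0.5, seed = 11)
  expect_lt(mean(cl_pre$z < 0.02), 0.05)
})
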