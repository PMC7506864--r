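truth_of <- function(ids, mm) {
  tibble::tibble(subplot_id = ids, height_mm = mm, n_probes = 5L)
}

est_of <- function(ids, mm) {
  tibble::tibble(subplot_id = ids, estimate_mm = mm,
                 n_valid_cells = 9L, method = "maximum_minimum",
                 cell_size_mm = 20)
}

test_that("absolute-error statistics follow the MAE +/- SD convention", {
  st <- absolute_error_stats(est_of(1:3, c(410, 420, 430)),
                             truth_of(1:3, c(400, 400, 400)))
  expect_equal(st$errors$abs_error_mm, c(10, 20, 30))
  expect_equal(st$mae_mm, 20)
  expect_equal(st$sd_mm, sd(c(10, 20, 30)))

  ident <- absolute_error_stats(est_of(1:3, c(400, 410, 390)),
                                truth_of(1:3, c(400, 410, 390)))
  expect_equal(ident$mae_mm, 0)
  expect_equal(ident$sd_mm, 0)

  # 25 random pairs match a direct recomputation
  set.seed(31)
  e <- runif(25, 300, 500); t <- runif(25, 300, 500)
  st2 <- absolute_error_stats(est_of(1:25, e), truth_of(1:25, t))
  expect_equal(st2$mae_mm, mean(abs(e - t)))
  expect_equal(st2$sd_mm, sd(abs(e - t)))

  expect_error(absolute_error_stats(est_of(1:3, e[1:3]), truth_of(2:4, 1:3)),
               "missing from the truth")
})

test_that("one-way ANOVA F matches the closed-form hand computation", {
  g <- tibble::tibble(
    group = rep(c("a", "b", "c"), each = 3),
    error_mm = c(1, 2, 3, 2, 3, 4, 21, 22, 23)
  )
  res <- anova_tukey(g, alpha = 0.01)
  # group means 2, 3, 22; grand mean 9; SSB = 3*(49+36+169) = 762 on 2 df;
  # SSW = 2+2+2 = 6 on 6 df; F = (762/2) / (6/6) = 381
  expect_equal(res$f_statistic, 381, tolerance = 1e-12)
  flagged <- res$tukey[res$tukey$significant, "contrast", drop = TRUE]
  expect_setequal(flagged, c("c-a", "c-b"))
  expect_true(all(res$tukey$adj_p >= 0 & res$tukey$adj_p <= 1))

  # three identical groups: nothing significant
  same <- tibble::tibble(group = rep(c("a", "b", "c"), each = 3),
                         error_mm = rep(c(5, 6, 7), 3))
  res_same <- anova_tukey(same)
  expect_false(any(res_same$tukey$significant))

  # degenerate zero-variance input reports p = 1 with a warning
  flat <- tibble::tibble(group = rep(c("a", "b"), each = 3), error_mm = 1)
  expect_warning(res_flat <- anova_tukey(flat), "p = 1")
  expect_equal(res_flat$p_value, 1)

  expect_error(anova_tukey(tibble::tibble(group = "a", error_mm = 1)),
               "two groups")
})

test_that("Pearson correlation matches the covariance-formula oracle", {
  t <- c(400, 420, 440)
  expect_equal(height_correlation(t, t), 1)
  expect_equal(height_correlation(-t + 900, t), -1)

  set.seed(41)
  e <- runif(25, 300, 500); tr <- e + rnorm(25, 0, 30)
  oracle <- sum((e - mean(e)) * (tr - mean(tr))) /
    sqrt(sum((e - mean(e))^2) * sum((tr - mean(tr))^2))
  expect_equal(height_correlation(e, tr), oracle)

  expect_warning(r0 <- height_correlation(rep(1, 5), 1:5), "zero variance")
  expect_true(is.na(r0))
  expect_error(height_correlation(1:2, 1:2), "at least 3")
})

test_that("a degenerate sweep reduces to one absolute_error_stats call", {
  layout <- small_layout(2L)
  sim <- simulate_study(sensors = list(lidar = sensor_hand_lidar()),
                        layout = layout, scale = 0.3, seed = 17)
  sw <- run_sweep(sim$clouds, layout, sim$truth,
                  methods = "maximum_minimum", cell_sizes_mm = 20)
  expect_equal(nrow(summarize_sweep(sw)), 1L)
  est <- sw |> dplyr::select(subplot_id, estimate_mm, n_valid_cells,
                             method, cell_size_mm)
  direct <- absolute_error_stats(est, sim$truth)
  expect_equal(summarize_sweep(sw)$mae_mm, direct$mae_mm)
  expect_equal(summarize_sweep(sw)$sd_mm, direct$sd_mm)

  expect_error(run_sweep(list(lidar = list(before = sim$clouds$lidar$before)),
                         layout, sim$truth),
               "missing a before or after")
})

test_that("sensor comparison picks minima and breaks ties to larger cells", {
  # synthetic sweep: sensor A strictly dominates sensor B
  mk <- function(sensor, method, cs, base) {
    tibble::tibble(
      sensor = sensor, method = method, cell_size_mm = cs, subplot_id = 1:5,
      estimate_mm = 400 + base + c(-2, -1, 0, 1, 2),
      truth_mm = 400, n_valid_cells = 9L
    ) |>
      dplyr::mutate(abs_error_mm = abs(estimate_mm - truth_mm))
  }
  sweep <- dplyr::bind_rows(
    mk("A", "maximum_minimum", 20, 5), mk("A", "maximum_minimum", 50, 5),
    mk("A", "average", 20, 40), mk("A", "average", 50, 60),
    mk("B", "maximum_minimum", 20, 30), mk("B", "maximum_minimum", 50, 25),
    mk("B", "average", 20, 90), mk("B", "average", 50, 80)
  )
  class(sweep) <- c("sweep_table", class(sweep))
  cmp <- suppressWarnings(compare_sensors(sweep, alpha = 0.05))
  b <- glance(cmp)
  expect_equal(b$method[b$sensor == "A"], "maximum_minimum")
  # tie between 20 and 50 mm at MAE: the larger cell wins
  expect_equal(b$cell_size_mm[b$sensor == "A"], 50)
  expect_equal(b$cell_size_mm[b$sensor == "B"], 50)
  # dominance: A's errors are smaller everywhere
  expect_lt(b$mae_mm[b$sensor == "A"], b$mae_mm[b$sensor == "B"])
  expect_true(all(tidy(cmp)$adj_p >= 0 & tidy(cmp)$adj_p <= 1))
})

test_that("plots build from sweep summaries without evaluation", {
  smry <- tibble::tibble(
    sensor = rep(c("lidar", "uav_sfm"), each = 4),
    method = rep(c("maximum", "average", "minimum", "maximum_minimum"), 2),
    cell_size_mm = 20, mae_mm = c(25, 28, 41, 11, 70, 120, 330, 26),
    sd_mm = 10, n_subplots = 25L
  )
  p <- plot_error_sweep(smry)
  expect_s3_class(p, "ggplot")
})
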