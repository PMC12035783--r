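series_at <- function(days, diam) {
  # daily series hitting the given (day, diameter) anchor points linearly
  all_days <- min(days):max(days)
  data.frame(day = all_days,
             diameter = approx(days, diam, xout = all_days)$y)
}

test_that("increment widths are half the diameter change, clamped at zero", {
  tr <- series_at(c(0, 3, 6, 9), c(10.00, 10.10, 10.10, 10.30))
  inc <- compute_increments(tr, c(0, 3, 6, 9))
  expect_equal(inc$width, c(50, 0, 100), tolerance = 1e-9)
  expect_equal(inc$cum_inner, c(150, 100, 100), tolerance = 1e-9)
  expect_equal(inc$cum_outer, c(100, 100, 0), tolerance = 1e-9)

  const <- series_at(c(0, 6), c(10, 10))
  expect_equal(compute_increments(const, c(0, 3, 6))$width, c(0, 0))

  shrink <- data.frame(day = 0:2, diameter = c(10.0, 9.9, 10.0))
  expect_equal(compute_increments(shrink, 0:2)$width, c(0, 50),
               tolerance = 1e-9)
})

test_that("width-extraction methods agree on clean monotone series", {
  tr <- series_at(c(0, 4, 8, 12), c(8, 8.2, 8.2, 8.5))
  b <- c(0, 4, 8, 12)
  w_end <- compute_increments(tr, b, method = "endpoint")$width
  w_day <- compute_increments(tr, b, method = "daily")$width
  w_max <- compute_increments(tr, b, method = "max")$width
  expect_equal(w_day, w_end, tolerance = 1e-9)
  expect_equal(w_max, w_end, tolerance = 1e-9)
})

test_that("running-max widths ignore a reversible mid-period shrinkage", {
  d <- c(10, 10.04, 10.00, 9.96, 10.04, 10.08)  # shrink and recover
  tr <- data.frame(day = 0:5, diameter = d)
  w <- compute_increments(tr, c(0, 2, 5), method = "max")$width
  expect_equal(w, c(20, 20), tolerance = 1e-9)  # growth 10 -> 10.04 -> 10.08
})

test_that("boundary validation errors are typed", {
  tr <- series_at(c(0, 9), c(10, 10.3))
  expect_error(compute_increments(tr, c(3, 0, 9)), class = "xylo_boundary_error")
  expect_error(compute_increments(tr, c(0, 12)), class = "xylo_boundary_error")
})

test_that("cells are dated by half-open interval membership with boundary flags", {
  inc <- increments_from_widths(c(50, 50, 50))
  cells <- data.frame(sample_id = "S", cell_class = "fibre",
                      cell_area = 80, lumen_area = 10, centroid_x = 0,
                      centroid_y = c(10, 60, 149, 150, -1))
  d <- assign_cells(cells, inc, cambium_y = 0)
  expect_equal(d$period_index[1:3], c(3L, 2L, 1L))
  expect_equal(d$flag[4], "pre_experiment")   # depth == total growth
  expect_equal(d$flag[5], "unassigned")       # negative depth
  expect_equal(sum(d$flag == "assigned") + sum(d$flag == "pre_experiment") +
                 sum(d$flag == "unassigned"), nrow(cells))
})

test_that("zero-width increments receive no cells and overlaps are rejected", {
  inc <- increments_from_widths(c(50, 0, 100))
  cells <- data.frame(sample_id = "S", cell_class = "fibre", cell_area = 80,
                      lumen_area = 10, centroid_x = 0,
                      centroid_y = seq(0.5, 149.5, by = 1))
  d <- assign_cells(cells, inc, cambium_y = 0)
  expect_equal(sum(d$period_index == 2, na.rm = TRUE), 0)
  expect_equal(sum(d$flag == "assigned"), nrow(cells))

  bad <- inc; bad$cum_outer[1] <- 20  # overlaps increment 3
  expect_error(assign_cells(cells, bad, cambium_y = 0),
               class = "xylo_increment_error")
})

test_that("assignment matches a brute-force scan on random instances", {
  set.seed(101)
  for (rep in 1:100) {
    n_inc <- sample(1:8, 1)
    widths <- round(runif(n_inc, 0, 40), 2)
    widths[sample(n_inc, 1)] <- 0  # always include a degenerate increment
    if (sum(widths) == 0) widths[1] <- 10
    inc <- increments_from_widths(widths)
    n_cells <- sample(1:50, 1)
    depth <- round(runif(n_cells, -5, sum(widths) + 5), 3)
    cells <- data.frame(sample_id = "S", cell_class = "fibre", cell_area = 1,
                        lumen_area = 0, centroid_x = 0, centroid_y = depth)
    d <- assign_cells(cells, inc, cambium_y = 0)
    got <- ifelse(d$flag == "assigned", as.character(d$period_index), d$flag)
    expect_identical(got, brute_force_assign(depth, inc))
  }
})

test_that("period index is non-increasing in depth on noise-free data", {
  p <- noise_free(sim_params(n_trees_per_treatment = 2, n_days = 30))
  exp <- simulate_experiment(p, tiny_schedule(30), seed = 13)
  zon <- date_experiment(exp$detections, exp$growth, period_boundaries(30, 3),
                         exp$schedule, cambium_y = 0)
  for (s in unique(zon$dated$sample_id)) {
    d <- zon$dated[zon$dated$sample_id == s & zon$dated$flag == "assigned", ]
    o <- order(d$depth_from_cambium)
    expect_true(all(diff(d$period_index[o]) <= 0))
  }
})

test_that("noise-free dating recovers the true production period for every cell", {
  p <- noise_free(sim_params(n_trees_per_treatment = 4))
  exp <- simulate_experiment(p, seed = 31)
  b <- period_boundaries(p$n_days, 3)
  zon <- date_experiment(exp$detections, exp$growth, b, exp$schedule,
                         cambium_y = 0)
  truth <- exp$truth$cells
  # increment i spans growth accrued on days (b_i, b_{i+1}]; day-0 growth
  # predates the first measured boundary, like pre-experiment wood
  true_period <- findInterval(truth$production_day, b, left.open = TRUE)
  true_period[truth$production_day < 1] <- NA
  dd <- zon$dated
  expect_identical(dd$flag == "pre_experiment", is.na(true_period))
  ok <- dd$period_index == true_period
  expect_equal(mean(ok, na.rm = TRUE), 1)
})

test_that("2 um placement noise still dates >= 90% of cells into 20 um increments", {
  p <- sim_params(n_trees_per_treatment = 4, diameter_noise_sd = 0,
                  shrinkage_amplitude = 0, placement_noise_sd = 2)
  exp <- simulate_experiment(p, seed = 37)
  b <- period_boundaries(p$n_days, 3)  # >= 20 um per 3-day watered period
  zon <- date_experiment(exp$detections, exp$growth, b, exp$schedule,
                         cambium_y = 0)
  truth <- exp$truth$cells
  true_period <- findInterval(truth$production_day, b, left.open = TRUE)
  true_period[truth$production_day < 1] <- NA
  # judge only cells whose true increment (per sample) is at least 20 um wide
  key <- paste(zon$increments$sample_id, zon$increments$period_index)
  width_of <- setNames(zon$increments$width, key)
  true_w <- width_of[paste(zon$dated$sample_id, true_period)]
  sel <- !is.na(true_period) & !is.na(true_w) & true_w >= 20
  expect_gte(mean(zon$dated$period_index[sel] == true_period[sel],
                  na.rm = TRUE), 0.9)
})
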