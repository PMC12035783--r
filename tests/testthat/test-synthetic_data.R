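test_that("schedules alternate DT/WT with drought lengths in the configured range", {
  s <- generate_schedule(n_cycles = 6, drought_range = c(3, 7), seed = 11)
  dt <- s[s$status == "droughted", ]
  expect_equal(nrow(dt), 6)
  expect_equal(sum(s$status == "watered"), 7)  # WT0 lead-in plus WT1..WT6
  lens <- dt$end_day - dt$start_day + 1
  expect_true(all(lens >= 3 & lens <= 7))
  expect_true(all(s$start_day[-1] == head(s$end_day, -1) + 1))
  expect_true(all(s$status[-1] != head(s$status, -1)))
})

test_that("degenerate fixed-length schedule spans exactly lead_in + 2 * len days", {
  s <- generate_schedule(n_cycles = 1, drought_range = c(3, 3),
                         watered_range = c(3, 3), n_days = 9, lead_in = 3,
                         seed = 1)
  expect_equal(s$label, c("WT0", "DT1", "WT1"))
  expect_equal(max(s$end_day) - min(s$start_day) + 1, 9)
})

test_that("schedule generation is deterministic for a fixed seed and errors on overflow", {
  expect_identical(generate_schedule(seed = 1), generate_schedule(seed = 1))
  expect_error(generate_schedule(n_cycles = 10, drought_range = c(7, 7),
                                 watered_range = c(7, 7), n_days = 30, seed = 1),
               class = "xylo_schedule_truncation_error")
})

test_that("parameter validation rejects non-physical settings", {
  expect_error(sim_params(n_days = 1), class = "xylo_param_error")
  expect_error(sim_params(drought_effect_wall = 0), class = "xylo_param_error")
  expect_error(sim_params(drought_effect_wall = 1.6), class = "xylo_param_error")
  expect_error(sim_params(lwp_baseline = 0.5), class = "xylo_param_error")
  expect_error(sim_params(cells_per_day = -1), class = "xylo_param_error")
})

test_that("control trees without shrinkage grow monotonically and conserve growth", {
  p <- noise_free(sim_params())
  tr <- simulate_tree(tiny_schedule(75), p, "CI", seed = 3)
  expect_true(all(diff(tr$series$diameter) >= 0))
  # conservation: diameter gain equals twice the summed radial growth
  gain_mm <- tr$series$diameter[75] - (p$initial_diameter + 2 * tr$growth_um[1] / 1000)
  expect_equal(gain_mm, 2 * sum(tr$growth_um[-1]) / 1000, tolerance = 1e-12)
})

test_that("PI trees reach the configured drought floor and rebound on rewatering", {
  p <- sim_params(lwp_drought_min = -2.4)
  s <- generate_schedule(seed = 21)
  tr <- simulate_tree(s, p, "PI", seed = 4)
  expect_lt(min(tr$lwp$psi_pd), -2.2)
  expect_gt(min(tr$lwp$psi_pd), -2.4 - 4 * p$lwp_noise_sd)
  # watered days sit near baseline
  status <- xylokinetics:::schedule_day_status(s, p$n_days)
  expect_lt(max(abs(tr$lwp_true[status == "watered"] - p$lwp_baseline)), 1e-9)
})

test_that("noise-free generative rule: phi * D cells of width D tile the growth", {
  p <- noise_free(sim_params(n_days = 10, pre_days = 0))
  s <- structure(data.frame(label = "WT0", start_day = 0, end_day = 9,
                            status = "watered"),
                 class = c("xylo_schedule", "data.frame"))
  tr <- simulate_tree(s, p, "CI", seed = 1)
  cells <- simulate_cells(tr, p, seed = 1)
  fib <- cells[cells$cell_class == "fibre", ]
  expect_equal(nrow(fib), 20)  # 2 cells/day * 10 days
  expect_equal(sort(fib$centroid_y), seq(5, 195, by = 10), tolerance = 1e-9)
  expect_true(all(abs(fib$cell_area - pi * 25) < 1e-9))
})

test_that("zero growth yields an empty cell table with a warning", {
  p <- noise_free(sim_params(n_days = 5, pre_days = 0))
  s <- structure(data.frame(label = "WT0", start_day = 0, end_day = 4,
                            status = "watered"),
                 class = c("xylo_schedule", "data.frame"))
  tr <- simulate_tree(s, p, "CI", seed = 1)
  tr$growth_um[] <- 0
  expect_warning(cells <- simulate_cells(tr, p, seed = 1), "zero total growth")
  expect_equal(nrow(cells), 0)
})

test_that("radial ordering: later-produced cells lie closer to the cambium", {
  p <- noise_free(sim_params(n_days = 30, pre_days = 5))
  s <- tiny_schedule(30)
  tr <- simulate_tree(s, p, "PI", seed = 9)
  cells <- simulate_cells(tr, p, seed = 9)
  truth <- attr(cells, "truth")
  fib <- truth[cells$cell_class == "fibre", ]
  o <- order(fib$center_depth, decreasing = TRUE)  # deepest = oldest
  expect_true(all(diff(fib$production_day[o]) >= 0))
})

test_that("experiment simulation is bit-identical for a fixed seed", {
  p <- sim_params(n_trees_per_treatment = 3, n_days = 30)
  s <- tiny_schedule(30)
  e1 <- simulate_experiment(p, s, seed = 42)
  e2 <- simulate_experiment(p, s, seed = 42)
  expect_identical(e1$detections, e2$detections)
  expect_identical(e1$growth, e2$growth)
  expect_identical(e1$lwp, e2$lwp)
  expect_identical(e1$cambium, e2$cambium)
})

test_that("drought multipliers scale affected-cell trait means as configured", {
  p <- sim_params(n_trees_per_treatment = 30, drought_effect_vessel_csa = 0.8,
                  drought_effect_fibre_csa = 0.9)
  exp <- simulate_experiment(p, seed = 77)
  truth <- exp$truth$cells
  pi_tree <- grepl("^PI", truth$sample_id)
  ves <- exp$detections$cell_class == "vessel"
  fib <- exp$detections$cell_class == "fibre"
  base_v <- pi * (p$mean_vessel_diameter / 2)^2
  base_f <- pi * (p$mean_fibre_diameter / 2)^2
  mv <- mean(exp$detections$cell_area[ves & pi_tree & truth$affected])
  mf <- mean(exp$detections$cell_area[fib & pi_tree & truth$affected])
  expect_equal(mv / base_v, 0.8, tolerance = 0.05)
  expect_equal(mf / base_f, 0.9, tolerance = 0.05)
  # unaffected cells stay at baseline
  expect_equal(mean(exp$detections$cell_area[ves & !truth$affected]) / base_v,
               1, tolerance = 0.05)
})

test_that("under the null configuration PI and CI vessel cohorts are exchangeable", {
  # compare per-tree mean vessel areas: cells within a tree share a random
  # tree factor, so the cell-level pooled t test would be anti-conservative
  pvals <- vapply(1:20, function(i) {
    p <- sim_params(n_trees_per_treatment = 6, null = TRUE)
    exp <- simulate_experiment(p, seed = 500 + i)
    ves <- exp$detections[exp$detections$cell_class == "vessel", ]
    by_tree <- tapply(ves$cell_area, ves$sample_id, mean)
    stats::t.test(by_tree[grepl("^PI", names(by_tree))],
                  by_tree[grepl("^CI", names(by_tree))])$p.value
  }, numeric(1))
  expect_lte(sum(pvals < 0.05), 4)       # ~1 expected under uniformity
  expect_gt(mean(pvals), 0.2)            # not piled near zero
  expect_lt(mean(pvals), 0.8)            # not piled near one
})
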