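test_that("production rate is growth per mean cell diameter per day", {
  expect_equal(cell_production_rate(200, 10, 10), 2.0, tolerance = 1e-12)
  expect_equal(cell_production_rate(0, 10, 10), 0)
  expect_equal(cell_production_rate(200, 10, 20),
               cell_production_rate(200, 10, 10) / 2, tolerance = 1e-12)
  expect_error(cell_production_rate(200, 0, 10), class = "xylo_param_error")
  expect_error(cell_production_rate(200, 10, -1), class = "xylo_param_error")
})

test_that("cycle and phase durations follow the count-over-rate identities", {
  expect_equal(cell_cycle_duration(4, 2), 2, tolerance = 1e-12)
  expect_equal(cell_cycle_duration(0, 2), 0)
  expect_true(is.na(cell_cycle_duration(4, 0)))
  expect_equal(phase_duration(6, 2), 3, tolerance = 1e-12)
  expect_equal(phase_rate(120, 30, 3), 30, tolerance = 1e-12)
  expect_equal(phase_rate(30, 30, 3), 0)
  expect_error(phase_rate(120, 30, 0), class = "xylo_param_error")

  set.seed(11)
  eta <- runif(1000, 0.1, 12)
  phi <- runif(1000, 0.05, 6)
  expect_equal(cell_cycle_duration(eta, phi) * phi, eta, tolerance = 1e-12)
  t_sigma <- phase_duration(eta, phi)
  s0 <- runif(1000, 1, 50); s1 <- runif(1000, 51, 400)
  expect_equal(phase_rate(s1, s0, t_sigma) * t_sigma + s0, s1,
               tolerance = 1e-12)
})

test_that("kinetics are invariant under uniform length rescaling", {
  c_scale <- 3.7
  p <- sim_params(n_trees_per_treatment = 3, n_days = 30)
  exp <- simulate_experiment(p, tiny_schedule(30), seed = 17)
  periods <- data.frame(period_label = c("P1", "P2"),
                        start_day = c(5, 18), end_day = c(15, 28))
  k1 <- estimate_kinetics(exp$detections, exp$growth, exp$cambium,
                          exp$phases, periods, cambium_y = 0)
  det2 <- exp$detections
  det2$cell_area <- det2$cell_area * c_scale^2
  det2$lumen_area <- det2$lumen_area * c_scale^2
  det2$centroid_y <- det2$centroid_y * c_scale
  g2 <- exp$growth
  init <- min(g2$diameter)
  g2$diameter <- init + (g2$diameter - init) * c_scale
  k2 <- estimate_kinetics(det2, g2, exp$cambium, exp$phases, periods,
                          cambium_y = 0)
  expect_equal(k2$phi, k1$phi, tolerance = 1e-9)
  expect_equal(k2$t_phi, k1$t_phi, tolerance = 1e-9)
  expect_equal(k2$t_sigma, k1$t_sigma, tolerance = 1e-9)
})

test_that("kinetics recover generator truth on the control arm", {
  p <- sim_params(n_trees_per_treatment = 6)
  exp <- simulate_experiment(p, seed = 23)
  ci <- unique(exp$growth$tree_id[exp$growth$treatment == "CI"])
  kin <- estimate_kinetics(
    exp$detections[exp$detections$sample_id %in% ci, ],
    exp$growth[exp$growth$tree_id %in% ci, ],
    exp$cambium[exp$cambium$sample_id %in% ci, ],
    exp$phases[exp$phases$sample_id %in% ci, ])
  expect_equal(mean(kin$phi), p$cells_per_day, tolerance = 0.1)
  expect_equal(mean(kin$t_phi), p$cambial_zone_cells / p$cells_per_day,
               tolerance = 0.15)
  # identities hold row-wise to machine precision
  ok <- !is.na(kin$t_phi)
  expect_equal(kin$t_phi[ok] * kin$phi[ok], kin$eta_c[ok], tolerance = 1e-12)
  expect_equal(kin$t_sigma[ok] * kin$phi[ok], kin$eta_x[ok], tolerance = 1e-12)
})

test_that("a zero-growth period reports zero production and flags durations", {
  p <- noise_free(sim_params(n_trees_per_treatment = 1, n_days = 30,
                             pre_days = 0))
  s <- tiny_schedule(30)
  tr <- simulate_tree(s, p, "CI", seed = 2, tree_id = "CI01", block = "B")
  tr$growth_um[16:30] <- 0  # growth stops from day 15
  tr$series$diameter <- p$initial_diameter + 2 * cumsum(tr$growth_um) / 1000
  cells <- simulate_cells(tr, p, seed = 2)
  cambium <- data.frame(sample_id = "CI01", day = c(5, 20), mean_count = 4)
  phases <- data.frame(sample_id = "CI01", eta_x = 6, size_begin = 20)
  periods <- data.frame(period_label = c("grew", "stopped"),
                        start_day = c(0, 16), end_day = c(14, 29))
  kin <- estimate_kinetics(cells, tr$series, cambium, phases, periods)
  stopped <- kin[kin$period_label == "stopped", ]
  expect_equal(stopped$phi, 0)
  expect_true(is.na(stopped$t_phi))
  expect_true(is.na(stopped$t_sigma))
  expect_gt(kin$phi[kin$period_label == "grew"], 0)
})
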