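sim_lwp_gamma <- function(n_per_arm = 100, mean_ci = 0.5, mean_pi = 2.2,
                          shape = 50, n_cycles = 4) {
  data.frame(
    psi_pd = -c(rgamma(n_per_arm, shape, shape / mean_ci),
                rgamma(n_per_arm, shape, shape / mean_pi)),
    treatment = rep(c("CI", "PI"), each = n_per_arm),
    cycle = rep(seq_len(n_cycles), length.out = 2 * n_per_arm))
}

test_that("Gamma-identity GLM recovers a known treatment shift in LWP magnitude", {
  set.seed(19)
  est <- p <- numeric(30)
  for (i in 1:30) {
    m <- fit_lwp_glm(sim_lwp_gamma())
    est[i] <- m$estimate_treatment
    p[i] <- m$p_treatment
  }
  expect_equal(mean(est), 1.7, tolerance = 0.05)  # 2.2 - 0.5 on magnitude scale
  expect_gte(mean(p < 0.05), 0.95)
})

test_that("LWP GLM preconditions are enforced", {
  d <- sim_lwp_gamma(n_cycles = 1)
  expect_error(fit_lwp_glm(d), class = "xylo_precondition_error")
  d2 <- sim_lwp_gamma()
  d2 <- d2[d2$treatment == "CI", ]
  expect_error(fit_lwp_glm(d2), class = "xylo_precondition_error")
  d3 <- sim_lwp_gamma()
  d3$psi_pd[1] <- 0
  expect_error(fit_lwp_glm(d3), class = "xylo_sign_error")
})

test_that("label_lwp joins treatment and numbers cycles from the schedule", {
  p <- sim_params(n_trees_per_treatment = 2, n_days = 20)
  exp <- simulate_experiment(p, tiny_schedule(20), seed = 3)
  lab <- label_lwp(exp$lwp, exp$growth, exp$schedule)
  expect_true(all(lab$treatment[grepl("^PI", lab$tree_id)] == "PI"))
  expect_equal(unique(lab$cycle), 1)  # single-cycle schedule
  orphan <- exp$lwp
  orphan$tree_id[1] <- "ghost"
  expect_error(label_lwp(orphan, exp$growth, exp$schedule),
               class = "xylo_join_error")
})

test_that("trait LMM finds an injected Treatment x Period interaction", {
  p <- sim_params(drought_effect_vessel_csa = 0.8)
  exp <- simulate_experiment(p, seed = 61)
  zon <- date_experiment(exp$detections, exp$growth,
                         period_boundaries(p$n_days, 3), exp$schedule)
  m <- fit_trait_lmm(zon$dated, "vessel_csa")
  expect_lt(m$p_interaction, 0.05)
  expect_s3_class(m$fit, "lme")
})

test_that("windowed contrasts point the right way under an injected CSA reduction", {
  p <- sim_params(drought_effect_vessel_csa = 0.8)
  exp <- simulate_experiment(p, seed = 67)
  zon <- date_experiment(exp$detections, exp$growth,
                         period_boundaries(p$n_days, 3), exp$schedule)
  w <- drought_windows(label_lwp(exp$lwp, exp$growth, exp$schedule))
  expect_gt(nrow(w), 0)
  m <- fit_trait_lmm(zon$dated, "vessel_csa", windows = w)
  est <- m$windows[!is.na(m$windows$p), ]
  expect_gt(nrow(est), 0)
  expect_lt(mean(est$estimate), 0)  # PI minus CI is negative
  expect_gt(mean(est$p < 0.05), 0.5)
})

test_that("trait LMM preconditions and sample-relabelling invariance hold", {
  p <- sim_params(n_trees_per_treatment = 4, n_days = 40)
  exp <- simulate_experiment(p, tiny_schedule(40), seed = 71)
  zon <- date_experiment(exp$detections, exp$growth, period_boundaries(40, 5),
                         exp$schedule)
  only_ci <- zon$dated[zon$dated$treatment == "CI", ]
  expect_error(fit_trait_lmm(only_ci, "fibre_csa"),
               class = "xylo_precondition_error")

  m1 <- fit_trait_lmm(zon$dated, "fibre_csa")
  relab <- zon$dated
  ids <- unique(relab$sample_id)
  new_ids <- setNames(sample(sprintf("X%02d", seq_along(ids))), ids)
  relab$sample_id <- unname(new_ids[relab$sample_id])
  m2 <- fit_trait_lmm(relab, "fibre_csa")
  expect_equal(m2$p_interaction, m1$p_interaction, tolerance = 1e-6)
})

test_that("wall-thickness LMM runs on derived per-cell wall estimates", {
  p <- sim_params(n_trees_per_treatment = 4, n_days = 40,
                  drought_effect_wall = 0.7)
  exp <- simulate_experiment(p, tiny_schedule(40), seed = 73)
  zon <- date_experiment(exp$detections, exp$growth, period_boundaries(40, 5),
                         exp$schedule)
  m <- fit_trait_lmm(zon$dated, "wall_thickness")
  expect_true(is.finite(m$p_interaction))
})

test_that("relative increment ratios compare treatments in the study's order", {
  g <- growth_from_ratios(c(1.1, 1.2, 1.3), c(1.1, 1.2, 1.3))
  m <- relative_increment_test(g)
  d <- m$terms[m$terms$measure == "diameter", ]
  expect_equal(d$statistic_t, 0, tolerance = 1e-9)
  expect_equal(d$p_t, 1, tolerance = 1e-9)
  expect_equal(d$mean_ratio_CI, 1.2, tolerance = 1e-9)

  set.seed(5)
  for (i in 1:5) {
    gg <- growth_from_ratios(rnorm(48, 1.20, 0.02), rnorm(48, 1.10, 0.02))
    mm <- relative_increment_test(gg)
    expect_lt(mm$terms$p_t[mm$terms$measure == "diameter"], 0.001)
    expect_lt(mm$terms$p_anova[mm$terms$measure == "diameter"], 0.001)
  }

  bad <- growth_from_ratios(1.1, 1.1)
  bad$diameter[bad$day == 0] <- 0
  expect_error(relative_increment_test(bad), class = "xylo_invariant_error")
})

test_that("drought windows are sub-threshold runs extended by the enlargement lag", {
  lwp <- data.frame(tree_id = rep(c("PI01", "PI02"), each = 30),
                    day = rep(0:29, 2),
                    psi_pd = rep(-0.5, 60), treatment = "PI")
  lwp$psi_pd[lwp$day %in% 10:12] <- -2.2
  lwp$psi_pd[lwp$day %in% 20:21] <- -2.3
  w <- drought_windows(lwp, threshold = -2, lag = 3)
  expect_equal(w$start_day, c(7, 17))
  expect_equal(w$end_day, c(12, 21))
  # overlapping windows merge
  lwp$psi_pd[lwp$day %in% 14:16] <- -2.4
  w2 <- drought_windows(lwp, threshold = -2, lag = 3)
  expect_equal(nrow(w2), 2)
  expect_equal(w2$start_day[1], 7)
  expect_equal(w2$end_day[1], 16)
  # no stress, no windows
  calm <- data.frame(tree_id = "PI01", day = 0:9, psi_pd = -0.4,
                     treatment = "PI")
  expect_equal(nrow(drought_windows(calm)), 0)
})
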