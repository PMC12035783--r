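#' Simulate one tree's growth, water-status and height series
#'
#' Produces a daily stem-diameter and height series plus a pre-dawn leaf
#' water potential (LWP) series for one tree under either continuous (CI)
#' or periodic (PI) irrigation.
#'
#' Mechanism: PI-tree LWP sits at `lwp_baseline` while watered and declines
#' along a square-root profile to `lwp_drought_min` over each drought phase,
#' rebounding to baseline on rewatering (CI trees stay at baseline). Radial
#' xylem growth runs at `cells_per_day * mean_fibre_diameter` um/day,
#' multiplied by a factor that is 1 above `lwp_threshold` and falls linearly
#' to 0 at `lwp_drought_min`. The observed diameter is the cumulative true
#' growth minus a reversible elastic shrinkage proportional to the
#' sub-threshold stress, plus caliper noise. Height is a scaled noisy copy of
#' the diameter trend.
#'
#' @param schedule A `xylo_schedule` (see [generate_schedule()]).
#' @param params A `xylo_params` (see [sim_params()]).
#' @param treatment `"CI"` or `"PI"`.
#' @param seed Optional seed; if `NULL` the current RNG state is used so that
#'   experiment-level seeding flows through.
#' @param tree_id,block Identifiers carried into the output tables.
#' @return An object of class `xylo_tree`: a list with `series` (day,
#'   diameter mm, height cm), `lwp` (day, psi_pd MPa), the true daily radial
#'   growth `growth_um`, the noise-free LWP signal `lwp_true`, the logical
#'   per-day vectors `subthreshold` and `affected` (drought trait effects,
#'   including the enlargement lag), and bookkeeping fields.
#' @export
simulate_tree <- function(schedule, params, treatment = c("CI", "PI"),
                          seed = NULL, tree_id = "T1", block = "A") {
  treatment <- match.arg(treatment)
  stopifnot(inherits(params, "xylo_params"))
  validate_schedule(schedule)
  if (!is.null(seed)) set.seed(seed)
  p <- params
  n <- p$n_days
  days <- 0:(n - 1)

  lwp_true <- rep(p$lwp_baseline, n)
  if (treatment == "PI") {
    dt <- schedule[schedule$status == "droughted", , drop = FALSE]
    for (i in seq_len(nrow(dt))) {
      span <- seq(dt$start_day[i], min(dt$end_day[i], n - 1))
      span <- span[span >= 0]
      if (!length(span)) next
      len <- dt$end_day[i] - dt$start_day[i] + 1
      frac <- (span - dt$start_day[i] + 1) / len
      lwp_true[span + 1] <- p$lwp_baseline +
        (p$lwp_drought_min - p$lwp_baseline) * sqrt(frac)
    }
  }
  subthreshold <- lwp_true < p$lwp_threshold

  # growth multiplier: 1 above threshold, linear to 0 at the drought floor
  mult <- rep(1, n)
  if (any(subthreshold)) {
    denom <- p$lwp_threshold - p$lwp_drought_min
    mult[subthreshold] <- pmax(0, (lwp_true[subthreshold] - p$lwp_drought_min) / denom)
  }
  base_rate <- p$cells_per_day * p$mean_fibre_diameter  # um/day radial
  growth_um <- base_rate * mult

  # drought-affected production days: a cell enlarges for `enlargement_lag`
  # days after production, so stress reaches back that far
  affected <- rep(FALSE, n)
  if (any(subthreshold)) {
    idx <- which(subthreshold)
    for (i in idx) affected[max(1, i - p$enlargement_lag):i] <- TRUE
  }

  stress <- ifelse(subthreshold,
                   (p$lwp_threshold - lwp_true) /
                     max(p$lwp_threshold - p$lwp_drought_min, .Machine$double.eps),
                   0)
  shrink <- p$shrinkage_amplitude * stress  # mm, elastic (recovers fully)

  diameter <- p$initial_diameter + 2 * cumsum(growth_um) / 1000 - shrink +
    stats::rnorm(n, 0, p$diameter_noise_sd)
  height <- 50 + (diameter - p$initial_diameter) * (10 / 3) +
    stats::rnorm(n, 0, 0.2)

  psi <- pmin(lwp_true + stats::rnorm(n, 0, p$lwp_noise_sd), -0.01)

  structure(list(
    tree_id = tree_id, block = block, treatment = treatment,
    series = data.frame(tree_id = tree_id, block = block,
                        treatment = treatment, day = days,
                        diameter = diameter, height = height,
                        stringsAsFactors = FALSE),
    lwp = data.frame(tree_id = tree_id, day = days, psi_pd = psi,
                     stringsAsFactors = FALSE),
    growth_um = growth_um, lwp_true = lwp_true,
    subthreshold = subthreshold, affected = affected,
    params = p, schedule = schedule
  ), class = "xylo_tree")
}

#' Simulate the detected-cell table for one tree
#'
#' Generates a cell-detection export table (the schema produced by the image
#' analysis step: class, cell area, lumen area, centroid coordinates) for one
#' simulated tree, by inverting the cell-production relation: fibres of mean
#' radial diameter D stack radially to consume each day's growth, so the
#' production rate is growth rate / D. Vessels are seeded as a Poisson process
#' with intensity `vessel_frequency * growth_mm * image_width_mm` per day and
#' placed uniformly within that day's growth band. Cell areas are lognormal
#' around the parameter means (CV `trait_cv`, per-tree factor CV `tree_cv`);
#' drought-affected days multiply vessel area, fibre area and fibre wall
#' thickness by the corresponding `drought_effect_*` factors. Fibre lumen
#' area follows a concentric-circle model from the drawn wall thickness.
#'
#' Radial geometry: the cambium sits at `centroid_y = 0` and depth increases
#' with y, so `centroid_y` equals depth-from-cambium plus Gaussian placement
#' noise. A band of pre-experiment wood (`pre_days` of watered growth) sits
#' beyond the experiment's total growth.
#'
#' @param tree A `xylo_tree` from [simulate_tree()].
#' @param params A `xylo_params`; defaults to the tree's own.
#' @param seed Optional seed.
#' @return A detection table (data frame with columns `sample_id`,
#'   `cell_class`, `cell_area`, `lumen_area`, `centroid_x`, `centroid_y`)
#'   with attribute `"truth"`: a row-aligned data frame of `production_day`
#'   (-1 for pre-experiment wood), `center_depth` (noise-free depth, um) and
#'   `affected` (drought trait effect applied).
#' @export
simulate_cells <- function(tree, params = tree$params, seed = NULL) {
  stopifnot(inherits(tree, "xylo_tree"))
  if (!is.null(seed)) set.seed(seed)
  p <- params
  base_rate <- p$cells_per_day * p$mean_fibre_diameter
  pre_growth <- rep(base_rate, p$pre_days)
  g <- c(pre_growth, tree$growth_um)                       # um/day
  day_of <- c(rep(-1L, p$pre_days), 0:(p$n_days - 1))      # -1 = pre-experiment
  affected <- c(rep(FALSE, p$pre_days), tree$affected)
  total <- sum(g)
  empty <- data.frame(sample_id = character(), cell_class = character(),
                      cell_area = numeric(), lumen_area = numeric(),
                      centroid_x = numeric(), centroid_y = numeric(),
                      stringsAsFactors = FALSE)
  if (total <= 0) {
    warning("tree has zero total growth; returning empty cell table")
    attr(empty, "truth") <- data.frame(production_day = integer(),
                                       center_depth = numeric(),
                                       affected = logical())
    return(empty)
  }
  cum <- cumsum(g)
  tree_f_fibre <- rlnorm_mcv(1, 1, p$tree_cv)
  tree_f_vessel <- rlnorm_mcv(1, 1, p$tree_cv)
  tree_f_wall <- rlnorm_mcv(1, 1, p$tree_cv)

  # --- fibres: stack radial diameters until the cumulative growth is consumed
  f_center <- numeric(0)
  f_diam <- numeric(0)
  pos <- 0
  pending <- NA_real_
  for (di in seq_along(g)) {
    if (g[di] <= 0) next
    repeat {
      if (is.na(pending)) pending <- rlnorm_mcv(1, p$mean_fibre_diameter, p$trait_cv)
      if (pos + pending > cum[di] + 1e-9) break
      f_center <- c(f_center, pos + pending / 2)
      pos <- pos + pending
      f_diam <- c(f_diam, pending)
      pending <- NA_real_
    }
  }
  f_day_idx <- findInterval(f_center, cum) + 1L   # index into g / day_of
  f_affected <- affected[f_day_idx]
  f_area <- pi * (f_diam / 2)^2 * tree_f_fibre *
    ifelse(f_affected, p$drought_effect_fibre_csa, 1)
  wall <- rlnorm_mcv(length(f_area), p$wall_thickness, p$trait_cv) * tree_f_wall *
    ifelse(f_affected, p$drought_effect_wall, 1)
  r_cell <- sqrt(f_area / pi)
  r_lumen <- pmax(r_cell * p$fibre_lumen_min, r_cell - wall)
  r_lumen <- pmin(r_lumen, r_cell * 0.999)
  f_lumen <- pi * r_lumen^2

  # --- vessels: Poisson seeding proportional to each day's growth
  lam <- p$vessel_frequency * (g / 1000) * p$image_width_mm * tree_f_vessel
  v_n <- stats::rpois(length(g), lam)
  v_day_idx <- rep(seq_along(g), v_n)
  v_lo <- c(0, utils::head(cum, -1))[v_day_idx]
  v_center <- v_lo + stats::runif(sum(v_n)) * g[v_day_idx]
  v_affected <- affected[v_day_idx]
  v_area <- rlnorm_mcv(sum(v_n), pi * (p$mean_vessel_diameter / 2)^2, p$trait_cv) *
    tree_f_vessel * ifelse(v_affected, p$drought_effect_vessel_csa, 1)
  v_lumen <- v_area * p$lumen_fraction_vessel

  center <- c(f_center, v_center)
  depth <- total - center
  n_cells <- length(center)
  if (n_cells == 0) {
    attr(empty, "truth") <- data.frame(production_day = integer(),
                                       center_depth = numeric(),
                                       affected = logical())
    return(empty)
  }
  cells <- data.frame(
    sample_id = tree$tree_id,
    cell_class = c(rep("fibre", length(f_center)), rep("vessel", length(v_center))),
    cell_area = c(f_area, v_area),
    lumen_area = c(f_lumen, v_lumen),
    centroid_x = stats::runif(n_cells, 0, p$image_width_mm * 1000),
    centroid_y = depth + stats::rnorm(n_cells, 0, p$placement_noise_sd),
    stringsAsFactors = FALSE
  )
  attr(cells, "truth") <- data.frame(
    production_day = day_of[c(f_day_idx, v_day_idx)],
    center_depth = depth,
    affected = c(f_affected, v_affected)
  )
  cells
}

#' Simulate a complete cyclic-drought experiment
#'
#' Runs [simulate_tree()] and [simulate_cells()] for every tree in a
#' two-treatment randomised block design (blocks B and C continuously
#' irrigated, A and D periodically irrigated), and adds the remaining study
#' tables: a 30-minute environment log, a per-sampling-day cambial profile
#' (cell counts along three radial files per sample), and a per-sample phase
#' table (cells in the enlargement/wall-thickening phase eta_x with begin and
#' end sizes).
#'
#' @param params A `xylo_params`.
#' @param schedule Optional `xylo_schedule`; by default six 3-7-day drought
#'   cycles are generated from the experiment seed.
#' @param seed Integer seed governing every random draw; fixed seed gives
#'   bit-identical output.
#' @return An object of class `xylo_experiment`: a list with data frames
#'   `growth`, `lwp`, `environment`, `detections`, `cambium`, `phases`, the
#'   `schedule`, and `truth` (parameters plus per-cell truth keyed by
#'   sample).
#' @export
simulate_experiment <- function(params = sim_params(), schedule = NULL,
                                seed = 1) {
  stopifnot(inherits(params, "xylo_params"))
  set.seed(seed)
  p <- params
  if (is.null(schedule)) {
    # phase lengths are random, so redraw (deterministically, on the seeded
    # stream) until the six cycles fit the experiment
    for (try in 1:50) {
      schedule <- tryCatch(generate_schedule(n_days = p$n_days),
                           xylo_schedule_truncation_error = function(e) NULL)
      if (!is.null(schedule)) break
    }
    if (is.null(schedule)) {
      stop(xylo_error("could not draw a schedule fitting n_days",
                      "xylo_schedule_truncation_error"))
    }
  }
  n_t <- p$n_trees_per_treatment
  blocks_ci <- rep(c("B", "C"), length.out = n_t)
  blocks_pi <- rep(c("A", "D"), length.out = n_t)
  layout <- data.frame(
    tree_id = c(sprintf("CI%02d", seq_len(n_t)), sprintf("PI%02d", seq_len(n_t))),
    treatment = rep(c("CI", "PI"), each = n_t),
    block = c(blocks_ci, blocks_pi),
    stringsAsFactors = FALSE
  )
  trees <- vector("list", nrow(layout))
  cells <- vector("list", nrow(layout))
  for (i in seq_len(nrow(layout))) {
    tr <- simulate_tree(schedule, p, layout$treatment[i],
                        tree_id = layout$tree_id[i], block = layout$block[i])
    trees[[i]] <- tr
    cells[[i]] <- simulate_cells(tr, p)
  }
  growth <- do.call(rbind, lapply(trees, `[[`, "series"))
  lwp <- do.call(rbind, lapply(trees, `[[`, "lwp"))
  truth_cells <- do.call(rbind, lapply(seq_along(cells), function(i) {
    tc <- attr(cells[[i]], "truth")
    if (nrow(tc)) tc$sample_id <- layout$tree_id[i]
    tc
  }))
  detections <- do.call(rbind, cells)
  rownames(detections) <- NULL
  attr(detections, "truth") <- NULL

  # environment log: 30-min cadence, diel temperature cycle around the
  # greenhouse means (21.8 C, 58% RH)
  n_steps <- p$n_days * 48
  tday <- rep(0:(p$n_days - 1), each = 48)
  hour <- rep(seq(0, 23.5, by = 0.5), p$n_days)
  temperature <- 21.8 + 6 * sin((hour - 9) / 24 * 2 * pi) +
    stats::rnorm(n_steps, 0, 0.8)
  rh <- pmin(100, pmax(0, 58 - 10 * sin((hour - 9) / 24 * 2 * pi) +
                         stats::rnorm(n_steps, 0, 3)))
  environment <- data.frame(timestamp = tday + hour / 24,
                            temperature = temperature,
                            relative_humidity = rh)

  # cambial profile: counts along three radial files every third day
  samp_days <- seq(0, p$n_days - 1, by = 3)
  cam <- expand.grid(sample_id = layout$tree_id, day = samp_days,
                     stringsAsFactors = FALSE)
  counts <- matrix(pmax(0L, as.integer(round(
    stats::rnorm(nrow(cam) * 3, p$cambial_zone_cells, 0.3)))), ncol = 3)
  cambium <- data.frame(cam, file1 = counts[, 1], file2 = counts[, 2],
                        file3 = counts[, 3])
  cambium$mean_count <- rowMeans(counts)

  phases <- data.frame(
    sample_id = layout$tree_id,
    eta_x = pmax(1, round(stats::rnorm(nrow(layout), p$enlargement_cohort, 0.3), 1)),
    size_begin = pi * (p$mean_fibre_diameter / 4)^2,
    stringsAsFactors = FALSE
  )

  pi_sub <- trees[[which(layout$treatment == "PI")[1]]]$subthreshold
  structure(list(
    growth = growth, lwp = lwp, environment = environment,
    detections = detections, cambium = cambium, phases = phases,
    schedule = schedule,
    truth = list(params = unclass(p), seed = seed,
                 subthreshold_days = which(pi_sub) - 1L,
                 cells = truth_cells)
  ), class = "xylo_experiment")
}

#' Write a simulated experiment to a directory of CSV files
#'
#' Writes `detections.csv`, `growth.csv`, `lwp.csv`, `environment.csv`,
#' `schedule.csv`, `cambium.csv`, `phases.csv` and `truth.json` (generator
#' ground truth: parameters, seed and sub-threshold days; per-cell truth is
#' kept out of the JSON and written to `truth_cells.csv`).
#'
#' @param exp A `xylo_experiment`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(exp, dir) {
  stopifnot(inherits(exp, "xylo_experiment"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_detection_table(exp$detections, file.path(dir, "detections.csv"))
  write_growth_table(exp$growth, file.path(dir, "growth.csv"))
  write_lwp_table(exp$lwp, file.path(dir, "lwp.csv"))
  write_environment_log(exp$environment, file.path(dir, "environment.csv"))
  write_schedule(exp$schedule, file.path(dir, "schedule.csv"))
  utils::write.csv(exp$cambium, file.path(dir, "cambium.csv"), row.names = FALSE)
  utils::write.csv(exp$phases, file.path(dir, "phases.csv"), row.names = FALSE)
  utils::write.csv(exp$truth$cells, file.path(dir, "truth_cells.csv"),
                   row.names = FALSE)
  jsonlite::write_json(exp$truth[c("params", "seed", "subthreshold_days")],
                       file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
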