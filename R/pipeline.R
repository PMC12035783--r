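#' Default pipeline configuration
#'
#' Returns the configuration skeleton understood by [run_pipeline()]:
#' input paths, dating resolution, smoother span, analysis periods, stats
#' flags and the root seed. Any subset can be overridden via a YAML file or
#' a named list.
#'
#' @return A nested list of defaults.
#' @export
default_config <- function() {
  list(
    seed = 1,
    out_dir = "xylo_out",
    simulate = list(enabled = TRUE, params = list()),
    paths = list(detections = NULL, growth = NULL, lwp = NULL,
                 environment = NULL, schedule = NULL, cambium = NULL,
                 phases = NULL),
    zonation = list(boundaries_by = 3, cambium_y = NULL),
    traits = list(span = 0.3, image_width = 0.4),
    kinetics = list(periods = NULL),
    stats = list(lwp_threshold = -2, enlargement_lag = 3, adjust = "none")
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Run the full analysis pipeline
#'
#' Executes simulate (optional) -> zonate -> traits -> kinetics -> stats from
#' a single configuration, writing every stage's tables under
#' `config$out_dir` plus a `manifest.json` recording the stages run, input
#' hashes, seed and package version. All randomness flows from the single
#' root seed. Any stage failure is re-raised with the stage name and already
#' written outputs are renamed with a `.partial` suffix.
#'
#' @param config A YAML file path or a named list overriding
#'   [default_config()].
#' @return Invisibly, a list with the stage outputs (`experiment`, `dated`,
#'   `increments`, `traits`, `contrasts`, `kinetics`, `stats`) and the
#'   manifest.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(default_config(), config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  out_file <- function(name) {
    f <- file.path(cfg$out_dir, name)
    written <<- c(written, f)
    f
  }
  fail <- function(stage, e) {
    for (f in written) if (file.exists(f)) file.rename(f, paste0(f, ".partial"))
    stop(xylo_error(sprintf("[%s] %s", stage, conditionMessage(e)),
                    "xylo_stage_error"))
  }
  stages <- character(0)

  # --- inputs -------------------------------------------------------------
  if (!isTRUE(cfg$simulate$enabled)) {
    need <- c("detections", "growth", "lwp", "schedule", "cambium", "phases")
    for (nm in need) {
      p <- cfg$paths[[nm]]
      if (is.null(p) || !file.exists(p)) {
        stop(xylo_error(sprintf("[inputs] missing %s path%s", nm,
                                if (is.null(p)) "" else paste0(": ", p)),
                        "xylo_stage_error"))
      }
    }
  }

  if (isTRUE(cfg$simulate$enabled)) {
    exp <- tryCatch({
      params <- do.call(sim_params, cfg$simulate$params)
      simulate_experiment(params, seed = cfg$seed)
    }, error = function(e) fail("simulate", e))
    tryCatch(write_experiment(exp, cfg$out_dir), error = function(e)
      fail("simulate", e))
    written <- c(written, file.path(cfg$out_dir,
      c("detections.csv", "growth.csv", "lwp.csv", "environment.csv",
        "schedule.csv", "cambium.csv", "phases.csv", "truth.json",
        "truth_cells.csv")))
    detections <- exp$detections; growth <- exp$growth; lwp <- exp$lwp
    schedule <- exp$schedule; cambium <- exp$cambium; phases <- exp$phases
    stages <- c(stages, "simulate")
  } else {
    exp <- NULL
    detections <- tryCatch(read_detection_table(cfg$paths$detections),
                           error = function(e) fail("inputs", e))
    growth <- tryCatch(read_growth_table(cfg$paths$growth),
                       error = function(e) fail("inputs", e))
    lwp <- tryCatch(read_lwp_table(cfg$paths$lwp),
                    error = function(e) fail("inputs", e))
    schedule <- tryCatch(read_schedule(cfg$paths$schedule),
                         error = function(e) fail("inputs", e))
    cambium <- tryCatch(utils::read.csv(cfg$paths$cambium),
                        error = function(e) fail("inputs", e))
    phases <- tryCatch(utils::read.csv(cfg$paths$phases),
                       error = function(e) fail("inputs", e))
    stages <- c(stages, "inputs")
  }

  # --- zonation -----------------------------------------------------------
  zon <- tryCatch({
    boundaries <- period_boundaries(max(growth$day) + 1,
                                    by = cfg$zonation$boundaries_by)
    date_experiment(detections, growth, boundaries, schedule,
                    cambium_y = cfg$zonation$cambium_y)
  }, error = function(e) fail("zonate", e))
  utils::write.csv(zon$dated, out_file("dated_cells.csv"), row.names = FALSE)
  utils::write.csv(zon$increments, out_file("increments.csv"),
                   row.names = FALSE)
  stages <- c(stages, "zonate")

  # --- traits -------------------------------------------------------------
  tr <- tryCatch({
    traits <- summarize_increments(zon$dated, zon$increments,
                                   image_width = cfg$traits$image_width)
    trait_cols <- c(vessel_csa = "mean_vessel_csa",
                    vessel_frequency = "vessel_frequency",
                    fibre_csa = "mean_fibre_csa",
                    wall_thickness = "mean_fibre_wall_thickness")
    tmap <- unique(growth[c("tree_id", "treatment")])
    traits$treatment <- tmap$treatment[match(traits$sample_id, tmap$tree_id)]
    traits$period_day <- (traits$start_day + traits$end_day) / 2
    contrasts <- list()
    for (nm in names(trait_cols)) {
      pts <- data.frame(day = traits$period_day, value = traits[[trait_cols[nm]]],
                        treatment = traits$treatment)
      pts <- pts[is.finite(pts$value), , drop = FALSE]
      ok <- all(table(pts$treatment)[c("CI", "PI")] >= 4, na.rm = FALSE)
      if (isTRUE(ok)) {
        s_pi <- smooth_trend(pts[pts$treatment == "PI", ], span = cfg$traits$span)
        s_ci <- smooth_trend(pts[pts$treatment == "CI", ], span = cfg$traits$span)
        ctr <- treatment_contrast(s_pi, s_ci)
        contrasts[[nm]] <- data.frame(trait = nm, day = ctr$day,
                                      contrast = ctr$value)
      }
    }
    list(traits = traits, contrasts = do.call(rbind, contrasts))
  }, error = function(e) fail("traits", e))
  utils::write.csv(tr$traits, out_file("traits.csv"), row.names = FALSE)
  if (!is.null(tr$contrasts)) {
    utils::write.csv(tr$contrasts, out_file("trait_contrasts.csv"),
                     row.names = FALSE)
  }
  stages <- c(stages, "traits")

  # --- kinetics -----------------------------------------------------------
  kin <- tryCatch({
    periods <- cfg$kinetics$periods %||% default_periods()
    if (is.list(periods) && !is.data.frame(periods)) {
      periods <- do.call(rbind, lapply(periods, as.data.frame))
    }
    estimate_kinetics(detections, growth, cambium, phases, periods, schedule,
                      cambium_y = cfg$zonation$cambium_y)
  }, error = function(e) fail("kinetics", e))
  utils::write.csv(kin, out_file("kinetics.csv"), row.names = FALSE)
  stages <- c(stages, "kinetics")

  # --- stats --------------------------------------------------------------
  st <- tryCatch({
    lwp_lab <- label_lwp(lwp, growth, schedule)
    glm_res <- fit_lwp_glm(lwp_lab)
    windows <- drought_windows(lwp_lab, threshold = cfg$stats$lwp_threshold,
                               lag = cfg$stats$enlargement_lag)
    lmm <- lapply(c("vessel_csa", "fibre_csa", "wall_thickness"),
                  function(trt) fit_trait_lmm(zon$dated, trt,
                                              windows = windows,
                                              adjust = cfg$stats$adjust))
    names(lmm) <- c("vessel_csa", "fibre_csa", "wall_thickness")
    inc_res <- relative_increment_test(growth)
    list(lwp_glm = glm_res, lmm = lmm, relative_increment = inc_res,
         windows = windows)
  }, error = function(e) fail("stats", e))
  stats_json <- list(
    lwp_glm = list(terms = st$lwp_glm$terms,
                   p_treatment = st$lwp_glm$p_treatment),
    windows = st$windows,
    lmm = lapply(st$lmm, function(m)
      list(trait = m$trait, p_interaction = m$p_interaction,
           windows = m$windows, notes = m$notes)),
    relative_increment = st$relative_increment$terms)
  jsonlite::write_json(stats_json, out_file("stats.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows", force = TRUE)
  stages <- c(stages, "stats")

  manifest <- list(
    package = "xylokinetics",
    version = as.character(utils::packageVersion("xylokinetics")),
    seed = cfg$seed,
    stages = stages,
    config = cfg[c("seed", "zonation", "traits", "stats")],
    files = {
      fs <- unique(written[file.exists(written)])
      stats::setNames(as.list(unname(tools::md5sum(fs))), basename(fs))
    })
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(experiment = exp, dated = zon$dated,
                 increments = zon$increments, traits = tr$traits,
                 contrasts = tr$contrasts, kinetics = kin, stats = st,
                 manifest = manifest))
}
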