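#' Simulation parameters for a synthetic cyclic-drought experiment
#'
#' Bundles every tunable of the synthetic-experiment generator with
#' validation. Defaults reproduce the greenhouse study conditions this
#' pipeline was built around: a 75-day experiment on eucalypt seedlings,
#' 24 continuously measured trees per irrigation treatment, a cambial
#' production rate of 2 cells/day feeding fibres of 10 um mean diameter
#' (20 um/day radial growth), a cambial zone about 4 cells wide, pre-dawn
#' leaf water potential (LWP) near -0.5 MPa when watered and excursions
#' to -2.4 MPa under drought, and a wood vessel frequency of 138 vessels
#' per mm^2 of transverse section.
#'
#' Drought acts through LWP: on days when simulated PI-tree LWP falls below
#' `lwp_threshold`, radial growth is multiplied by a factor that declines
#' linearly from 1 at the threshold to 0 at `lwp_drought_min`, elastic
#' shrinkage episodes appear in the observed diameter, and cells whose
#' enlargement window (production day through `enlargement_lag` days later)
#' overlaps a sub-threshold day have their traits multiplied by the
#' `drought_effect_*` factors. A multiplier of 1 means no drought effect on
#' that trait.
#'
#' @param n_trees_per_treatment Trees per irrigation arm (CI and PI).
#' @param n_days Experiment length in days.
#' @param cells_per_day True cambial cell production rate phi (cells/day).
#' @param mean_fibre_diameter Mean radial fibre diameter D (um); the baseline
#'   radial growth rate is `cells_per_day * mean_fibre_diameter` um/day.
#' @param mean_vessel_diameter Mean vessel lumen diameter (um).
#' @param vessel_frequency True areal vessel frequency (vessels/mm^2);
#'   vessels are seeded at `vessel_frequency * growth_mm * image_width_mm`
#'   per day.
#' @param cambial_zone_cells True cambial-zone width eta_c (cells).
#' @param enlargement_cohort True number of cells in the enlargement /
#'   wall-thickening phase eta_x (cells).
#' @param enlargement_lag Days a newly produced cell keeps enlarging; drought
#'   trait effects reach cells produced up to this many days before a
#'   sub-threshold day (default eta_x / phi = 3 days).
#' @param wall_thickness Baseline fibre wall thickness (um).
#' @param lumen_fraction_vessel Fraction of a vessel's cell area that is lumen.
#' @param lwp_baseline Watered-state pre-dawn LWP (MPa, negative).
#' @param lwp_drought_min LWP floor reached at the end of a drought cycle
#'   (MPa, negative).
#' @param lwp_threshold LWP below which drought effects engage (MPa).
#' @param lwp_noise_sd Observation noise on LWP (MPa).
#' @param drought_effect_vessel_csa,drought_effect_fibre_csa,drought_effect_wall
#'   Multipliers in (0, 1.5] applied to vessel cross-sectional area, fibre
#'   cross-sectional area and fibre wall thickness of drought-affected cells.
#' @param shrinkage_amplitude Maximum elastic diameter shrinkage per
#'   sub-threshold day (mm); recovered on rewatering.
#' @param trait_cv Lognormal coefficient of variation of per-cell trait draws.
#' @param tree_cv Lognormal CV of per-tree trait multipliers (between-tree
#'   variability).
#' @param placement_noise_sd Gaussian noise on radial cell placement (um).
#' @param diameter_noise_sd Measurement noise on daily stem diameter (mm).
#' @param initial_diameter Stem diameter at day 0 (mm).
#' @param pre_days Days of pre-experiment growth included so sections carry a
#'   band of pre-experiment wood.
#' @param fibre_lumen_min Minimum fibre lumen radius as a fraction of cell
#'   radius (keeps lumen area strictly positive).
#' @param image_width_mm Tangential width of the analysed image (mm); fixed at
#'   the study's 0.4 mm.
#' @param null If `TRUE`, return the generator's null configuration: all
#'   drought trait multipliers 1, `lwp_drought_min = lwp_baseline` and zero
#'   shrinkage, making the PI and CI arms fully exchangeable. Used for type-I
#'   error calibration.
#' @return An object of class `xylo_params` (a validated named list).
#' @export
sim_params <- function(n_trees_per_treatment = 24,
                       n_days = 75,
                       cells_per_day = 2.0,
                       mean_fibre_diameter = 10,
                       mean_vessel_diameter = 35,
                       vessel_frequency = 138,
                       cambial_zone_cells = 4,
                       enlargement_cohort = 6,
                       enlargement_lag = 3,
                       wall_thickness = 1.5,
                       lumen_fraction_vessel = 0.9,
                       lwp_baseline = -0.5,
                       lwp_drought_min = -2.4,
                       lwp_threshold = -2.0,
                       lwp_noise_sd = 0.05,
                       drought_effect_vessel_csa = 1,
                       drought_effect_fibre_csa = 1,
                       drought_effect_wall = 1,
                       shrinkage_amplitude = 0.1,
                       trait_cv = 0.3,
                       tree_cv = 0.05,
                       placement_noise_sd = 2,
                       diameter_noise_sd = 0.01,
                       initial_diameter = 5,
                       pre_days = 10,
                       fibre_lumen_min = 0.05,
                       image_width_mm = 0.4,
                       null = FALSE) {
  p <- as.list(environment())
  p$null <- NULL
  if (null) {
    p$drought_effect_vessel_csa <- 1
    p$drought_effect_fibre_csa <- 1
    p$drought_effect_wall <- 1
    p$lwp_drought_min <- p$lwp_baseline
    p$shrinkage_amplitude <- 0
  }
  validate_params(p)
  structure(p, class = "xylo_params")
}

validate_params <- function(p) {
  pos <- c("n_trees_per_treatment", "n_days", "cells_per_day",
           "mean_fibre_diameter", "mean_vessel_diameter", "vessel_frequency",
           "cambial_zone_cells", "enlargement_cohort", "wall_thickness",
           "initial_diameter", "image_width_mm")
  for (f in pos) {
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1 || !is.finite(p[[f]]) ||
        p[[f]] <= 0) {
      stop(xylo_error(sprintf("parameter '%s' must be a positive number", f),
                      "xylo_param_error"))
    }
  }
  nonneg <- c("enlargement_lag", "lwp_noise_sd", "shrinkage_amplitude",
              "trait_cv", "tree_cv", "placement_noise_sd", "diameter_noise_sd",
              "pre_days")
  for (f in nonneg) {
    if (!is.numeric(p[[f]]) || p[[f]] < 0) {
      stop(xylo_error(sprintf("parameter '%s' must be non-negative", f),
                      "xylo_param_error"))
    }
  }
  if (p$n_days < 2) {
    stop(xylo_error("n_days must be at least 2", "xylo_param_error"))
  }
  for (f in c("drought_effect_vessel_csa", "drought_effect_fibre_csa",
              "drought_effect_wall")) {
    if (p[[f]] <= 0 || p[[f]] > 1.5) {
      stop(xylo_error(sprintf("multiplier '%s' must lie in (0, 1.5]", f),
                      "xylo_param_error"))
    }
  }
  for (f in c("lwp_baseline", "lwp_drought_min", "lwp_threshold")) {
    if (p[[f]] > 0) {
      stop(xylo_error(sprintf("'%s' is a water potential and must be <= 0 MPa", f),
                      "xylo_param_error"))
    }
  }
  if (p$lwp_drought_min > p$lwp_baseline) {
    stop(xylo_error("lwp_drought_min must be at or below lwp_baseline",
                    "xylo_param_error"))
  }
  if (p$lumen_fraction_vessel <= 0 || p$lumen_fraction_vessel >= 1) {
    stop(xylo_error("lumen_fraction_vessel must lie in (0, 1)",
                    "xylo_param_error"))
  }
  invisible(p)
}

#' Noise-free variant of a parameter set
#'
#' Convenience for recovery tests: switches off placement noise, diameter
#' measurement noise, LWP noise, per-cell and per-tree trait scatter, and
#' shrinkage, leaving the deterministic generative skeleton.
#'
#' @param p A `xylo_params` object.
#' @return A `xylo_params` object with all noise terms set to zero.
#' @export
noise_free <- function(p) {
  stopifnot(inherits(p, "xylo_params"))
  p$placement_noise_sd <- 0
  p$diameter_noise_sd <- 0
  p$lwp_noise_sd <- 0
  p$trait_cv <- 0
  p$tree_cv <- 0
  p$shrinkage_amplitude <- 0
  p
}
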