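#' Cambial cell production rate
#'
#' Rate of cell production in a period: the period's total radial growth
#' divided by the mean radial diameter of the cells formed and the period
#' length, `phi = g / (D * t)` — equivalently the daily radial growth rate in
#' units of one cell diameter per day. (The source methods give only the
#' symbol glossary for this relation; this unit-consistent form is the one
#' under which cells/day emerges and is used throughout.)
#'
#' @param g Total radial growth in the period, um (>= 0).
#' @param D Mean diameter of cells formed in the period, um (> 0).
#' @param t Days in the period (> 0).
#' @return Cell production rate phi, cells/day.
#' @export
cell_production_rate <- function(g, D, t) {
  if (any(D <= 0) || any(t <= 0)) {
    stop(xylo_error("D and t must be positive", "xylo_param_error"))
  }
  if (any(g < 0)) stop(xylo_error("g must be >= 0", "xylo_param_error"))
  g / (D * t)
}

#' Cell-cycle duration
#'
#' Time for one cambial cell cycle: the cambial-zone width in cells divided
#' by the production rate, `t_phi = eta_c / phi`. A zero rate leaves the
#' duration undefined (`NA`), except that an empty cambial zone gives 0.
#'
#' @param eta_c Number of cells in the cambial zone (>= 0).
#' @param phi Cell production rate, cells/day.
#' @return Cell-cycle duration in days.
#' @export
cell_cycle_duration <- function(eta_c, phi) {
  if (any(eta_c < 0) || any(phi < 0)) {
    stop(xylo_error("eta_c and phi must be >= 0", "xylo_param_error"))
  }
  ifelse(eta_c == 0, 0, ifelse(phi == 0, NA_real_, eta_c / phi))
}

#' Duration of a developmental phase
#'
#' Time a cell spends enlarging (or thickening its wall): the number of cells
#' currently in that phase divided by the production rate,
#' `t_sigma = eta_x / phi`.
#'
#' @param eta_x Cells in the phase (>= 0).
#' @param phi Cell production rate, cells/day.
#' @return Phase duration in days (`NA` when `phi = 0` and `eta_x > 0`).
#' @export
phase_duration <- function(eta_x, phi) cell_cycle_duration(eta_x, phi)

#' Rate of enlargement or wall thickening
#'
#' Net size change over the phase divided by its duration:
#' `rate = (size_end - size_begin) / t_sigma`.
#'
#' @param size_end,size_begin Final and initial cell size (um^2 for areas,
#'   um for wall thickness).
#' @param t_sigma Phase duration, days (> 0).
#' @return Rate in size units per day.
#' @export
phase_rate <- function(size_end, size_begin, t_sigma) {
  if (any(!is.finite(t_sigma)) || any(t_sigma <= 0)) {
    stop(xylo_error("t_sigma must be positive and finite", "xylo_param_error"))
  }
  (size_end - size_begin) / t_sigma
}

#' Default analysis periods for kinetics comparisons
#'
#' The two xylem growth periods compared in the study — Period 1 (days
#' 18-28) and Period 2 (days 60-72) — plus the stretch in between.
#'
#' @return Data frame with `period_label`, `start_day`, `end_day` (inclusive).
#' @export
default_periods <- function() {
  data.frame(period_label = c("Period 1", "in-between", "Period 2"),
             start_day = c(18, 29, 60), end_day = c(28, 59, 72),
             stringsAsFactors = FALSE)
}

#' Estimate cambial kinetics per sample and period
#'
#' For each tree and analysis period, measures the radial growth `g` from the
#' tree's diameter series (clamped daily increments summed over the period),
#' the mean equivalent-circle diameter `D` of fibres dated to the period, and
#' the period length `t`, then applies the kinetics relations: production
#' rate `phi = g/(D t)`, cell-cycle duration `t_phi = eta_c / phi` using the
#' mean cambial-file count over the period's sampling days (nearest day if
#' none fall inside), phase duration `t_sigma = eta_x / phi` from the
#' per-sample phase table, and enlargement rate
#' `(size_end - size_begin)/t_sigma` with `size_end` the mean fibre area
#' dated to the period.
#'
#' @param detections Detection table for all samples.
#' @param growth Growth table for the same samples.
#' @param cambium Cambial profile table (`sample_id`, `day`, `mean_count` or
#'   `file1..file3`).
#' @param phases Per-sample phase table (`sample_id`, `eta_x`, optional
#'   `size_begin`).
#' @param periods Period definitions as in [default_periods()].
#' @param schedule Optional schedule for increment status labels.
#' @param cambium_y As in [assign_cells()].
#' @return A kinetics data frame, one row per sample x period, with inputs
#'   echoed (`g`, `D`, `t`, `eta_c`, `eta_x`, `size_begin`, `size_end`) and
#'   the estimates `phi`, `t_phi`, `t_sigma`, `enlargement_rate`. Periods
#'   with no dated fibres or zero growth have their dependent estimates
#'   flagged `NA`.
#' @export
estimate_kinetics <- function(detections, growth, cambium, phases,
                              periods = default_periods(), schedule = NULL,
                              cambium_y = NULL) {
  if (!"mean_count" %in% names(cambium)) {
    files <- intersect(c("file1", "file2", "file3"), names(cambium))
    if (!length(files)) {
      stop(xylo_error("cambium table needs mean_count or file1..file3 columns",
                      "xylo_schema_error"))
    }
    cambium$mean_count <- rowMeans(cambium[files], na.rm = TRUE)
  }
  boundaries <- sort(unique(c(periods$start_day, periods$end_day)))
  zon <- date_experiment(detections, growth, boundaries, schedule,
                         cambium_y = cambium_y)
  samples <- unique(detections$sample_id)
  out <- list()
  for (s in samples) {
    dmap <- zon$increments[zon$increments$sample_id == s, , drop = FALSE]
    cells <- zon$dated[zon$dated$sample_id == s &
                         zon$dated$flag == "assigned", , drop = FALSE]
    cam <- cambium[cambium$sample_id == s, , drop = FALSE]
    ph <- phases[phases$sample_id == s, , drop = FALSE]
    eta_x <- if (nrow(ph)) ph$eta_x[1] else NA_real_
    size_begin <- if (nrow(ph) && "size_begin" %in% names(ph))
      ph$size_begin[1] else NA_real_
    for (j in seq_len(nrow(periods))) {
      p0 <- periods$start_day[j]; p1 <- periods$end_day[j]
      idx <- dmap$period_index[dmap$start_day >= p0 & dmap$end_day <= p1]
      g <- sum(dmap$width[dmap$period_index %in% idx])
      # g spans the diameter change from day p0 to day p1, i.e. p1 - p0 days
      # of growth, so t uses the same convention to keep phi unbiased
      t_days <- p1 - p0
      fib <- cells[cells$period_index %in% idx &
                     cells$cell_class == "fibre", , drop = FALSE]
      D <- if (nrow(fib)) mean(fibre_diameter(fib$cell_area)) else NA_real_
      size_end <- if (nrow(fib)) mean(fib$cell_area) else NA_real_
      in_p <- cam$day >= p0 & cam$day <= p1
      eta_c <- if (any(in_p)) mean(cam$mean_count[in_p])
               else if (nrow(cam)) cam$mean_count[which.min(abs(cam$day - (p0 + p1) / 2))]
               else NA_real_
      phi <- if (g == 0) 0
             else if (is.na(D)) NA_real_
             else cell_production_rate(g, D, t_days)
      t_phi <- if (is.na(phi) || is.na(eta_c)) NA_real_
               else cell_cycle_duration(eta_c, phi)
      t_sigma <- if (is.na(phi) || is.na(eta_x)) NA_real_
                 else phase_duration(eta_x, phi)
      rate <- if (is.na(t_sigma) || is.na(size_end) || is.na(size_begin) ||
                  t_sigma <= 0) NA_real_
              else phase_rate(size_end, size_begin, t_sigma)
      out[[length(out) + 1]] <- data.frame(
        sample_id = s, period_label = periods$period_label[j],
        start_day = p0, end_day = p1,
        g = g, D = D, t = t_days, eta_c = eta_c, eta_x = eta_x,
        size_begin = size_begin, size_end = size_end,
        phi = phi, t_phi = t_phi, t_sigma = t_sigma,
        enlargement_rate = rate, n_fibres = nrow(fib),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
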