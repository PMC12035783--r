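#' Fibre wall thickness under a concentric-circle model
#'
#' Treats the cell and its lumen as concentric circles of the measured areas,
#' so the wall thickness is the difference of the equivalent radii:
#' `WT = sqrt(cell_area / pi) - sqrt(lumen_area / pi)`. Scales linearly under
#' uniform length rescaling.
#'
#' @param cell_area Cell cross-sectional area, um^2.
#' @param lumen_area Lumen area, um^2; must satisfy `0 <= lumen < cell`.
#' @return Wall thickness in um.
#' @export
wall_thickness <- function(cell_area, lumen_area) {
  if (any(lumen_area < 0 | lumen_area >= cell_area)) {
    stop(xylo_error("lumen_area must satisfy 0 <= lumen_area < cell_area",
                    "xylo_invariant_error"))
  }
  sqrt(cell_area / pi) - sqrt(lumen_area / pi)
}

#' Areal vessel frequency of a growth increment
#'
#' Vessels counted in an increment divided by the transverse area they
#' occupy: the increment's radial growth width times the tangential image
#' width (0.4 mm in the study).
#'
#' @param n_vessels Vessel count (>= 0).
#' @param growth_width Radial growth width of the increment, mm.
#' @param image_width Tangential image width, mm.
#' @return Vessels per mm^2. Zero vessels give 0 even for zero width; a
#'   positive count over zero width is undefined and returns `NA` with a
#'   warning rather than failing.
#' @export
vessel_frequency <- function(n_vessels, growth_width, image_width = 0.4) {
  if (any(n_vessels < 0) || any(growth_width < 0) || image_width <= 0) {
    stop(xylo_error("counts and widths must be non-negative, image_width positive",
                    "xylo_param_error"))
  }
  out <- ifelse(n_vessels == 0, 0, n_vessels / (growth_width * image_width))
  undef <- n_vessels > 0 & growth_width == 0
  if (any(undef)) {
    warning("vessel count over zero growth width: frequency undefined (NA)")
    out[undef] <- NA_real_
  }
  out
}

#' Equivalent-circle diameter of a cell
#'
#' The study reports fibre "radial diameter" but the detection export carries
#' only areas, so the default diameter is the equivalent-circle diameter
#' `2 * sqrt(area / pi)`.
#'
#' @param area Cell area, um^2.
#' @return Diameter in um.
#' @export
fibre_diameter <- function(area) equivalent_diameter(area)

#' Summarise dated cells into increment-level anatomical traits
#'
#' Aggregates a dated cell table per (sample, period): fibre and vessel
#' counts, mean vessel cross-sectional area, vessel frequency (via
#' [vessel_frequency()] with that increment's width), mean fibre area, mean
#' fibre equivalent-circle diameter and mean fibre wall thickness (via
#' [wall_thickness()]). Means over an empty class are `NA`.
#'
#' @param dated Dated cell table from [assign_cells()] or
#'   [date_experiment()] (only `flag == "assigned"` rows are used).
#' @param increments Increment table; if it carries a `sample_id` column each
#'   sample uses its own widths, otherwise the single table applies to all.
#' @param image_width Tangential image width in mm.
#' @return An increment-traits data frame, one row per sample x period
#'   actually present in `increments`.
#' @export
summarize_increments <- function(dated, increments, image_width = 0.4) {
  per_sample <- "sample_id" %in% names(increments)
  cells <- dated[dated$flag == "assigned", , drop = FALSE]
  samples <- unique(dated$sample_id)
  out <- vector("list", length(samples))
  for (k in seq_along(samples)) {
    s <- samples[k]
    inc <- if (per_sample) increments[increments$sample_id == s, , drop = FALSE]
           else increments
    cs <- cells[cells$sample_id == s, , drop = FALSE]
    rows <- lapply(seq_len(nrow(inc)), function(i) {
      p <- inc$period_index[i]
      cc <- cs[cs$period_index == p, , drop = FALSE]
      fib <- cc[cc$cell_class == "fibre", , drop = FALSE]
      ves <- cc[cc$cell_class == "vessel", , drop = FALSE]
      data.frame(
        sample_id = s, period_index = p,
        start_day = inc$start_day[i], end_day = inc$end_day[i],
        width = inc$width[i], status = inc$status[i],
        n_fibres = nrow(fib), n_vessels = nrow(ves),
        mean_vessel_csa = if (nrow(ves)) mean(ves$cell_area) else NA_real_,
        vessel_frequency = suppressWarnings(
          vessel_frequency(nrow(ves), inc$width[i] / 1000, image_width)),
        mean_fibre_csa = if (nrow(fib)) mean(fib$cell_area) else NA_real_,
        mean_fibre_diameter = if (nrow(fib))
          mean(fibre_diameter(fib$cell_area)) else NA_real_,
        mean_fibre_wall_thickness = if (nrow(fib))
          mean(wall_thickness(fib$cell_area, fib$lumen_area)) else NA_real_,
        stringsAsFactors = FALSE)
    })
    out[[k]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Smooth a day-resolved trait profile
#'
#' Local linear regression (`loess`, degree 1) of trait values against day,
#' evaluated on a uniform grid spanning the data range only (no
#' extrapolation). Local-linear smoothing reproduces a linear signal exactly
#' at interior points, so trend lines are not biased on ramps.
#'
#' @param points Data frame with columns `day` and `value` (>= 4 rows).
#' @param span Loess span (fraction of points per local fit).
#' @param n_grid Number of grid points.
#' @return An object of class `xylo_trend`: list with `day` (grid), `value`
#'   (smooth) and `span`.
#' @export
smooth_trend <- function(points, span = 0.3, n_grid = 200) {
  stopifnot(all(c("day", "value") %in% names(points)))
  points <- points[is.finite(points$value) & is.finite(points$day), , drop = FALSE]
  if (nrow(points) < 4) {
    stop(xylo_error("need at least 4 points to smooth", "xylo_param_error"))
  }
  fit <- stats::loess(value ~ day, data = points, span = span, degree = 1,
                      surface = "direct")
  grid <- seq(min(points$day), max(points$day), length.out = n_grid)
  structure(list(day = grid,
                 value = as.numeric(stats::predict(fit, newdata =
                                                     data.frame(day = grid))),
                 span = span),
            class = "xylo_trend")
}

#' Pointwise difference of two smoothed trends
#'
#' Evaluates `a - b` (conventionally PI minus CI) on a common uniform grid
#' over the overlap of the two day ranges, interpolating each curve linearly
#' onto it.
#'
#' @param a,b `xylo_trend` objects for the same trait.
#' @param n_grid Grid size for the common grid.
#' @return A `xylo_trend` whose `value` is the pointwise contrast.
#' @export
treatment_contrast <- function(a, b, n_grid = 200) {
  stopifnot(inherits(a, "xylo_trend"), inherits(b, "xylo_trend"))
  lo <- max(min(a$day), min(b$day))
  hi <- min(max(a$day), max(b$day))
  if (lo >= hi) {
    stop(xylo_error("trend day ranges do not overlap", "xylo_range_error"))
  }
  grid <- seq(lo, hi, length.out = n_grid)
  va <- stats::approx(a$day, a$value, xout = grid)$y
  vb <- stats::approx(b$day, b$value, xout = grid)$y
  structure(list(day = grid, value = va - vb, span = a$span),
            class = "xylo_trend")
}
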