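#' Column-name maps for detection tables
#'
#' The pipeline's canonical detection columns are `sample_id`, `cell_class`,
#' `cell_area`, `lumen_area`, `centroid_x` and `centroid_y`. Image-analysis
#' exports drift between software versions, so the reader takes a named map
#' from canonical name to the header found in the file. `qupath_column_map()`
#' covers the common QuPath detection-export headers, in which the cell
#' detector's "Nucleus: Area" field holds the lumen area for wood cells.
#'
#' @return A named character vector mapping canonical column names to file
#'   headers.
#' @export
detection_column_map <- function() {
  c(sample_id = "sample_id", cell_class = "cell_class",
    cell_area = "cell_area", lumen_area = "lumen_area",
    centroid_x = "centroid_x", centroid_y = "centroid_y")
}

#' @rdname detection_column_map
#' @export
qupath_column_map <- function() {
  c(sample_id = "Image", cell_class = "Class",
    cell_area = "Cell: Area", lumen_area = "Nucleus: Area",
    centroid_x = "Centroid X", centroid_y = "Centroid Y")
}

read_csv_checked <- function(path) {
  if (!file.exists(path)) {
    stop(xylo_error(sprintf("file not found: %s", path), "xylo_io_error"))
  }
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(xylo_error(
      sprintf("%s lacks required column(s): %s", what,
              paste(missing, collapse = ", ")),
      "xylo_schema_error"))
  }
}

check_numeric <- function(x, col, what) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(v) & x != "")
  if (length(bad)) {
    stop(xylo_error(
      sprintf("%s: non-numeric value in column '%s' at row(s) %s", what, col,
              paste(utils::head(bad, 5), collapse = ", ")),
      "xylo_row_error"))
  }
  v
}

#' Read a cell-detection export table
#'
#' Reads a CSV of detected cells, renames columns through `column_map`,
#' validates the type invariants (positive cell area, `0 <= lumen_area <
#' cell_area`, finite centroids) and optionally converts pixel units to
#' micrometres. Rows whose class label is neither a fibre nor a vessel label
#' are routed to class `"other"`. Extra columns are preserved untouched.
#'
#' @param path CSV file path.
#' @param column_map Named map canonical -> file header; see
#'   [detection_column_map()].
#' @param pixel_size Optional pixel edge length in um; areas are multiplied
#'   by `pixel_size^2` and coordinates by `pixel_size`.
#' @param class_labels Named list with elements `fibre` and `vessel` giving
#'   the accepted (case-insensitive) labels for each class.
#' @return A validated detection data frame with canonical column names.
#' @export
read_detection_table <- function(path, column_map = detection_column_map(),
                                 pixel_size = NULL,
                                 class_labels = list(fibre = c("fibre", "fiber"),
                                                     vessel = "vessel")) {
  raw <- read_csv_checked(path)
  require_columns(raw, unname(column_map), "detection table")
  df <- raw
  names(df)[match(unname(column_map), names(df))] <- names(column_map)
  for (col in c("cell_area", "lumen_area", "centroid_x", "centroid_y")) {
    df[[col]] <- check_numeric(df[[col]], col, "detection table")
  }
  if (!is.null(pixel_size)) {
    df$cell_area <- df$cell_area * pixel_size^2
    df$lumen_area <- df$lumen_area * pixel_size^2
    df$centroid_x <- df$centroid_x * pixel_size
    df$centroid_y <- df$centroid_y * pixel_size
  }
  cls <- tolower(trimws(df$cell_class))
  df$cell_class <- ifelse(cls %in% tolower(class_labels$fibre), "fibre",
                          ifelse(cls %in% tolower(class_labels$vessel),
                                 "vessel", "other"))
  validate_detections(df)
  df
}

validate_detections <- function(df) {
  bad <- which(!is.finite(df$cell_area) | df$cell_area <= 0)
  if (length(bad)) {
    stop(xylo_error(sprintf("cell_area must be positive and finite (row %d)",
                            bad[1]), "xylo_invariant_error"))
  }
  bad <- which(!is.finite(df$lumen_area) | df$lumen_area < 0 |
                 df$lumen_area >= df$cell_area)
  if (length(bad)) {
    stop(xylo_error(
      sprintf("lumen_area must satisfy 0 <= lumen < cell_area (row %d)", bad[1]),
      "xylo_invariant_error"))
  }
  if (any(!is.finite(df$centroid_x)) || any(!is.finite(df$centroid_y))) {
    stop(xylo_error("centroid coordinates must be finite",
                    "xylo_invariant_error"))
  }
  invisible(df)
}

#' @rdname read_detection_table
#' @param df Detection data frame with canonical columns.
#' @export
write_detection_table <- function(df, path) {
  require_columns(df, names(detection_column_map()), "detection table")
  validate_detections(df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read the daily tree growth table
#'
#' One row per tree-day with columns `tree_id`, `block`, `treatment`, `day`,
#' `diameter` (mm) and `height` (cm). Days must form a contiguous range per
#' tree and diameters must be positive.
#'
#' @param path CSV file path.
#' @return A validated growth data frame.
#' @export
read_growth_table <- function(path) {
  df <- read_csv_checked(path)
  require_columns(df, c("tree_id", "block", "treatment", "day", "diameter",
                        "height"), "growth table")
  for (col in c("day", "diameter", "height")) {
    df[[col]] <- check_numeric(df[[col]], col, "growth table")
  }
  if (any(df$diameter <= 0)) {
    stop(xylo_error("diameter must be positive", "xylo_invariant_error"))
  }
  for (id in unique(df$tree_id)) {
    d <- sort(df$day[df$tree_id == id])
    if (anyDuplicated(d)) {
      stop(xylo_error(sprintf("tree %s has duplicated day %d", id,
                              d[duplicated(d)][1]), "xylo_contiguity_error"))
    }
    gaps <- diff(d)
    if (any(gaps != 1)) {
      miss <- d[which(gaps != 1)[1]] + 1
      stop(xylo_error(sprintf("tree %s is missing day %d", id, miss),
                      "xylo_contiguity_error"))
    }
  }
  df
}

#' @rdname read_growth_table
#' @param df Growth data frame.
#' @export
write_growth_table <- function(df, path) {
  require_columns(df, c("tree_id", "block", "treatment", "day", "diameter",
                        "height"), "growth table")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read the pre-dawn leaf water potential table
#'
#' Columns `tree_id`, `day`, `psi_pd` (MPa); water potentials must be
#' non-positive.
#'
#' @param path CSV file path.
#' @return A validated LWP data frame.
#' @export
read_lwp_table <- function(path) {
  df <- read_csv_checked(path)
  require_columns(df, c("tree_id", "day", "psi_pd"), "LWP table")
  df$day <- check_numeric(df$day, "day", "LWP table")
  df$psi_pd <- check_numeric(df$psi_pd, "psi_pd", "LWP table")
  bad <- which(df$psi_pd > 0)
  if (length(bad)) {
    stop(xylo_error(
      sprintf("psi_pd must be <= 0 MPa (row %d has %+.2f)", bad[1],
              df$psi_pd[bad[1]]), "xylo_sign_error"))
  }
  df
}

#' @rdname read_lwp_table
#' @param df LWP data frame.
#' @export
write_lwp_table <- function(df, path) {
  require_columns(df, c("tree_id", "day", "psi_pd"), "LWP table")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read the environment logger table
#'
#' Columns `timestamp` (days from experiment start, fractional), `temperature`
#' (deg C) and `relative_humidity` (percent, 0-100).
#'
#' @param path CSV file path.
#' @return A validated environment data frame.
#' @export
read_environment_log <- function(path) {
  df <- read_csv_checked(path)
  require_columns(df, c("timestamp", "temperature", "relative_humidity"),
                  "environment log")
  for (col in c("timestamp", "temperature", "relative_humidity")) {
    df[[col]] <- check_numeric(df[[col]], col, "environment log")
  }
  if (any(df$relative_humidity < 0 | df$relative_humidity > 100)) {
    stop(xylo_error("relative_humidity must lie in [0, 100]",
                    "xylo_invariant_error"))
  }
  df
}

#' @rdname read_environment_log
#' @param df Environment data frame.
#' @export
write_environment_log <- function(df, path) {
  require_columns(df, c("timestamp", "temperature", "relative_humidity"),
                  "environment log")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a treatment schedule table
#'
#' Columns `label`, `start_day`, `end_day`, `status`; cycles must be
#' contiguous and alternate droughted/watered.
#'
#' @param path CSV file path.
#' @return A validated `xylo_schedule` data frame.
#' @export
read_schedule <- function(path) {
  df <- read_csv_checked(path)
  require_columns(df, c("label", "start_day", "end_day", "status"),
                  "schedule")
  df$start_day <- check_numeric(df$start_day, "start_day", "schedule")
  df$end_day <- check_numeric(df$end_day, "end_day", "schedule")
  validate_schedule(df)
  structure(df, class = c("xylo_schedule", "data.frame"))
}

#' @rdname read_schedule
#' @param df Schedule data frame.
#' @export
write_schedule <- function(df, path) {
  validate_schedule(df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
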