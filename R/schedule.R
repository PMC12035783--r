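#' Generate a cyclic drought/watering treatment schedule
#'
#' Builds the alternating drought-treatment (DT) / watering-treatment (WT)
#' cycle structure applied to the periodically irrigated (PI) trees: a watered
#' lead-in (`WT0`) followed by `DT1, WT1, ..., DTk, WTk`. Drought durations
#' are drawn uniformly from `drought_range` (the study withheld water for 3-7
#' days per cycle, adjusted to visible stress), watered durations from
#' `watered_range`. Continuously irrigated (CI) trees ignore the schedule.
#'
#' @param n_cycles Number of drought/watering cycles (the study used 6).
#' @param drought_range Integer range `c(min, max)` of drought-phase lengths
#'   in days.
#' @param watered_range Integer range of watering-phase lengths in days.
#' @param n_days Total experiment length the schedule must fit in; the
#'   trailing watered phase is extended to day `n_days - 1`.
#' @param lead_in Length of the initial watered phase `WT0` in days.
#' @param seed Optional integer seed; the draw is deterministic for a fixed
#'   seed.
#' @return A data frame of class `xylo_schedule` with columns `label`
#'   (`WT0`, `DT1`, `WT1`, ...), `start_day`, `end_day` (inclusive, day 0 =
#'   first experiment day) and `status` (`droughted` / `watered`). Cycles are
#'   contiguous, non-overlapping and alternate DT/WT.
#' @export
generate_schedule <- function(n_cycles = 6,
                              drought_range = c(3, 7),
                              watered_range = c(4, 7),
                              n_days = 75,
                              lead_in = 3,
                              seed = NULL) {
  if (n_cycles < 1) stop(xylo_error("n_cycles must be >= 1", "xylo_param_error"))
  if (any(drought_range <= 0) || any(watered_range <= 0) || lead_in < 0) {
    stop(xylo_error("phase length ranges must be positive", "xylo_param_error"))
  }
  if (!is.null(seed)) set.seed(seed)
  d_len <- sample(seq(drought_range[1], drought_range[2]), n_cycles, replace = TRUE)
  w_len <- sample(seq(watered_range[1], watered_range[2]), n_cycles, replace = TRUE)
  label <- "WT0"
  len <- lead_in
  status <- "watered"
  for (i in seq_len(n_cycles)) {
    label <- c(label, paste0("DT", i), paste0("WT", i))
    len <- c(len, d_len[i], w_len[i])
    status <- c(status, "droughted", "watered")
  }
  end <- cumsum(len) - 1
  start <- c(0, utils::head(end, -1) + 1)
  if (start[length(start)] > n_days - 1) {
    stop(xylo_error(
      sprintf("schedule spans %d days but n_days is %d", max(end) + 1, n_days),
      "xylo_schedule_truncation_error"))
  }
  # last watered phase absorbs any remaining days
  end[length(end)] <- n_days - 1
  structure(
    data.frame(label = label, start_day = start, end_day = end,
               status = status, stringsAsFactors = FALSE),
    class = c("xylo_schedule", "data.frame"))
}

validate_schedule <- function(schedule) {
  need <- c("label", "start_day", "end_day", "status")
  missing <- setdiff(need, names(schedule))
  if (length(missing)) {
    stop(xylo_error(paste("schedule lacks column(s):",
                          paste(missing, collapse = ", ")),
                    "xylo_schema_error"))
  }
  if (any(schedule$end_day < schedule$start_day)) {
    stop(xylo_error("schedule has a cycle with end_day < start_day",
                    "xylo_schedule_error"))
  }
  gaps <- schedule$start_day[-1] - utils::head(schedule$end_day, -1)
  if (any(gaps != 1)) {
    stop(xylo_error("schedule cycles must be contiguous and non-overlapping",
                    "xylo_schedule_error"))
  }
  if (!all(schedule$status %in% c("droughted", "watered"))) {
    stop(xylo_error("schedule status must be 'droughted' or 'watered'",
                    "xylo_schedule_error"))
  }
  if (any(schedule$status[-1] == utils::head(schedule$status, -1))) {
    stop(xylo_error("schedule phases must alternate droughted/watered",
                    "xylo_schedule_error"))
  }
  invisible(schedule)
}

# Per-day status vector ("droughted"/"watered") for days 0..n_days-1.
# Days beyond the schedule are treated as watered.
schedule_day_status <- function(schedule, n_days) {
  validate_schedule(schedule)
  status <- rep("watered", n_days)
  for (i in seq_len(nrow(schedule))) {
    days <- seq(schedule$start_day[i], min(schedule$end_day[i], n_days - 1))
    days <- days[days >= 0]
    status[days + 1] <- schedule$status[i]
  }
  status
}

# Cycle label per day ("WT0", "DT1", ...); days past the schedule inherit the
# final label.
schedule_day_label <- function(schedule, n_days) {
  validate_schedule(schedule)
  lab <- rep(schedule$label[nrow(schedule)], n_days)
  for (i in seq_len(nrow(schedule))) {
    days <- seq(schedule$start_day[i], min(schedule$end_day[i], n_days - 1))
    days <- days[days >= 0]
    lab[days + 1] <- schedule$label[i]
  }
  lab
}
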