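# Fixed single-cycle schedule for deterministic unit fixtures
tiny_schedule <- function(n_days = 20) {
  structure(data.frame(
    label = c("WT0", "DT1", "WT1"),
    start_day = c(0, 4, 9),
    end_day = c(3, 8, n_days - 1),
    status = c("watered", "droughted", "watered"),
    stringsAsFactors = FALSE), class = c("xylo_schedule", "data.frame"))
}

# Increment table built directly from widths (oldest first), youngest at depth 0
increments_from_widths <- function(widths, start_day = 0, by = 3) {
  n <- length(widths)
  cum <- cumsum(widths)
  total <- cum[n]
  data.frame(period_index = seq_len(n),
             start_day = start_day + (seq_len(n) - 1) * by,
             end_day = start_day + seq_len(n) * by,
             width = widths,
             cum_inner = total - c(0, head(cum, -1)),
             cum_outer = total - cum,
             status = "control")
}

# Independent brute-force dating: scan every (cell, increment) pair
brute_force_assign <- function(depth, increments) {
  total <- max(increments$cum_inner)
  vapply(depth, function(d) {
    if (d >= total) return("pre_experiment")
    if (d < 0) return("unassigned")
    for (i in seq_len(nrow(increments))) {
      if (d >= increments$cum_outer[i] && d < increments$cum_inner[i]) {
        return(as.character(increments$period_index[i]))
      }
    }
    "none"
  }, character(1))
}

# Growth table with prescribed start/end values per tree (linear in between)
growth_from_ratios <- function(ratios_ci, ratios_pi, start = 10, days = 5) {
  mk <- function(r, trt, i) {
    data.frame(tree_id = sprintf("%s%02d", trt, i), block = "A",
               treatment = trt, day = 0:(days - 1),
               diameter = seq(start, start * r, length.out = days),
               height = seq(50, 50 * r, length.out = days))
  }
  rbind(
    do.call(rbind, lapply(seq_along(ratios_ci), function(i) mk(ratios_ci[i], "CI", i))),
    do.call(rbind, lapply(seq_along(ratios_pi), function(i) mk(ratios_pi[i], "PI", i))))
}
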