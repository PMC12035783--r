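#' Attach treatment and cycle labels to an LWP table
#'
#' @param lwp LWP data frame (`tree_id`, `day`, `psi_pd`).
#' @param growth Growth table supplying `tree_id` -> `treatment`.
#' @param schedule `xylo_schedule` supplying the cycle label per day.
#' @return The LWP table with `treatment` and `cycle` columns.
#' @export
label_lwp <- function(lwp, growth, schedule) {
  map <- unique(growth[c("tree_id", "treatment")])
  lwp$treatment <- map$treatment[match(lwp$tree_id, map$tree_id)]
  if (anyNA(lwp$treatment)) {
    stop(xylo_error("LWP table contains trees absent from the growth table",
                    "xylo_join_error"))
  }
  lab <- schedule_day_label(schedule, max(lwp$day) + 1)
  # cycle number: WT0 and DT1/WT1 -> 1, DT2/WT2 -> 2, ...
  lwp$cycle <- pmax(1, as.integer(sub("^[DW]T", "", lab[lwp$day + 1])))
  lwp
}

#' Gamma identity-link GLM for pre-dawn leaf water potential
#'
#' Fits `|psi_pd| ~ Treatment + Cycle` with a Gamma error distribution and
#' identity link. Water potentials are negative with a hard zero bound, so
#' the model is fitted on their magnitudes (positive support, variance
#' increasing with stress); coefficients are therefore on the magnitude
#' scale, where a positive treatment coefficient means more negative water
#' potential in that arm.
#'
#' @param lwp LWP table with `psi_pd`, `treatment` and `cycle` columns (see
#'   [label_lwp()]).
#' @param alpha Significance threshold recorded in the result.
#' @return A `xylo_model`: list with `model_label`, `terms` (coefficient
#'   table: estimate, SE, t, p), `p_treatment`, and the `fit`.
#' @export
fit_lwp_glm <- function(lwp, alpha = 0.05) {
  for (col in c("psi_pd", "treatment", "cycle")) {
    if (!col %in% names(lwp)) {
      stop(xylo_error(sprintf("LWP table lacks column '%s'", col),
                      "xylo_schema_error"))
    }
  }
  if (length(unique(lwp$cycle)) < 2) {
    stop(xylo_error("need at least 2 cycles to fit the LWP GLM",
                    "xylo_precondition_error"))
  }
  if (length(unique(lwp$treatment)) < 2) {
    stop(xylo_error("both treatments must be present",
                    "xylo_precondition_error"))
  }
  d <- data.frame(mag = -lwp$psi_pd,
                  treatment = factor(lwp$treatment),
                  cycle = factor(lwp$cycle))
  if (any(d$mag <= 0)) {
    stop(xylo_error("psi_pd magnitudes must be positive to fit a Gamma GLM",
                    "xylo_sign_error"))
  }
  fit <- tryCatch(
    stats::glm(mag ~ treatment + cycle, data = d,
               family = stats::Gamma(link = "identity")),
    error = function(e) {
      start <- stats::coef(stats::lm(mag ~ treatment + cycle, data = d))
      stats::glm(mag ~ treatment + cycle, data = d,
                 family = stats::Gamma(link = "identity"), start = start)
    })
  note <- if (!fit$converged) "GLM did not converge" else NULL
  sm <- summary(fit)$coefficients
  terms <- data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
                      statistic = sm[, 3], p = sm[, 4], row.names = NULL,
                      stringsAsFactors = FALSE)
  trt_row <- grep("^treatment", terms$term)[1]
  structure(list(model_label = "lwp_gamma_glm", terms = terms,
                 p_treatment = terms$p[trt_row],
                 estimate_treatment = terms$estimate[trt_row],
                 alpha = alpha, notes = note, fit = fit),
            class = "xylo_model")
}

#' Linear mixed-effects Treatment x Period model for a cell trait
#'
#' Fits `trait ~ Treatment * Period` with a random intercept per sample to a
#' dated cell table, and reports marginal F tests plus windowed PI-minus-CI
#' contrasts of the estimated marginal means. The study's model formula also
#' lists a per-cell random intercept, but with one observation per cell that
#' term is unidentifiable, so the default random structure is sample-level
#' only.
#'
#' @param dated Dated cell table from [date_experiment()] (needs
#'   `sample_id`, `treatment`, `period_index`, `period_day`, `cell_class`,
#'   `cell_area`, `lumen_area`).
#' @param trait One of `"vessel_csa"`, `"fibre_csa"`, `"fibre_diameter"`,
#'   `"wall_thickness"`.
#' @param windows Optional data frame of day windows (`start_day`,
#'   `end_day`); each window's contrast averages the marginal means of the
#'   periods whose midpoint falls inside it. See [drought_windows()].
#' @param adjust Multiplicity adjustment across windows (`"none"`, matching
#'   the study's reporting, or any method of [stats::p.adjust()]).
#' @param alpha Significance threshold recorded in the result.
#' @return A `xylo_model`: `anova` (marginal F table), `p_interaction`,
#'   `windows` (window, estimate, SE, p), `notes`, `fit`.
#' @export
fit_trait_lmm <- function(dated, trait = c("vessel_csa", "fibre_csa",
                                           "fibre_diameter", "wall_thickness"),
                          windows = NULL, adjust = "none", alpha = 0.05) {
  trait <- match.arg(trait)
  d <- dated[dated$flag == "assigned", , drop = FALSE]
  d <- switch(trait,
    vessel_csa = {
      x <- d[d$cell_class == "vessel", , drop = FALSE]
      x$value <- x$cell_area; x
    },
    fibre_csa = {
      x <- d[d$cell_class == "fibre", , drop = FALSE]
      x$value <- x$cell_area; x
    },
    fibre_diameter = {
      x <- d[d$cell_class == "fibre", , drop = FALSE]
      x$value <- fibre_diameter(x$cell_area); x
    },
    wall_thickness = {
      x <- d[d$cell_class == "fibre", , drop = FALSE]
      x$value <- wall_thickness(x$cell_area, x$lumen_area); x
    })
  if (length(unique(d$treatment)) < 2) {
    stop(xylo_error("both treatments must be present",
                    "xylo_precondition_error"))
  }
  tab <- table(unique(d[c("sample_id", "treatment")])$treatment)
  if (any(tab < 2)) {
    stop(xylo_error("need at least 2 samples per treatment",
                    "xylo_precondition_error"))
  }
  # keep periods observed in both treatments so every marginal mean exists
  per_ok <- names(which(apply(table(d$period_index, d$treatment) > 0, 1, all)))
  d <- d[d$period_index %in% as.integer(per_ok), , drop = FALSE]
  if (length(unique(d$period_index)) < 2) {
    stop(xylo_error("need at least 2 periods with data in both treatments",
                    "xylo_precondition_error"))
  }
  d$treatment <- factor(d$treatment)
  d$period_f <- factor(d$period_index)
  d$sample_id <- factor(d$sample_id)
  notes <- character(0)
  fit <- tryCatch(
    nlme::lme(value ~ treatment * period_f, random = ~ 1 | sample_id,
              data = d, na.action = stats::na.omit),
    error = function(e) {
      notes <<- c(notes, paste("random intercept dropped:", conditionMessage(e)))
      nlme::gls(value ~ treatment * period_f, data = d,
                na.action = stats::na.omit)
    })
  an <- as.data.frame(stats::anova(fit, type = "marginal"))
  an$term <- rownames(an)
  p_int <- an[an$term == "treatment:period_f", "p-value"]

  win_tab <- NULL
  if (!is.null(windows) && nrow(windows)) {
    mids <- tapply(d$period_day, d$period_f, function(x) x[1])
    emm <- emmeans::emmeans(fit, ~ treatment * period_f, data = d)
    grid <- as.data.frame(emm)
    rows <- list()
    for (i in seq_len(nrow(windows))) {
      inwin <- levels(d$period_f)[mids >= windows$start_day[i] &
                                    mids <= windows$end_day[i]]
      if (!length(inwin)) {
        rows[[i]] <- data.frame(start_day = windows$start_day[i],
                                end_day = windows$end_day[i],
                                n_periods = 0, estimate = NA_real_,
                                se = NA_real_, p = NA_real_)
        next
      }
      v <- numeric(nrow(grid))
      pi_rows <- grid$treatment == "PI" & grid$period_f %in% inwin
      ci_rows <- grid$treatment == "CI" & grid$period_f %in% inwin
      v[pi_rows] <- 1 / sum(pi_rows)
      v[ci_rows] <- -1 / sum(ci_rows)
      ct <- summary(emmeans::contrast(emm, method = list(window = v)))
      rows[[i]] <- data.frame(start_day = windows$start_day[i],
                              end_day = windows$end_day[i],
                              n_periods = length(inwin),
                              estimate = ct$estimate, se = ct$SE, p = ct$p.value)
    }
    win_tab <- do.call(rbind, rows)
    win_tab$p_adjusted <- stats::p.adjust(win_tab$p, method = adjust)
  }
  structure(list(model_label = paste0("lmm_", trait), trait = trait,
                 anova = an, p_interaction = p_int, windows = win_tab,
                 alpha = alpha, notes = if (length(notes)) notes else NULL,
                 fit = fit),
            class = "xylo_model")
}

#' Relative increment comparison of diameter and height growth
#'
#' Computes each tree's relative increment (end value over start value) for
#' stem diameter and height, screens for a treatment difference with a
#' one-way ANOVA, then compares the periodically and continuously irrigated
#' arms with a two-sample t test (the study's order of operations).
#'
#' @param growth Growth table (`tree_id`, `treatment`, `day`, `diameter`,
#'   `height`).
#' @return A `xylo_model` with one row per measure in `terms`: mean ratios
#'   by treatment, ANOVA p, t statistic and t-test p.
#' @export
relative_increment_test <- function(growth) {
  res <- lapply(c("diameter", "height"), function(measure) {
    ratios <- do.call(rbind, lapply(split(growth, growth$tree_id), function(g) {
      g <- g[order(g$day), ]
      start <- g[[measure]][1]; end <- g[[measure]][nrow(g)]
      if (start <= 0) {
        stop(xylo_error(sprintf("non-positive starting %s for tree %s",
                                measure, g$tree_id[1]), "xylo_invariant_error"))
      }
      data.frame(tree_id = g$tree_id[1], treatment = g$treatment[1],
                 ratio = end / start, stringsAsFactors = FALSE)
    }))
    av <- summary(stats::aov(ratio ~ treatment, data = ratios))[[1]]
    tt <- stats::t.test(ratio ~ treatment, data = ratios)
    means <- tapply(ratios$ratio, ratios$treatment, mean)
    data.frame(measure = measure,
               mean_ratio_CI = unname(means["CI"]),
               mean_ratio_PI = unname(means["PI"]),
               p_anova = av[["Pr(>F)"]][1],
               statistic_t = unname(tt$statistic), p_t = tt$p.value,
               stringsAsFactors = FALSE)
  })
  structure(list(model_label = "relative_increment",
                 terms = do.call(rbind, res)),
            class = "xylo_model")
}

#' Derive drought test windows from the observed water potential
#'
#' Finds runs of days on which the periodically irrigated trees' mean
#' pre-dawn LWP sits below `threshold`, and extends each run `lag` days
#' backwards: cells keep enlarging for about `lag` days after production, so
#' cells produced up to `lag` days before a stress day carry its imprint.
#' Overlapping windows are merged.
#'
#' @param lwp LWP table with a `treatment` column (see [label_lwp()]).
#' @param threshold Stress threshold in MPa.
#' @param lag Enlargement lag in days.
#' @return Data frame of windows (`start_day`, `end_day`), possibly empty.
#' @export
drought_windows <- function(lwp, threshold = -2, lag = 3) {
  if (!"treatment" %in% names(lwp)) {
    stop(xylo_error("LWP table needs a treatment column (see label_lwp)",
                    "xylo_schema_error"))
  }
  pi_lwp <- lwp[lwp$treatment == "PI", , drop = FALSE]
  daily <- tapply(pi_lwp$psi_pd, pi_lwp$day, mean)
  days <- as.integer(names(daily))
  sub <- days[daily < threshold]
  if (!length(sub)) {
    return(data.frame(start_day = integer(), end_day = integer()))
  }
  runs <- split(sub, cumsum(c(1, diff(sub) > 1)))
  win <- do.call(rbind, lapply(runs, function(r) {
    data.frame(start_day = max(min(days), min(r) - lag), end_day = max(r))
  }))
  win <- win[order(win$start_day), , drop = FALSE]
  merged <- win[1, , drop = FALSE]
  for (i in seq_len(nrow(win))[-1]) {
    if (win$start_day[i] <= merged$end_day[nrow(merged)]) {
      merged$end_day[nrow(merged)] <- max(merged$end_day[nrow(merged)],
                                          win$end_day[i])
    } else {
      merged <- rbind(merged, win[i, ])
    }
  }
  rownames(merged) <- NULL
  merged
}

#' @export
print.xylo_model <- function(x, ...) {
  cat("<xylo_model>", x$model_label, "\n")
  if (!is.null(x$terms)) print(x$terms, digits = 4)
  if (!is.null(x$p_interaction)) {
    cat("Treatment x Period interaction p =", format.pval(x$p_interaction), "\n")
  }
  if (!is.null(x$windows)) {
    cat("Window contrasts (PI - CI):\n")
    print(x$windows, digits = 4)
  }
  if (!is.null(x$notes)) cat("notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}
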