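#!/usr/bin/env Rscript
# Stage 4 — cambial kinetics per sample and growth period.
#
# Estimates, for Period 1 (days 18-28), the in-between stretch and Period 2
# (days 60-72): the cell production rate phi = g/(D t), the cell-cycle
# duration t_phi = eta_c/phi from the cambial-file counts, the enlargement
# duration t_sigma = eta_x/phi and the enlargement rate. A mixed-effects
# model (random intercept per tree) then compares treatments and periods.

library(xylokinetics)
suppressMessages(library(nlme))

ind <- "results/experiment"
detections <- read_detection_table(file.path(ind, "detections.csv"))
growth <- read_growth_table(file.path(ind, "growth.csv"))
schedule <- read_schedule(file.path(ind, "schedule.csv"))
cambium <- read.csv(file.path(ind, "cambium.csv"))
phases <- read.csv(file.path(ind, "phases.csv"))

kin <- estimate_kinetics(detections, growth, cambium, phases,
                         schedule = schedule)
tmap <- unique(growth[c("tree_id", "treatment")])
kin$treatment <- tmap$treatment[match(kin$sample_id, tmap$tree_id)]
write.csv(kin, "results/kinetics.csv", row.names = FALSE)

cat("Mean kinetics by treatment and period:\n")
agg <- aggregate(cbind(phi, t_phi, t_sigma, enlargement_rate) ~
                   treatment + period_label, kin, mean, na.action = na.omit)
print(agg, digits = 3)

ok <- !is.na(kin$t_phi)
for (resp in c("phi", "t_phi")) {
  fml <- stats::as.formula(paste(resp, "~ treatment * period_label"))
  fit <- lme(fml, random = ~ 1 | sample_id, data = kin[ok, ],
             na.action = na.omit)
  an <- anova(fit, type = "marginal")
  cat(sprintf("%s: treatment p = %.3f, period p = %.3g, interaction p = %.3f\n",
              resp, an["treatment", "p-value"],
              an["period_label", "p-value"],
              an["treatment:period_label", "p-value"]))
}
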