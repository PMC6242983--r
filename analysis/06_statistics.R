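#!/usr/bin/env Rscript
# The study's statistical design on a simulated longitudinal cohort: per-mouse
# wound closure from digitized tracings, nested two-factor mixed ANOVAs with
# Tukey HSD for each outcome, Pearson correlation panel, and the markdown
# summary report.

library(mpmwound)

out_dir <- "results/06_stats"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

days <- c(1, 3, 5, 7, 10)

# redox: transient dip at days 3-5, day-10 deficit in the diabetic group
redox_eff <- function(group, day) {
  dip <- ifelse(day %in% c(3, 5), -0.08, 0)
  dip + ifelse(group == "diabetic" & day == 10, -0.06, 0)
}
# A1/A2: elevated at day 3, declining after (proliferation-linked)
a1a2_eff <- function(group, day)
  c("1" = 0.1, "3" = 0.3, "5" = 0.2, "7" = 0.05, "10" = -0.1)[as.character(day)]

tab <- rbind(
  simulate_outcome_table(baseline = 0.55, effect = redox_eff,
                         outcome_name = "redox", seed = 61L),
  simulate_outcome_table(baseline = 1.2, effect = a1a2_eff,
                         sd_mouse = 0.1, sd_residual = 0.12,
                         outcome_name = "a1a2", seed = 62L))
write.csv(tab, file.path(out_dir, "measurement_table.csv"), row.names = FALSE)

# wound closure per mouse from digitized tracings (diabetic heals slower)
curves <- list(control = c(1, 0.92, 0.75, 0.55, 0.38, 0.18),
               diabetic = c(1, 0.97, 0.9, 0.8, 0.68, 0.5))
closure <- do.call(rbind, lapply(1:8, function(i) {
  g <- if (i <= 4) "control" else "diabetic"
  tr <- generate_wound_tracings(curves[[g]], days = c(0, days), seed = 70L + i)
  cbind(mouse_id = paste0("w", i), group = g, closure_from_tracings(tr))
}))
write.csv(closure, file.path(out_dir, "wound_closure.csv"), row.names = FALSE)

results <- list()
for (oc in c("redox", "a1a2")) {
  res <- nested_anova(tab, oc)
  results[[oc]] <- res
  write.csv(res$anova, file.path(out_dir, sprintf("anova_%s.csv", oc)),
            row.names = FALSE)
  write.csv(res$tukey, file.path(out_dir, sprintf("tukey_%s.csv", oc)),
            row.names = FALSE)
  pg <- res$anova$p[res$anova$effect == "group"]
  pd <- res$anova$p[res$anova$effect == "day"]
  message(sprintf("%s: F-test p(group) = %.4g, p(day) = %.4g", oc, pg, pd))
}

report <- build_report(tab, results, path = file.path(out_dir, "report.md"))
message(sprintf("report: %d lines -> %s", length(report),
                file.path(out_dir, "report.md")))
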