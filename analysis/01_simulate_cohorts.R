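#!/usr/bin/env Rscript

# Step 1 — simulate the two surveillance-style cohorts.
#
# Draws a development cohort and an external cohort from the published-
# network fixture (13 ground-truth nodes; outcome prevalence calibrated to
# 1.26%), renders them as raw messy report tables (real-valued ages,
# unknown genders, decoy AE terms), and stores them for the later steps.
# Raw cohorts go under scratch/ (large); the summary table under results/.

source("analysis/common.R")

b <- gbs_fixture_network()

us <- emulate_raw_reports(b, N_US, seed = SEED_US, mess = MESS)
eu <- emulate_raw_reports(b, N_EU, seed = SEED_EU, mess = MESS)
write_reports(us, us_reports_path)
write_reports(eu, eu_reports_path)

summarize <- function(t, label) {
  out <- apply_exclusions(t)
  log <- out$log
  gbs <- mean(vapply(out$reports$ae_terms,
                     function(s) "gbs" %in% s, logical(1)))
  data.frame(cohort = label, raw_reports = nrow(t),
             retained = log$count[log$rule == "retained"],
             excluded_missing_age = log$count[log$rule == "missing_age"],
             excluded_under_age = log$count[log$rule == "age_below_0.5"],
             excluded_unknown_gender =
               log$count[log$rule == "unknown_gender"],
             gbs_prevalence_pct = round(100 * gbs, 3))
}
summary <- rbind(summarize(us, "development"), summarize(eu, "external"))
write.csv(summary, file.path(RESULTS, "simulation_summary.csv"),
          row.names = FALSE)

cat("Simulated cohorts (outcome prevalence in % after exclusions):\n")
print(summary, row.names = FALSE)
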