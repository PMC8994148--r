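# Shared settings for the analysis scripts. Cohort sizes mirror the two
# surveillance cohorts (development ~80k reports, external ~12.5k); the
# seeds fix the whole workflow.

library(gbsbn)

SEED_US <- 20260101
SEED_EU <- 20260102
SEED_CV <- 20260103

N_US <- 80000
N_EU <- 12495
TOP_K <- 25          # AE vocabulary size for the synthetic cohorts
N_DECOYS <- 15       # independent decoy AEs the MB reduction should prune
CV_REPEATS <- 5

MESS <- list(missing_age = 0.01, under_age = 0.005,
             unknown_gender = 0.01, decoy_terms = N_DECOYS)

SCRATCH <- "scratch"
RESULTS <- "results"
dir.create(SCRATCH, showWarnings = FALSE)
dir.create(RESULTS, showWarnings = FALSE)

us_reports_path <- file.path(SCRATCH, "us_reports.csv")
eu_reports_path <- file.path(SCRATCH, "eu_reports.csv")
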