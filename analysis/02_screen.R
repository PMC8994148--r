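#!/usr/bin/env Rscript

# Step 2 — descriptive statistics and AE screening.
#
# Part A reproduces the published summary-table statistics from the bundled
# tables alone: outcome proportions, demographic shares, and the
# chi-square screening counts (reconstructed integer counts, uncorrected
# Pearson test, strict p < .001).
# Part B runs the same screening operationally on the simulated
# development cohort from step 1.

source("analysis/common.R")

## Part A: published tables ------------------------------------------------
tabs <- cohort_summary_tables()
t1 <- tabs$table1
us <- t1[t1$cohort == "us" & t1$characteristic == "total", ]
eu <- t1[t1$cohort == "eu" & t1$characteristic == "total", ]
us_n <- us$n_gbs + us$n_nongbs
eu_n <- eu$n_gbs + eu$n_nongbs
male <- t1[t1$cohort == "us" & t1$level == "male", ]
mid <- t1[t1$cohort == "us" & t1$level == "50-64", ]

t1_stats <- data.frame(
  statistic = c("us_gbs_prevalence_pct", "eu_gbs_prevalence_pct",
                "us_gbs_male_share_pct", "us_gbs_age_50_64_share_pct"),
  value = round(c(prevalence_per_mille(us$n_gbs, us_n) / 10,
                  prevalence_per_mille(eu$n_gbs, eu_n) / 10,
                  prevalence_per_mille(male$n_gbs, us$n_gbs) / 10,
                  prevalence_per_mille(mid$n_gbs, us$n_gbs) / 10), 2))
write.csv(t1_stats, file.path(RESULTS, "table1_statistics.csv"),
          row.names = FALSE)

t2 <- tabs$table2
group_p <- function(gbs_pm, non_pm, n_g, n_n) {
  a <- reconstruct_count(gbs_pm, n_g)
  c_ <- reconstruct_count(non_pm, n_n)
  if (a + c_ == 0L) return(NA_real_)
  chi_square_2x2(a, n_g - a, c_, n_n - c_)$p_value
}
us_p <- mapply(group_p, t2$us_gbs_pm, t2$us_nongbs_pm,
               MoreArgs = list(n_g = us$n_gbs, n_n = us$n_nongbs))
eu_p <- mapply(group_p, t2$eu_gbs_pm, t2$eu_nongbs_pm,
               MoreArgs = list(n_g = eu$n_gbs, n_n = eu$n_nongbs))
positive <- reconstruct_count(t2$us_gbs_pm, us$n_gbs) / us$n_gbs >
  reconstruct_count(t2$us_nongbs_pm, us$n_nongbs) / us$n_nongbs
cmp <- compare_cohorts(
  data.frame(term = t2$term,
             count = reconstruct_count(t2$us_total_pm, us_n),
             group_size = us_n),
  data.frame(term = t2$term,
             count = reconstruct_count(t2$eu_total_pm, eu_n),
             group_size = eu_n))

counts <- data.frame(
  statistic = c("us_significant_aes", "us_positive_significant_aes",
                "eu_significant_aes", "us_eu_no_difference_terms"),
  value = c(sum(us_p < 0.001, na.rm = TRUE),
            sum(us_p < 0.001 & positive, na.rm = TRUE),
            sum(eu_p < 0.001, na.rm = TRUE),
            sum(!cmp$differs & cmp$testable)))
write.csv(counts, file.path(RESULTS, "screening_counts.csv"),
          row.names = FALSE)
cat("Published-table screening counts:\n")
print(counts, row.names = FALSE)

## Part B: screening of the simulated development cohort -------------------
if (!file.exists(us_reports_path))
  stop("run analysis/01_simulate_cohorts.R first")
us_rep <- load_reports(us_reports_path)
cln <- apply_exclusions(us_rep)$reports
vocab <- select_top_k_aes(cln, TOP_K, exclude = "GBS")
m <- build_case_matrix(cln, vocab, "GBS")
scr <- screen_aes(m, alpha = 0.001)
scr[-1] <- lapply(scr[-1], function(x) if (is.numeric(x)) signif(x, 6)
                  else x)
write.csv(scr, file.path(RESULTS, "synthetic_screening.csv"),
          row.names = FALSE)
cat("\nSynthetic development cohort:", sum(scr$significant),
    "of", nrow(scr), "AE terms significantly associated with the outcome",
    "at p < .001\n")
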