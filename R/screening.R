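#' Prevalence in cases per thousand reports
#'
#' @param count number of reports with the event.
#' @param group_size total number of reports in the group (positive).
#' @return `1000 * count / group_size`, at full precision (round only for
#'   presentation).
#' @export
#' @examples
#' prevalence_per_mille(996, 79165)   # 12.58 per mille ~ 1.26%
prevalence_per_mille <- function(count, group_size) {
  stopifnot(all(group_size > 0), all(count >= 0), all(count <= group_size))
  1000 * count / group_size
}

#' Recover an integer count from a rounded per-mille prevalence
#'
#' Inverse of the presentation rounding used in published prevalence tables:
#' the nearest integer to `per_mille * group_size / 1000`. Recovery is exact
#' whenever `0.005 * group_size / 1000 < 0.5`, which holds for all cohort
#' group sizes used here. The sentinel `"<0.01"` maps to 0: no integer count
#' in `[1, group_size]` can print below 0.01 per mille at these group sizes.
#'
#' @param per_mille numeric (or character, to admit the `"<0.01"` sentinel)
#'   prevalence in per mille.
#' @param group_size group size the prevalence refers to.
#' @return Integer count.
#' @export
#' @examples
#' reconstruct_count(296.18, 996)    # 295
reconstruct_count <- function(per_mille, group_size) {
  if (is.character(per_mille)) {
    per_mille <- ifelse(grepl("^\\s*<", per_mille), 0,
                        suppressWarnings(as.numeric(per_mille)))
  }
  stopifnot(all(per_mille >= 0, na.rm = TRUE))
  as.integer(round(per_mille * group_size / 1000))
}

#' Pearson chi-square test for a 2x2 table
#'
#' Uncorrected by default: `X2 = N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`,
#' with the p-value from the chi-square distribution on 1 degree of freedom.
#' A Yates-corrected variant is available behind `correct = TRUE` but is not
#' the default, since the screening convention here is the plain Pearson
#' statistic.
#'
#' @param a,b,c,d non-negative counts: `a` = exposed & event, `b` = exposed &
#'   no event, `c`, `d` analogous for unexposed.
#' @param correct apply the Yates continuity correction.
#' @return List with `statistic` and `p_value`.
#' @export
chi_square_2x2 <- function(a, b, c, d, correct = FALSE) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  n <- a + b + c + d
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0)) {
    lab <- c("row 1", "row 2", "column 1", "column 2")[margins == 0]
    stop("degenerate 2x2 table: zero margin in ",
         paste(lab, collapse = ", "))
  }
  dev <- abs(a * d - b * c)
  if (correct) dev <- max(0, dev - n / 2)
  stat <- n * dev^2 / prod(margins)
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Screen AE variables for association with the outcome
#'
#' One uncorrected Pearson chi-square test per AE variable against the
#' outcome, at a Bonferroni-style fixed threshold (default `alpha = 0.001`,
#' i.e. 0.05 over 50 tests) applied as a strict inequality `p < alpha`.
#' AEs absent from both outcome groups are untestable: they get `NA`
#' statistics, `significant = FALSE` and `direction = "none"`, and are never
#' counted among significant terms.
#'
#' @param m a [case_matrix()] whose AE variables are binary with states
#'   `c("false", "true")`.
#' @param alpha significance threshold in (0, 1).
#' @param correct use the Yates-corrected statistic.
#' @return Data frame with one row per AE variable: `term`, `n_total`,
#'   `n_event`, `n_nonevent` (counts with the AE), `prevalence_overall`,
#'   `prevalence_event_group`, `prevalence_nonevent_group` (per mille),
#'   `chi2`, `p_value`, `testable`, `significant` and `direction`
#'   (`"positive"`, `"negative"`, `"none"`).
#' @export
screen_aes <- function(m, alpha = 0.001, correct = FALSE) {
  stopifnot(alpha > 0, alpha < 1)
  ae_vars <- setdiff(names(m$cards), c(m$outcome, "age", "gender"))
  event <- m$data[, m$outcome] == 2L
  n_event <- sum(event)
  n_nonevent <- sum(!event)
  if (n_event == 0L || n_nonevent == 0L)
    stop("both outcome groups must be non-empty for screening")
  rows <- lapply(ae_vars, function(v) {
    present <- m$data[, v] == 2L
    a <- sum(present & event)
    c_ <- sum(present & !event)
    testable <- (a + c_) > 0L && (a + c_) < n_event + n_nonevent
    if (testable) {
      ts <- chi_square_2x2(a, n_event - a, c_, n_nonevent - c_,
                           correct = correct)
      chi2 <- ts$statistic; p <- ts$p_value
    } else {
      chi2 <- NA_real_; p <- NA_real_
    }
    significant <- isTRUE(p < alpha)
    pe <- prevalence_per_mille(a, n_event)
    pn <- prevalence_per_mille(c_, n_nonevent)
    direction <- if (!significant) "none" else
      if (pe > pn) "positive" else "negative"
    data.frame(term = v, n_total = a + c_, n_event = a, n_nonevent = c_,
               prevalence_overall = prevalence_per_mille(a + c_,
                                                         n_event + n_nonevent),
               prevalence_event_group = pe,
               prevalence_nonevent_group = pn,
               chi2 = chi2, p_value = p, testable = testable,
               significant = significant, direction = direction,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Compare per-term prevalence between two cohorts
#'
#' One 2x2 chi-square test per term on total prevalence (cohort x
#' AE-presence), using the same fixed threshold convention as
#' [screen_aes()]. Terms with zero cases in both cohorts are untestable and
#' flagged; a term missing from one cohort is an error.
#'
#' @param r1,r2 data frames with columns `term`, `count`, `group_size`.
#' @param alpha significance threshold; `differs` means `p < alpha`.
#' @param correct use the Yates-corrected statistic.
#' @return Data frame with `term`, `chi2`, `p_value`, `testable`, `differs`.
#' @export
compare_cohorts <- function(r1, r2, alpha = 0.001, correct = FALSE) {
  missing1 <- setdiff(r2$term, r1$term)
  missing2 <- setdiff(r1$term, r2$term)
  if (length(missing1) || length(missing2))
    stop("term(s) missing from one cohort: ",
         paste(c(missing1, missing2), collapse = ", "))
  r2 <- r2[match(r1$term, r2$term), ]
  rows <- lapply(seq_len(nrow(r1)), function(i) {
    a <- r1$count[i]; n1 <- r1$group_size[i]
    c_ <- r2$count[i]; n2 <- r2$group_size[i]
    testable <- (a + c_) > 0L && (a + c_) < n1 + n2
    if (testable) {
      ts <- chi_square_2x2(a, n1 - a, c_, n2 - c_, correct = correct)
      chi2 <- ts$statistic; p <- ts$p_value
    } else {
      chi2 <- NA_real_; p <- NA_real_
    }
    data.frame(term = r1$term[i], chi2 = chi2, p_value = p,
               testable = testable, differs = isTRUE(p < alpha),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Published cohort summary tables
#'
#' Loads the published demographic and AE-prevalence summary tables bundled
#' with the package: the US cohort (VAERS, trivalent influenza vaccine
#' reports, 1990-2017; 79,165 reports, 996 GBS) and the European cohort
#' (EudraVigilance, all influenza vaccines, 2003-2016; 12,495 reports, 214
#' GBS). `table2` carries per-mille prevalences of the 50 most prevalent AE
#' terms by outcome group and cohort, with `"<0.01"` sentinels preserved as
#' printed; use [reconstruct_count()] to recover integer counts.
#'
#' @return List with data frames `table1` (demographics: counts by cohort,
#'   outcome group, age group and gender) and `table2` (per-term per-mille
#'   prevalences).
#' @export
cohort_summary_tables <- function() {
  dir <- system.file("extdata", package = "gbsbn", mustWork = TRUE)
  table1 <- utils::read.csv(file.path(dir, "cohort_table1.csv"),
                            stringsAsFactors = FALSE)
  table2 <- utils::read.csv(file.path(dir, "cohort_table2.csv"),
                            stringsAsFactors = FALSE,
                            colClasses = "character", check.names = FALSE)
  num <- setdiff(names(table2),
                 c("term", "us_gbs_pm", "us_p", "eu_p", "us_vs_eu_p"))
  for (v in num) table2[[v]] <- as.numeric(table2[[v]])
  list(table1 = table1, table2 = table2)
}
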