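#' Canonicalize an adverse-event term
#'
#' Matching between report terms and the analysis vocabulary is exact string
#' match after trimming and case-folding; runs of non-alphanumeric characters
#' collapse to a single underscore so that canonical terms double as valid
#' variable names. No MedDRA hierarchy logic is applied.
#'
#' @param term character vector of AE preferred terms.
#' @return Character vector of canonical terms.
#' @export
#' @examples
#' sanitize_term("  Muscular weakness ")   # "muscular_weakness"
#' sanitize_term("Guillain-Barre syndrome")
sanitize_term <- function(term) {
  x <- tolower(trimws(term))
  x <- gsub("[^a-z0-9]+", "_", x)
  gsub("^_+|_+$", "", x)
}

#' Read a raw adverse-event report table
#'
#' Reads one report per row from delimited text. AE terms come either from a
#' single list column (`schema$ae_terms`, split on `schema$term_sep`) or from
#' one indicator column per term (`schema$ae_indicators`, where any value in
#' `c("1", "true", "TRUE", "yes")` marks presence).
#'
#' @param path path to a delimited text file with a header row.
#' @param schema list naming the columns: `id`, `age`, `gender`, and either
#'   `ae_terms` (+ optional `term_sep`, default `";"`) or `ae_indicators`
#'   (character vector of indicator column names).
#' @param sep field separator (`","` default, `"\t"` accepted).
#'
#' @return A `report_table`: a data frame with columns `report_id` (character),
#'   `age` (numeric, `NA` when missing or unparseable), `gender` (one of
#'   `"male"`, `"female"`, `"unknown"`) and `ae_terms` (list column of
#'   canonical term sets).
#' @export
load_reports <- function(path,
                         schema = list(id = "report_id", age = "age",
                                       gender = "gender",
                                       ae_terms = "ae_terms",
                                       term_sep = ";"),
                         sep = ",") {
  if (!file.exists(path)) stop("report file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  needed <- c(schema$id, schema$age, schema$gender,
              schema$ae_terms, schema$ae_indicators)
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols))
    stop("schema column(s) absent from file: ",
         paste(missing_cols, collapse = ", "))

  id <- as.character(df[[schema$id]])
  if (anyDuplicated(id))
    stop("duplicated report_id: ", id[duplicated(id)][1L])
  age <- suppressWarnings(as.numeric(df[[schema$age]]))
  gender <- tolower(trimws(df[[schema$gender]]))
  gender[!gender %in% c("male", "female")] <- "unknown"

  if (!is.null(schema$ae_terms)) {
    term_sep <- if (is.null(schema$term_sep)) ";" else schema$term_sep
    ae <- lapply(strsplit(df[[schema$ae_terms]], term_sep, fixed = TRUE),
                 function(x) unique(sanitize_term(x[nzchar(trimws(x))])))
  } else {
    truthy <- c("1", "true", "yes")
    terms <- sanitize_term(schema$ae_indicators)
    ae <- lapply(seq_len(nrow(df)), function(i) {
      present <- vapply(schema$ae_indicators, function(col)
        tolower(trimws(df[[col]][i])) %in% truthy, logical(1))
      unique(terms[present])
    })
  }
  report_table(report_id = id, age = age, gender = gender, ae_terms = ae)
}

#' Construct a report table in memory
#'
#' @param report_id character vector of unique report identifiers.
#' @param age numeric ages in years (`NA` allowed before exclusions).
#' @param gender character vector with values in `male`, `female`, `unknown`.
#' @param ae_terms list of character vectors of AE terms (canonicalized on
#'   construction).
#' @return A `report_table` data frame.
#' @export
report_table <- function(report_id, age, gender, ae_terms) {
  report_id <- as.character(report_id)
  if (anyDuplicated(report_id))
    stop("duplicated report_id: ", report_id[duplicated(report_id)][1L])
  stopifnot(all(gender %in% c("male", "female", "unknown")))
  if (any(!is.na(age) & age < 0)) stop("negative age")
  ae_terms <- lapply(ae_terms, function(x) unique(sanitize_term(x)))
  out <- data.frame(report_id = report_id, age = as.numeric(age),
                    gender = as.character(gender),
                    stringsAsFactors = FALSE)
  out$ae_terms <- ae_terms
  class(out) <- c("report_table", "data.frame")
  out
}

#' Apply the report exclusion rules
#'
#' Reports are excluded if (1) the age is missing or below 0.5 years, or
#' (2) the gender is unknown. The age rules take precedence in the log: a
#' report failing an age rule and the gender rule is counted once, under age.
#'
#' @param t a [report_table()].
#' @return A list with `reports` (the retained `report_table`) and `log`, a
#'   data frame with one row per rule (`missing_age`, `age_below_0.5`,
#'   `unknown_gender`) plus a `retained` row, and a `count` column.
#' @export
apply_exclusions <- function(t) {
  missing_age <- is.na(t$age)
  under_age <- !missing_age & t$age < 0.5
  unknown_gender <- !missing_age & !under_age & t$gender == "unknown"
  keep <- !(missing_age | under_age | unknown_gender)
  log <- data.frame(
    rule = c("missing_age", "age_below_0.5", "unknown_gender", "retained"),
    count = c(sum(missing_age), sum(under_age), sum(unknown_gender),
              sum(keep)),
    stringsAsFactors = FALSE
  )
  reports <- t[keep, , drop = FALSE]
  class(reports) <- c("report_table", "data.frame")
  list(reports = reports, log = log)
}

#' Discretize age in years into the four analysis age groups
#'
#' Bins are half-open: `[0.5, 18)`, `[18, 50)`, `[50, 65)`, `[65, Inf)`, so
#' every age of at least half a year falls in exactly one group and
#' fractional ages between the printed labels (for example 17.6) fall in the
#' lower group.
#'
#' @param age numeric vector of ages in years, all `>= 0.5` (exclusions must
#'   run first).
#' @return Factor with levels `"0.5-17"`, `"18-49"`, `"50-64"`, `">=65"`.
#' @export
#' @examples
#' discretize_age(c(0.5, 17.6, 18, 64.9, 65))
discretize_age <- function(age) {
  if (anyNA(age) || any(age < 0.5))
    stop("discretize_age requires non-missing ages >= 0.5; ",
         "run apply_exclusions first")
  cut(age, breaks = c(0.5, 18, 50, 65, Inf), right = FALSE,
      labels = age_group_labels())
}

#' @rdname discretize_age
#' @export
age_group_labels <- function() c("0.5-17", "18-49", "50-64", ">=65")

#' Select the most prevalent AE terms
#'
#' Terms are ranked by report-level prevalence (number of reports mentioning
#' the term at least once), in decreasing order; ties are broken
#' lexicographically for reproducibility. The outcome term must be excluded
#' so that it does not compete for a slot.
#'
#' @param t a [report_table()].
#' @param k number of terms to return.
#' @param exclude character vector of canonical terms to leave out (at least
#'   the outcome term).
#' @return Character vector of `k` canonical terms, prevalence non-increasing.
#' @export
select_top_k_aes <- function(t, k, exclude = character()) {
  stopifnot(k >= 1)
  exclude <- sanitize_term(exclude)
  counts <- table(unlist(lapply(t$ae_terms, unique)))
  counts <- counts[!names(counts) %in% exclude]
  if (length(counts) < k)
    stop("requested top ", k, " AE terms but only ", length(counts),
         " distinct terms are available")
  ord <- order(-as.integer(counts), names(counts))
  names(counts)[ord][seq_len(k)]
}

#' Build the discrete case matrix from cleaned reports
#'
#' Produces the variable layout used throughout the analysis: outcome, age
#' group, gender, then the AE vocabulary, in that order. An AE cell is true
#' iff the (canonicalized) term is present in the report's term set.
#'
#' @param t a cleaned [report_table()] (exclusions applied).
#' @param ae_vocabulary character vector of AE terms to binarize.
#' @param outcome_term AE term defining the outcome variable (true iff
#'   present in a report's term set); must not appear in `ae_vocabulary`.
#' @return A [case_matrix()] with `1 + 1 + 1 + length(ae_vocabulary)`
#'   variables; binary variables have states `c("false", "true")`, gender
#'   `c("female", "male")`, age group the four labels of
#'   [age_group_labels()].
#' @export
build_case_matrix <- function(t, ae_vocabulary, outcome_term) {
  outcome_term <- sanitize_term(outcome_term)
  ae_vocabulary <- sanitize_term(ae_vocabulary)
  if (anyDuplicated(ae_vocabulary)) stop("duplicated terms in ae_vocabulary")
  if (outcome_term %in% ae_vocabulary)
    stop("outcome term '", outcome_term, "' must not be in ae_vocabulary")
  if (nrow(t) && (anyNA(t$age) || any(t$age < 0.5) ||
                  any(t$gender == "unknown")))
    stop("reports must pass apply_exclusions before matrix construction")

  n <- nrow(t)
  has_term <- function(term)
    vapply(t$ae_terms, function(s) term %in% s, logical(1))
  bin <- c("false", "true")
  data <- matrix(1L, n, 3L + length(ae_vocabulary),
                 dimnames = list(NULL, c(outcome_term, "age", "gender",
                                         ae_vocabulary)))
  data[, 1L] <- 1L + has_term(outcome_term)
  data[, 2L] <- as.integer(discretize_age(t$age))
  data[, 3L] <- 1L + (t$gender == "male")
  for (term in ae_vocabulary) data[, term] <- 1L + has_term(term)
  levels <- c(
    stats::setNames(list(bin), outcome_term),
    list(age = age_group_labels(), gender = c("female", "male")),
    stats::setNames(rep(list(bin), length(ae_vocabulary)), ae_vocabulary)
  )
  case_matrix(data, levels, outcome = outcome_term)
}
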