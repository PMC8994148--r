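#' Stratified k-fold assignment
#'
#' Folds are stratified on the outcome label: within each class, indices are
#' shuffled and dealt round-robin, so fold sizes differ by at most one and
#' per-fold class counts differ by at most one. With a rare outcome this
#' prevents single-class validation folds.
#'
#' @param labels vector of class labels (one per report).
#' @param k number of folds (each class must have at least `k` members).
#' @param seed optional integer; when given, the assignment is a
#'   deterministic function of it (the caller's RNG state is untouched).
#'   When `NULL`, the current RNG stream is used.
#' @return Integer vector of fold ids in `1:k`.
#' @export
stratified_kfold <- function(labels, k, seed = NULL) {
  stopifnot(k >= 2)
  tab <- table(labels)
  if (any(tab < k))
    stop("class '", names(tab)[which.min(tab)], "' has fewer than k = ",
         k, " members")
  assign_folds <- function() {
    fold <- integer(length(labels))
    for (cl in names(tab)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  }
  if (is.null(seed)) assign_folds() else withr::with_seed(seed, assign_folds())
}

#' Receiver operating characteristic curve
#'
#' Classification rule is strict: a report is called positive when its score
#' exceeds the threshold. Candidate thresholds are the midpoints between
#' consecutive distinct score values, plus `-Inf` and `Inf` sentinels so the
#' curve always contains the (1,1) and (0,0) corners; equal scores are
#' grouped at a single threshold.
#'
#' @param scores numeric scores (higher = more likely positive).
#' @param labels logical (or 0/1) outcome per report; both classes must be
#'   present.
#' @return Object of class `roc_curve`: data frame `threshold`, `tpr`,
#'   `fpr`, ordered by increasing threshold (TPR and FPR non-increasing).
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  if (all(labels) || !any(labels))
    stop("both classes must be present to build a ROC curve")
  P <- sum(labels); N <- sum(!labels)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  last <- c(s[-length(s)] != s[-1], TRUE)  # last index of each score group
  ctp <- cumsum(l)[last]; cfp <- cumsum(!l)[last]
  d <- s[last]                             # distinct scores, descending
  m <- length(d)
  mids_desc <- if (m > 1) (d[-m] + d[-1]) / 2 else numeric(0)
  thr <- c(-Inf, rev(mids_desc), Inf)
  tpr <- c(1, if (m > 1) rev(ctp[-m] / P), 0)
  fpr <- c(1, if (m > 1) rev(cfp[-m] / N), 0)
  structure(data.frame(threshold = thr, tpr = tpr, fpr = fpr),
            class = c("roc_curve", "data.frame"))
}

#' Area under a ROC curve
#'
#' Trapezoidal rule over the (FPR, TPR) points; with tied scores grouped at
#' single thresholds this equals the Mann-Whitney concordance probability
#' with ties counted one half.
#'
#' @param c a [roc_curve()].
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(c) {
  x <- rev(c$fpr); y <- rev(c$tpr)  # ascending in FPR
  sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
}

#' Youden-index threshold
#'
#' The threshold maximizing `TPR - FPR` (equivalently sensitivity +
#' specificity - 1); ties are broken toward the smaller threshold, which
#' favours sensitivity.
#'
#' @param c a [roc_curve()].
#' @return A threshold (possibly `-Inf` when no cutpoint beats classifying
#'   everything positive, i.e. the scores are uninformative).
#' @export
youden_threshold <- function(c) {
  j <- c$tpr - c$fpr
  # rows ascend in threshold; take the smallest among the (numerically
  # tied) maximizers — true J differences are multiples of 1/P or 1/N,
  # far above the 1e-9 float guard
  c$threshold[min(which(j >= max(j) - 1e-9))]
}

#' Sensitivity, specificity and accuracy at a threshold
#'
#' Positive call iff `score > threshold` (strict).
#'
#' @param scores numeric scores.
#' @param labels logical (or 0/1) outcomes.
#' @param threshold classification threshold.
#' @return List with `sensitivity`, `specificity`, `accuracy`.
#' @export
confusion_metrics <- function(scores, labels, threshold) {
  labels <- as.logical(labels)
  pred <- scores > threshold
  tp <- sum(pred & labels); fn <- sum(!pred & labels)
  tn <- sum(!pred & !labels); fp <- sum(pred & !labels)
  list(sensitivity = tp / (tp + fn),
       specificity = tn / (tn + fp),
       accuracy = (tp + tn) / length(labels))
}

.normal_ci_summary <- function(folds) {
  metrics <- c("threshold", "auc", "sensitivity", "specificity", "accuracy")
  rows <- lapply(metrics, function(mt) {
    x <- folds[[mt]]
    half <- 1.96 * stats::sd(x) / sqrt(length(x))
    data.frame(metric = mt, mean = mean(x), lower = mean(x) - half,
               upper = mean(x) + half, sd = stats::sd(x),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Repeated stratified cross-validation of a fixed-structure model
#'
#' The structure `g` is learned once beforehand and held fixed; each fold
#' refits only the CPTs by maximum likelihood on the training folds, scores
#' the validation fold, picks the threshold on the validation fold itself by
#' the Youden index (the fidelity default; `threshold_on = "train"` gives
#' the conservative alternative of tuning it on the training folds), and
#' records the fold metrics. Summaries are means with approximate-normal
#' 95% confidence intervals (`mean +/- 1.96 sd / sqrt(#folds)`). Validation
#' reports whose evidence has zero fitted probability under both outcome
#' states (possible with sparse maximum-likelihood CPTs) are scored at the
#' training-fold marginal (see [predict_scores()]).
#'
#' @param m a [case_matrix()].
#' @param g a fixed [dag()] over (a subset of) the variables of `m`.
#' @param k number of folds.
#' @param repeats number of repetitions of the k-fold split.
#' @param seed integer seed making the whole procedure reproducible.
#' @param target outcome node (default: the matrix outcome).
#' @param threshold_on `"validation"` (fidelity default) or `"train"`.
#' @param fallback CPT fallback policy, see [fit_mle()].
#' @return Object of class `cv_result`: list with `folds` (data frame
#'   `rep`, `fold`, `threshold`, `auc`, `sensitivity`, `specificity`,
#'   `accuracy`) and `summary` (per-metric mean, 95% CI, sd). Folds whose
#'   validation part is single-class are skipped with a warning and recorded
#'   in `skipped`.
#' @export
repeated_cv <- function(m, g, k = 5, repeats = 100, seed = 1,
                        target = m$outcome,
                        threshold_on = c("validation", "train"),
                        fallback = "uniform") {
  threshold_on <- match.arg(threshold_on)
  labels_all <- m$data[, target] == 2L
  rows <- vector("list", k * repeats)
  skipped <- 0L
  withr::with_seed(seed, {
    for (r in seq_len(repeats)) {
      fold_id <- stratified_kfold(labels_all, k)
      for (f in seq_len(k)) {
        val <- fold_id == f
        fit <- fit_mle(g, cm_subset(m, !val), fallback = fallback)
        scores <- predict_scores(fit, cm_subset(m, val), target,
                                  impossible = "prior")
        labels <- labels_all[val]
        if (all(labels) || !any(labels)) {
          warning("skipping single-class validation fold (rep ", r,
                  ", fold ", f, ")")
          skipped <- skipped + 1L
          next
        }
        curve <- roc_curve(scores, labels)
        thr <- if (threshold_on == "validation") youden_threshold(curve)
        else {
          tr_scores <- predict_scores(fit, cm_subset(m, !val), target,
                                      impossible = "prior")
          youden_threshold(roc_curve(tr_scores, labels_all[!val]))
        }
        cm <- confusion_metrics(scores, labels, thr)
        rows[[(r - 1L) * k + f]] <-
          data.frame(rep = r, fold = f, threshold = thr, auc = auc(curve),
                     sensitivity = cm$sensitivity,
                     specificity = cm$specificity, accuracy = cm$accuracy)
      }
    }
  })
  folds <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  structure(list(folds = folds, summary = .normal_ci_summary(folds),
                 skipped = skipped),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("cv_result over", nrow(x$folds), "folds",
      if (x$skipped) paste0("(", x$skipped, " skipped)"), "\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' External validation of a trained model on a second cohort
#'
#' Applies a network trained on one cohort to score another cohort built
#' over the same vocabulary. By default the threshold is chosen by the
#' Youden index on the external cohort's own ROC curve; a fixed
#' (transferred) threshold can be supplied instead.
#'
#' @param b a trained `discrete_bn`.
#' @param m_B external [case_matrix()]; must provide all network variables
#'   (extra columns are projected away).
#' @param target outcome node (default: the matrix outcome).
#' @param threshold `"youden"` or a fixed numeric threshold.
#' @return List with `auc`, `threshold`, `sensitivity`, `specificity`,
#'   `accuracy` and the score vector `scores`.
#' @export
external_validate <- function(b, m_B, target = m_B$outcome,
                              threshold = "youden") {
  scores <- predict_scores(b, m_B, target, impossible = "prior")
  labels <- m_B$data[, target] == 2L
  curve <- roc_curve(scores, labels)
  thr <- if (identical(threshold, "youden")) youden_threshold(curve)
  else as.numeric(threshold)
  cm <- confusion_metrics(scores, labels, thr)
  list(auc = auc(curve), threshold = thr, sensitivity = cm$sensitivity,
       specificity = cm$specificity, accuracy = cm$accuracy,
       scores = scores)
}
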