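# Evaluation: confusion counting under the at-or-above-threshold
# convention, balanced accuracy, ROC/AUC, exhaustive threshold sweeps,
# stratified k-fold cross-validation, the binomial sign test and the
# minor-allele-frequency shift diagnostic for mislabeled controls.

#' Confusion counts at a score threshold
#'
#' Scores at or above the threshold are positive predictions; scores
#' below are negative (inclusive convention).
#'
#' @param scores numeric vector.
#' @param labels -1/+1 vector of the same length.
#' @param threshold real threshold.
#' @return a `confusion_counts` list with `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_at_threshold <- function(scores, labels, threshold) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(-1, 1)))
  pred_pos <- scores >= threshold
  structure(list(tp = sum(pred_pos & labels == 1),
                 fp = sum(pred_pos & labels == -1),
                 tn = sum(!pred_pos & labels == -1),
                 fn = sum(!pred_pos & labels == 1)),
            class = "confusion_counts")
}

#' Balanced accuracy
#'
#' Mean of sensitivity and specificity,
#' \eqn{(tp/(tp+fn) + tn/(tn+fp))/2}; robust to class imbalance.
#'
#' @param counts a `confusion_counts` (or list with tp/fp/tn/fn).
#' @return fraction in `[0, 1]`.
#' @export
balanced_accuracy <- function(counts) {
  with(counts, {
    if (tp + fn == 0 || tn + fp == 0)
      stop_("balanced accuracy undefined: a class is absent")
    (tp / (tp + fn) + tn / (tn + fp)) / 2
  })
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney statistic
#' \eqn{P(s_+ > s_-) + 0.5 P(s_+ = s_-)} over all positive-negative
#' pairs, via midranks (so tied scores contribute 1/2).
#'
#' @param scores numeric vector.
#' @param labels -1/+1 vector.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(-1, 1)))
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == -1)
  if (n_pos == 0 || n_neg == 0)
    stop_("AUC undefined: both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Exhaustive threshold sweep
#'
#' Evaluates every distinct observed score as a threshold, plus one
#' sentinel above the maximum (at which everything is predicted
#' negative). This grid is exact: no finer grid changes any confusion
#' count. The optimal threshold maximizes balanced accuracy, taking the
#' smallest threshold on ties.
#'
#' @inheritParams roc_auc
#' @return a `sweep_result` with `thresholds` (sorted), per-threshold
#'   `balanced_accuracy` and `fpr`, `optimal_threshold` and
#'   `counts_at_optimum`.
#' @export
threshold_sweep <- function(scores, labels) {
  thr <- c(sort(unique(scores)), max(scores) + 1)
  per <- lapply(thr, function(t) confusion_at_threshold(scores, labels, t))
  ba <- vapply(per, balanced_accuracy, numeric(1))
  fpr <- vapply(per, function(cc) cc$fp / (cc$fp + cc$tn), numeric(1))
  best <- which.max(ba)              # which.max returns the first maximum
  structure(list(thresholds = thr, balanced_accuracy = ba, fpr = fpr,
                 optimal_threshold = thr[best],
                 counts_at_optimum = per[[best]]),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  i <- match(x$optimal_threshold, x$thresholds)
  cat(sprintf(paste0("sweep_result: %d thresholds; optimum %.4g ",
                     "(balanced accuracy %.4f, FPR %.4f)\n"),
              length(x$thresholds), x$optimal_threshold,
              x$balanced_accuracy[i], x$fpr[i]))
  invisible(x)
}

#' Cross-validation fold indices
#'
#' Partitions indices into k folds of sizes differing by at most one;
#' stratified folds preserve the class ratio within one example per
#' class. Reproducible under `seed`.
#'
#' @param labels class labels (any coding) or a [variant_dataset()]
#'   (its `label` column is used).
#' @param k number of folds (default 5).
#' @param stratified preserve class proportions per fold? (default TRUE)
#' @param seed shuffle seed.
#' @return list of k folds, each `list(train =, test =)` index vectors;
#'   the test sets partition `1:n`.
#' @export
kfold_cv <- function(labels, k = 5, stratified = TRUE, seed = NULL) {
  if (inherits(labels, "variant_dataset")) labels <- labels$label
  n <- length(labels)
  stopifnot(k >= 2, n >= k)
  # round-robin over a shuffled order; the fold offset carries over from
  # one class to the next so per-class AND total fold sizes differ by <= 1
  assign_fold <- function(idx, offset) {
    f <- (offset + seq_along(idx) - 1L) %% k + 1L
    split(sample(idx), f)
  }
  local_seed(seed, {
    if (stratified) {
      if (any(table(labels) < k))
        stop_("a class has fewer examples than folds; cannot stratify")
      offset <- 0L
      fold_members <- rep(list(integer()), k)
      for (idx in split(seq_len(n), labels)) {
        part <- assign_fold(idx, offset)
        for (f in names(part))
          fold_members[[as.integer(f)]] <-
            c(fold_members[[as.integer(f)]], part[[f]])
        offset <- (offset + length(idx)) %% k
      }
      test_sets <- lapply(fold_members, sort)
    } else {
      test_sets <- lapply(assign_fold(seq_len(n), 0L), sort)
    }
    lapply(test_sets, function(ts)
      list(train = setdiff(seq_len(n), ts), test = ts))
  })
}

#' One-sided binomial sign test
#'
#' Probability of observing at least `wins` successes in `n` fair coin
#' flips: \eqn{p = \sum_{k=wins}^{n} \binom{n}{k} 2^{-n}}. Used to
#' compare two methods across cross-validation folds (ties excluded
#' before calling); e.g. winning all 5 folds gives p = 0.03125.
#'
#' @param wins number of comparisons won by the method, `0 <= wins <= n`.
#' @param n number of (tie-free) comparisons.
#' @return one-sided p-value.
#' @export
sign_test <- function(wins, n) {
  stopifnot(n >= 1, wins >= 0, wins <= n)
  stats::pbinom(wins - 1, n, 0.5, lower.tail = FALSE)
}

#' Minor-allele-frequency shift diagnostic
#'
#' Control sets assembled from population polymorphisms likely contain
#' some mislabeled true positives, which are expected to sit at lower
#' allele frequencies than genuine neutral polymorphisms. This
#' diagnostic splits the labeled negatives at a posterior cutoff into
#' predicted-positive (false positives under the given labels) and
#' predicted-negative (neutral) sets and compares their MAF
#' distributions: a positive `mean_shift` (neutral mean minus
#' false-positive mean) means the confident false positives are shifted
#' toward rare alleles, consistent with label contamination.
#'
#' @param records prediction records (see [prediction_records()]) aligned
#'   by `key` with `variants`.
#' @param variants a [variant_dataset()]; only labeled negatives with a
#'   MAF value enter the diagnostic.
#' @param cutoff posterior cutoff; negatives with `posterior >= cutoff`
#'   count as (confident) false positives.
#' @param bin_width MAF histogram bin width on `[0, 0.5]` (default 0.02,
#'   i.e. 25 bins).
#' @return list with `fp_hist` and `tn_hist` (normalized bin counts,
#'   each summing to 1, with the bin mid-points as names), `breaks`,
#'   and `mean_shift`.
#' @export
maf_shift <- function(records, variants, cutoff, bin_width = 0.02) {
  m <- match(variant_keys(variants), records$key)
  if (anyNA(m)) stop_("records do not cover all variants")
  post <- records$posterior[m]
  neg <- variants$label == -1L & !is.na(variants$maf) & !is.na(post)
  fp <- neg & post >= cutoff
  tn <- neg & post < cutoff
  if (!any(fp)) stop_("no false-positive side: no labeled negative reaches ",
                      "the cutoff")
  if (!any(tn)) stop_("no neutral side: every labeled negative reaches the ",
                      "cutoff")
  breaks <- seq(0, 0.5, by = bin_width)
  hist_norm <- function(x) {
    h <- graphics::hist(x, breaks = breaks, plot = FALSE)$counts
    stats::setNames(h / sum(h), breaks[-length(breaks)] + bin_width / 2)
  }
  list(fp_hist = hist_norm(variants$maf[fp]),
       tn_hist = hist_norm(variants$maf[tn]),
       breaks = breaks,
       mean_shift = mean(variants$maf[tn]) - mean(variants$maf[fp]))
}
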