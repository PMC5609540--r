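## Classification of patients above/below the clinical endoxifen threshold
## from CYP2D6 diplotype activity.
##
## The test statistic is the seven-level diplotype activity ordering
## EM/UM (3) > EM/EM (2) > EM/IM (1.5) > EM/PM (1) > IM/IM (0.75) >
## IM/PM (0.5) > PM/PM (0); a patient is test-positive at cutoff c when
## their activity is strictly greater than c.  The positive class is
## "endoxifen at or above the clinical threshold" (clinical benefit).

#' Clinical endoxifen threshold (ng/mL)
#'
#' The plasma endoxifen concentration below which reduced clinical
#' benefit was reported: 5.9 ng/mL (15.8 nM).
#' @export
CLINICAL_THRESHOLD_NGML <- 5.9

#' Binarize endoxifen outcomes at the clinical threshold
#'
#' Labels each patient as above (`E >= threshold`, the documented
#' boundary convention) or below the clinical endoxifen threshold, and
#' attaches the numeric diplotype ROC activity.
#'
#' @param records A `cohort` data frame (needs `e_ngml` and either
#'   `roc_activity` or `category`).
#' @param threshold_ngml Threshold in ng/mL (default 5.9).
#' @return A `threshold_outcomes` data frame with `id`, `above`
#'   (logical) and `activity`; attributes `threshold_ngml`, `n_above`,
#'   `n_below`.
#' @export
#' @examples
#' co <- simulate_cohort(n = 200, seed = 3)
#' out <- binarize_outcome(co)
#' mean(out$above)
binarize_outcome <- function(records, threshold_ngml = CLINICAL_THRESHOLD_NGML) {
  stopifnot(is.data.frame(records), "e_ngml" %in% names(records))
  activity <- if ("roc_activity" %in% names(records)) {
    records$roc_activity
  } else {
    roc_activity(records$category)
  }
  out <- data.frame(
    id = if ("id" %in% names(records)) records$id
         else sprintf("P%05d", seq_len(nrow(records))),
    above = records$e_ngml >= threshold_ngml,
    activity = activity,
    stringsAsFactors = FALSE
  )
  class(out) <- c("threshold_outcomes", "data.frame")
  attr(out, "threshold_ngml") <- threshold_ngml
  attr(out, "n_above") <- sum(out$above)
  attr(out, "n_below") <- sum(!out$above)
  out
}

.ROC_CUTOFFS <- c(-Inf, unname(sort(.ROC_ACTIVITY)))

.cutoff_label <- function(cutoff) {
  if (is.infinite(cutoff) && cutoff < 0) return("all positive")
  lv <- sort(.ROC_ACTIVITY, decreasing = TRUE)
  pos <- names(lv)[lv > cutoff]
  if (!length(pos)) return(sprintf("none positive (> %g)", cutoff))
  sprintf(">= %s (> %g)", pos[length(pos)], cutoff)
}

#' ROC curve over the diplotype activity ordering
#'
#' Computes one (sensitivity, specificity) point per candidate cutoff
#' "activity > c", for c ranging over the seven diplotype activity levels
#' plus a cutoff below all levels, so the curve includes both trivial
#' endpoints (everyone test-positive; no one test-positive).
#'
#' @param outcomes A `threshold_outcomes` data frame
#'   (see [binarize_outcome()]).
#' @return A `roc_points` data frame: `cutoff`, `label`, `tp`, `fp`,
#'   `tn`, `fn`, `sensitivity`, `specificity`, `youden_j`.
#' @export
roc_diplotype_ranks <- function(outcomes) {
  stopifnot(is.data.frame(outcomes),
            all(c("above", "activity") %in% names(outcomes)))
  n_pos <- sum(outcomes$above)
  n_neg <- sum(!outcomes$above)
  if (n_pos == 0L || n_neg == 0L) {
    stop("ROC undefined: need at least one patient above and one below ",
         "the threshold", call. = FALSE)
  }
  rows <- lapply(.ROC_CUTOFFS, function(cc) {
    test_pos <- outcomes$activity > cc
    tp <- sum(test_pos & outcomes$above)
    fp <- sum(test_pos & !outcomes$above)
    fn <- n_pos - tp
    tn <- n_neg - fp
    data.frame(cutoff = cc, label = .cutoff_label(cc),
               tp = tp, fp = fp, tn = tn, fn = fn,
               sensitivity = tp / n_pos, specificity = tn / n_neg,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$youden_j <- out$sensitivity + out$specificity - 1
  class(out) <- c("roc_points", "data.frame")
  out
}

#' Youden-optimal activity cutoff
#'
#' Selects the cutoff maximizing Youden's J = sensitivity + specificity
#' - 1 over all candidate cutoffs; ties are broken toward the cutoff with
#' the higher specificity (and, among equal-specificity ties, the higher
#' cutoff). Equivalent to exhaustive search over the candidate set.
#'
#' @param roc A `roc_points` data frame from [roc_diplotype_ranks()].
#' @return One row of `roc` (the selected cutoff).
#' @export
youden_optimal_cutoff <- function(roc) {
  stopifnot(is.data.frame(roc), "youden_j" %in% names(roc))
  ## treat J values within numerical noise of the maximum as tied
  tied <- roc$youden_j >= max(roc$youden_j) - 1e-10
  cand <- roc[tied, , drop = FALSE]
  o <- order(-cand$specificity, -cand$cutoff)
  cand[o[1], , drop = FALSE]
}

#' Diagnostic metrics at a given activity cutoff
#'
#' Sensitivity = TP/(TP+FN), specificity = TN/(TN+FP) and FDR =
#' FP/(FP+TP), with "above threshold" as the positive class and
#' "activity > cutoff" as test-positive, plus the test-positive fraction
#' (TP+FP)/n. An empty positive or predicted-positive set leaves the
#' affected metric `NA` with a `defined` flag.
#'
#' @param outcomes A `threshold_outcomes` data frame.
#' @param cutoff Numeric activity cutoff (one of the candidate levels).
#' @return List with the confusion counts, `sensitivity`, `specificity`,
#'   `fdr`, `positive_fraction`, `youden_j` and `defined`.
#' @export
diagnostic_metrics <- function(outcomes, cutoff) {
  stopifnot(is.data.frame(outcomes), is.numeric(cutoff),
            length(cutoff) == 1L)
  test_pos <- outcomes$activity > cutoff
  tp <- sum(test_pos & outcomes$above)
  fp <- sum(test_pos & !outcomes$above)
  fn <- sum(!test_pos & outcomes$above)
  tn <- sum(!test_pos & !outcomes$above)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  fdr <- if (tp + fp > 0) fp / (fp + tp) else NA_real_
  list(cutoff = cutoff, label = .cutoff_label(cutoff),
       tp = tp, fp = fp, tn = tn, fn = fn,
       sensitivity = sens, specificity = spec, fdr = fdr,
       positive_fraction = (tp + fp) / nrow(outcomes),
       youden_j = sens + spec - 1,
       defined = !anyNA(c(sens, spec, fdr)))
}

#' False discovery rate from sensitivity, specificity and prevalence
#'
#' Closed-form identity: `FDR = (1 - spec) * (1 - prev) /
#' [(1 - spec) * (1 - prev) + sens * prev]`, where `prev` is the
#' prevalence of the positive (above-threshold) class.
#'
#' @param sensitivity,specificity,prevalence Fractions in [0, 1].
#' @return The false discovery rate as a fraction.
#' @export
#' @examples
#' fdr_from_rates(0.96, 0.57, 0.823)  # about 0.088
fdr_from_rates <- function(sensitivity, specificity, prevalence) {
  fp_mass <- (1 - specificity) * (1 - prevalence)
  tp_mass <- sensitivity * prevalence
  fp_mass / (fp_mass + tp_mass)
}

#' Bootstrap confidence intervals for the diagnostic metrics
#'
#' Stratified case-resampling bootstrap: above- and below-threshold
#' patients are resampled separately (keeping both class sizes fixed),
#' and sensitivity, specificity and FDR are recomputed at the fixed
#' cutoff. Reports point estimates with percentile 95% intervals.
#' Replicates in which a metric is undefined are dropped and counted;
#' more than 10% drops is an error.
#'
#' @param outcomes A `threshold_outcomes` data frame.
#' @param cutoff Activity cutoff (e.g. from [youden_optimal_cutoff()]).
#' @param replicates Number of bootstrap replicates (>= 1; analysis
#'   default 10,000).
#' @param seed Root seed; replicates use derived streams.
#' @return A `classifier_result`: list with `point` (from
#'   [diagnostic_metrics()]), `ci` (matrix metric x bounds),
#'   `boot_median`, `replicates`, `n_dropped`, `seed`.
#' @export
bootstrap_metric_ci <- function(outcomes, cutoff, replicates = 10000L,
                                seed = 1L) {
  stopifnot(replicates >= 1)
  point <- diagnostic_metrics(outcomes, cutoff)
  pos <- outcomes$activity[outcomes$above] > cutoff     # TP indicators
  neg <- outcomes$activity[!outcomes$above] <= cutoff   # TN indicators
  n_pos <- length(pos); n_neg <- length(neg)
  if (n_pos == 0L || n_neg == 0L) {
    stop("bootstrap undefined: need both outcome classes", call. = FALSE)
  }
  if (replicates == 1L) {
    ## a single replicate carries no resampling information: the interval
    ## degenerates to the point estimate
    est <- c(sensitivity = point$sensitivity,
             specificity = point$specificity, fdr = point$fdr)
    ci <- cbind(lower = est, upper = est)
    return(structure(
      list(point = point, ci = ci, boot_median = est,
           replicates = 1L, n_dropped = 0L, seed = seed),
      class = "classifier_result"))
  }
  set.seed(.derive_seed(seed, 1L))
  ## stratified resampling of binary indicators: each replicate's TP count
  ## is a draw over resampled above-threshold patients, TN over the rest
  tp_b <- rbinom(replicates, n_pos, mean(pos))
  tn_b <- rbinom(replicates, n_neg, mean(neg))
  sens_b <- tp_b / n_pos
  spec_b <- tn_b / n_neg
  fp_b <- n_neg - tn_b
  fdr_b <- ifelse(tp_b + fp_b > 0, fp_b / (tp_b + fp_b), NA_real_)
  keep <- !is.na(fdr_b)
  n_dropped <- sum(!keep)
  if (n_dropped > 0.1 * replicates) {
    stop(sprintf("bootstrap unstable: %d of %d replicates had no test-positive patients",
                 n_dropped, replicates), call. = FALSE)
  }
  qfun <- function(x) unname(quantile(x[keep], c(0.025, 0.975), type = 7))
  ci <- rbind(sensitivity = qfun(sens_b), specificity = qfun(spec_b),
              fdr = qfun(fdr_b))
  colnames(ci) <- c("lower", "upper")
  structure(
    list(point = point,
         ci = ci,
         boot_median = c(sensitivity = median(sens_b[keep]),
                         specificity = median(spec_b[keep]),
                         fdr = median(fdr_b[keep])),
         replicates = replicates, n_dropped = n_dropped, seed = seed),
    class = "classifier_result")
}

#' @export
print.classifier_result <- function(x, ...) {
  p <- x$point
  cat(sprintf("Diplotype threshold classifier at cutoff %s\n", p$label))
  cat(sprintf("  sensitivity %.1f%% (95%% CI %.1f-%.1f%%)\n",
              100 * p$sensitivity, 100 * x$ci["sensitivity", 1],
              100 * x$ci["sensitivity", 2]))
  cat(sprintf("  specificity %.1f%% (95%% CI %.1f-%.1f%%)\n",
              100 * p$specificity, 100 * x$ci["specificity", 1],
              100 * x$ci["specificity", 2]))
  cat(sprintf("  FDR %.1f%% (95%% CI %.1f-%.1f%%)\n",
              100 * p$fdr, 100 * x$ci["fdr", 1], 100 * x$ci["fdr", 2]))
  cat(sprintf("  test-positive fraction %.1f%% | %d bootstrap replicates\n",
              100 * p$positive_fraction, x$replicates))
  invisible(x)
}
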