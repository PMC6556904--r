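## Confusion-based metrics in both printed formulations, ROC/AUC, and
## specificity-level thresholding.

#' Confusion counts at a score threshold
#'
#' A sample is predicted positive iff its score is greater than or equal to
#' the threshold (ties count as positive).
#'
#' @param scores Numeric scores.
#' @param labels 0/1 labels aligned to `scores`.
#' @param threshold Decision threshold.
#' @return Object of class `confusion_counts`: list with `TP`, `TN`, `FP`,
#'   `FN` and the equivalent totals `N_pos` (= TP + FN), `N_neg` (= TN + FP),
#'   `N_pos_as_neg` (= FN), `N_neg_as_pos` (= FP).
#' @export
confusion <- function(scores, labels, threshold) {
  if (length(scores) == 0L) stop("empty input")
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  pred <- scores >= threshold
  counts <- list(TP = sum(pred & labels == 1L),
                 TN = sum(!pred & labels == 0L),
                 FP = sum(pred & labels == 0L),
                 FN = sum(!pred & labels == 1L))
  counts$N_pos <- counts$TP + counts$FN
  counts$N_neg <- counts$TN + counts$FP
  counts$N_pos_as_neg <- counts$FN
  counts$N_neg_as_pos <- counts$FP
  structure(counts, class = "confusion_counts")
}

# textbook formulation from TP/TN/FP/FN
.metrics_tp <- function(c) {
  mcc_den <- sqrt(prod(c(c$TP + c$FP, c$TP + c$FN, c$TN + c$FP, c$TN + c$FN)))
  list(Sn = if (c$TP + c$FN > 0) c$TP / (c$TP + c$FN) else NA_real_,
       Sp = if (c$TN + c$FP > 0) c$TN / (c$TN + c$FP) else NA_real_,
       Acc = (c$TP + c$TN) / (c$TP + c$TN + c$FP + c$FN),
       MCC = if (mcc_den > 0) (c$TP * c$TN - c$FP * c$FN) / mcc_den else NA_real_)
}

# intuitive formulation from N+, N-, N-+, N+-
.metrics_n <- function(c) {
  Np <- c$N_pos; Nn <- c$N_neg
  Npn <- c$N_pos_as_neg; Nnp <- c$N_neg_as_pos
  mcc_den_sq <- if (Np > 0 && Nn > 0) {
    (1 + (Nnp - Npn) / Np) * (1 + (Npn - Nnp) / Nn)
  } else NA_real_
  list(Sn = if (Np > 0) 1 - Npn / Np else NA_real_,
       Sp = if (Nn > 0) 1 - Nnp / Nn else NA_real_,
       Acc = 1 - (Npn + Nnp) / (Np + Nn),
       MCC = if (!is.na(mcc_den_sq) && mcc_den_sq > 0) {
         (1 - (Npn / Np + Nnp / Nn)) / sqrt(mcc_den_sq)
       } else NA_real_)
}

#' Performance metrics from confusion counts
#'
#' Computes sensitivity, specificity, accuracy and the Matthews correlation
#' coefficient in both of their standard printed formulations -- the textbook
#' TP/TN/FP/FN form and the equivalent form written in the class totals
#' N+, N-, and the misclassification counts N-+ (positives predicted
#' negative) and N+- (negatives predicted positive) -- and asserts their
#' numerical equality before returning. When a marginal is zero the MCC
#' denominator vanishes; the MCC is then reported as 0 with
#' `mcc_defined = FALSE`.
#'
#' @param counts `confusion_counts` from [confusion()].
#' @return Object of class `metrics_report`: list with `Sn`, `Sp`, `Acc`,
#'   `MCC`, `mcc_defined` and the input `counts`.
#' @export
metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  a <- .metrics_tp(counts)
  b <- .metrics_n(counts)
  for (nm in c("Sn", "Sp", "Acc", "MCC")) {
    if (!is.na(a[[nm]]) && !is.na(b[[nm]]) &&
        abs(a[[nm]] - b[[nm]]) > 1e-9) {
      stop("internal error: metric formulations disagree for ", nm, " (",
           a[[nm]], " vs ", b[[nm]], ")")
    }
  }
  mcc_defined <- !is.na(a$MCC)
  structure(list(Sn = a$Sn, Sp = a$Sp, Acc = a$Acc,
                 MCC = if (mcc_defined) a$MCC else 0,
                 mcc_defined = mcc_defined, counts = counts),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Sn=%.4f Sp=%.4f Acc=%.4f MCC=%.4f%s\n", x$Sn, x$Sp, x$Acc,
              x$MCC, if (x$mcc_defined) "" else " (undefined, reported as 0)"))
  invisible(x)
}

#' ROC curve and AUC
#'
#' Area under the receiver operating characteristic curve by trapezoidal
#' integration over all distinct score thresholds. Tied scores are collapsed
#' into single curve points, which makes the result identical to the
#' rank/Mann-Whitney formulation `U / (n_pos * n_neg)`.
#'
#' @param scores Numeric scores.
#' @param labels 0/1 labels (both classes required).
#' @return List with `auc` and `curve` (`data.frame` of `threshold`, `fpr`,
#'   `tpr`, starting at (0, 0)).
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels))
  P <- sum(labels == 1L)
  N <- sum(labels == 0L)
  if (P == 0L || N == 0L) stop("roc_auc requires both classes")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  n <- length(s)
  keep <- c(s[-n] != s[-1L], TRUE)  # last index of each tied block
  tpr <- c(0, cumsum(y)[keep] / P)
  fpr <- c(0, cumsum(1L - y)[keep] / N)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1L) + utils::tail(tpr, -1L)) / 2)
  list(auc = auc,
       curve = data.frame(threshold = c(Inf, s[keep]), fpr = fpr, tpr = tpr))
}

#' Score threshold achieving a target specificity
#'
#' Returns the smallest threshold `t` such that the fraction of negative
#' scores strictly below `t` is at least the target. For a target of 1.0
#' (100% specificity) the threshold is `max(neg_scores) + delta`, with
#' `delta` the smallest increment of the score grid, so that no defining
#' negative is ever predicted positive.
#'
#' @param neg_scores Scores of the defining negative set (non-empty).
#' @param target_specificity Target in (0, 1\].
#' @param delta Score-grid increment used at target 1.0 (default 1e-6).
#' @return Numeric threshold.
#' @export
threshold_at_specificity <- function(neg_scores, target_specificity,
                                     delta = 1e-6) {
  if (length(neg_scores) == 0L) stop("neg_scores must be non-empty")
  stopifnot(target_specificity > 0, target_specificity <= 1)
  if (target_specificity == 1) {
    return(max(neg_scores) + delta)
  }
  cand <- sort(unique(neg_scores))
  for (t in cand) {
    if (mean(neg_scores < t) >= target_specificity) return(t)
  }
  max(neg_scores) + delta
}

#' Evaluate scores against labels at a threshold
#'
#' Convenience wrapper combining [confusion()], [metrics()] and [roc_auc()].
#'
#' @param scores Numeric scores.
#' @param labels 0/1 labels.
#' @param threshold Decision threshold (default 0.5).
#' @return `metrics_report` with an additional `AUC` element.
#' @export
evaluate_scores <- function(scores, labels, threshold = 0.5) {
  rep <- metrics(confusion(scores, labels, threshold))
  rep$AUC <- roc_auc(scores, labels)$auc
  rep
}

#' Write a metrics report as TSV
#'
#' @param report `metrics_report` (optionally with `AUC`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(report, path) {
  tab <- data.frame(metric = c("Sn", "Sp", "Acc", "MCC",
                               if (!is.null(report$AUC)) "AUC"),
                    value = c(report$Sn, report$Sp, report$Acc, report$MCC,
                              if (!is.null(report$AUC)) report$AUC))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
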