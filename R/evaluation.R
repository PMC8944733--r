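#' Confusion matrix from predicted and true labels
#'
#' @param predicted,truth equal-length vectors (character or factor) over
#'   `"positive"` / `"negative"`.
#' @return Object of class `confusion_matrix`: list with integer `TP`, `TN`,
#'   `FP`, `FN`.
#' @export
confusion <- function(predicted, truth) {
  predicted <- as.character(predicted); truth <- as.character(truth)
  if (length(predicted) != length(truth))
    stop("predicted and truth must have the same length")
  ok <- c("positive", "negative")
  if (!all(predicted %in% ok) || !all(truth %in% ok))
    stop("labels must be 'positive' or 'negative'")
  structure(list(
    TP = sum(predicted == "positive" & truth == "positive"),
    TN = sum(predicted == "negative" & truth == "negative"),
    FP = sum(predicted == "positive" & truth == "negative"),
    FN = sum(predicted == "negative" & truth == "positive")),
    class = "confusion_matrix")
}

#' @rdname confusion
#' @param TP,TN,FP,FN non-negative counts, for building a confusion matrix
#'   directly.
#' @export
confusion_counts <- function(TP, TN, FP, FN) {
  counts <- c(TP = TP, TN = TN, FP = FP, FN = FN)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (sum(counts) < 1) stop("empty confusion matrix")
  structure(lapply(counts, as.integer), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$TP, x$FN, x$FP, x$TN), 2, 2,
              dimnames = list(truth = c("positive", "negative"),
                              predicted = c("positive", "negative")))
  print(m)
  invisible(x)
}

#' Classification statistics of a confusion matrix
#'
#' The eight retrospective-validation statistics: accuracy
#' `Ac = (TP+TN)/total`; Cohen's kappa `k = (Po - Pc)/(1 - Pc)` with
#' `Po = Ac` and chance agreement
#' `Pc = ((TP+FP)(TP+FN) + (FN+TN)(FP+TN)) / total^2`; sensitivity
#' `Sn = TP/(TP+FN)`; specificity `Sp = TN/(TN+FP)`; precision of positives
#' `P_pos = TP/(TP+FP)` and of negatives `P_neg = TN/(TN+FN)`; the Matthews
#' correlation coefficient
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`; and the
#' false accept rate `FAR% = 100 * FP/(FP+TN)`.
#'
#' Zero-denominator conventions: ratio statistics with an empty margin are
#' `NA`; an MCC with zero denominator is 0.
#'
#' @param cm a `confusion_matrix`.
#' @return Object of class `metrics_report`: named list with `Ac`, `Po`,
#'   `Pc`, `kappa`, `Sn`, `Sp`, `P_pos`, `P_neg`, `MCC`, `FAR_percent`,
#'   `n_correct`, `n_incorrect`, `total`.
#' @examples
#' classification_metrics(confusion_counts(TP = 581, TN = 649, FP = 2, FN = 70))
#' @export
classification_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  TP <- cm$TP; TN <- cm$TN; FP <- cm$FP; FN <- cm$FN
  total <- TP + TN + FP + FN
  if (total < 1) stop("empty confusion matrix")
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  ac <- (TP + TN) / total
  pc <- ((TP + FP) * (TP + FN) + (FN + TN) * (FP + TN)) / total^2
  kappa <- if (pc == 1) NA_real_ else (ac - pc) / (1 - pc)
  mcc_den <- sqrt(as.numeric(TP + FP) * (TP + FN) * (TN + FP) * (TN + FN))
  mcc <- if (mcc_den == 0) 0 else (as.numeric(TP) * TN - as.numeric(FP) * FN) / mcc_den
  far <- if (FP + TN == 0) NA_real_ else 100 * FP / (FP + TN)
  structure(list(Ac = ac, Po = ac, Pc = pc, kappa = kappa,
                 Sn = ratio(TP, TP + FN), Sp = ratio(TN, TN + FP),
                 P_pos = ratio(TP, TP + FP), P_neg = ratio(TN, TN + FN),
                 MCC = mcc, FAR_percent = far,
                 n_correct = TP + TN, n_incorrect = FP + FN, total = total),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  # display convention: 3 decimals for proportions, 2 for percentages
  cat(sprintf("Ac %.3f  kappa %.3f  Sn %.3f  Sp %.3f  Ppos %.3f  Pneg %.3f  MCC %.3f  FAR%% %.2f\n",
              x$Ac, x$kappa, x$Sn, x$Sp, x$P_pos, x$P_neg, x$MCC, x$FAR_percent))
  cat(sprintf("correct %d / %d\n", x$n_correct, x$total))
  invisible(x)
}

#' Friedman rank test across methods and blocks
#'
#' Ranks `k` methods within each of `n` blocks (average ranks on ties; rank
#' 1 = best) and computes the Friedman chi-square statistic
#' \deqn{\chi^2 = \frac{12}{n k (k+1)} \sum_j R_j^2 - 3 n (k+1)}
#' with `k - 1` degrees of freedom, where `R_j` is the rank sum of method
#' `j`.
#'
#' @param performance numeric matrix, methods in columns, blocks
#'   (dataset/metric combinations) in rows; no missing cells.
#' @param higher_is_better if `TRUE` (default) larger values rank better.
#' @return Object of class `friedman_result`: list with `avg_ranks`,
#'   `rank_sums`, `statistic`, `df`, `p_value`, `n_blocks`, `k_methods`.
#' @export
friedman_rank <- function(performance, higher_is_better = TRUE) {
  performance <- as.matrix(performance)
  if (anyNA(performance)) stop("missing cells in the performance table")
  n <- nrow(performance); k <- ncol(performance)
  if (k < 2 || n < 2) stop("need >= 2 methods and >= 2 blocks")
  ranks <- t(apply(performance, 1, function(row)
    rank(if (higher_is_better) -row else row)))
  rs <- colSums(ranks)
  stat <- 12 / (n * k * (k + 1)) * sum(rs^2) - 3 * n * (k + 1)
  mnames <- colnames(performance)
  if (is.null(mnames)) mnames <- paste0("method", seq_len(k))
  structure(list(avg_ranks = stats::setNames(rs / n, mnames),
                 rank_sums = stats::setNames(rs, mnames),
                 statistic = stat, df = k - 1,
                 p_value = stats::pchisq(stat, k - 1, lower.tail = FALSE),
                 n_blocks = n, k_methods = k),
            class = "friedman_result")
}

#' @export
print.friedman_result <- function(x, ...) {
  cat(sprintf("Friedman chi-square %.4f, df %d, p %.4g (%d blocks, %d methods)\n",
              x$statistic, x$df, x$p_value, x$n_blocks, x$k_methods))
  cat("average ranks:\n")
  print(round(x$avg_ranks, 3))
  invisible(x)
}
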