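#' Confusion-table metrics
#'
#' ACC, Precision, Recall, F1 and MCC from the 2x2 contingency table of
#' binary calls against true labels. Conventions for degenerate tables:
#' Precision/Recall are 0 when their denominator is 0, F1 is 0 when
#' precision + recall = 0, and MCC is 0 when any marginal is zero.
#'
#' @param true binary vector of true labels.
#' @param calls binary vector of predicted calls.
#' @return named list: `ACC`, `Precision`, `Recall`, `F1`, `MCC`.
#' @export
confusion_metrics <- function(true, calls) {
  if (length(true) != length(calls)) stop("length mismatch")
  true <- as.integer(true); calls <- as.integer(calls)
  tp <- as.numeric(sum(true == 1L & calls == 1L))
  fp <- as.numeric(sum(true == 0L & calls == 1L))
  tn <- as.numeric(sum(true == 0L & calls == 0L))
  fn <- as.numeric(sum(true == 1L & calls == 0L))
  n <- tp + fp + tn + fn
  acc <- (tp + tn) / n
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  denom2 <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom2 > 0) (tp * tn - fp * fn) / sqrt(denom2) else 0
  list(ACC = acc, Precision = prec, Recall = rec, F1 = f1, MCC = mcc)
}

#' Ranking metrics: AUROC and AUPRC
#'
#' AUROC is the tie-corrected Mann-Whitney statistic (mean ranks over
#' tied scores). AUPRC is the area under the precision-recall curve with
#' step interpolation: thresholds sweep the distinct scores from high to
#' low and each recall increment contributes at the precision reached
#' there.
#'
#' @param true binary vector.
#' @param probs numeric scores (higher = more likely positive).
#' @return named list `AUROC`, `AUPRC`; both `NA` (with a warning) when
#'   only one class is present.
#' @export
rank_metrics <- function(true, probs) {
  if (length(true) != length(probs)) stop("length mismatch")
  true <- as.integer(true)
  npos <- sum(true == 1L); nneg <- sum(true == 0L)
  if (npos == 0L || nneg == 0L) {
    warning("single-class input: AUROC/AUPRC undefined")
    return(list(AUROC = NA_real_, AUPRC = NA_real_))
  }
  r <- rank(probs, ties.method = "average")
  auroc <- (sum(r[true == 1L]) - npos * (npos + 1) / 2) / (npos * nneg)

  ord <- order(probs, decreasing = TRUE)
  ts <- true[ord]; ps <- probs[ord]
  # group tied scores: cumulative counts at each distinct threshold
  last_of_group <- c(ps[-1] != ps[-length(ps)], TRUE)
  cum_tp <- cumsum(ts)[last_of_group]
  cum_n <- seq_along(ts)[last_of_group]
  precision <- cum_tp / cum_n
  recall <- cum_tp / npos
  prev_recall <- c(0, recall[-length(recall)])
  auprc <- sum((recall - prev_recall) * precision)
  list(AUROC = auroc, AUPRC = auprc)
}

PATTERNS <- c("01", "10", "010", "101")

#' Structural-pattern accuracy
#'
#' Counts the (overlapping) windows of the TRUE label string equal to
#' `pattern`; a window is a hit iff the predicted calls reproduce the
#' pattern character-for-character at those positions. Accuracy is
#' hits / occurrences (`NA` when the pattern never occurs).
#'
#' @param true binary vector of true labels in sequence order.
#' @param calls binary vector of predicted calls.
#' @param pattern one of `"01"`, `"10"`, `"010"`, `"101"`.
#' @return object of class `pattern_stats`: list with `pattern`,
#'   `occurrences`, `hits`, `accuracy`.
#' @export
pattern_accuracy <- function(true, calls, pattern) {
  if (length(true) != length(calls)) stop("length mismatch")
  if (!pattern %in% PATTERNS) {
    stop(sprintf("invalid pattern '%s' (expected one of %s)",
                 pattern, paste(PATTERNS, collapse = ", ")))
  }
  pat <- as.integer(strsplit(pattern, "")[[1]])
  k <- length(pat)
  n <- length(true)
  occ <- 0L; hits <- 0L
  if (n >= k) {
    for (i in seq_len(n - k + 1L)) {
      w <- i:(i + k - 1L)
      if (all(true[w] == pat)) {
        occ <- occ + 1L
        if (all(calls[w] == pat)) hits <- hits + 1L
      }
    }
  }
  structure(list(pattern = pattern, occurrences = occ, hits = hits,
                 accuracy = if (occ > 0L) hits / occ else NA_real_),
            class = "pattern_stats")
}

#' @export
print.pattern_stats <- function(x, ...) {
  cat(sprintf("pattern '%s': %d/%d hit (accuracy %s)\n", x$pattern, x$hits,
              x$occurrences,
              if (is.na(x$accuracy)) "NA" else sprintf("%.3f", x$accuracy)))
  invisible(x)
}

#' Pool pattern statistics over a protein set
#'
#' Micro aggregation: occurrences and hits are summed across proteins
#' before dividing (no windows cross protein boundaries).
#'
#' @param stats_list list of `pattern_stats` for the same pattern.
#' @return a pooled `pattern_stats`.
#' @export
pool_pattern_stats <- function(stats_list) {
  pat <- unique(vapply(stats_list, `[[`, "", "pattern"))
  stopifnot(length(pat) == 1L)
  occ <- sum(vapply(stats_list, `[[`, 0L, "occurrences"))
  hits <- sum(vapply(stats_list, `[[`, 0L, "hits"))
  structure(list(pattern = pat, occurrences = occ, hits = hits,
                 accuracy = if (occ > 0L) hits / occ else NA_real_),
            class = "pattern_stats")
}

#' Full evaluation report for one pooled set of residues
#'
#' The seven standard metrics (ACC, Precision, Recall, F1, MCC, AUROC,
#' AUPRC) plus the four structural-pattern accuracies, computed on
#' pooled residues with per-protein pattern windows (pass a list of
#' per-protein vectors to keep windows from crossing chains).
#'
#' @param true binary vector, or list of per-protein binary vectors.
#' @param probs positive-class probabilities, matching `true`'s shape.
#' @param threshold call threshold (default 0.5).
#' @return named list with the seven metrics and a `patterns` sublist of
#'   `pattern_stats`.
#' @export
evaluate_predictions <- function(true, probs, threshold = 0.5) {
  if (!is.list(true)) { true <- list(true); probs <- list(probs) }
  stopifnot(length(true) == length(probs))
  calls <- lapply(probs, function(p) as.integer(p >= threshold))
  all_true <- unlist(true); all_probs <- unlist(probs); all_calls <- unlist(calls)
  out <- confusion_metrics(all_true, all_calls)
  out <- c(out, rank_metrics(all_true, all_probs))
  out$patterns <- lapply(stats::setNames(PATTERNS, PATTERNS), function(pt) {
    pool_pattern_stats(Map(function(tr, cl) pattern_accuracy(tr, cl, pt),
                           true, calls))
  })
  out$threshold <- threshold
  out$n_residues <- length(all_true)
  out
}
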