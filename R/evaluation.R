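#' Segmentation confusion metrics
#'
#' Thresholds the probability grid and computes the standard confusion-count
#' metrics over valid cells: IOU, Dice, sensitivity (reported as `se`, the
#' segmentation-suite usage of "SE"), precision (`pc`), F1, specificity
#' (`sp`) and accuracy (`acc`). With an empty positive class the
#' sensitivity-family metrics are `NA`.
#'
#' @param probs numeric matrix/array of probabilities (or a 1 x H x W array).
#' @param truth 0/1 matrix of the same spatial shape, or a `label_grid`.
#' @param threshold probability cutoff (default 0.5).
#' @param validity optional logical mask restricting evaluation; defaults to
#'   the truth's validity when it is a `label_grid`, else all cells.
#' @return named list: `tp fp tn fn iou dice se pc f1 sp acc`.
#' @export
confusion_metrics <- function(probs, truth, threshold = 0.5,
                              validity = NULL) {
  if (inherits(truth, "label_grid")) {
    if (is.null(validity)) validity <- truth$validity
    truth <- truth$values
  }
  probs <- drop(probs)
  truth <- drop(truth)
  if (!identical(dim(probs), dim(truth))) {
    stop("geometry error: prediction and truth shapes differ")
  }
  if (is.null(validity)) validity <- array(TRUE, dim = dim(truth))
  p <- probs[validity] >= threshold
  t <- truth[validity] == 1
  tp <- sum(p & t); fp <- sum(p & !t)
  fn <- sum(!p & t); tn <- sum(!p & !t)
  se <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  pc <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (!is.na(se) && !is.na(pc) && se + pc > 0) {
    2 * pc * se / (pc + se)
  } else NA_real_
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       iou = if (tp + fp + fn > 0) tp / (tp + fp + fn) else NA_real_,
       dice = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn)
              else NA_real_,
       se = se, pc = pc, f1 = f1,
       sp = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       acc = (tp + tn) / (tp + tn + fp + fn))
}

#' Area under the ROC curve
#'
#' Rank-based AUC (equivalent to the Mann-Whitney statistic); score ties
#' count one half.
#'
#' @param scores numeric predictions.
#' @param truth 0/1 labels (or logical), same length / shape.
#' @param validity optional logical mask.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, truth, validity = NULL) {
  if (inherits(truth, "label_grid")) {
    if (is.null(validity)) validity <- truth$validity
    truth <- truth$values
  }
  scores <- drop(scores); truth <- drop(truth)
  if (!is.null(validity)) {
    scores <- scores[validity]; truth <- truth[validity]
  }
  y <- as.numeric(truth) == 1
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0 || n0 == 0) {
    stop("undefined error: both classes must be present")
  }
  r <- rank(scores)
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve coordinates
#'
#' False/true positive rates at every distinct score threshold, ordered from
#' the (0, 0) to the (1, 1) corner — suitable for TSV export and plotting.
#' The trapezoidal area under these coordinates equals [roc_auc()].
#'
#' @param scores,truth,validity as in [roc_auc()].
#' @return data.frame with columns `threshold`, `fpr`, `tpr`.
#' @export
roc_curve <- function(scores, truth, validity = NULL) {
  if (inherits(truth, "label_grid")) {
    if (is.null(validity)) validity <- truth$validity
    truth <- truth$values
  }
  scores <- drop(scores); truth <- drop(truth)
  if (!is.null(validity)) {
    scores <- scores[validity]; truth <- truth[validity]
  }
  y <- as.numeric(truth) == 1
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0 || n0 == 0) {
    stop("undefined error: both classes must be present")
  }
  th <- c(Inf, sort(unique(scores), decreasing = TRUE))
  out <- data.frame(
    threshold = th,
    fpr = vapply(th, function(t) sum(scores[!y] >= t) / n0, numeric(1)),
    tpr = vapply(th, function(t) sum(scores[y] >= t) / n1, numeric(1))
  )
  out
}

#' Per-gene correlation between predicted and observed expression
#'
#' One correlation per gene across spots (rows = genes, columns = matched
#' spots). Genes with zero variance in either matrix are excluded with a
#' warning.
#'
#' @param pred,truth gene-by-spot matrices with identical dimnames layout.
#' @param kind `"pearson"` or `"spearman"`.
#' @return list with `per_gene_r` (named) and `mean_r`.
#' @export
per_gene_correlation <- function(pred, truth,
                                 kind = c("pearson", "spearman")) {
  kind <- match.arg(kind)
  if (!identical(dim(pred), dim(truth))) {
    stop("geometry error: matrices differ in shape")
  }
  if (ncol(pred) < 2L) stop("data error: need at least 2 spots")
  vp <- apply(pred, 1L, stats::var)
  vt <- apply(truth, 1L, stats::var)
  keep <- vp > 0 & vt > 0
  if (any(!keep)) {
    warning(sum(!keep), " zero-variance gene(s) excluded")
  }
  r <- vapply(which(keep), function(i) {
    stats::cor(pred[i, ], truth[i, ], method = kind)
  }, numeric(1))
  names(r) <- rownames(pred)[keep]
  list(per_gene_r = r, mean_r = mean(r))
}

#' t-based confidence interval of a mean across folds
#'
#' Mean of fold-level values with the Student-t 95% (by default) confidence
#' interval, as used to summarise cross-validation correlations.
#'
#' @param values numeric vector of per-fold values (length >= 2).
#' @param level confidence level (default 0.95).
#' @return list with `mean`, `lo`, `hi`.
#' @export
correlation_ci <- function(values, level = 0.95) {
  k <- length(values)
  if (k < 2L) stop("data error: need >= 2 fold values")
  m <- mean(values)
  half <- stats::qt(1 - (1 - level) / 2, df = k - 1) *
    stats::sd(values) / sqrt(k)
  list(mean = m, lo = m - half, hi = m + half)
}

#' Harrell's concordance index
#'
#' Comparable pairs are (i, j) with t_i < t_j and event_i = 1; a pair is
#' concordant when risk_i > risk_j, risk ties count one half.
#'
#' @param risks predicted risk scores (higher = worse prognosis).
#' @param time,event survival outcome.
#' @return C-index in \[0, 1\].
#' @export
concordance_index <- function(risks, time, event) {
  n <- length(risks)
  conc <- 0; comp <- 0
  for (i in seq_len(n)) {
    if (event[i] != 1) next
    later <- time > time[i]
    comp <- comp + sum(later)
    conc <- conc + sum(risks[i] > risks[later]) +
      0.5 * sum(risks[i] == risks[later])
  }
  if (comp == 0) stop("undefined error: no comparable pairs")
  conc / comp
}

#' Median-risk group split
#'
#' Splits samples into high/low risk groups at the median predicted risk;
#' samples exactly at the median go to the low-risk group, so the split is
#' ceiling(n/2) low vs floor(n/2) high for distinct risks.
#'
#' @param risks numeric risk scores.
#' @return factor with levels `low`, `high`.
#' @export
median_split <- function(risks) {
  med <- stats::median(risks)
  factor(ifelse(risks <= med, "low", "high"), levels = c("low", "high"))
}

#' Two-group log-rank test
#'
#' Standard chi-square log-rank statistic (1 df) comparing survival between
#' two groups, plus the Kaplan-Meier step functions for plotting.
#'
#' @param time,event survival outcome.
#' @param group two-level factor (e.g. from [median_split()]).
#' @return list with `statistic`, `p_value`, and `km` (a data.frame of
#'   per-group step-function coordinates: group, time, survival).
#' @export
km_logrank <- function(time, event, group) {
  group <- as.factor(group)
  if (nlevels(group) != 2L || any(table(group) == 0L)) {
    stop("protocol error: need two nonempty groups")
  }
  g1 <- group == levels(group)[1]
  times <- sort(unique(time[event == 1]))
  o1 <- 0; e1 <- 0; v <- 0
  for (tt in times) {
    at1 <- sum(time >= tt & g1)
    at2 <- sum(time >= tt & !g1)
    d1 <- sum(time == tt & event == 1 & g1)
    d2 <- sum(time == tt & event == 1 & !g1)
    d <- d1 + d2; atr <- at1 + at2
    if (atr == 0) next
    o1 <- o1 + d1
    e1 <- e1 + d * at1 / atr
    if (atr > 1) {
      v <- v + d * (at1 / atr) * (at2 / atr) * (atr - d) / (atr - 1)
    }
  }
  stat <- if (v > 0) (o1 - e1)^2 / v else 0
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  km <- do.call(rbind, lapply(levels(group), function(lv) {
    sel <- group == lv
    tt <- sort(unique(time[sel & event == 1]))
    s <- 1
    rows <- data.frame(group = lv, time = 0, survival = 1)
    for (t0 in tt) {
      at <- sum(time[sel] >= t0)
      d <- sum(time[sel] == t0 & event[sel] == 1)
      s <- s * (1 - d / at)
      rows <- rbind(rows, data.frame(group = lv, time = t0, survival = s))
    }
    rows
  }))
  list(statistic = stat, p_value = p, km = km)
}

#' Binary classification metrics
#'
#' Accuracy, precision, recall and F1 for binary labels; the positive class
#' defaults to the second factor level (e.g. `"responder"`). `average =
#' "macro"` averages precision/recall/F1 over both classes treated as
#' positive in turn.
#'
#' @param pred_labels,truth label vectors (factor/character/0-1).
#' @param positive positive class label; default the second sorted level.
#' @param average `"binary"` (default) or `"macro"`.
#' @return named list: `accuracy`, `precision`, `recall`, `f1`.
#' @export
classification_metrics <- function(pred_labels, truth, positive = NULL,
                                   average = c("binary", "macro")) {
  average <- match.arg(average)
  pred_labels <- as.character(pred_labels)
  truth <- as.character(truth)
  classes <- sort(unique(c(pred_labels, truth)))
  if (is.null(positive)) positive <- classes[length(classes)]
  one <- function(pos) {
    tp <- sum(pred_labels == pos & truth == pos)
    fp <- sum(pred_labels == pos & truth != pos)
    fn <- sum(pred_labels != pos & truth == pos)
    pc <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    rc <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    f1 <- if (!is.na(pc) && !is.na(rc) && pc + rc > 0) {
      2 * pc * rc / (pc + rc)
    } else NA_real_
    c(pc, rc, f1)
  }
  acc <- mean(pred_labels == truth)
  if (average == "binary") {
    m <- one(positive)
  } else {
    m <- rowMeans(vapply(classes, one, numeric(3)), na.rm = TRUE)
  }
  list(accuracy = acc, precision = m[1], recall = m[2], f1 = m[3])
}
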