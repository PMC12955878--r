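test_that("confusion metrics match counts and the Dice/IOU identity", {
  truth <- matrix(c(1, 1, 0, 0, 1, 0), 2, 3)
  perfect <- truth * 0.9 + 0.05
  m <- confusion_metrics(perfect, truth)
  for (nm in c("iou", "dice", "se", "pc", "f1", "sp", "acc")) {
    expect_equal(m[[nm]], 1)
  }

  for (seed in 1:20) {
    set.seed(seed)
    probs <- matrix(runif(60), 6, 10)
    truth <- matrix(rbinom(60, 1, 0.4), 6, 10)
    valid <- matrix(runif(60) < 0.8, 6, 10)
    m <- confusion_metrics(probs, truth, validity = valid)
    # brute-force cell loop
    tp <- fp <- tn <- fn <- 0
    for (i in 1:6) for (j in 1:10) {
      if (!valid[i, j]) next
      p <- probs[i, j] >= 0.5
      t <- truth[i, j] == 1
      if (p && t) tp <- tp + 1 else if (p) fp <- fp + 1
      else if (t) fn <- fn + 1 else tn <- tn + 1
    }
    expect_equal(m$tp, tp); expect_equal(m$fp, fp)
    expect_equal(m$tn, tn); expect_equal(m$fn, fn)
    expect_equal(m$iou, tp / (tp + fp + fn))
    if (!is.na(m$dice)) {
      expect_equal(m$dice, 2 * m$iou / (1 + m$iou), tolerance = 1e-12)
    }
  }

  none <- confusion_metrics(matrix(0.2, 2, 2), matrix(0, 2, 2))
  expect_true(is.na(none$se))
})

test_that("AUC equals the Mann-Whitney pairwise oracle and its invariances", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(rep(0.5, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  expect_error(roc_auc(runif(4), rep(1, 4)), "both classes")

  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(10:50, 1)
    scores <- round(runif(n), 2)   # force some ties
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    pos <- scores[y == 1]; neg <- scores[y == 0]
    oracle <- mean(outer(pos, neg, function(a, b)
      (a > b) + 0.5 * (a == b)))
    a <- roc_auc(scores, y)
    expect_equal(a, oracle, tolerance = 1e-12)
    # invariant under strictly monotone transforms
    expect_equal(roc_auc(exp(3 * scores), y), a, tolerance = 1e-12)
    # invariant under permutation
    p <- sample(n)
    expect_equal(roc_auc(scores[p], y[p]), a, tolerance = 1e-12)
  }
})

test_that("ROC curve coordinates integrate to the rank AUC", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 40
    scores <- round(runif(n), 2)
    y <- rbinom(n, 1, 0.5); y[1:2] <- c(0, 1)
    rc <- roc_curve(scores, y)
    expect_equal(rc$fpr[1], 0); expect_equal(rc$tpr[1], 0)
    expect_equal(rc$fpr[nrow(rc)], 1); expect_equal(rc$tpr[nrow(rc)], 1)
    trap <- sum(diff(rc$fpr) * (head(rc$tpr, -1) + tail(rc$tpr, -1)) / 2)
    expect_equal(trap, roc_auc(scores, y), tolerance = 1e-12)
  }
})

test_that("per-gene correlations match the textbook formula", {
  set.seed(1)
  truth <- matrix(rnorm(40), 4, 10,
                  dimnames = list(paste0("g", 1:4), NULL))
  expect_equal(unname(per_gene_correlation(truth, truth)$per_gene_r),
               rep(1, 4))
  expect_equal(unname(per_gene_correlation(-truth, truth)$per_gene_r),
               rep(-1, 4))

  pred <- truth + matrix(rnorm(40), 4, 10)
  r <- per_gene_correlation(pred, truth)$per_gene_r
  for (i in 1:4) {
    x <- pred[i, ]; y <- truth[i, ]
    oracle <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(unname(r[i]), oracle, tolerance = 1e-12)
  }
  sp <- per_gene_correlation(pred, truth, kind = "spearman")$per_gene_r
  expect_equal(unname(sp[1]), cor(pred[1, ], truth[1, ], method = "spearman"))

  flat <- pred; flat[2, ] <- 3
  expect_warning(pg <- per_gene_correlation(flat, truth), "zero-variance")
  expect_false("g2" %in% names(pg$per_gene_r))
  expect_error(per_gene_correlation(pred[, 1, drop = FALSE],
                                    truth[, 1, drop = FALSE]), "2 spots")
})

test_that("t-based CI brackets the mean and shrinks like 1/sqrt(n)", {
  ci <- correlation_ci(c(0.7, 0.8, 0.75))
  expect_lt(ci$lo, ci$mean); expect_gt(ci$hi, ci$mean)
  expect_equal(ci$mean, 0.75)
  # against qt-based manual value
  half <- qt(0.975, 2) * sd(c(0.7, 0.8, 0.75)) / sqrt(3)
  expect_equal(ci$hi - ci$mean, half)

  set.seed(2)
  widths <- vapply(c(10, 40, 160), function(n) {
    w <- replicate(200, {
      ci <- correlation_ci(rnorm(n, 0.5, 0.1))
      ci$hi - ci$lo
    })
    mean(w)
  }, numeric(1))
  expect_equal(widths[1] / widths[2], 2, tolerance = 0.15)
  expect_equal(widths[2] / widths[3], 2, tolerance = 0.15)
})

test_that("the concordance index matches the exhaustive pair loop", {
  t5 <- c(1, 2, 3, 4, 5)
  expect_equal(concordance_index(5:1, t5, rep(1, 5)), 1)
  expect_equal(concordance_index(1:5, t5, rep(1, 5)), 0)
  expect_error(concordance_index(1, 1, 0), "no comparable")

  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(10:40, 1)
    risks <- round(rnorm(n), 1)
    time <- round(rexp(n), 2)
    event <- rbinom(n, 1, 0.7)
    if (sum(event) == 0) event[1] <- 1
    conc <- comp <- 0
    for (i in 1:n) for (j in 1:n) {
      if (i == j || event[i] != 1 || !(time[i] < time[j])) next
      comp <- comp + 1
      if (risks[i] > risks[j]) conc <- conc + 1
      else if (risks[i] == risks[j]) conc <- conc + 0.5
    }
    if (comp == 0) next
    expect_equal(concordance_index(risks, time, event), conc / comp)
  }
})

test_that("the log-rank test matches survival::survdiff", {
  skip_if_not_installed("survival")
  ident <- km_logrank(c(1, 2, 3, 1, 2, 3), c(1, 1, 0, 1, 1, 0),
                      factor(rep(c("low", "high"), each = 3),
                             levels = c("low", "high")))
  expect_equal(ident$statistic, 0, tolerance = 1e-12)

  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(20:60, 1)
    time <- round(rexp(n), 3)
    event <- rbinom(n, 1, 0.7)
    group <- factor(sample(c("low", "high"), n, replace = TRUE),
                    levels = c("low", "high"))
    if (length(unique(group)) < 2 || sum(event) < 2) next
    ours <- km_logrank(time, event, group)
    ref <- survival::survdiff(survival::Surv(time, event) ~ group)
    expect_equal(ours$statistic, unname(ref$chisq), tolerance = 1e-8)
    expect_equal(ours$p_value,
                 pchisq(ref$chisq, 1, lower.tail = FALSE), tolerance = 1e-8)
  }
})

test_that("KM curves step at event times with product-limit survival", {
  time <- c(1, 2, 2, 4)
  event <- c(1, 1, 0, 1)
  group <- factor(rep("low", 4), levels = c("low", "high"))
  expect_error(km_logrank(time, event, group), "two nonempty groups")
  group2 <- factor(c("low", "low", "high", "high"),
                   levels = c("low", "high"))
  km <- km_logrank(time, event, group2)$km
  low <- km[km$group == "low", ]
  expect_equal(low$survival, c(1, 0.5, 0))
})

test_that("median-split assigns ties to the low-risk group", {
  g <- median_split(c(1, 2, 3, 4, 5))
  expect_equal(as.character(g[3]), "low")
  expect_equal(sum(g == "low"), 3L)
  expect_equal(sum(g == "high"), 2L)
  g2 <- median_split(1:4)
  expect_equal(sum(g2 == "low"), 2L)
})

test_that("classification metrics match confusion-count oracles", {
  pred <- c("r", "r", "n", "n")
  truth <- c("r", "r", "n", "n")
  m <- classification_metrics(pred, truth, positive = "r")
  expect_equal(unlist(m), c(accuracy = 1, precision = 1, recall = 1, f1 = 1))

  all_r <- classification_metrics(rep("r", 4), c("r", "r", "n", "n"),
                                  positive = "r")
  expect_equal(all_r$recall, 1)
  all_n <- classification_metrics(rep("n", 4), c("r", "r", "n", "n"),
                                  positive = "r")
  expect_equal(all_n$recall, 0)

  for (seed in 1:10) {
    set.seed(seed)
    pred <- sample(c("r", "n"), 30, replace = TRUE)
    truth <- sample(c("r", "n"), 30, replace = TRUE)
    m <- classification_metrics(pred, truth, positive = "r")
    tp <- sum(pred == "r" & truth == "r")
    fp <- sum(pred == "r" & truth == "n")
    fn <- sum(pred == "n" & truth == "r")
    expect_equal(m$accuracy, mean(pred == truth))
    if (tp + fp > 0) expect_equal(m$precision, tp / (tp + fp))
    if (tp + fn > 0) expect_equal(m$recall, tp / (tp + fn))
  }
})

test_that("metrics are invariant under simultaneous permutation", {
  set.seed(3)
  n <- 40
  probs <- runif(n); truth <- rbinom(n, 1, 0.5)
  truth[1:2] <- c(0, 1)
  p <- sample(n)
  m1 <- confusion_metrics(matrix(probs, 4), matrix(truth, 4))
  m2 <- confusion_metrics(matrix(probs[p], 4), matrix(truth[p], 4))
  expect_equal(m1, m2)
  risks <- rnorm(n); time <- rexp(n); event <- rbinom(n, 1, 0.8)
  event[1] <- 1
  expect_equal(concordance_index(risks[p], time[p], event[p]),
               concordance_index(risks, time, event))
})
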