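test_that("the ConvNeXt-V2 block is residual and shape-preserving", {
  x <- rand_array(c(3, 8, 8), seed = 1)
  y <- convnextv2_block(x, seed = 2)
  expect_equal(dim(y), c(3L, 8L, 8L, 1L))
  ident <- convnextv2_block(x, seed = 2, zero_branch = TRUE)
  expect_equal(ident[, , , 1], x, tolerance = 1e-12)
})

test_that("global response normalization matches a hand-computed instance", {
  # 2 channels x 2 x 1 spatial, 1 sample, gamma = 1, beta = 0
  x <- array(c(3, 4, 0, 0, 0, 0, 1, 2), c(2, 2, 2, 1))
  # channel norms: g1 = sqrt(3^2 + 0 + 0 + 1) = sqrt(10);
  #                g2 = sqrt(16 + 0 + 0 + 4) = sqrt(20)
  g1 <- sqrt(10); g2 <- sqrt(20)
  m <- (g1 + g2) / 2
  out <- grn_normalize(x, gamma = 1, beta = 0)
  expect_equal(out[1, 1, 1, 1], 3 * g1 / m + 3, tolerance = 1e-6)
  expect_equal(out[2, 1, 1, 1], 4 * g2 / m + 4, tolerance = 1e-6)
  expect_equal(out[1, 1, 2, 1], 0)
  expect_equal(out[2, 2, 2, 1], 2 * g2 / m + 2, tolerance = 1e-6)
})

test_that("backbone embeddings are deterministic with documented geometry", {
  spec <- appnet_spec(3, stage_depths = c(1, 1, 1, 1),
                      stage_widths = c(4, 6, 8, 10), embed_dim = 5)
  net <- build_appnet(spec, seed = 3)
  x <- rand_array(c(3, 80, 64), seed = 4)
  f1 <- appnet_backbone(net, x)
  f2 <- appnet_backbone(net, x)
  expect_identical(f1, f2)
  expect_equal(nrow(f1), 5L)
  # stem stride 4 then three floor-halvings: 80x64 -> 20x16 -> 10x8 -> 5x4 -> 2x2
  env <- new.env()
  invisible(histex:::appnet_backbone_fw_tr(net, histex:::as_nchw(x), env))
  expect_equal(env$gap_dim[2:3], c(2L, 2L))
  expect_error(appnet_spec(3, stage_widths = c(8, 8, 16, 32)), "increasing")
})

test_that("Cox loss reproduces the hand-computed cases", {
  expect_equal(cox_loss(0.3, time = 1, event = 1)$loss, 0)
  expect_equal(cox_loss(c(2, 2), c(1, 2), c(1, 1), mode = "as_printed",
                        normalize = FALSE)$loss, log(2))
  expect_equal(cox_loss(c(1, 1), c(1, 2), c(1, 1), mode = "risk_set",
                        normalize = FALSE)$loss, log(2) / 2)
  expect_error(cox_loss(c(1, 2), c(1, 2), c(0, 0)), "num_uncensored")
  # unit mode scales the vector to unit Euclidean norm; the default RMS mode
  # scales it to norm sqrt(n), keeping each score O(1)
  out <- cox_loss(c(3, 4), c(1, 2), c(1, 0), normalize = "unit")
  expect_equal(sum(out$normalized_risks^2), 1)
  rms <- cox_loss(c(3, 4), c(1, 2), c(1, 0), normalize = "rms")
  expect_equal(sum(rms$normalized_risks^2), 2)
})

test_that("risk-set Cox loss matches the reference partial likelihood", {
  skip_if_not_installed("survival")
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(10:50, 1)
    risks <- rnorm(n)
    time <- rexp(n)             # continuous: no ties
    event <- rbinom(n, 1, 0.7)
    if (sum(event) == 0) event[1] <- 1
    ours <- cox_loss(risks, time, event, mode = "risk_set",
                     normalize = FALSE)
    ref <- survival::coxph(survival::Surv(time, event) ~ offset(risks),
                           method = "breslow")
    expect_equal(ours$loss, -ref$loglik[1] / sum(event), tolerance = 1e-6)
  }
  # Breslow ties: tied event times share the full risk-set denominator
  tied <- cox_loss(c(1, 0.5, -1), time = c(2, 2, 3), event = c(1, 1, 0),
                   mode = "risk_set", normalize = FALSE)
  denom <- exp(1) + exp(0.5) + exp(-1)
  expect_equal(tied$loss, -((1 - log(denom)) + (0.5 - log(denom))) / 2)
})

test_that("Cox loss gradients agree with finite differences", {
  set.seed(9)
  n <- 12
  risks <- rnorm(n); time <- rexp(n); event <- rbinom(n, 1, 0.6)
  event[1] <- 1
  for (mode in c("risk_set", "as_printed")) {
    lo <- cox_loss(risks, time, event, mode = mode)
    h <- 1e-6
    num <- vapply(seq_len(n), function(i) {
      rp <- risks; rp[i] <- rp[i] + h
      lp <- cox_loss(rp, time, event, mode = mode)$loss
      rp[i] <- rp[i] - 2 * h
      lm <- cox_loss(rp, time, event, mode = mode)$loss
      (lp - lm) / (2 * h)
    }, numeric(1))
    expect_equal(lo$grad, num, tolerance = 1e-5)
  }
})

test_that("stratified folds preserve censoring proportions", {
  event <- rep(c(0, 1), c(40, 60))
  fold <- stratified_kfold(event, k = 5, seed = 2)
  expect_equal(sort(unique(fold)), 1:5)
  for (f in 1:5) {
    expect_equal(sum(fold == f & event == 0), 8L)
    expect_equal(sum(fold == f & event == 1), 12L)
  }
  expect_identical(fold, stratified_kfold(event, k = 5, seed = 2))
  expect_false(identical(fold, stratified_kfold(event, k = 5, seed = 3)))
  expect_error(stratified_kfold(c(0, 1), k = 5), "protocol error")
  expect_warning(stratified_kfold(rep(c(0, 1), c(2, 18)), k = 5, seed = 1),
                 "fewer than k")
})

test_that("pseudo-bulk averages valid cells only", {
  v <- array(7, c(2, 4, 4))
  dimnames(v) <- list(c("a", "b"), NULL, NULL)
  validity <- matrix(TRUE, 4, 4)
  expect_equal(unname(pseudo_bulk(v, validity)), c(7, 7))
  one <- matrix(FALSE, 4, 4); one[2, 3] <- TRUE
  v[, 2, 3] <- c(1, 2)
  expect_equal(unname(pseudo_bulk(v, one)), c(1, 2))
  expect_error(pseudo_bulk(v, matrix(FALSE, 4, 4)), "no valid cells")

  for (seed in 1:10) {
    set.seed(seed)
    v <- array(rnorm(3 * 5 * 5), c(3, 5, 5))
    val <- matrix(runif(25) < 0.6, 5, 5)
    if (!any(val)) val[1, 1] <- TRUE
    pb <- pseudo_bulk(v, val)
    oracle <- sapply(1:3, function(g) {
      s <- 0; k <- 0
      for (i in 1:5) for (j in 1:5) if (val[i, j]) {
        s <- s + v[g, i, j]; k <- k + 1
      }
      s / k
    })
    expect_equal(unname(pb), oracle)
  }
})

test_that("covariate encoding is dictionary-stable with an unknown slot", {
  train <- data.frame(stage = c("I", "II", "II"), sex = c("f", "m", "f"))
  enc <- encode_covariates(train)
  expect_equal(nrow(enc$matrix), 3L + 3L)  # 2 + unknown per covariate
  expect_equal(colSums(enc$matrix), rep(2, 3))
  test <- data.frame(stage = c("III"), sex = c("f"))
  enc2 <- encode_covariates(test, levels = enc$levels)
  expect_equal(unname(enc2$matrix["stage=(unknown)", 1]), 1)
  expect_equal(unname(enc2$matrix["sex=f", 1]), 1)
})

test_that("risk predictions are equivariant under sample permutation", {
  spec <- appnet_spec(2, stage_depths = c(1, 1, 1, 1),
                      stage_widths = c(3, 4, 5, 6), embed_dim = 4,
                      head = "cox", head_hidden = 3)
  net <- build_appnet(spec, seed = 5)
  grids <- lapply(1:6, function(i) rand_array(c(2, 32, 32), seed = 50 + i))
  r <- predict_risk(net, grids)
  p <- c(4, 1, 6, 2, 3, 5)
  expect_equal(predict_risk(net, grids[p]), r[p], tolerance = 1e-12)

  # zero weights, zero input -> zero risk
  zero_net <- build_appnet(spec, seed = 5)
  for (l in histex:::appnet_layers(zero_net)) {
    l$params <- lapply(l$params, function(x) x * 0)
  }
  zr <- predict_risk(zero_net, list(array(0, c(2, 32, 32))))
  expect_equal(zr, 0)
})

test_that("classifier probabilities are proper and label-flip symmetric", {
  spec <- appnet_spec(2, stage_depths = c(1, 1, 1, 1),
                      stage_widths = c(3, 4, 5, 6), embed_dim = 4,
                      head = "classifier", n_classes = 2)
  net <- build_appnet(spec, seed = 7)
  net$classes <- c("a", "b")
  grids <- lapply(1:4, function(i) rand_array(c(2, 32, 32), seed = 70 + i))
  p <- predict_icb(net, grids)
  expect_equal(dim(p), c(4L, 2L))
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(rowSums(p), rep(1, 4))
  expect_error(fit_icb_net(grids, rep("a", 4), spec = spec, epochs = 1),
               "single class")
})

test_that("a separable ICB cohort is classified above 0.9 held-out accuracy", {
  coh <- make_icb_cohort(n = 80, class_balance = 0.5, separation = 4,
                         seed = 9, n_genes = 4, shape = c(32, 32))
  folds <- stratified_kfold(as.integer(coh$labels), k = 5, seed = 2)
  spec <- appnet_spec(4, stage_depths = c(1, 1, 1, 1),
                      stage_widths = c(6, 12, 18, 24), embed_dim = 12,
                      expansion = 2, head = "classifier")
  preds <- character(80)
  for (f in 1:5) {
    tr <- which(folds != f); te <- which(folds == f)
    net <- fit_icb_net(coh$grids[tr], coh$labels[tr], spec = spec,
                       epochs = 25, lr0 = 5e-3, batch_size = 20, seed = f)
    p <- predict_icb(net, coh$grids[te])
    preds[te] <- colnames(p)[max.col(p)]
  }
  m <- classification_metrics(preds, as.character(coh$labels),
                              positive = "responder")
  expect_gt(m$accuracy, 0.9)
  expect_gt(m$f1, 0.9)
})

test_that("flipping training labels flips confident predictions", {
  coh <- make_icb_cohort(n = 24, class_balance = 0.5, separation = 6,
                         seed = 14, n_genes = 2, shape = c(32, 32),
                         bandwidth = 0, field_sd = 0.3)
  spec <- appnet_spec(2, stage_depths = c(1, 1, 1, 1),
                      stage_widths = c(3, 4, 5, 6), embed_dim = 4,
                      expansion = 2, head = "classifier")
  net1 <- fit_icb_net(coh$grids, coh$labels, spec = spec, epochs = 30,
                      lr0 = 1e-2, batch_size = 12, seed = 3)
  flipped <- factor(ifelse(coh$labels == "responder", "non_responder",
                           "responder"),
                    levels = c("non_responder", "responder"))
  net2 <- fit_icb_net(coh$grids, flipped, spec = spec, epochs = 30,
                      lr0 = 1e-2, batch_size = 12, seed = 3)
  p1 <- predict_icb(net1, coh$grids)
  p2 <- predict_icb(net2, coh$grids)
  l1 <- colnames(p1)[max.col(p1)]
  l2 <- colnames(p2)[max.col(p2)]
  expect_gt(mean(l1 != l2), 0.9)
})

test_that("a covariate-driven Cox cohort is recovered by the survival head", {
  # survival governed purely by an ordinal clinical stage with known hazard
  # ratios; the slide grids are identical across patients, so the head can
  # only learn through the one-hot covariate pathway
  set.seed(31)
  n <- 90
  stage <- sample(paste0("s", 1:5), n, replace = TRUE)
  lp <- (as.integer(substring(stage, 2)) - 3) * 2
  time <- rexp(n, exp(lp))
  event <- rep(1L, n)
  covariate <- data.frame(stage = stage)
  base <- array(rnorm(2 * 32 * 32, sd = 0.3), c(2, 32, 32))
  grids <- lapply(1:n, function(i) base)
  folds <- stratified_kfold(event, k = 3, seed = 1)
  spec <- appnet_spec(2, stage_depths = c(1, 1, 1, 1),
                      stage_widths = c(3, 4, 5, 6), embed_dim = 4,
                      head = "cox", head_hidden = 4)
  cs <- vapply(1:3, function(f) {
    tr <- which(folds != f); te <- which(folds == f)
    net <- fit_survival_net(grids[tr], time[tr], event[tr],
                            covariates = covariate[tr, , drop = FALSE],
                            spec = spec, epochs = 150, lr0 = 1e-2, seed = f)
    rk <- predict_risk(net, grids[te], covariate[te, , drop = FALSE])
    concordance_index(rk, time[te], event[te])
  }, numeric(1))
  expect_gt(mean(cs), 0.8)
})
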