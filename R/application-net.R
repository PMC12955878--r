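#' Application network specification
#'
#' Configures the ConvNeXt-V2-style backbone that consumes predicted spatial
#' expression grids: a 4 x 4 stride-4 stem convolution with layer
#' normalization, four stages of residual blocks (depthwise 7 x 7 ->
#' layer norm -> pointwise expansion -> GELU -> global response
#' normalization -> pointwise projection, plus drop-path identity) separated
#' by layer-normalized 2 x 2 stride-2 downsampling convolutions, then global
#' average pooling, layer normalization and a linear embedding. Downsampling
#' floors odd spatial sizes (80 x 64 input -> 20 x 16 stem -> 10 x 8 ->
#' 5 x 4 -> 2 x 2 before pooling).
#'
#' @param in_channels input gene channels.
#' @param stage_depths blocks per stage (default 1, 1, 2, 1).
#' @param stage_widths channel widths per stage, increasing
#'   (default 40, 80, 160, 320).
#' @param embed_dim output embedding length (default 64).
#' @param expansion pointwise expansion ratio inside blocks (default 4).
#' @param drop_path drop-path rate (default 0).
#' @param head `"cox"` or `"classifier"`.
#' @param head_hidden hidden width of the two survival head layers
#'   (default 32).
#' @param n_classes classifier classes (default 2).
#' @return an `appnet_spec` list.
#' @export
appnet_spec <- function(in_channels,
                        stage_depths = c(1L, 1L, 2L, 1L),
                        stage_widths = c(40L, 80L, 160L, 320L),
                        embed_dim = 64L, expansion = 4L, drop_path = 0,
                        head = c("cox", "classifier"),
                        head_hidden = 32L, n_classes = 2L) {
  head <- match.arg(head)
  if (length(stage_depths) != 4L || length(stage_widths) != 4L) {
    stop("config error: exactly four stages are required")
  }
  if (any(diff(stage_widths) <= 0)) {
    stop("config error: stage widths must be increasing")
  }
  structure(list(in_channels = as.integer(in_channels),
                 stage_depths = as.integer(stage_depths),
                 stage_widths = as.integer(stage_widths),
                 embed_dim = as.integer(embed_dim),
                 expansion = as.integer(expansion),
                 drop_path = drop_path, head = head,
                 head_hidden = as.integer(head_hidden),
                 n_classes = as.integer(n_classes)),
            class = "appnet_spec")
}

new_convnext_block <- function(channels, expansion = 4L, drop_path = 0) {
  list(dw = layer_depthwise(channels, k = 7L, pad = 3L),
       ln = layer_ln(channels),
       pw1 = layer_conv2d(channels, channels * expansion, k = 1L, pad = 0L),
       act = layer_gelu(),
       grn = layer_grn(channels * expansion),
       pw2 = layer_conv2d(channels * expansion, channels, k = 1L, pad = 0L),
       dp = layer_droppath(drop_path))
}

cnb_fw <- function(blk, x, train = FALSE) {
  y <- blk$dw$fw(x, train)
  y <- blk$ln$fw(y, train)
  y <- blk$pw1$fw(y, train)
  y <- blk$act$fw(y, train)
  y <- blk$grn$fw(y, train)
  y <- blk$pw2$fw(y, train)
  blk$dp$fw(y, train) + x
}

cnb_bw <- function(blk, dout) {
  d <- blk$dp$bw(dout)
  d <- blk$pw2$bw(d)
  d <- blk$grn$bw(d)
  d <- blk$act$bw(d)
  d <- blk$pw1$bw(d)
  d <- blk$ln$bw(d)
  blk$dw$bw(d) + dout
}

#' ConvNeXt-V2 residual block
#'
#' Functional form of one backbone block (freshly initialized): depthwise
#' 7 x 7 convolution, channel layer normalization, pointwise expansion, GELU,
#' global response normalization, pointwise projection, plus the
#' (drop-path-scaled) identity shortcut. With zeroed branch weights the block
#' is the identity.
#'
#' @param x C x H x W (x N) array.
#' @param seed initialization seed.
#' @param expansion pointwise expansion ratio.
#' @param zero_branch zero all branch weights (identity check).
#' @return array of the same shape.
#' @export
convnextv2_block <- function(x, seed = 1L, expansion = 4L,
                             zero_branch = FALSE) {
  x <- as_nchw(x)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  blk <- new_convnext_block(dim(x)[1], expansion)
  if (zero_branch) {
    for (nm in c("dw", "pw1", "pw2")) {
      blk[[nm]]$params <- lapply(blk[[nm]]$params, function(p) p * 0)
    }
  }
  cnb_fw(blk, x)
}

#' Global response normalization (functional)
#'
#' y = gamma * x * (g_c / mean_c(g_c)) + beta + x, where g_c is channel c's
#' spatial L2 norm per sample. `gamma`/`beta` default to 1/0 so the
#' normalization is visible.
#'
#' @param x C x H x W (x N) array.
#' @param gamma,beta per-channel affine parameters.
#' @return array of the same shape.
#' @export
grn_normalize <- function(x, gamma = 1, beta = 0) {
  x <- as_nchw(x)
  g <- layer_grn(dim(x)[1])
  g$params$gamma <- rep_len(gamma, dim(x)[1])
  g$params$beta <- rep_len(beta, dim(x)[1])
  g$fw(x)
}

#' Build an untrained application network
#'
#' @param spec an [appnet_spec()].
#' @param n_covariates length of the one-hot clinical covariate vector
#'   concatenated before the survival head (0 for none).
#' @param seed initialization seed.
#' @return a `histex_appnet` object.
#' @export
build_appnet <- function(spec, n_covariates = 0L, seed = 1L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  w <- spec$stage_widths
  stem <- list(conv = layer_conv2d(spec$in_channels, w[1], k = 4L,
                                   stride = 4L, pad = 0L),
               ln = layer_ln(w[1]))
  stages <- vector("list", 4L)
  downs <- vector("list", 4L)
  for (s in 1:4) {
    if (s > 1L) {
      downs[[s]] <- list(ln = layer_ln(w[s - 1]),
                         conv = layer_conv2d(w[s - 1], w[s], k = 2L,
                                             stride = 2L, pad = 0L))
    }
    stages[[s]] <- lapply(seq_len(spec$stage_depths[s]), function(i) {
      new_convnext_block(w[s], spec$expansion, spec$drop_path)
    })
  }
  final_ln <- layer_ln(w[4])
  embed <- layer_linear(w[4], spec$embed_dim)
  if (spec$head == "cox") {
    head <- list(fc1 = layer_linear(spec$embed_dim + n_covariates,
                                    spec$head_hidden),
                 act = layer_gelu(),
                 fc2 = layer_linear(spec$head_hidden, 1L))
  } else {
    head <- list(fc = layer_linear(spec$embed_dim, spec$n_classes))
  }
  net <- list(spec = spec, stem = stem, downs = downs, stages = stages,
              final_ln = final_ln, embed = embed, head = head,
              n_covariates = as.integer(n_covariates), trained = FALSE,
              covariate_levels = NULL, loss_trace = numeric(0))
  class(net) <- "histex_appnet"
  net
}

appnet_layers <- function(net) {
  collect_layers(list(net$stem, net$downs, net$stages, net$final_ln,
                      net$embed, net$head))
}

appnet_backbone_fw <- function(net, x, train = FALSE) {
  x <- net$stem$ln$fw(net$stem$conv$fw(x, train), train)
  for (s in 1:4) {
    if (s > 1L) {
      x <- net$downs[[s]]$conv$fw(net$downs[[s]]$ln$fw(x, train), train)
    }
    for (blk in net$stages[[s]]) x <- cnb_fw(blk, x, train)
  }
  d <- dim(x)
  pooled <- rowMeans(array(aperm(x, c(1, 4, 2, 3)),
                           dim = c(d[1] * d[4], d[2] * d[3])))
  pooled <- matrix(pooled, d[1], d[4])
  pooled <- net$final_ln$fw(pooled, train)
  net$embed$fw(pooled, train)
}

# backward through GAP: spread gradient uniformly over spatial cells
appnet_backbone_bw <- function(net, dfeat, gap_dim) {
  d <- net$embed$bw(dfeat)
  d <- net$final_ln$bw(d)
  hw <- gap_dim[2] * gap_dim[3]
  big <- array(0, dim = c(gap_dim[1], gap_dim[4], gap_dim[2], gap_dim[3]))
  big[] <- rep(as.vector(d) / hw, times = hw)
  dx <- aperm(big, c(1, 3, 4, 2))
  for (s in 4:1) {
    for (blk in rev(net$stages[[s]])) dx <- cnb_bw(blk, dx)
    if (s > 1L) {
      dx <- net$downs[[s]]$ln$bw(net$downs[[s]]$conv$bw(dx))
    }
  }
  net$stem$conv$bw(net$stem$ln$bw(dx))
}

#' Backbone forward pass
#'
#' Maps a G x H x W expression grid (or a batch) to the fixed-length
#' embedding produced by global average pooling, layer normalization and the
#' linear projection.
#'
#' @param net a `histex_appnet`.
#' @param grids one grid array or a list of them.
#' @return embed_dim x N matrix.
#' @export
appnet_backbone <- function(net, grids) {
  x <- if (is.list(grids)) stack_batch(lapply(grids, as_input_array))
       else as_nchw(as_input_array(grids))
  appnet_backbone_fw(net, x, train = FALSE)
}

head_fw <- function(net, feats, covariates = NULL, train = FALSE) {
  if (net$spec$head == "cox") {
    z <- if (net$n_covariates > 0L) rbind(feats, covariates) else feats
    h <- net$head$act$fw(net$head$fc1$fw(z, train), train)
    as.numeric(net$head$fc2$fw(h, train))
  } else {
    logits <- net$head$fc$fw(feats, train)
    logits
  }
}

head_bw <- function(net, dout) {
  if (net$spec$head == "cox") {
    d <- net$head$fc2$bw(matrix(dout, 1L))
    d <- net$head$fc1$bw(net$head$act$bw(d))
    if (net$n_covariates > 0L) {
      d <- d[seq_len(net$spec$embed_dim), , drop = FALSE]
    }
    d
  } else {
    net$head$fc$bw(dout)
  }
}

softmax_cols <- function(logits) {
  z <- sweep(logits, 2L, apply(logits, 2L, max))
  e <- exp(z)
  sweep(e, 2L, colSums(e), "/")
}

#' Cox partial-likelihood loss
#'
#' loss = -(1 / n_uncensored) * sum over uncensored i of
#' (risk_i - log denominator_i), where risks are first L2-normalized over
#' the batch. In `risk_set` mode (default) the denominator sums
#' exp(risk_j) over the risk set \{j : t_j >= t_i\} — the standard partial
#' likelihood with Breslow tie handling. In `as_printed` mode the denominator
#' sums over all samples regardless of time, reproducing the formula exactly
#' as printed.
#'
#' @param risks numeric vector of raw (pre-normalization) risk scores.
#' @param time,event survival times and event indicators (1 = uncensored).
#' @param mode `"risk_set"` or `"as_printed"`.
#' @param normalize how the risk vector is L2-normalized before the loss:
#'   `"rms"` (default) divides by the root-mean-square norm
#'   `||risk|| / sqrt(n)`, keeping each score on an O(1) scale independent of
#'   batch size; `"unit"` divides by the plain Euclidean norm; `"none"`
#'   disables normalization. `TRUE`/`FALSE` are accepted as aliases for
#'   `"unit"`/`"none"`.
#' @return list with `loss`, `grad` (w.r.t. the raw risks) and
#'   `normalized_risks`.
#' @examples
#' cox_loss(0.3, time = 1, event = 1)$loss            # exactly 0
#' cox_loss(c(1, 1), c(1, 2), c(1, 1),
#'          mode = "as_printed", normalize = FALSE)$loss  # log(2)
#' @export
cox_loss <- function(risks, time, event, mode = c("risk_set", "as_printed"),
                     normalize = "rms") {
  mode <- match.arg(mode)
  if (isTRUE(normalize)) normalize <- "unit"
  if (isFALSE(normalize)) normalize <- "none"
  normalize <- match.arg(normalize, c("rms", "unit", "none"))
  n <- length(risks)
  stopifnot(length(time) == n, length(event) == n)
  d_events <- sum(event == 1)
  if (d_events == 0L) {
    stop("undefined-loss error: no uncensored samples (num_uncensored = 0)")
  }
  if (normalize != "none") {
    nrm <- sqrt(sum(risks^2))
    if (normalize == "rms") nrm <- nrm / sqrt(n)
    if (nrm == 0) nrm <- 1
    r <- risks / nrm
  } else {
    r <- risks
    nrm <- 1
  }
  er <- exp(r)
  if (mode == "as_printed") {
    denom <- sum(er)
    loss <- -sum((r - log(denom)) * event) / d_events
    dr <- -(event - d_events * er / denom) / d_events
  } else {
    ord <- order(time)
    r_o <- r[ord]; e_o <- event[ord]; er_o <- er[ord]
    # cumulative sum from the end: denom_i = sum_{t_j >= t_i} e^{r_j}
    rev_cum <- rev(cumsum(rev(er_o)))
    # Breslow: tied times share the risk-set denominator of the first tie
    t_o <- time[ord]
    first_idx <- match(t_o, t_o)          # index of first occurrence per time
    denom_o <- rev_cum[first_idx]
    loss <- -sum((r_o - log(denom_o)) * e_o) / d_events
    # dL/dr_k = -(1/d) [ e_k - e^{r_k} * sum_{events i with t_i <= t_k} 1/denom_i ]
    inv_d <- e_o / denom_o
    cum_inv <- cumsum(inv_d)
    # samples tied with an event at the same time are in that event's risk set
    last_idx <- length(t_o) + 1L - match(t_o, rev(t_o))
    cum_at_k <- cum_inv[last_idx]
    dr_o <- -(e_o - er_o * cum_at_k) / d_events
    dr <- numeric(n)
    dr[ord] <- dr_o
  }
  if (normalize != "none") {
    # chain rule through r = v / c(v) with c proportional to ||v||:
    # dv = (dr - r * sum(dr * r) / sum(r^2)) / c
    grad <- (dr - r * sum(dr * r) / sum(r * r)) / nrm
  } else {
    grad <- dr
  }
  list(loss = loss, grad = grad, normalized_risks = r)
}

#' Stratified k-fold assignment
#'
#' Random folds preserving the censored/uncensored proportion: each stratum
#' is shuffled and dealt round-robin, so fold sizes differ by at most one and
#' per-fold stratum counts by at most one sample.
#'
#' @param event integer/logical stratum labels (typically the event
#'   indicator).
#' @param k number of folds (default 5).
#' @param seed RNG seed.
#' @return integer vector of fold labels in 1..k.
#' @export
stratified_kfold <- function(event, k = 5L, seed = 1L) {
  n <- length(event)
  if (k > n) stop("protocol error: k exceeds number of records")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  fold <- integer(n)
  offset <- 0L
  for (s in unique(event)) {
    idx <- which(event == s)
    if (length(idx) < k) {
      warning("stratum ", s, " has fewer than k members; best effort")
    }
    idx <- sample(idx)
    fold[idx] <- ((seq_along(idx) - 1L + offset) %% k) + 1L
    offset <- offset + length(idx)
  }
  fold
}

#' Pseudo-bulk expression profile
#'
#' Per-gene mean of (predicted) expression over valid cells, the slide-level
#' profile comparable to bulk RNA-seq.
#'
#' @param grid an `expression_grid`, or a G x H x W array (then `validity`
#'   must be supplied).
#' @param validity H x W logical.
#' @return named numeric vector, one mean per gene.
#' @export
pseudo_bulk <- function(grid, validity = NULL) {
  if (inherits(grid, "expression_grid")) {
    values <- grid$values
    validity <- grid$validity
    genes <- grid$gene_names
  } else {
    values <- grid
    genes <- dimnames(grid)[[1]]
  }
  if (is.null(validity)) stop("data error: validity required")
  if (!any(validity)) stop("data error: no valid cells")
  d <- dim(values)
  m <- values
  dim(m) <- c(d[1], d[2] * d[3])
  out <- as.numeric(m[, as.vector(validity), drop = FALSE] %*%
                      rep(1 / sum(validity), sum(validity)))
  names(out) <- genes
  out
}

#' Encode clinical covariates as one-hot vectors
#'
#' Fits category dictionaries on the training data; unseen categories at
#' inference map to an explicit `"(unknown)"` slot.
#'
#' @param data data.frame of categorical covariates.
#' @param levels optional previously fitted dictionary (list of level
#'   vectors); fitted from `data` when `NULL`.
#' @return list with `matrix` (features x samples) and `levels`.
#' @export
encode_covariates <- function(data, levels = NULL) {
  if (is.null(data) || ncol(data) == 0L) {
    return(list(matrix = matrix(0, 0L, if (is.null(data)) 0L else nrow(data)),
                levels = list()))
  }
  if (is.null(levels)) {
    levels <- lapply(data, function(col) c(sort(unique(as.character(col))),
                                           "(unknown)"))
    names(levels) <- names(data)
  }
  blocks <- lapply(names(levels), function(nm) {
    lv <- levels[[nm]]
    v <- as.character(data[[nm]])
    v[!v %in% lv] <- "(unknown)"
    m <- matrix(0, length(lv), nrow(data),
                dimnames = list(paste(nm, lv, sep = "="), NULL))
    m[cbind(match(v, lv), seq_len(nrow(data)))] <- 1
    m
  })
  list(matrix = do.call(rbind, blocks), levels = levels)
}

#' Train the survival application network
#'
#' Fits the ConvNeXt-V2 backbone plus the two-layer survival head on
#' expression grids (with optional one-hot clinical covariates) by
#' full-batch AdamW on the Cox partial likelihood.
#'
#' @param grids list of G x H x W arrays (or `expression_grid`s).
#' @param time,event survival outcome per sample.
#' @param covariates optional data.frame of categorical clinical covariates.
#' @param spec an [appnet_spec()] with `head = "cox"`.
#' @param epochs,lr0,weight_decay optimizer settings (published defaults:
#'   300 epochs, AdamW, initial learning rate 5e-3).
#' @param seed RNG seed.
#' @param cox_mode,cox_normalize see [cox_loss()].
#' @param verbose print loss every 50 epochs.
#' @return a trained `histex_appnet`.
#' @export
fit_survival_net <- function(grids, time, event, covariates = NULL,
                             spec = NULL, epochs = 300L, lr0 = 5e-3,
                             weight_decay = 1e-4, seed = 1L,
                             cox_mode = "risk_set", cox_normalize = "rms",
                             verbose = FALSE) {
  xs <- stack_batch(lapply(grids, as_input_array))
  if (is.null(spec)) {
    spec <- appnet_spec(dim(xs)[1], head = "cox")
  }
  enc <- encode_covariates(covariates)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  net <- build_appnet(spec, n_covariates = nrow(enc$matrix), seed = seed)
  net$covariate_levels <- enc$levels
  layers <- appnet_layers(net)
  opt <- make_optimizer(layers, "adamw", lr = lr0,
                        weight_decay = weight_decay)
  trace <- numeric(epochs)
  env <- new.env()
  for (epoch in seq_len(epochs)) {
    lr <- cosine_lr(lr0, epoch, epochs)
    feats <- appnet_backbone_fw_tr(net, xs, env)
    risks <- head_fw(net, feats, enc$matrix, train = TRUE)
    lo <- cox_loss(risks, time, event, mode = cox_mode,
                   normalize = cox_normalize)
    if (!is.finite(lo$loss)) {
      stop("numerical failure: loss became ", lo$loss, " at epoch ", epoch)
    }
    trace[epoch] <- lo$loss
    zero_grads(layers)
    dfeat <- head_bw(net, lo$grad)
    appnet_backbone_bw(net, dfeat, env$gap_dim)
    optimizer_step(opt, lr)
    if (verbose && epoch %% 50L == 0L) {
      message("epoch ", epoch, " cox loss ", signif(lo$loss, 4))
    }
  }
  net$trained <- TRUE
  net$loss_trace <- trace
  net
}

# training-mode backbone forward that also records the pre-pool dimensions
appnet_backbone_fw_tr <- function(net, x, env) {
  x <- net$stem$ln$fw(net$stem$conv$fw(x, TRUE), TRUE)
  for (s in 1:4) {
    if (s > 1L) {
      x <- net$downs[[s]]$conv$fw(net$downs[[s]]$ln$fw(x, TRUE), TRUE)
    }
    for (blk in net$stages[[s]]) x <- cnb_fw(blk, x, TRUE)
  }
  d <- dim(x)
  env$gap_dim <- d
  pooled <- rowMeans(array(aperm(x, c(1, 4, 2, 3)),
                           dim = c(d[1] * d[4], d[2] * d[3])))
  pooled <- matrix(pooled, d[1], d[4])
  pooled <- net$final_ln$fw(pooled, TRUE)
  net$embed$fw(pooled, TRUE)
}

#' Predict risk scores
#'
#' @param net a trained `histex_appnet` with a Cox head.
#' @param grids list of grids (or one grid).
#' @param covariates data.frame matching the training covariates (unseen
#'   categories map to the unknown slot).
#' @return numeric risk score per sample (raw, unnormalized).
#' @export
predict_risk <- function(net, grids, covariates = NULL) {
  feats <- appnet_backbone(net, grids)
  cov <- encode_covariates(covariates, levels = net$covariate_levels)$matrix
  if (net$n_covariates > 0L && nrow(cov) != net$n_covariates) {
    stop("config error: covariate encoding mismatch")
  }
  head_fw(net, feats, cov, train = FALSE)
}

#' Train the immunotherapy-response classifier
#'
#' ConvNeXt-V2 backbone plus a single linear layer trained with
#' cross-entropy; published defaults are AdamW, learning rate 5e-5,
#' batch size 20, 200 epochs.
#'
#' @param grids list of expression grids.
#' @param labels binary labels (factor or 0/1; positive class = responder).
#' @param spec an [appnet_spec()] with `head = "classifier"`.
#' @param epochs,lr0,batch_size,weight_decay optimizer settings.
#' @param seed RNG seed.
#' @param verbose print loss every 50 epochs.
#' @return a trained `histex_appnet` with `classes` attribute.
#' @export
fit_icb_net <- function(grids, labels, spec = NULL, epochs = 200L,
                        lr0 = 5e-5, batch_size = 20L, weight_decay = 1e-4,
                        seed = 1L, verbose = FALSE) {
  y <- as.factor(labels)
  if (nlevels(y) < 2L) {
    stop("protocol error: training labels contain a single class")
  }
  yi <- as.integer(y)
  xs <- lapply(grids, as_input_array)
  if (is.null(spec)) {
    spec <- appnet_spec(dim(xs[[1]])[1], head = "classifier",
                        n_classes = nlevels(y))
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  net <- build_appnet(spec, seed = seed)
  layers <- appnet_layers(net)
  opt <- make_optimizer(layers, "adamw", lr = lr0,
                        weight_decay = weight_decay)
  n <- length(xs)
  env <- new.env()
  trace <- numeric(epochs)
  for (epoch in seq_len(epochs)) {
    lr <- cosine_lr(lr0, epoch, epochs)
    ord <- sample.int(n)
    ep_loss <- 0
    for (b0 in seq(1L, n, by = batch_size)) {
      sel <- ord[b0:min(b0 + batch_size - 1L, n)]
      xb <- stack_batch(xs[sel])
      feats <- appnet_backbone_fw_tr(net, xb, env)
      logits <- head_fw(net, feats, train = TRUE)
      p <- softmax_cols(logits)
      tgt <- matrix(0, nrow(p), length(sel))
      tgt[cbind(yi[sel], seq_along(sel))] <- 1
      loss <- -mean(log(pmax(p[cbind(yi[sel], seq_along(sel))], 1e-12)))
      if (!is.finite(loss)) {
        stop("numerical failure: loss became ", loss, " at epoch ", epoch)
      }
      ep_loss <- ep_loss + loss * length(sel)
      zero_grads(layers)
      dlogits <- (p - tgt) / length(sel)
      dfeat <- head_bw(net, dlogits)
      appnet_backbone_bw(net, dfeat, env$gap_dim)
      optimizer_step(opt, lr)
    }
    trace[epoch] <- ep_loss / n
    if (verbose && epoch %% 50L == 0L) {
      message("epoch ", epoch, " CE loss ", signif(trace[epoch], 4))
    }
  }
  net$trained <- TRUE
  net$loss_trace <- trace
  net$classes <- levels(y)
  net
}

#' Predict class probabilities
#'
#' @param net a trained classifier `histex_appnet`.
#' @param grids list of grids.
#' @return samples x classes probability matrix (rows sum to 1).
#' @export
predict_icb <- function(net, grids) {
  feats <- appnet_backbone(net, grids)
  p <- t(softmax_cols(head_fw(net, feats, train = FALSE)))
  colnames(p) <- net$classes
  p
}

#' @export
print.histex_appnet <- function(x, ...) {
  cat("histex_appnet:", x$spec$in_channels, "->",
      paste(x$spec$stage_widths, collapse = "/"), "->",
      x$spec$embed_dim, paste0("(", x$spec$head, " head)"),
      if (x$trained) "trained" else "untrained", "\n")
  cat("  parameters:", format(n_parameters(appnet_layers(x)),
                              big.mark = ","), "\n")
  invisible(x)
}
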