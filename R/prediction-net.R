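#' Prediction network specification
#'
#' Configures the five-level convolutional encoder-decoder that maps an image
#' feature map (C x 80 x 64) to a tumor probability mask (1 x 80 x 64,
#' `sigmoid_mask` head) or a spatial expression map (G x 80 x 64,
#' `linear_grid` head). Encoder levels hold two 3 x 3 conv blocks
#' (conv -> batch norm -> ReLU) each, with 2 x 2 max-pool halvings between
#' the first four levels; the deepest features pass through a ConvMixer
#' (repeated depthwise 7 x 7 + pointwise convolutions); the decoder mirrors
#' the encoder with bilinear x2 upsampling and multi-scale attention-gated
#' skip connections.
#'
#' @param in_channels input feature channels (default 768).
#' @param level_channels five strictly increasing level widths
#'   (default 64, 128, 256, 512, 1024).
#' @param mixer_repeats ConvMixer repeat count (default 7).
#' @param mixer_kernel ConvMixer depthwise kernel size (default 7).
#' @param out_channels output channels (1 for segmentation, G for regression).
#' @param head `"sigmoid_mask"` or `"linear_grid"`.
#' @return a `unet_spec` list.
#' @export
unet_spec <- function(in_channels = 768L,
                      level_channels = c(64L, 128L, 256L, 512L, 1024L),
                      mixer_repeats = 7L, mixer_kernel = 7L,
                      out_channels = 1L,
                      head = c("sigmoid_mask", "linear_grid")) {
  head <- match.arg(head)
  if (length(level_channels) != 5L) {
    stop("config error: exactly five encoder levels are required")
  }
  if (any(diff(level_channels) <= 0)) {
    stop("config error: level channels must be strictly increasing")
  }
  if (mixer_repeats < 1L) {
    stop("config error: mixer_repeats must be >= 1")
  }
  structure(list(in_channels = as.integer(in_channels),
                 level_channels = as.integer(level_channels),
                 mixer_repeats = as.integer(mixer_repeats),
                 mixer_kernel = as.integer(mixer_kernel),
                 out_channels = as.integer(out_channels),
                 head = head),
            class = "unet_spec")
}

#' Training configuration for the prediction network
#'
#' Defaults follow the published protocol: Adam with weight decay 1e-4,
#' cosine-annealed learning rate from 1e-3, up to 200 epochs, batch size 5;
#' MSE loss for expression regression, BCE for segmentation.
#'
#' @param loss `"mse"` or `"bce"`.
#' @param lr0 initial learning rate.
#' @param weight_decay Adam L2 coefficient.
#' @param max_epochs epoch budget.
#' @param batch_size slides per batch.
#' @param seed RNG seed controlling initialization and batch order.
#' @param masked_loss restrict the loss to valid (spot-bearing) cells; the
#'   default `FALSE` follows the training convention of including blank cells
#'   (blank information is part of the target map).
#' @return a `training_config` list.
#' @export
training_config <- function(loss = c("mse", "bce"), lr0 = 1e-3,
                            weight_decay = 1e-4, max_epochs = 200L,
                            batch_size = 5L, seed = 1L,
                            masked_loss = FALSE) {
  loss <- match.arg(loss)
  stopifnot(lr0 > 0, weight_decay >= 0, max_epochs >= 1, batch_size >= 1)
  structure(list(loss = loss, lr0 = lr0, weight_decay = weight_decay,
                 max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed), masked_loss = masked_loss),
            class = "training_config")
}

new_conv_block <- function(in_ch, out_ch, k = 3L, pad = 1L) {
  list(conv = layer_conv2d(in_ch, out_ch, k = k, pad = pad),
       bn = layer_bn(out_ch), relu = layer_relu())
}

cb_fw <- function(cb, x, train = FALSE) {
  cb$relu$fw(cb$bn$fw(cb$conv$fw(x, train), train), train)
}

cb_bw <- function(cb, dout) {
  cb$conv$bw(cb$bn$bw(cb$relu$bw(dout)))
}

new_msag <- function(channels) {
  list(
    b1 = layer_conv2d(channels, channels, k = 1L, pad = 0L),
    b1n = layer_bn(channels),
    b2 = layer_conv2d(channels, channels, k = 3L, pad = 1L),
    b2n = layer_bn(channels),
    b3 = layer_conv2d(channels, channels, k = 3L, pad = 2L, dil = 2L),
    b3n = layer_bn(channels),
    relu = layer_relu(),
    att = layer_conv2d(3L * channels, 1L, k = 1L, pad = 0L),
    attn = layer_bn(1L),
    sig = layer_sigmoid()
  )
}

concat_c <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, dim = c(da[1] + db[1], da[2], da[3], da[4]))
  out[seq_len(da[1]), , , ] <- a
  out[da[1] + seq_len(db[1]), , , ] <- b
  out
}

msag_fw <- function(g, skip, gate, train = FALSE) {
  if (!identical(dim(skip), dim(gate))) {
    stop("geometry error: skip and gating shapes differ")
  }
  u <- skip + gate
  y1 <- g$b1n$fw(g$b1$fw(u, train), train)
  y2 <- g$b2n$fw(g$b2$fw(u, train), train)
  y3 <- g$b3n$fw(g$b3$fw(u, train), train)
  cat3 <- g$relu$fw(concat_c(concat_c(y1, y2), y3), train)
  alpha <- g$sig$fw(g$attn$fw(g$att$fw(cat3, train), train), train)
  cdim <- dim(skip)[1]
  a_big <- alpha[rep(1L, cdim), , , , drop = FALSE]
  if (train) g$cache_env$val <- list(skip = skip, alpha = alpha)
  list(gated = skip * a_big, alpha = alpha)
}

msag_bw <- function(g, dout) {
  ca <- g$cache_env$val
  cdim <- dim(ca$skip)[1]
  a_big <- ca$alpha[rep(1L, cdim), , , , drop = FALSE]
  dskip_direct <- dout * a_big
  dalpha <- colSums(chan_mat(dout * ca$skip))
  dim(dalpha) <- c(1L, dim(dout)[2], dim(dout)[3], dim(dout)[4])
  dcat <- g$relu$bw(g$att$bw(g$attn$bw(g$sig$bw(dalpha))))
  d <- dim(dcat)[1] / 3L
  du <- g$b1$bw(g$b1n$bw(dcat[seq_len(d), , , , drop = FALSE])) +
    g$b2$bw(g$b2n$bw(dcat[d + seq_len(d), , , , drop = FALSE])) +
    g$b3$bw(g$b3n$bw(dcat[2L * d + seq_len(d), , , , drop = FALSE]))
  list(dskip = dskip_direct + du, dgate = du)
}

#' Multi-scale attention gate
#'
#' Applies a freshly initialized multi-scale attention gate to a skip tensor
#' and a gating tensor of identical shape: the sum of the two passes through
#' three parallel convolution branches (pointwise 1 x 1; ordinary 3 x 3
#' pad 1; dilated 3 x 3 pad 2 dilation 2), each batch-normalized; the
#' concatenation is ReLU-activated and compressed by a batch-normalized
#' pointwise convolution with sigmoid activation into a per-location
#' attention field alpha in (0, 1), which multiplies the skip features.
#'
#' Inside [build_unet()] the same gate structure is a persistent trained
#' module; this functional form exists for inspection and property checks.
#'
#' @param skip,gating C x H x W (x N) arrays of equal shape.
#' @param seed seed for the gate's random initialization.
#' @return list with `gated` (same shape as `skip`) and `alpha`
#'   (1 x H x W x N).
#' @export
msag_gate <- function(skip, gating, seed = 1L) {
  skip <- as_nchw(skip); gating <- as_nchw(gating)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  g <- new_msag(dim(skip)[1])
  g$cache_env <- new.env(parent = emptyenv())
  msag_fw(g, skip, gating)
}

#' Convolution block
#'
#' One prediction-module building block: 3 x 3 convolution (stride 1,
#' padding 1) -> batch normalization -> ReLU, freshly initialized. Spatial
#' dimensions are preserved and outputs are non-negative.
#'
#' @param x C x H x W (x N) array.
#' @param out_channels output width.
#' @param seed initialization seed.
#' @param weights optional list(w, b) overriding the random initialization.
#' @return out_channels x H x W x N array.
#' @export
conv_block <- function(x, out_channels, seed = 1L, weights = NULL) {
  x <- as_nchw(x)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  cb <- new_conv_block(dim(x)[1], out_channels)
  if (!is.null(weights)) cb$conv$params <- weights
  cb_fw(cb, x)
}

#' ConvMixer bottleneck
#'
#' Repeated depthwise (7 x 7, padding 3) + pointwise convolution pairs, each
#' convolution followed by batch normalization and ReLU; channel and spatial
#' dimensions are preserved across all repeats.
#'
#' @param x C x H x W (x N) array.
#' @param repeats number of depthwise/pointwise pairs (default 7; must be
#'   >= 1).
#' @param kernel depthwise kernel size (default 7).
#' @param seed initialization seed.
#' @return array of the same dimensions.
#' @export
convmixer_bottleneck <- function(x, repeats = 7L, kernel = 7L, seed = 1L) {
  if (repeats < 1L) stop("config error: repeats must be >= 1")
  x <- as_nchw(x)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  mix <- new_convmixer(dim(x)[1], repeats, kernel)
  mixer_fw(mix, x)
}

new_convmixer <- function(channels, repeats, kernel) {
  lapply(seq_len(repeats), function(i) {
    list(dw = layer_depthwise(channels, k = kernel,
                              pad = (kernel - 1L) %/% 2L),
         dwn = layer_bn(channels), dwr = layer_relu(),
         pw = layer_conv2d(channels, channels, k = 1L, pad = 0L),
         pwn = layer_bn(channels), pwr = layer_relu())
  })
}

mixer_fw <- function(mix, x, train = FALSE) {
  for (m in mix) {
    x <- m$dwr$fw(m$dwn$fw(m$dw$fw(x, train), train), train)
    x <- m$pwr$fw(m$pwn$fw(m$pw$fw(x, train), train), train)
  }
  x
}

mixer_bw <- function(mix, dout) {
  for (m in rev(mix)) {
    dout <- m$pw$bw(m$pwn$bw(m$pwr$bw(dout)))
    dout <- m$dw$bw(m$dwn$bw(m$dwr$bw(dout)))
  }
  dout
}

#' Build an untrained prediction network
#'
#' Instantiates all layers of the encoder-decoder described by a
#' [unet_spec()], with seeded Kaiming initialization.
#'
#' @param spec a `unet_spec`.
#' @param seed initialization seed.
#' @return a `histex_unet` object (untrained).
#' @export
build_unet <- function(spec, seed = 1L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  ch <- spec$level_channels
  in_ch <- c(spec$in_channels, ch[1:4])
  enc <- lapply(1:5, function(i) {
    list(new_conv_block(in_ch[i], ch[i]), new_conv_block(ch[i], ch[i]))
  })
  pool <- lapply(1:4, function(i) layer_maxpool2())
  mixer <- new_convmixer(ch[5], spec$mixer_repeats, spec$mixer_kernel)
  up <- lapply(1:4, function(i) {
    list(ups = layer_upsample2(), cb = new_conv_block(ch[i + 1], ch[i]))
  })
  msag <- lapply(1:4, function(i) {
    g <- new_msag(ch[i])
    g$cache_env <- new.env(parent = emptyenv())
    g
  })
  dec <- lapply(1:4, function(i) {
    list(new_conv_block(2L * ch[i], ch[i]), new_conv_block(ch[i], ch[i]))
  })
  head_conv <- layer_conv2d(ch[1], spec$out_channels, k = 1L, pad = 0L)
  head_act <- if (spec$head == "sigmoid_mask") layer_sigmoid() else NULL
  net <- list(spec = spec, enc = enc, pool = pool, mixer = mixer, up = up,
              msag = msag, dec = dec, head_conv = head_conv,
              head_act = head_act, trained = FALSE, loss_trace = numeric(0))
  class(net) <- "histex_unet"
  net
}

unet_layers <- function(net) {
  collect_layers(list(net$enc, net$pool, net$mixer,
                      lapply(net$up, function(u) list(u$ups, u$cb)),
                      lapply(net$msag, function(g)
                        g[setdiff(names(g), "cache_env")]),
                      net$dec, net$head_conv, net$head_act))
}

#' Encoder forward pass
#'
#' Runs the five encoder levels (without the mixer or decoder), returning the
#' bottleneck features and the four skip tensors. Spatial dimensions must be
#' divisible by 16 (four 2 x 2 poolings) — the reason spot grids are padded
#' from 78 to 80 rows.
#'
#' @param net a `histex_unet`.
#' @param x input array (C x H x W, optionally x N).
#' @return list with `bottleneck` and `skips` (list of 4).
#' @export
unet_encoder_forward <- function(net, x) {
  x <- as_nchw(x)
  d <- dim(x)
  if (d[2] %% 16L || d[3] %% 16L) {
    stop("geometry error: encoder input spatial dims must be divisible by ",
         "16, got ", d[2], " x ", d[3])
  }
  skips <- vector("list", 4L)
  for (i in 1:4) {
    x <- cb_fw(net$enc[[i]][[2]], cb_fw(net$enc[[i]][[1]], x))
    skips[[i]] <- x
    x <- net$pool[[i]]$fw(x)
  }
  x <- cb_fw(net$enc[[5]][[2]], cb_fw(net$enc[[5]][[1]], x))
  list(bottleneck = x, skips = skips)
}

unet_fw <- function(net, x, train = FALSE) {
  d <- dim(x)
  if (d[1] != net$spec$in_channels) {
    stop("config error: input has ", d[1], " channels, spec expects ",
         net$spec$in_channels)
  }
  if (d[2] %% 16L || d[3] %% 16L) {
    stop("geometry error: input spatial dims must be divisible by 16, got ",
         d[2], " x ", d[3])
  }
  skips <- vector("list", 4L)
  for (i in 1:4) {
    x <- cb_fw(net$enc[[i]][[2]], cb_fw(net$enc[[i]][[1]], x, train), train)
    skips[[i]] <- x
    x <- net$pool[[i]]$fw(x, train)
  }
  x <- cb_fw(net$enc[[5]][[2]], cb_fw(net$enc[[5]][[1]], x, train), train)
  x <- mixer_fw(net$mixer, x, train)
  for (i in 4:1) {
    x <- net$up[[i]]$ups$fw(x, train)
    x <- cb_fw(net$up[[i]]$cb, x, train)
    gs <- msag_fw(net$msag[[i]], skips[[i]], x, train)
    x <- concat_c(gs$gated, x)
    x <- cb_fw(net$dec[[i]][[2]], cb_fw(net$dec[[i]][[1]], x, train), train)
  }
  x <- net$head_conv$fw(x, train)
  if (!is.null(net$head_act)) x <- net$head_act$fw(x, train)
  x
}

unet_bw <- function(net, dout) {
  if (!is.null(net$head_act)) dout <- net$head_act$bw(dout)
  d <- net$head_conv$bw(dout)
  ch <- net$spec$level_channels
  dskips <- vector("list", 4L)
  for (i in 1:4) {
    d <- cb_bw(net$dec[[i]][[1]], cb_bw(net$dec[[i]][[2]], d))
    dg <- d[seq_len(ch[i]), , , , drop = FALSE]
    dx <- d[ch[i] + seq_len(ch[i]), , , , drop = FALSE]
    gb <- msag_bw(net$msag[[i]], dg)
    dskips[[i]] <- gb$dskip
    d <- net$up[[i]]$ups$bw(cb_bw(net$up[[i]]$cb, dx + gb$dgate))
  }
  d <- cb_bw(net$enc[[5]][[1]], cb_bw(net$enc[[5]][[2]], mixer_bw(net$mixer, d)))
  for (i in 4:1) {
    d <- net$pool[[i]]$bw(d) + dskips[[i]]
    d <- cb_bw(net$enc[[i]][[1]], cb_bw(net$enc[[i]][[2]], d))
  }
  d
}

#' Forward pass of the prediction network
#'
#' @param net a `histex_unet`.
#' @param x C x H x W (x N) array — typically a feature map's `values`.
#' @return output array: out_channels x H x W (x N); values in (0, 1) for the
#'   `sigmoid_mask` head.
#' @export
unet_forward <- function(net, x) {
  squeeze <- length(dim(x)) == 3L
  y <- unet_fw(net, as_nchw(x), train = FALSE)
  if (squeeze) {
    d <- dim(y)
    dim(y) <- d[1:3]
  }
  y
}

as_input_array <- function(x) {
  if (inherits(x, "feature_map")) x$values else x
}

as_target_array <- function(y) {
  if (inherits(y, "label_grid")) {
    array(y$values, dim = c(1L, nrow(y$values), ncol(y$values)))
  } else if (inherits(y, "expression_grid")) {
    y$values
  } else y
}

stack_batch <- function(lst) {
  d <- dim(lst[[1]])
  out <- array(0, dim = c(d, length(lst)))
  for (i in seq_along(lst)) out[, , , i] <- lst[[i]]
  out
}

#' Train the prediction network
#'
#' Mini-batch training with Adam (weight decay 1e-4) and a cosine-annealed
#' learning rate, reproducible under the config seed. Targets must share the
#' padded model geometry of the inputs; the loss is computed over the full
#' grid, blank cells included (set `masked_loss` in the config to restrict it
#' to valid cells).
#'
#' @param inputs list of feature maps (or C x H x W arrays).
#' @param targets list of `expression_grid` / `label_grid` objects (or
#'   arrays) aligned with `inputs`.
#' @param spec a [unet_spec()]; `out_channels`/`head` must match the targets.
#' @param config a [training_config()].
#' @param validity optional H x W logical used with `masked_loss`.
#' @param verbose print the running loss every 20 epochs.
#' @return a trained `histex_unet` with a `loss_trace`.
#' @export
train_unet <- function(inputs, targets, spec, config = training_config(),
                       validity = NULL, verbose = FALSE) {
  stopifnot(length(inputs) >= 1L, length(inputs) == length(targets))
  xs <- lapply(inputs, as_input_array)
  ys <- lapply(targets, as_target_array)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  net <- build_unet(spec, seed = config$seed)
  if (spec$head == "linear_grid") {
    # start the regression head at the per-gene target mean so early steps
    # model structure rather than the global offset
    tgt_mean <- Reduce(`+`, lapply(ys, function(y) {
      rowMeans(chan_mat(as_nchw(y)))
    })) / length(ys)
    net$head_conv$params$b <- tgt_mean
  }
  layers <- unet_layers(net)
  opt <- make_optimizer(layers, "adam", lr = config$lr0,
                        weight_decay = config$weight_decay)
  n <- length(xs)
  mask <- NULL
  if (config$masked_loss) {
    if (is.null(validity)) stop("config error: masked_loss needs validity")
    mask <- validity
  }
  trace <- numeric(config$max_epochs)
  for (epoch in seq_len(config$max_epochs)) {
    lr <- cosine_lr(config$lr0, epoch, config$max_epochs)
    ord <- sample.int(n)
    ep_loss <- 0
    for (b0 in seq(1L, n, by = config$batch_size)) {
      sel <- ord[b0:min(b0 + config$batch_size - 1L, n)]
      xb <- stack_batch(xs[sel])
      yb <- stack_batch(ys[sel])
      pred <- unet_fw(net, xb, train = TRUE)
      if (!is.null(mask)) {
        mfull <- array(rep(as.numeric(mask),
                           each = dim(pred)[1]),
                       dim = dim(pred))
        lo <- if (config$loss == "mse") mse_loss(pred * mfull, yb * mfull)
              else bce_loss(pred * mfull + (1 - mfull) * 0.5, yb * mfull)
        lo$grad <- lo$grad * mfull
      } else {
        lo <- if (config$loss == "mse") mse_loss(pred, yb)
              else bce_loss(pred, yb)
      }
      if (!is.finite(lo$loss)) {
        stop("numerical failure: loss became ", lo$loss, " at epoch ", epoch)
      }
      ep_loss <- ep_loss + lo$loss * length(sel)
      zero_grads(layers)
      unet_bw(net, array(lo$grad, dim = dim(pred)))
      optimizer_step(opt, lr)
    }
    trace[epoch] <- ep_loss / n
    if (verbose && epoch %% 20L == 0L) {
      message("epoch ", epoch, " loss ", signif(trace[epoch], 4))
    }
  }
  net$trained <- TRUE
  net$loss_trace <- trace
  net$config <- config
  net
}

#' @export
print.histex_unet <- function(x, ...) {
  cat("histex_unet:", x$spec$in_channels, "->",
      paste(x$spec$level_channels, collapse = "/"), "->",
      x$spec$out_channels, paste0("(", x$spec$head, ")"),
      if (x$trained) "trained" else "untrained", "\n")
  cat("  parameters:", format(n_parameters(unet_layers(x)), big.mark = ","),
      "\n")
  invisible(x)
}

#' @export
predict.histex_unet <- function(object, newdata, ...) {
  if (inherits(newdata, "feature_map") || is.array(newdata) &&
      length(dim(newdata)) <= 3L) {
    return(unet_forward(object, as_input_array(newdata)))
  }
  lapply(newdata, function(x) unet_forward(object, as_input_array(x)))
}

#' Count trainable parameters
#'
#' @param net a `histex_unet` or `histex_appnet`.
#' @return integer parameter count (a deterministic function of the spec).
#' @export
count_parameters <- function(net) {
  layers <- if (inherits(net, "histex_unet")) unet_layers(net)
            else appnet_layers(net)
  n_parameters(layers)
}

#' Leave-one-out cross-validation over slides
#'
#' For each slide, trains on all others and predicts the held-out slide.
#' Fold order is the slide order; each fold's manifest records the training
#' and test indices.
#'
#' @param inputs,targets,spec,config as in [train_unet()].
#' @return list with `predictions` (one output array per slide) and
#'   `folds` (list of manifests with `test`, `train` indices).
#' @export
loocv_unet <- function(inputs, targets, spec, config = training_config()) {
  n <- length(inputs)
  if (n < 2L) stop("protocol error: LOOCV needs at least 2 slides")
  preds <- vector("list", n)
  folds <- vector("list", n)
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    net <- train_unet(inputs[tr], targets[tr], spec, config)
    preds[[i]] <- unet_forward(net, as_input_array(inputs[[i]]))
    folds[[i]] <- list(test = i, train = tr)
  }
  list(predictions = preds, folds = folds)
}
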