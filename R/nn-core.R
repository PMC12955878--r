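# Minimal convolutional network engine.
#
# Tensors are numeric arrays with dim (C, H, W, N) — channel first, batch
# last — so a per-channel view is a C x (H*W*N) matrix without copying.
# Each layer is an environment holding `params`, `grads`, a `fw(x, train)`
# closure and a `bw(dout)` closure; convolutions are evaluated as im2col
# gathers followed by BLAS matrix multiplies, and every backward pass is
# hand-derived (verified against finite differences in the test suite).

as_nchw <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("geometry error: expected an array")
  if (length(d) == 3L) dim(x) <- c(d, 1L)
  x
}

chan_mat <- function(x) {
  d <- dim(x)
  dim(x) <- c(d[1], prod(d[-1]))
  x
}

pad_hw <- function(x, pad) {
  if (pad == 0L) return(x)
  d <- dim(x)
  out <- array(0, dim = c(d[1], d[2] + 2L * pad, d[3] + 2L * pad, d[4]))
  out[, pad + seq_len(d[2]), pad + seq_len(d[3]), ] <- x
  out
}

unpad_hw <- function(x, pad, h, w) {
  if (pad == 0L) return(x)
  x[, pad + seq_len(h), pad + seq_len(w), , drop = FALSE]
}

conv_out_len <- function(n, k, stride, pad, dil) {
  (n + 2L * pad - ((k - 1L) * dil + 1L)) %/% stride + 1L
}

# Linear gather indices mapping a padded (C, Hp, Wp, N) array to the
# (C*k*k) x (Ho*Wo*N) im2col matrix. Rows ordered c fastest, then kh, kw;
# columns ordered ho fastest, then wo, then n. The flat gather vector and the
# per-kernel-position row blocks (used by the scatter in backward) are
# precomputed once per input shape and cached by the layer.
im2col_index <- function(c_in, hp, wp, n, k, stride, dil) {
  ho <- conv_out_len(hp, k, stride, 0L, dil)
  wo <- conv_out_len(wp, k, stride, 0L, dil)
  patch_off <- outer(seq_len(c_in),
                     c_in * dil * (seq_len(k) - 1L), "+")
  patch_off <- outer(as.vector(patch_off),
                     c_in * hp * dil * (seq_len(k) - 1L), "+")
  base <- outer(c_in * stride * (seq_len(ho) - 1L),
                c_in * hp * stride * (seq_len(wo) - 1L), "+")
  base <- outer(as.vector(base), c_in * hp * wp * (seq_len(n) - 1L), "+")
  idx <- outer(as.vector(patch_off), as.vector(base), "+")
  l <- ho * wo * n
  kk_rows <- lapply(seq_len(k * k), function(kk) (kk - 1L) * c_in + seq_len(c_in))
  kk_idx <- lapply(kk_rows, function(rows) as.vector(idx[rows, , drop = FALSE]))
  list(idx = as.vector(idx), nrow = c_in * k * k, l = l,
       kk_idx = kk_idx, ho = ho, wo = wo)
}

kaiming_init <- function(fan_in, n) {
  stats::rnorm(n, sd = sqrt(2 / fan_in))
}

#' @keywords internal
layer_conv2d <- function(in_ch, out_ch, k = 3L, stride = 1L, pad = 1L,
                         dil = 1L) {
  self <- new.env(parent = emptyenv())
  self$params <- list(
    w = matrix(kaiming_init(in_ch * k * k, in_ch * k * k * out_ch),
               in_ch * k * k, out_ch),
    b = numeric(out_ch)
  )
  self$grads <- list()
  self$kind <- "conv2d"
  self$conf <- list(in_ch = in_ch, out_ch = out_ch, k = as.integer(k),
                    stride = as.integer(stride), pad = as.integer(pad),
                    dil = as.integer(dil))
  self$fw <- function(x, train = FALSE) {
    cf <- self$conf
    d <- dim(x)
    if (d[1] != cf$in_ch) {
      stop("config error: conv expects ", cf$in_ch, " channels, got ", d[1])
    }
    xp <- pad_hw(x, cf$pad)
    dp <- dim(xp)
    key <- paste(dp, collapse = "x")
    if (is.null(self$idx_key) || self$idx_key != key) {
      self$idx_cache <- im2col_index(cf$in_ch, dp[2], dp[3], dp[4],
                                     cf$k, cf$stride, cf$dil)
      self$idx_key <- key
    }
    ic <- self$idx_cache
    col <- xp[ic$idx]
    dim(col) <- c(ic$nrow, ic$l)
    out <- crossprod(self$params$w, col) + self$params$b
    if (train) {
      self$cache <- list(col = col, in_dim = d, pad_dim = dp)
    }
    array(out, dim = c(cf$out_ch, ic$ho, ic$wo, d[4]))
  }
  self$bw <- function(dout) {
    cf <- self$conf
    dm <- chan_mat(dout)
    cache <- self$cache
    self$grads$w <- cache$col %*% t(dm)
    self$grads$b <- rowSums(dm)
    dcol <- self$params$w %*% dm
    dxp <- numeric(prod(cache$pad_dim))
    ic <- self$idx_cache
    cb <- cf$in_ch
    for (kk in seq_len(cf$k * cf$k)) {
      rows <- (kk - 1L) * cb + seq_len(cb)
      ib <- ic$kk_idx[[kk]]
      dxp[ib] <- dxp[ib] + as.vector(dcol[rows, , drop = FALSE])
    }
    dim(dxp) <- cache$pad_dim
    unpad_hw(dxp, cf$pad, cache$in_dim[2], cache$in_dim[3])
  }
  self
}

#' @keywords internal
layer_depthwise <- function(channels, k = 7L, pad = 3L) {
  self <- new.env(parent = emptyenv())
  self$params <- list(
    w = matrix(kaiming_init(k * k, k * k * channels), k * k, channels),
    b = numeric(channels)
  )
  self$grads <- list()
  self$kind <- "depthwise"
  self$conf <- list(channels = channels, k = as.integer(k),
                    pad = as.integer(pad))
  self$fw <- function(x, train = FALSE) {
    cf <- self$conf
    d <- dim(x)
    if (d[1] != cf$channels) {
      stop("config error: depthwise expects ", cf$channels, " channels")
    }
    xp <- pad_hw(x, cf$pad)
    dp <- dim(xp)
    key <- paste(dp, collapse = "x")
    if (is.null(self$idx_key) || self$idx_key != key) {
      self$idx_cache <- im2col_index(cf$channels, dp[2], dp[3], dp[4],
                                     cf$k, 1L, 1L)
      self$idx_key <- key
    }
    ic <- self$idx_cache
    col <- xp[ic$idx]
    dim(col) <- c(ic$nrow, ic$l)
    cb <- cf$channels
    out <- matrix(self$params$b, cb, ncol(col))
    for (kk in seq_len(cf$k * cf$k)) {
      rows <- (kk - 1L) * cb + seq_len(cb)
      out <- out + col[rows, , drop = FALSE] * self$params$w[kk, ]
    }
    if (train) self$cache <- list(col = col, in_dim = d, pad_dim = dp)
    array(out, dim = c(cb, ic$ho, ic$wo, d[4]))
  }
  self$bw <- function(dout) {
    cf <- self$conf
    cb <- cf$channels
    dm <- chan_mat(dout)
    cache <- self$cache
    dw <- matrix(0, cf$k * cf$k, cb)
    dxp <- numeric(prod(cache$pad_dim))
    ic <- self$idx_cache
    for (kk in seq_len(cf$k * cf$k)) {
      rows <- (kk - 1L) * cb + seq_len(cb)
      blk <- cache$col[rows, , drop = FALSE]
      dw[kk, ] <- rowSums(blk * dm)
      ib <- ic$kk_idx[[kk]]
      dxp[ib] <- dxp[ib] + as.vector(dm * self$params$w[kk, ])
    }
    self$grads$w <- dw
    self$grads$b <- rowSums(dm)
    dim(dxp) <- cache$pad_dim
    unpad_hw(dxp, cf$pad, cache$in_dim[2], cache$in_dim[3])
  }
  self
}

#' @keywords internal
layer_bn <- function(channels, momentum = 0.1, eps = 1e-5) {
  self <- new.env(parent = emptyenv())
  self$params <- list(gamma = rep(1, channels), beta = numeric(channels))
  self$grads <- list()
  self$kind <- "bn"
  self$running_mean <- numeric(channels)
  self$running_var <- rep(1, channels)
  self$conf <- list(channels = channels, momentum = momentum, eps = eps)
  self$fw <- function(x, train = FALSE) {
    d <- dim(x)
    xm <- chan_mat(x)
    if (train) {
      mu <- rowMeans(xm)
      v <- rowMeans(xm * xm) - mu^2
      self$running_mean <- (1 - self$conf$momentum) * self$running_mean +
        self$conf$momentum * mu
      self$running_var <- (1 - self$conf$momentum) * self$running_var +
        self$conf$momentum * v
    } else {
      mu <- self$running_mean
      v <- self$running_var
    }
    ivar <- 1 / sqrt(v + self$conf$eps)
    xhat <- (xm - mu) * ivar
    y <- self$params$gamma * xhat + self$params$beta
    if (train) self$cache <- list(xhat = xhat, ivar = ivar)
    array(y, dim = d)
  }
  self$bw <- function(dout) {
    d <- dim(dout)
    dm <- chan_mat(dout)
    xhat <- self$cache$xhat
    self$grads$gamma <- rowSums(dm * xhat)
    self$grads$beta <- rowSums(dm)
    l <- ncol(dm)
    t1 <- dm - rowMeans(dm) - xhat * rowMeans(dm * xhat)
    dx <- (self$params$gamma * self$cache$ivar) * t1
    array(dx, dim = d)
  }
  self
}

# Layer normalization over the channel axis at each spatial location / sample
# (channels-first ConvNeXt convention), with per-channel affine.
#' @keywords internal
layer_ln <- function(channels, eps = 1e-6) {
  self <- new.env(parent = emptyenv())
  self$params <- list(gamma = rep(1, channels), beta = numeric(channels))
  self$grads <- list()
  self$kind <- "ln"
  self$conf <- list(channels = channels, eps = eps)
  self$fw <- function(x, train = FALSE) {
    d <- dim(x)
    if (is.null(d)) dim(x) <- d <- c(length(x), 1L)
    xm <- chan_mat(x)
    cdim <- nrow(xm)
    mu <- colMeans(xm)
    xc <- xm - rep(mu, each = cdim)
    v <- colMeans(xc * xc)
    ivar <- 1 / sqrt(v + self$conf$eps)
    xhat <- xc * rep(ivar, each = cdim)
    y <- self$params$gamma * xhat + self$params$beta
    if (train) self$cache <- list(xhat = xhat, ivar = ivar)
    array(y, dim = d)
  }
  self$bw <- function(dout) {
    d <- dim(dout)
    dm <- chan_mat(dout)
    xhat <- self$cache$xhat
    self$grads$gamma <- rowSums(dm * xhat)
    self$grads$beta <- rowSums(dm)
    dxhat <- dm * self$params$gamma
    cdim <- nrow(dm)
    t1 <- dxhat - rep(colMeans(dxhat), each = cdim)
    t2 <- xhat * rep(colMeans(dxhat * xhat), each = cdim)
    dx <- (t1 - t2) * rep(self$cache$ivar, each = cdim)
    array(dx, dim = d)
  }
  self
}

#' @keywords internal
layer_relu <- function() {
  self <- new.env(parent = emptyenv())
  self$params <- list(); self$grads <- list()
  self$kind <- "relu"
  self$fw <- function(x, train = FALSE) {
    y <- pmax(x, 0)
    if (train) self$cache <- x > 0
    y
  }
  self$bw <- function(dout) dout * self$cache
  self
}

#' @keywords internal
layer_sigmoid <- function() {
  self <- new.env(parent = emptyenv())
  self$params <- list(); self$grads <- list()
  self$kind <- "sigmoid"
  self$fw <- function(x, train = FALSE) {
    y <- 1 / (1 + exp(-x))
    if (train) self$cache <- y
    y
  }
  self$bw <- function(dout) dout * self$cache * (1 - self$cache)
  self
}

#' @keywords internal
layer_gelu <- function() {
  self <- new.env(parent = emptyenv())
  self$params <- list(); self$grads <- list()
  self$kind <- "gelu"
  self$fw <- function(x, train = FALSE) {
    if (train) self$cache <- x
    x * stats::pnorm(x)
  }
  self$bw <- function(dout) {
    x <- self$cache
    dout * (stats::pnorm(x) + x * stats::dnorm(x))
  }
  self
}

#' @keywords internal
layer_maxpool2 <- function() {
  self <- new.env(parent = emptyenv())
  self$params <- list(); self$grads <- list()
  self$kind <- "maxpool2"
  self$fw <- function(x, train = FALSE) {
    d <- dim(x)
    if (d[2] %% 2L || d[3] %% 2L) {
      stop("geometry error: max pooling needs even spatial dims, got ",
           d[2], " x ", d[3])
    }
    ho <- d[2] %/% 2L; wo <- d[3] %/% 2L
    dim(x) <- c(d[1], 2L, ho, 2L, wo, d[4])
    a11 <- x[, 1, , 1, , , drop = FALSE]
    a21 <- x[, 2, , 1, , , drop = FALSE]
    a12 <- x[, 1, , 2, , , drop = FALSE]
    a22 <- x[, 2, , 2, , , drop = FALSE]
    y <- pmax(a11, a21, a12, a22)
    if (train) {
      m11 <- a11 == y
      m21 <- (a21 == y) & !m11
      m12 <- (a12 == y) & !(m11 | m21)
      m22 <- (a22 == y) & !(m11 | m21 | m12)
      self$cache <- list(m = list(m11, m21, m12, m22), in_dim = d)
    }
    dim(y) <- c(d[1], ho, wo, d[4])
    y
  }
  self$bw <- function(dout) {
    d <- self$cache$in_dim
    ho <- d[2] %/% 2L; wo <- d[3] %/% 2L
    dx <- array(0, dim = c(d[1], 2L, ho, 2L, wo, d[4]))
    m <- self$cache$m
    dy <- array(dout, dim = c(d[1], 1L, ho, 1L, wo, d[4]))
    dx[, 1, , 1, , ] <- dy * m[[1]]
    dx[, 2, , 1, , ] <- dy * m[[2]]
    dx[, 1, , 2, , ] <- dy * m[[3]]
    dx[, 2, , 2, , ] <- dy * m[[4]]
    dim(dx) <- d
    dx
  }
  self
}

apply_axis_matrix <- function(x, a, axis) {
  d <- dim(x)
  perm <- c(axis, setdiff(seq_along(d), axis))
  xp <- aperm(x, perm)
  dp <- dim(xp)
  dim(xp) <- c(dp[1], prod(dp[-1]))
  y <- a %*% xp
  dim(y) <- c(nrow(a), dp[-1])
  aperm(y, order(perm))
}

#' @keywords internal
layer_upsample2 <- function() {
  self <- new.env(parent = emptyenv())
  self$params <- list(); self$grads <- list()
  self$kind <- "upsample2"
  self$fw <- function(x, train = FALSE) {
    d <- dim(x)
    key <- paste(d[2], d[3])
    if (is.null(self$key) || self$key != key) {
      self$a_h <- bilinear_matrix(d[2], 2L * d[2])
      self$a_w <- bilinear_matrix(d[3], 2L * d[3])
      self$key <- key
    }
    y <- apply_axis_matrix(x, self$a_h, 2L)
    apply_axis_matrix(y, self$a_w, 3L)
  }
  self$bw <- function(dout) {
    dx <- apply_axis_matrix(dout, t(self$a_w), 3L)
    apply_axis_matrix(dx, t(self$a_h), 2L)
  }
  self
}

#' @keywords internal
layer_linear <- function(in_dim, out_dim) {
  self <- new.env(parent = emptyenv())
  self$params <- list(
    w = matrix(kaiming_init(in_dim, in_dim * out_dim), out_dim, in_dim),
    b = numeric(out_dim)
  )
  self$grads <- list()
  self$kind <- "linear"
  self$fw <- function(x, train = FALSE) {
    if (is.null(dim(x))) dim(x) <- c(length(x), 1L)
    if (train) self$cache <- x
    self$params$w %*% x + self$params$b
  }
  self$bw <- function(dout) {
    self$grads$w <- dout %*% t(self$cache)
    self$grads$b <- rowSums(dout)
    t(self$params$w) %*% dout
  }
  self
}

# Global response normalization (ConvNeXt-V2): per sample, each channel's
# spatial L2 norm is divided by the cross-channel mean norm and used to
# re-scale the channel, with learned affine, plus an identity shortcut:
# y = gamma * x * (g_c / mean_c g_c) + beta + x.
#' @keywords internal
layer_grn <- function(channels, eps = 1e-6) {
  self <- new.env(parent = emptyenv())
  self$params <- list(gamma = numeric(channels), beta = numeric(channels))
  self$grads <- list()
  self$kind <- "grn"
  self$conf <- list(channels = channels, eps = eps)
  self$fw <- function(x, train = FALSE) {
    d <- dim(x)
    hw <- d[2] * d[3]
    x2 <- aperm(x, c(2, 3, 1, 4))
    dim(x2) <- c(hw, d[1] * d[4])
    g <- sqrt(colSums(x2 * x2))          # per (channel, sample) spatial norm
    g <- matrix(g, d[1], d[4])
    m <- colMeans(g)
    nx <- g / rep(m + self$conf$eps, each = d[1])
    nx_big <- nx[, rep(seq_len(d[4]), each = hw), drop = FALSE]
    xm <- chan_mat(x)
    y <- self$params$gamma * (xm * nx_big) + self$params$beta + xm
    if (train) self$cache <- list(x = x, g = g, m = m, nx = nx,
                                  nx_big = nx_big, hw = hw)
    array(y, dim = d)
  }
  self$bw <- function(dout) {
    d <- dim(dout)
    ca <- self$cache
    hw <- ca$hw
    dm <- chan_mat(dout)
    xm <- chan_mat(ca$x)
    self$grads$gamma <- rowSums(dm * xm * ca$nx_big)
    self$grads$beta <- rowSums(dm)
    t_mat <- dm * self$params$gamma           # dL/d(x*nx)
    dx <- dm + t_mat * ca$nx_big              # identity + direct term
    # s[c, n] = sum_l t * x  (per channel/sample)
    tx <- t_mat * xm
    dim(tx) <- c(d[1], hw, d[4])
    s <- matrix(colSums(array(aperm(tx, c(2, 1, 3)),
                              dim = c(hw, d[1] * d[4]))), d[1], d[4])
    cdim <- d[1]
    meps <- ca$m + self$conf$eps
    sg <- colSums(s * ca$g)
    dg <- s / rep(meps, each = cdim) -
      rep(sg / (cdim * meps^2), each = cdim)
    # dx += dg * x / g  (guard zero norms)
    gsafe <- pmax(ca$g, 1e-12)
    fac <- dg / gsafe
    fac_big <- fac[, rep(seq_len(d[4]), each = hw), drop = FALSE]
    dx <- dx + fac_big * xm
    array(dx, dim = d)
  }
  self
}

#' @keywords internal
layer_droppath <- function(rate = 0) {
  self <- new.env(parent = emptyenv())
  self$params <- list(); self$grads <- list()
  self$kind <- "droppath"
  self$rate <- rate
  self$fw <- function(x, train = FALSE) {
    if (!train || self$rate <= 0) {
      self$cache <- NULL
      return(x)
    }
    d <- dim(x)
    keep <- stats::rbinom(d[4], 1L, 1 - self$rate) / (1 - self$rate)
    mask <- array(rep(keep, each = prod(d[1:3])), dim = d)
    self$cache <- mask
    x * mask
  }
  self$bw <- function(dout) {
    if (is.null(self$cache)) dout else dout * self$cache
  }
  self
}

# ---- parameter plumbing -----------------------------------------------------

collect_layers <- function(node) {
  if (is.environment(node)) return(list(node))
  if (is.list(node)) return(unlist(lapply(node, collect_layers),
                                   recursive = FALSE))
  list()
}

n_parameters <- function(layers) {
  sum(vapply(layers, function(l) sum(lengths(l$params)), numeric(1)))
}

params_vector <- function(layers) {
  unlist(lapply(layers, function(l) lapply(l$params, as.numeric)),
         use.names = FALSE)
}

grads_vector <- function(layers) {
  unlist(lapply(layers, function(l) {
    lapply(names(l$params), function(nm) {
      g <- l$grads[[nm]]
      if (is.null(g)) numeric(length(l$params[[nm]])) else as.numeric(g)
    })
  }), use.names = FALSE)
}

set_params_vector <- function(layers, theta) {
  pos <- 0L
  for (l in layers) {
    for (nm in names(l$params)) {
      n <- length(l$params[[nm]])
      v <- theta[pos + seq_len(n)]
      attributes(v) <- attributes(l$params[[nm]])
      if (is.matrix(l$params[[nm]])) dim(v) <- dim(l$params[[nm]])
      l$params[[nm]] <- v
      pos <- pos + n
    }
  }
  invisible(layers)
}

zero_grads <- function(layers) {
  for (l in layers) l$grads <- list()
  invisible(layers)
}

# ---- optimizers -------------------------------------------------------------

make_optimizer <- function(layers, type = c("adam", "adamw"), lr = 1e-3,
                           weight_decay = 0, beta1 = 0.9, beta2 = 0.999,
                           eps = 1e-8) {
  type <- match.arg(type)
  st <- new.env(parent = emptyenv())
  st$type <- type; st$lr <- lr; st$wd <- weight_decay
  st$b1 <- beta1; st$b2 <- beta2; st$eps <- eps; st$t <- 0L
  st$m <- lapply(layers, function(l) lapply(l$params, function(p) p * 0))
  st$v <- st$m
  st$layers <- layers
  st
}

optimizer_step <- function(opt, lr = NULL) {
  if (is.null(lr)) lr <- opt$lr
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$b1^opt$t
  bc2 <- 1 - opt$b2^opt$t
  for (i in seq_along(opt$layers)) {
    l <- opt$layers[[i]]
    for (nm in names(l$params)) {
      g <- l$grads[[nm]]
      if (is.null(g)) next
      p <- l$params[[nm]]
      if (opt$type == "adam" && opt$wd > 0) g <- g + opt$wd * p
      m <- opt$b1 * opt$m[[i]][[nm]] + (1 - opt$b1) * g
      v <- opt$b2 * opt$v[[i]][[nm]] + (1 - opt$b2) * g * g
      opt$m[[i]][[nm]] <- m
      opt$v[[i]][[nm]] <- v
      step <- lr * (m / bc1) / (sqrt(v / bc2) + opt$eps)
      if (opt$type == "adamw" && opt$wd > 0) step <- step + lr * opt$wd * p
      l$params[[nm]] <- p - step
    }
  }
  invisible(opt)
}

cosine_lr <- function(lr0, epoch, max_epochs) {
  lr0 * 0.5 * (1 + cos(pi * (epoch - 1) / max(max_epochs - 1, 1)))
}

# ---- losses -----------------------------------------------------------------

mse_loss <- function(pred, target) {
  d <- pred - target
  list(loss = mean(d * d), grad = 2 * d / length(d))
}

bce_loss <- function(prob, target, eps = 1e-7) {
  p <- pmin(pmax(prob, eps), 1 - eps)
  loss <- -mean(target * log(p) + (1 - target) * log(1 - p))
  grad <- (p - target) / (p * (1 - p)) / length(p)
  list(loss = loss, grad = grad)
}
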