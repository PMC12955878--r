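mini_spec <- function(out_channels = 2L, head = "linear_grid") {
  unet_spec(in_channels = 3L, level_channels = c(4L, 5L, 6L, 7L, 8L),
            mixer_repeats = 2L, mixer_kernel = 3L,
            out_channels = out_channels, head = head)
}

test_that("network specification enforces its invariants", {
  expect_error(unet_spec(level_channels = c(4, 5, 6, 7)), "five")
  expect_error(unet_spec(level_channels = c(8, 8, 16, 32, 64)),
               "strictly increasing")
  expect_error(unet_spec(mixer_repeats = 0), "mixer_repeats")
  def <- unet_spec()
  expect_equal(def$level_channels, c(64L, 128L, 256L, 512L, 1024L))
  expect_equal(def$in_channels, 768L)
  expect_equal(def$mixer_repeats, 7L)
})

test_that("conv blocks preserve spatial dims and clamp at zero", {
  x <- rand_array(c(3, 80, 64), seed = 1)
  y <- conv_block(x, out_channels = 5)
  expect_equal(dim(y), c(5L, 80L, 64L, 1L))
  expect_gte(min(y), 0)
  zeroed <- conv_block(x, out_channels = 5,
                       weights = list(w = matrix(0, 27, 5), b = numeric(5)))
  expect_equal(max(abs(zeroed)), 0)
})

test_that("encoder halves spatial dims four times down to C5 x 5 x 4", {
  net <- build_unet(mini_spec(), seed = 1)
  x <- rand_array(c(3, 80, 64), seed = 2)
  enc <- unet_encoder_forward(net, x)
  expect_equal(dim(enc$bottleneck), c(8L, 5L, 4L, 1L))
  expect_equal(vapply(enc$skips, function(s) dim(s)[2], numeric(1)),
               c(80, 40, 20, 10))
  expect_equal(vapply(enc$skips, function(s) dim(s)[1], numeric(1)),
               c(4, 5, 6, 7))
  expect_error(unet_encoder_forward(net, rand_array(c(3, 78, 64))),
               "divisible by 16")
})

test_that("the attention gate bounds and shapes hold", {
  skip_t <- rand_array(c(4, 8, 8), seed = 3)
  gate_t <- rand_array(c(4, 8, 8), seed = 4)
  out <- msag_gate(skip_t, gate_t, seed = 5)
  expect_equal(dim(out$alpha), c(1L, 8L, 8L, 1L))
  expect_true(all(out$alpha > 0 & out$alpha < 1))
  expect_true(all(abs(out$gated[, , , 1]) <= abs(skip_t) + 1e-12))
  expect_equal(dim(out$gated), c(4L, 8L, 8L, 1L))
  expect_error(msag_gate(skip_t, rand_array(c(4, 6, 8))), "geometry error")
})

test_that("the ConvMixer bottleneck preserves shape across repeats", {
  x <- rand_array(c(6, 5, 4), seed = 6)
  y <- convmixer_bottleneck(x, repeats = 7, kernel = 7)
  expect_equal(dim(y), c(6L, 5L, 4L, 1L))
  y2 <- convmixer_bottleneck(x, repeats = 2, kernel = 3)
  expect_equal(dim(y2), dim(y))
  expect_error(convmixer_bottleneck(x, repeats = 0), "repeats")
})

test_that("forward passes are deterministic and head-bounded", {
  spec <- mini_spec(out_channels = 1L, head = "sigmoid_mask")
  net <- build_unet(spec, seed = 9)
  x <- rand_array(c(3, 16, 16), seed = 10)
  y1 <- unet_forward(net, x)
  y2 <- unet_forward(net, x)
  expect_identical(y1, y2)
  expect_equal(dim(y1), c(1L, 16L, 16L))
  expect_true(all(y1 > 0 & y1 < 1))
  expect_error(unet_forward(net, rand_array(c(5, 16, 16))), "config error")
})

test_that("parameter counts are a deterministic function of the spec", {
  n1 <- count_parameters(build_unet(mini_spec(), seed = 1))
  n2 <- count_parameters(build_unet(mini_spec(), seed = 99))
  expect_identical(n1, n2)
  bigger <- unet_spec(in_channels = 3, level_channels = c(8, 10, 12, 14, 16),
                      mixer_repeats = 2, mixer_kernel = 3, out_channels = 2,
                      head = "linear_grid")
  expect_gt(count_parameters(build_unet(bigger, seed = 1)), n1)
})

test_that("analytic gradients match finite differences on a 2-level miniature", {
  # two-level encoder/decoder with one attention-gated skip: the smallest
  # wiring that exercises conv blocks, pooling, the mixer pair, bilinear
  # upsampling, the gate, concatenation and both loss heads
  for (loss_kind in c("mse", "bce")) {
    set.seed(17)
    cb1 <- histex:::new_conv_block(2L, 3L)
    pool <- histex:::layer_maxpool2()
    cb2 <- histex:::new_conv_block(3L, 4L)
    mix <- histex:::new_convmixer(4L, 1L, 3L)
    ups <- histex:::layer_upsample2()
    upcb <- histex:::new_conv_block(4L, 3L)
    gate <- histex:::new_msag(3L)
    gate$cache_env <- new.env()
    dec <- histex:::new_conv_block(6L, 3L)
    head <- histex:::layer_conv2d(3L, 1L, k = 1L, pad = 0L)
    act <- histex:::layer_sigmoid()
    layers <- histex:::collect_layers(list(
      cb1, pool, cb2, mix, ups, upcb,
      gate[setdiff(names(gate), "cache_env")], dec, head, act))

    x <- rand_array(c(2, 8, 8, 2), seed = 18)
    target <- if (loss_kind == "mse") rand_array(c(1, 8, 8, 2), seed = 19)
              else array(rbinom(128, 1, 0.5), c(1, 8, 8, 2))
    fwbw <- function(do_bw = FALSE) {
      h1 <- histex:::cb_fw(cb1, x, TRUE)
      p <- pool$fw(h1, TRUE)
      h2 <- histex:::cb_fw(cb2, p, TRUE)
      m <- histex:::mixer_fw(mix, h2, TRUE)
      u <- histex:::cb_fw(upcb, ups$fw(m, TRUE), TRUE)
      g <- histex:::msag_fw(gate, h1, u, TRUE)
      cat2 <- histex:::concat_c(g$gated, u)
      d <- histex:::cb_fw(dec, cat2, TRUE)
      o <- head$fw(d, TRUE)
      if (loss_kind == "bce") o <- act$fw(o, TRUE)
      lo <- if (loss_kind == "mse") histex:::mse_loss(o, target)
            else histex:::bce_loss(o, target)
      if (do_bw) {
        dd <- array(lo$grad, dim = dim(o))
        if (loss_kind == "bce") dd <- act$bw(dd)
        dd <- head$bw(dd)
        dd <- histex:::cb_bw(dec, dd)
        dg <- dd[1:3, , , , drop = FALSE]
        du <- dd[4:6, , , , drop = FALSE]
        gb <- histex:::msag_bw(gate, dg)
        dd <- ups$bw(histex:::cb_bw(upcb, du + gb$dgate))
        dd <- histex:::mixer_bw(mix, dd)
        dd <- histex:::cb_bw(cb2, dd)
        dd <- pool$bw(dd) + gb$dskip
        histex:::cb_bw(cb1, dd)
      }
      lo$loss
    }
    histex:::zero_grads(layers)
    invisible(fwbw(do_bw = TRUE))
    g <- histex:::grads_vector(layers)
    theta <- histex:::params_vector(layers)
    set.seed(20 + nchar(loss_kind))
    idx <- sample(length(theta), 60)
    h <- 1e-5
    num <- vapply(idx, function(i) {
      tp <- theta; tp[i] <- tp[i] + h
      histex:::set_params_vector(layers, tp); lp <- fwbw()
      tp[i] <- tp[i] - 2 * h
      histex:::set_params_vector(layers, tp); lm <- fwbw()
      histex:::set_params_vector(layers, theta)
      (lp - lm) / (2 * h)
    }, numeric(1))
    rel <- abs(num - g[idx]) / pmax(abs(num) + abs(g[idx]), 1e-4)
    expect_lt(max(rel), 1e-4)
  }
})

test_that("training is seed-reproducible with a decreasing loss trend", {
  slide <- tiny_slide(seed = 30)
  asn <- map_spots_to_grid(slide$layout)
  norm <- normalize_counts(slide$counts)
  eg <- pad_to_model_grid(build_expression_grid(norm, asn,
                                                slide$smooth_genes))
  ext <- stub_extractor(output_dim = 3, pool_grid = 2)
  pspec <- patch_spec(side_px = 9, resize_to = 16)
  fm <- extract_features(crop_patches(slide$image, slide$layout, pspec),
                         ext, pspec)
  fmap <- assemble_feature_map(fm, asn)
  spec <- unet_spec(in_channels = 3, level_channels = c(4, 5, 6, 7, 8),
                    mixer_repeats = 1, mixer_kernel = 3,
                    out_channels = dim(eg$values)[1], head = "linear_grid")
  cfg <- training_config("mse", lr0 = 5e-3, max_epochs = 12, seed = 42)
  n1 <- train_unet(list(fmap), list(eg), spec, cfg)
  n2 <- train_unet(list(fmap), list(eg), spec, cfg)
  expect_identical(n1$loss_trace, n2$loss_trace)
  expect_lt(mean(tail(n1$loss_trace, 4)), mean(head(n1$loss_trace, 4)))
  expect_identical(unet_forward(n1, fmap$values),
                   unet_forward(n2, fmap$values))
})

test_that("LOOCV trains one fold per slide and never sees its test slide", {
  slides <- lapply(1:3, function(s) {
    sl <- tiny_slide(seed = 40 + s)
    asn <- map_spots_to_grid(sl$layout)
    norm <- normalize_counts(sl$counts)
    eg <- pad_to_model_grid(build_expression_grid(norm, asn,
                                                  sl$smooth_genes[1]))
    ext <- stub_extractor(output_dim = 3, pool_grid = 2)
    pspec <- patch_spec(side_px = 9, resize_to = 16)
    fm <- extract_features(crop_patches(sl$image, sl$layout, pspec),
                           ext, pspec)
    list(fmap = assemble_feature_map(fm, asn), eg = eg)
  })
  spec <- unet_spec(in_channels = 3, level_channels = c(4, 5, 6, 7, 8),
                    mixer_repeats = 1, mixer_kernel = 3, out_channels = 1,
                    head = "linear_grid")
  cfg <- training_config("mse", lr0 = 5e-3, max_epochs = 4, seed = 1)
  cv <- loocv_unet(lapply(slides, `[[`, "fmap"),
                   lapply(slides, `[[`, "eg"), spec, cfg)
  expect_length(cv$predictions, 3L)
  for (i in 1:3) {
    expect_equal(cv$folds[[i]]$test, i)
    expect_false(i %in% cv$folds[[i]]$train)
    expect_equal(sort(c(cv$folds[[i]]$test, cv$folds[[i]]$train)), 1:3)
    expect_equal(dim(cv$predictions[[i]]), c(1L, 16L, 16L))
  }
  expect_error(loocv_unet(slides[1], slides[1], spec, cfg), "protocol error")
})
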