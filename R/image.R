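#' Read an H&E image
#'
#' PNG and TIFF are supported. Returns an H x W x 3 numeric array in \[0, 1\];
#' grayscale images are expanded to three channels, alpha channels dropped.
#'
#' @param path image file path.
#' @return H x W x 3 array.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        stop("data error: the 'tiff' package is required for TIFF input")
      }
      tiff::readTIFF(path)
    },
    stop("format error: unsupported image extension '", ext, "'")
  )
  as_rgb_array(img)
}

as_rgb_array <- function(img) {
  if (length(dim(img)) == 2L) {
    img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  } else if (dim(img)[3] > 3L) {
    img <- img[, , 1:3, drop = FALSE]
  } else if (dim(img)[3] == 1L) {
    img <- array(rep(img[, , 1], 3L), dim = c(dim(img)[1:2], 3L))
  }
  img
}

#' Patch cropping / normalization specification
#'
#' @param side_px patch edge in source pixels. In whole-slide mode this is
#'   `round(scale_factor * fiducial_diameter)`; high-resolution Visium images
#'   use a fixed 30 px.
#' @param resize_to target resolution fed to the feature extractor
#'   (default 224).
#' @param mean,std per-channel normalization constants (ImageNet defaults).
#' @return a `patch_spec` list.
#' @export
patch_spec <- function(side_px = 30L, resize_to = 224L,
                       mean = c(0.485, 0.456, 0.406),
                       std = c(0.229, 0.224, 0.225)) {
  stopifnot(side_px >= 1L, resize_to >= 1L)
  structure(list(side_px = as.integer(side_px),
                 resize_to = as.integer(resize_to),
                 mean = mean, std = std),
            class = "patch_spec")
}

#' Patch side length from the fiducial spot diameter
#'
#' Whole-slide mode derives the crop size from the slide's fiducial spot
#' diameter and a user-supplied scale factor (the factor linking spot size to
#' the tissue neighbourhood each patch should cover).
#'
#' @param fiducial_diameter_px fiducial spot diameter in pixels.
#' @param scale_factor multiplicative factor (required; no universal default).
#' @return integer patch side.
#' @export
patch_side_from_fiducial <- function(fiducial_diameter_px, scale_factor) {
  as.integer(round(scale_factor * fiducial_diameter_px))
}

#' Crop spot-centred patches
#'
#' Crops one square `spec$side_px` patch centred on each in-tissue spot's
#' pixel centre. Crops that extend beyond the image border are zero-padded to
#' full size. Spot centres outside the image are an error.
#'
#' @param image H x W x 3 array in \[0, 1\].
#' @param layout a `spot_layout`.
#' @param spec a [patch_spec()].
#' @return named list of side x side x 3 arrays, one per in-tissue barcode,
#'   in layout order.
#' @export
crop_patches <- function(image, layout, spec = patch_spec()) {
  layout <- layout[layout$in_tissue, , drop = FALSE]
  h <- dim(image)[1]; w <- dim(image)[2]
  cx <- round(layout$pixel_x); cy <- round(layout$pixel_y)
  outside <- cx < 1 | cx > w | cy < 1 | cy > h
  if (any(outside)) {
    stop("reference error: spot centre(s) outside image for barcode(s) ",
         paste(utils::head(layout$barcode[outside], 4L), collapse = ", "))
  }
  s <- spec$side_px
  half_lo <- (s - 1L) %/% 2L
  patches <- vector("list", nrow(layout))
  for (i in seq_len(nrow(layout))) {
    r0 <- cy[i] - half_lo; r1 <- r0 + s - 1L
    c0 <- cx[i] - half_lo; c1 <- c0 + s - 1L
    patch <- array(0, dim = c(s, s, 3L))
    rr <- max(r0, 1L):min(r1, h)
    cc <- max(c0, 1L):min(c1, w)
    patch[rr - r0 + 1L, cc - c0 + 1L, ] <- image[rr, cc, , drop = FALSE]
    patches[[i]] <- patch
  }
  names(patches) <- layout$barcode
  patches
}

# Interpolation matrix for 1-d bilinear resampling with half-pixel centres
# (align_corners = FALSE convention). Rows = output pixels, cols = input.
bilinear_matrix <- function(n_in, n_out) {
  a <- matrix(0, n_out, n_in)
  scale <- n_in / n_out
  for (o in seq_len(n_out)) {
    src <- (o - 0.5) * scale - 0.5      # 0-based source coordinate
    src <- min(max(src, 0), n_in - 1)
    lo <- floor(src)
    frac <- src - lo
    hi <- min(lo + 1, n_in - 1)
    a[o, lo + 1] <- a[o, lo + 1] + (1 - frac)
    a[o, hi + 1] <- a[o, hi + 1] + frac
  }
  a
}

#' Bilinear image resize
#'
#' Separable bilinear resampling with half-pixel centre alignment; the same
#' kernel is used for patch preparation and the x2 decoder upsampling.
#'
#' @param img H x W or H x W x C numeric array.
#' @param h_out,w_out output size.
#' @return resized array.
#' @export
resize_bilinear <- function(img, h_out, w_out) {
  d <- dim(img)
  if (length(d) == 2L) {
    a_h <- bilinear_matrix(d[1], h_out)
    a_w <- bilinear_matrix(d[2], w_out)
    return(a_h %*% img %*% t(a_w))
  }
  out <- array(0, dim = c(h_out, w_out, d[3]))
  a_h <- bilinear_matrix(d[1], h_out)
  a_w <- bilinear_matrix(d[2], w_out)
  for (ch in seq_len(d[3])) out[, , ch] <- a_h %*% img[, , ch] %*% t(a_w)
  out
}

#' Prepare a patch for feature extraction
#'
#' Bilinear-resizes a 3-channel patch to `spec$resize_to` squared and applies
#' per-channel (x - mean) / std normalization with the standard ImageNet
#' constants.
#'
#' @param patch H x W x 3 array in \[0, 1\].
#' @param spec a [patch_spec()].
#' @return resize_to x resize_to x 3 normalized array.
#' @export
prepare_patch <- function(patch, spec = patch_spec()) {
  if (length(dim(patch)) != 3L || dim(patch)[3] != 3L) {
    stop("format error: patch must be H x W x 3")
  }
  r <- spec$resize_to
  out <- if (dim(patch)[1] == r && dim(patch)[2] == r) patch else
    resize_bilinear(patch, r, r)
  for (ch in 1:3) out[, , ch] <- (out[, , ch] - spec$mean[ch]) / spec$std[ch]
  out
}

#' Deterministic stub feature extractor
#'
#' A self-contained patch featuriser for pipelines and tests that must not
#' depend on downloaded pretrained weights: pooled colour statistics (an
#' 8 x 8 grid of per-channel means, per-channel standard deviations, and
#' horizontal/vertical gradient magnitudes) are pushed through a fixed,
#' internally seeded random linear map to `output_dim`. The same patch always
#' yields a bit-identical vector.
#'
#' @param output_dim feature dimension (default 768, matching pathology
#'   transformer embeddings).
#' @param pool_grid pooling grid resolution (default 8).
#' @return a `feature_extractor`: list with `output_dim` and `fn(patch)`.
#' @export
stub_extractor <- function(output_dim = 768L, pool_grid = 8L) {
  stat_dim <- 3L * pool_grid^2 + 3L + 2L
  # fixed projection, independent of the user's RNG state
  proj <- local({
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(760313L)
    matrix(stats::rnorm(stat_dim * output_dim) / sqrt(stat_dim),
           stat_dim, output_dim)
  })
  fn <- function(patch) {
    d <- dim(patch)
    g <- pool_grid
    rows <- pmin(ceiling(seq_len(d[1]) / d[1] * g), g)
    cols <- pmin(ceiling(seq_len(d[2]) / d[2] * g), g)
    pooled <- vapply(1:3, function(ch) {
      m <- rowsum(patch[, , ch], rows)
      m <- rowsum(t(m), cols)
      cnt <- tabulate(rows, g) %o% tabulate(cols, g)
      as.vector(t(m) / cnt)
    }, numeric(g * g))
    sds <- vapply(1:3, function(ch) stats::sd(patch[, , ch]), numeric(1))
    gx <- mean(abs(diff(patch[, , 1])))
    gy <- mean(abs(t(diff(t(patch[, , 1])))))
    stats_vec <- c(as.vector(pooled), sds, gx, gy)
    as.numeric(crossprod(proj, stats_vec))
  }
  structure(list(output_dim = as.integer(output_dim), fn = fn,
                 name = "stub"),
            class = "feature_extractor")
}

#' Wrap a user-supplied featuriser
#'
#' Adapter for external feature extractors (e.g. a pretrained pathology
#' transformer exported to R): supply a deterministic function mapping one
#' normalized patch to a numeric vector of fixed length.
#'
#' @param fn function(patch) -> numeric vector.
#' @param output_dim length of the returned vectors.
#' @param name label recorded in manifests.
#' @return a `feature_extractor`.
#' @export
feature_extractor <- function(fn, output_dim, name = "external") {
  structure(list(output_dim = as.integer(output_dim), fn = fn, name = name),
            class = "feature_extractor")
}

#' Extract a feature matrix from patches
#'
#' Runs the extractor on each prepared patch, producing the n_patches x C
#' feature matrix in patch order. The blank-patch feature vector (the
#' extractor applied to an all-zero normalized patch) is computed once and
#' attached; it fills spot-free grid cells downstream.
#'
#' @param patches named list of raw patches (as from [crop_patches()]).
#' @param extractor a `feature_extractor`.
#' @param spec a [patch_spec()] used by [prepare_patch()].
#' @return a `feature_matrix`: list with `features` (n x C matrix, rownames =
#'   barcodes), `patch_order` and `blank_vector`.
#' @export
extract_features <- function(patches, extractor = stub_extractor(),
                             spec = patch_spec()) {
  n <- length(patches)
  feats <- matrix(0, n, extractor$output_dim)
  for (i in seq_len(n)) {
    v <- tryCatch(extractor$fn(prepare_patch(patches[[i]], spec)),
                  error = function(e) {
                    stop("extractor failure on patch '", names(patches)[i],
                         "': ", conditionMessage(e))
                  })
    if (length(v) != extractor$output_dim) {
      stop("extractor failure on patch '", names(patches)[i],
           "': returned length ", length(v))
    }
    feats[i, ] <- v
  }
  rownames(feats) <- names(patches)
  blank <- array(0, dim = c(spec$resize_to, spec$resize_to, 3L))
  blank <- prepare_patch(blank, spec)
  structure(list(features = feats, patch_order = names(patches),
                 blank_vector = as.numeric(extractor$fn(blank))),
            class = "feature_matrix")
}
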