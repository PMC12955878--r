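#' Assemble a feature map from per-patch features
#'
#' Places each patch's feature vector at its spot's grid cell, yielding the
#' C x H x W network input that preserves the relative spot layout, then pads
#' the height by two blank rows so four 2 x 2 poolings divide evenly
#' (78 x 64 -> 80 x 64). Cells without a spot — including the padding rows —
#' hold the blank-patch feature vector.
#'
#' @param fm a `feature_matrix` from [extract_features()].
#' @param assignment a `grid_assignment`; every barcode in `fm` must be
#'   assigned.
#' @param pad apply [pad_to_model_grid()] (default `TRUE`).
#' @return a `feature_map`: list with `values` (C x H x W array), `validity`
#'   (H x W logical) and `blank_vector`.
#' @export
assemble_feature_map <- function(fm, assignment, pad = TRUE) {
  unknown <- setdiff(fm$patch_order, rownames(assignment$cell_of))
  if (length(unknown)) {
    stop("reference error: barcodes not in assignment: ",
         paste(utils::head(unknown, 4L), collapse = ", "))
  }
  h <- assignment$shape[1]; w <- assignment$shape[2]
  cdim <- ncol(fm$features)
  values <- array(fm$blank_vector, dim = c(cdim, h, w))
  validity <- matrix(FALSE, h, w)
  cells <- assignment$cell_of[fm$patch_order, , drop = FALSE]
  cell_lin <- (cells[, 1] - 1L) + h * (cells[, 2] - 1L)
  idx <- rep(seq_len(cdim), times = nrow(cells)) +
    cdim * rep(cell_lin, each = cdim)
  values[idx] <- as.vector(t(fm$features))
  validity[cells] <- TRUE
  out <- structure(list(values = values, validity = validity,
                        blank_vector = fm$blank_vector),
                   class = "feature_map")
  if (pad) out <- pad_to_model_grid(out)
  out
}

#' @export
print.feature_map <- function(x, ...) {
  d <- dim(x$values)
  cat("feature_map:", d[1], "channels x", d[2], "x", d[3],
      sprintf("(%d valid cells%s)\n", sum(x$validity),
              if (isTRUE(attr(x, "padded"))) ", padded" else ""))
  invisible(x)
}

#' Tile a whole-slide image into the model grid
#'
#' Pads the image with blank (white) pixels to a 5:4 aspect ratio, centred,
#' and tiles it row-major into 80 x 64 = 5,120 square patches. The patch side
#' is s = ceiling(max(H / 80, W / 64)) so the padded image is exactly
#' 80s x 64s and coverage is guaranteed for non-divisible sizes.
#'
#' @param image H x W x 3 array in \[0, 1\].
#' @param grid tiling grid (rows, cols), default c(80, 64).
#' @param materialize return pixel patches (default `TRUE`); set `FALSE` to
#'   get only the manifest.
#' @return list with `patches` (row-major list of s x s x 3 arrays, or
#'   `NULL`), and `manifest`: patch side `s`, pad offsets (top, left), padded
#'   size, original size and grid.
#' @export
tile_wsi <- function(image, grid = c(80L, 64L), materialize = TRUE) {
  h <- dim(image)[1]; w <- dim(image)[2]
  if (h < 1 || w < 1) stop("data error: empty image")
  s <- as.integer(ceiling(max(h / grid[1], w / grid[2])))
  hp <- grid[1] * s; wp <- grid[2] * s
  top <- (hp - h) %/% 2L; left <- (wp - w) %/% 2L
  padded <- array(1, dim = c(hp, wp, 3L))   # white = blank tissue
  padded[top + seq_len(h), left + seq_len(w), ] <- as_rgb_array(image)
  patches <- NULL
  if (materialize) {
    patches <- vector("list", grid[1] * grid[2])
    idx <- 1L
    for (gr in seq_len(grid[1])) {
      r0 <- (gr - 1L) * s
      for (gc in seq_len(grid[2])) {
        c0 <- (gc - 1L) * s
        patches[[idx]] <- padded[r0 + seq_len(s), c0 + seq_len(s), ,
                                 drop = FALSE]
        idx <- idx + 1L
      }
    }
  }
  list(patches = patches,
       manifest = list(s = s, pad_top = top, pad_left = left,
                       padded_size = c(hp, wp), original_size = c(h, w),
                       grid = as.integer(grid)))
}

#' Reconstruct the padded image from tiles
#'
#' Inverse of [tile_wsi()]: stitching the manifest's patches back gives the
#' padded image exactly.
#'
#' @param tiles result of [tile_wsi()] with materialized patches.
#' @return padded image array.
#' @export
untile_wsi <- function(tiles) {
  man <- tiles$manifest
  s <- man$s; grid <- man$grid
  out <- array(0, dim = c(man$padded_size, 3L))
  idx <- 1L
  for (gr in seq_len(grid[1])) {
    for (gc in seq_len(grid[2])) {
      out[(gr - 1L) * s + seq_len(s), (gc - 1L) * s + seq_len(s), ] <-
        tiles$patches[[idx]]
      idx <- idx + 1L
    }
  }
  out
}

#' High-resolution tiling by image segmentation
#'
#' Splits the image into an N x N block grid, tiles each block independently
#' with [tile_wsi()], and records each block's offset so per-block
#' predictions stitch into a (80 N) x (64 N) output geometry.
#'
#' @param image H x W x 3 array.
#' @param n_segments N >= 1.
#' @param grid per-block tiling grid, default c(80, 64).
#' @param materialize return pixel patches per block.
#' @return list with `blocks` (list of [tile_wsi()] results, row-major over
#'   the N x N blocks, each annotated with `block_row`, `block_col` and the
#'   stitched `offset` in output-grid cells) and `stitched_shape`.
#' @export
tile_wsi_highres <- function(image, n_segments = 1L, grid = c(80L, 64L),
                             materialize = TRUE) {
  n <- as.integer(n_segments)
  if (n < 1L) stop("parameter error: n_segments must be >= 1")
  h <- dim(image)[1]; w <- dim(image)[2]
  row_brk <- floor(seq(0, h, length.out = n + 1))
  col_brk <- floor(seq(0, w, length.out = n + 1))
  blocks <- vector("list", n * n)
  idx <- 1L
  for (br in seq_len(n)) {
    for (bc in seq_len(n)) {
      sub <- image[(row_brk[br] + 1):row_brk[br + 1],
                   (col_brk[bc] + 1):col_brk[bc + 1], , drop = FALSE]
      tl <- tile_wsi(sub, grid = grid, materialize = materialize)
      tl$block_row <- br; tl$block_col <- bc
      tl$offset <- c((br - 1L) * grid[1], (bc - 1L) * grid[2])
      blocks[[idx]] <- tl
      idx <- idx + 1L
    }
  }
  list(blocks = blocks,
       stitched_shape = c(grid[1] * n, grid[2] * n))
}

#' Stitch per-block prediction grids into the high-resolution output
#'
#' @param block_grids list of G x 80 x 64 arrays in the block order returned
#'   by [tile_wsi_highres()].
#' @param tiling the [tile_wsi_highres()] result.
#' @return G x (80 N) x (64 N) array.
#' @export
stitch_highres <- function(block_grids, tiling) {
  shp <- tiling$stitched_shape
  g <- dim(block_grids[[1]])[1]
  out <- array(0, dim = c(g, shp[1], shp[2]))
  for (i in seq_along(block_grids)) {
    off <- tiling$blocks[[i]]$offset
    d <- dim(block_grids[[i]])
    out[, off[1] + seq_len(d[2]), off[2] + seq_len(d[3])] <- block_grids[[i]]
  }
  out
}
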