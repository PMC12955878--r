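#' Map hexagonally arranged spots to a dense grid
#'
#' Visium spots are hexagonally packed: odd array rows are offset by one
#' column and columns advance in steps of two. Collapsing the column index by
#' parity packs the lattice into a dense matrix while preserving relative
#' spot proximity. A spot with array indices (r, c) lands in grid cell
#' (r + 1, phi(r, c)) where phi = c/2 + 1 for even r and (c + 1)/2 for odd r
#' (1-based, the convention of the printed 78 x 64 spot ID matrix; R arrays
#' are 1-based so the same numbers index the returned structures directly).
#'
#' @param layout a [spot_layout()]. Spots with `in_tissue = FALSE` are
#'   excluded before mapping.
#' @param n_rows,n_cols grid shape. Defaults infer the full-Visium dialect
#'   from the layout (78 rows, 64 columns when `array_col` reaches 127).
#' @param dialect `"visium_hex"` (default) applies the parity transform;
#'   `"rectangular"` passes array indices through unchanged (+1), an extension
#'   for legacy rectangular arrays.
#' @return A `grid_assignment`: list with `shape` (rows, cols), `cell_of`
#'   (n x 2 integer matrix of 1-based cells, rownames = barcodes) and
#'   `barcode_at` (rows x cols character matrix, `NA` for empty cells).
#' @examples
#' lay <- spot_layout(c("a", "b"), c(2, 1), c(4, 1), c(0, 0), c(0, 0))
#' asn <- map_spots_to_grid(lay, n_rows = 4, n_cols = 4)
#' asn$cell_of  # a -> (3, 3), b -> (2, 1)
#' @export
map_spots_to_grid <- function(layout, n_rows = NULL, n_cols = NULL,
                              dialect = c("visium_hex", "rectangular")) {
  dialect <- match.arg(dialect)
  validate_spot_layout(layout, hex = dialect == "visium_hex")
  layout <- layout[layout$in_tissue, , drop = FALSE]
  r <- layout$array_row
  c <- layout$array_col
  if (dialect == "visium_hex") {
    row <- r + 1L
    col <- ifelse(r %% 2L == 0L, c %/% 2L + 1L, (c + 1L) %/% 2L)
  } else {
    row <- r + 1L
    col <- c + 1L
  }
  if (is.null(n_rows)) n_rows <- max(row, 0L)
  if (is.null(n_cols)) n_cols <- max(col, 0L)
  if (length(row) && (max(row) > n_rows || max(col) > n_cols)) {
    stop("layout error: spot indices exceed grid shape ",
         n_rows, " x ", n_cols)
  }
  key <- (row - 1L) * n_cols + col
  if (anyDuplicated(key)) {
    d <- which(duplicated(key) | duplicated(key, fromLast = TRUE))
    stop("collision error: barcodes ",
         paste(utils::head(layout$barcode[d], 4L), collapse = ", "),
         " map to the same grid cell")
  }
  cell_of <- cbind(row = row, col = col)
  rownames(cell_of) <- layout$barcode
  barcode_at <- matrix(NA_character_, n_rows, n_cols)
  barcode_at[cbind(row, col)] <- layout$barcode
  structure(list(shape = c(n_rows, n_cols), cell_of = cell_of,
                 barcode_at = barcode_at),
            class = "grid_assignment")
}

#' @export
print.grid_assignment <- function(x, ...) {
  cat("grid_assignment:", nrow(x$cell_of), "spots on a",
      x$shape[1], "x", x$shape[2], "grid\n")
  invisible(x)
}

#' Build a spatial expression grid
#'
#' Places each panel gene's (normalized) expression value at its spot's grid
#' cell, producing the G x H x W spatial expression map used as regression
#' target. Cells without an assigned spot hold 0 and are marked invalid.
#'
#' @param counts gene-by-spot numeric matrix (rows = genes, columns = spot
#'   barcodes), already normalized (see [normalize_counts()]).
#' @param assignment a `grid_assignment` covering the counts' barcodes.
#' @param genes character vector of panel genes; all must be present in
#'   `counts` rownames.
#' @return An `expression_grid`: list with `values` (G x H x W array,
#'   dimnames gene names on the first axis), `gene_names`, and `validity`
#'   (H x W logical).
#' @export
build_expression_grid <- function(counts, assignment, genes = rownames(counts)) {
  counts <- as.matrix(counts)
  missing_genes <- setdiff(genes, rownames(counts))
  if (length(missing_genes)) {
    stop("missing-gene error: ",
         paste(utils::head(missing_genes, 5L), collapse = ", "),
         " absent from counts")
  }
  bcs <- rownames(assignment$cell_of)
  missing_bc <- setdiff(bcs, colnames(counts))
  if (length(missing_bc)) {
    stop("reference error: assigned barcodes absent from counts: ",
         paste(utils::head(missing_bc, 4L), collapse = ", "))
  }
  h <- assignment$shape[1]; w <- assignment$shape[2]
  g <- length(genes)
  values <- array(0, dim = c(g, h, w), dimnames = list(genes, NULL, NULL))
  validity <- matrix(FALSE, h, w)
  cells <- assignment$cell_of
  validity[cells] <- TRUE
  sub <- counts[genes, bcs, drop = FALSE]
  # linear index into (g, h, w) for gene k at cell (r, c): k + g*((r-1)+h*(c-1))
  cell_lin <- (cells[, 1] - 1L) + h * (cells[, 2] - 1L)
  idx <- rep(seq_len(g), times = length(bcs)) +
    g * rep(cell_lin, each = g)
  values[idx] <- as.vector(sub)
  structure(list(values = values, gene_names = genes, validity = validity),
            class = "expression_grid")
}

#' Recover the gene-by-spot matrix from an expression grid
#'
#' Exact inverse of [build_expression_grid()] on valid cells; used to report
#' grid-space network predictions per spot.
#'
#' @param grid an `expression_grid`.
#' @param assignment the `grid_assignment` the grid was built with.
#' @return gene-by-spot matrix with columns ordered like the assignment's
#'   barcodes.
#' @export
unmap_grid <- function(grid, assignment) {
  h <- assignment$shape[1]; w <- assignment$shape[2]
  dv <- dim(grid$values)
  if (dv[2] != h || dv[3] != w) {
    stop("geometry error: grid is ", dv[2], " x ", dv[3],
         " but assignment expects ", h, " x ", w)
  }
  bcs <- rownames(assignment$cell_of)
  g <- dv[1]
  out <- matrix(0, g, length(bcs),
                dimnames = list(grid$gene_names, bcs))
  cells <- assignment$cell_of
  cell_lin <- (cells[, 1] - 1L) + h * (cells[, 2] - 1L)
  idx <- rep(seq_len(g), times = length(bcs)) + g * rep(cell_lin, each = g)
  out[] <- grid$values[idx]
  out
}

#' Build a binary tumor mask grid
#'
#' Converts a barcode -> label table into the H x W {0,1} mask used as the
#' segmentation target: tumor spots 1, normal spots 0, unassigned cells 0.
#'
#' @param labels data.frame with columns `barcode` and `label`, or a named
#'   character vector (names = barcodes). Labels must be `"tumor"` or
#'   `"normal"` (case-insensitive).
#' @param assignment a `grid_assignment`; every labelled barcode must appear.
#' @return A `label_grid`: list with `values` (H x W 0/1 matrix) and
#'   `validity` (H x W logical, `TRUE` at labelled cells).
#' @export
build_tumor_mask <- function(labels, assignment) {
  if (is.data.frame(labels)) {
    bc <- as.character(labels$barcode)
    lb <- as.character(labels$label)
  } else {
    bc <- names(labels)
    lb <- as.character(labels)
  }
  lb <- tolower(lb)
  bad <- setdiff(unique(lb), c("tumor", "normal"))
  if (length(bad)) {
    stop("label error: unknown label(s) ", paste(bad, collapse = ", "))
  }
  unknown <- setdiff(bc, rownames(assignment$cell_of))
  if (length(unknown)) {
    stop("reference error: labelled barcodes not in assignment: ",
         paste(utils::head(unknown, 4L), collapse = ", "))
  }
  h <- assignment$shape[1]; w <- assignment$shape[2]
  values <- matrix(0, h, w)
  validity <- matrix(FALSE, h, w)
  cells <- assignment$cell_of[bc, , drop = FALSE]
  values[cells] <- as.numeric(lb == "tumor")
  validity[cells] <- TRUE
  structure(list(values = values, validity = validity),
            class = "label_grid")
}

#' Pad a grid to the model geometry
#'
#' The encoder performs four 2 x 2 max-pool halvings, so both spatial
#' dimensions must be divisible by 16. The 78-row spot grid is therefore
#' padded to 80 rows by appending two blank rows at the bottom (high row
#' indices); the same padding is applied to targets. Works on any grid whose
#' height is two short of a multiple of 16 (e.g. 14 -> 16 for reduced test
#' geometry). Padding an already-padded grid is an error.
#'
#' @param grid an `expression_grid`, `label_grid` or `feature_map`.
#' @param fill value for the padded rows: default 0 for expression/label
#'   grids; feature maps use their blank-patch vector (see
#'   [assemble_feature_map()]).
#' @return The same type of object with height + 2 and `validity` `FALSE`
#'   in the new rows; carries attribute `padded = TRUE`.
#' @export
pad_to_model_grid <- function(grid, fill = NULL) {
  if (isTRUE(attr(grid, "padded"))) {
    stop("geometry error: grid is already padded")
  }
  if (inherits(grid, "label_grid")) {
    h <- nrow(grid$values); w <- ncol(grid$values)
    check_padded_height(h)
    v <- rbind(grid$values, matrix(if (is.null(fill)) 0 else fill, 2, w))
    grid$values <- v
    grid$validity <- rbind(grid$validity, matrix(FALSE, 2, w))
  } else if (inherits(grid, "expression_grid")) {
    d <- dim(grid$values)
    check_padded_height(d[2])
    v <- array(0, dim = c(d[1], d[2] + 2L, d[3]),
               dimnames = dimnames(grid$values))
    v[, seq_len(d[2]), ] <- grid$values
    if (!is.null(fill)) v[, d[2] + 1:2, ] <- fill
    grid$values <- v
    grid$validity <- rbind(grid$validity, matrix(FALSE, 2, d[3]))
  } else if (inherits(grid, "feature_map")) {
    d <- dim(grid$values)
    check_padded_height(d[2])
    fill_vec <- if (is.null(fill)) grid$blank_vector else fill
    v <- array(fill_vec, dim = c(d[1], d[2] + 2L, d[3]))
    v[, seq_len(d[2]), ] <- grid$values
    grid$values <- v
    grid$validity <- rbind(grid$validity, matrix(FALSE, 2, d[3]))
  } else {
    stop("geometry error: unsupported grid type")
  }
  attr(grid, "padded") <- TRUE
  grid
}

check_padded_height <- function(h) {
  if ((h + 2L) %% 16L != 0L) {
    stop("geometry error: height ", h, " + 2 padding rows is not a multiple ",
         "of 16 (got ", h + 2L, ")")
  }
  invisible(h)
}

#' @export
print.expression_grid <- function(x, ...) {
  d <- dim(x$values)
  cat("expression_grid:", d[1], "genes x", d[2], "x", d[3],
      sprintf("(%d valid cells)\n", sum(x$validity)))
  invisible(x)
}

#' @export
print.label_grid <- function(x, ...) {
  cat("label_grid:", nrow(x$values), "x", ncol(x$values),
      sprintf("(%d valid, %d tumor)\n", sum(x$validity), sum(x$values)))
  invisible(x)
}
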