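#' Construct a spot layout
#'
#' A spot layout holds the per-spot geometry of a spatial transcriptomics
#' slide: the opaque spot barcode, its hexagonal array indices, its pixel
#' centre in the paired H&E image, and the in-tissue flag. On the 10x Visium
#' hexagonal lattice `array_row` and `array_col` always have equal parity
#' (even rows carry even columns, odd rows odd columns); the full-Visium
#' dialect uses rows 0..77 and columns 0..127.
#'
#' @param barcode character vector of unique spot identifiers.
#' @param array_row,array_col integer hexagonal array indices (0-based, as
#'   emitted by Space Ranger).
#' @param pixel_x,pixel_y numeric image coordinates of the spot centres, in
#'   pixels.
#' @param in_tissue logical; whether the spot overlaps tissue. Spots with
#'   `in_tissue = FALSE` are dropped before grid mapping.
#' @param check validate invariants (uniqueness, parity). Default `TRUE`.
#' @return A `data.frame` of class `spot_layout`.
#' @export
spot_layout <- function(barcode, array_row, array_col, pixel_x, pixel_y,
                        in_tissue = TRUE, check = TRUE) {
  out <- data.frame(
    barcode = as.character(barcode),
    array_row = as.integer(array_row),
    array_col = as.integer(array_col),
    pixel_x = as.numeric(pixel_x),
    pixel_y = as.numeric(pixel_y),
    in_tissue = rep_len(as.logical(in_tissue), length(barcode)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("spot_layout", "data.frame")
  if (check) validate_spot_layout(out)
  out
}

#' Validate a spot layout
#'
#' Checks barcode uniqueness, non-negative array indices and the hexagonal
#' parity constraint (row and column index of every spot share parity).
#'
#' @param layout a `spot_layout`.
#' @param hex enforce the hexagonal parity constraint. Set `FALSE` for
#'   rectangular (legacy ST) layouts.
#' @return `layout`, invisibly. Errors on violation.
#' @export
validate_spot_layout <- function(layout, hex = TRUE) {
  if (anyDuplicated(layout$barcode)) {
    dup <- layout$barcode[duplicated(layout$barcode)][1L]
    stop("layout error: duplicated barcode '", dup, "'")
  }
  if (any(layout$array_row < 0L) || any(layout$array_col < 0L)) {
    stop("layout error: negative array indices")
  }
  if (hex) {
    bad <- (layout$array_row %% 2L) != (layout$array_col %% 2L)
    if (any(bad)) {
      stop("layout error: parity violation for barcode(s) ",
           paste(utils::head(layout$barcode[bad], 3L), collapse = ", "),
           " (hex lattice requires array_row and array_col of equal parity)")
    }
  }
  invisible(layout)
}

#' Read a Space Ranger tissue-positions table
#'
#' Supports both dialects: the header-less `tissue_positions_list.csv`
#' (columns barcode, in_tissue, array_row, array_col, pxl_row_in_fullres,
#' pxl_col_in_fullres) and the headered `tissue_positions.csv`. Pixel row maps
#' to `pixel_y`, pixel column to `pixel_x`.
#'
#' @param path CSV file path.
#' @param hex validate the hexagonal parity constraint (default `TRUE`).
#' @return A `spot_layout`.
#' @export
read_tissue_positions <- function(path, hex = TRUE) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("barcode", first, ignore.case = TRUE)
  df <- utils::read.csv(path, header = has_header,
                        stringsAsFactors = FALSE)
  if (!has_header) {
    if (ncol(df) != 6L) stop("data error: expected 6 columns in ", path)
    names(df) <- c("barcode", "in_tissue", "array_row", "array_col",
                   "pxl_row_in_fullres", "pxl_col_in_fullres")
  } else {
    names(df) <- tolower(names(df))
  }
  req <- c("barcode", "in_tissue", "array_row", "array_col")
  if (!all(req %in% names(df))) {
    stop("data error: missing columns ",
         paste(setdiff(req, names(df)), collapse = ", "), " in ", path)
  }
  rowcol <- grep("pxl.*row", names(df), value = TRUE)[1L]
  colcol <- grep("pxl.*col", names(df), value = TRUE)[1L]
  if (is.na(rowcol) || is.na(colcol)) {
    stop("data error: missing pixel coordinate columns in ", path)
  }
  out <- spot_layout(df$barcode, df$array_row, df$array_col,
                     pixel_x = df[[colcol]], pixel_y = df[[rowcol]],
                     in_tissue = df$in_tissue != 0, check = FALSE)
  validate_spot_layout(out, hex = hex)
  out
}

#' Write a tissue-positions table
#'
#' Writes the headered Space Ranger dialect consumed by
#' [read_tissue_positions()].
#'
#' @param layout a `spot_layout`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_tissue_positions <- function(layout, path) {
  df <- data.frame(
    barcode = layout$barcode,
    in_tissue = as.integer(layout$in_tissue),
    array_row = layout$array_row,
    array_col = layout$array_col,
    pxl_row_in_fullres = layout$pixel_y,
    pxl_col_in_fullres = layout$pixel_x
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
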