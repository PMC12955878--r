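#' Read a MatrixMarket count triplet with barcode/feature lists
#'
#' Standard Space Ranger-style trio: `matrix.mtx` (genes x spots sparse
#' triplets), `features.tsv` (gene IDs in column 1, optional symbol in
#' column 2) and `barcodes.tsv` (one barcode per line).
#'
#' @param mtx,features,barcodes file paths. `features`/`barcodes` default to
#'   files of those names next to `mtx`.
#' @param use_symbol use the second features column as rownames if present.
#' @return A `dgCMatrix` (genes x spots) with dimnames.
#' @export
read_counts_mtx <- function(mtx,
                            features = file.path(dirname(mtx), "features.tsv"),
                            barcodes = file.path(dirname(mtx), "barcodes.tsv"),
                            use_symbol = FALSE) {
  m <- methods::as(Matrix::readMM(mtx), "CsparseMatrix")
  feat <- utils::read.delim(features, header = FALSE,
                            stringsAsFactors = FALSE)
  bcs <- readLines(barcodes)
  if (nrow(feat) != nrow(m) || length(bcs) != ncol(m)) {
    stop("data error: matrix is ", nrow(m), " x ", ncol(m), " but ",
         nrow(feat), " features / ", length(bcs), " barcodes supplied")
  }
  rn <- if (use_symbol && ncol(feat) >= 2L) feat[[2]] else feat[[1]]
  dimnames(m) <- list(make.unique(as.character(rn)), bcs)
  m
}

#' Write counts as a MatrixMarket triplet trio
#'
#' @param counts gene-by-spot matrix (dense or sparse) with dimnames.
#' @param dir output directory; writes `matrix.mtx`, `features.tsv`,
#'   `barcodes.tsv`.
#' @return `dir`, invisibly.
#' @export
write_counts_mtx <- function(counts, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  m <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                               "generalMatrix"), "CsparseMatrix")
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  utils::write.table(data.frame(rownames(counts), rownames(counts)),
                     file.path(dir, "features.tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Read a dense delimited gene-by-spot table
#'
#' Rows = genes (first column gene names), columns = spot barcodes.
#'
#' @param path TSV/CSV path; separator inferred from extension.
#' @return numeric matrix with dimnames.
#' @export
read_counts_dense <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                          check.names = FALSE, stringsAsFactors = FALSE)
  as.matrix(df)
}

#' Normalize spot counts
#'
#' Library-size normalization per spot: counts are scaled so every spot's
#' total equals `scale_factor` (default 10,000) and then transformed with the
#' natural log1p. Spots whose total is zero are left as zeros and counted in
#' a warning.
#'
#' @param raw non-negative gene-by-spot matrix (dense or sparse).
#' @param scale_factor per-spot library-size target.
#' @return matrix of the same shape and dimnames (dense).
#' @examples
#' normalize_counts(matrix(c(0, 4), 1, 2, dimnames = list("g", c("a", "b"))))
#' @export
normalize_counts <- function(raw, scale_factor = 1e4) {
  m <- as.matrix(raw)
  if (any(m < 0)) stop("data error: negative counts")
  tot <- colSums(m)
  zero <- tot == 0
  if (any(zero)) {
    warning(sum(zero), " all-zero spot(s) left as zeros")
    tot[zero] <- 1
  }
  out <- log1p(sweep(m, 2L, tot / scale_factor, "/"))
  dimnames(out) <- dimnames(m)
  out
}

#' Write a grid array with a JSON sidecar
#'
#' Serializes an `expression_grid`, `label_grid` or `feature_map` as an RDS
#' array plus a JSON sidecar (`<path>.json`) recording the indexing
#' convention, axes and gene panel, so downstream consumers need not guess
#' the layout.
#'
#' @param grid the grid object.
#' @param path output `.rds` path.
#' @return `path`, invisibly.
#' @export
write_grid <- function(grid, path) {
  saveRDS(grid, path)
  meta <- list(
    class = class(grid)[1],
    dim = dim(if (is.matrix(grid$values)) grid$values else grid$values),
    convention = "rows/cols 1-based; channel axis first for 3-d arrays; row 1 = array_row 0",
    padded = isTRUE(attr(grid, "padded")),
    gene_names = grid$gene_names,
    n_valid = sum(grid$validity)
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Read a grid written by [write_grid()]
#' @param path `.rds` path.
#' @return the grid object.
#' @export
read_grid <- function(path) readRDS(path)
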