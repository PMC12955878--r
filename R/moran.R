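#' Binary k-nearest-neighbour spatial weights
#'
#' Builds the binary spatial weight matrix used for spatial autocorrelation:
#' each spot gives weight 1 to its `k` nearest neighbours (Euclidean distance,
#' row-wise, so the matrix may be asymmetric) and 0 elsewhere. Distance ties
#' are broken by ascending spot index. No self-neighbours.
#'
#' @param coords n x 2 numeric matrix of spot positions. For hex lattices use
#'   [hex_coords()] so neighbour distances are uniform in array space.
#' @param k number of neighbours (default 15).
#' @return A `spatial_weights`: list with `n`, `k`, `neighbors` (list of
#'   integer index vectors) and `total_weight` (sum of all weights, n * k).
#' @export
knn_weights <- function(coords, k = 15L) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 2L) stop("parameter error: need at least 2 spots")
  if (k >= n) stop("parameter error: k (", k, ") must be < n (", n, ")")
  d2 <- as.matrix(stats::dist(coords))^2
  diag(d2) <- Inf
  neighbors <- lapply(seq_len(n), function(i) {
    # order() is a stable sort on ties, so equal distances resolve to the
    # lower index
    order(d2[i, ])[seq_len(k)]
  })
  structure(list(n = n, k = as.integer(k), neighbors = neighbors,
                 total_weight = n * as.integer(k)),
            class = "spatial_weights")
}

#' Array-space hex coordinates
#'
#' Maps Visium array indices to 2-D positions on which all six hexagonal
#' neighbours are equidistant: x = array_col / 2, y = array_row * sqrt(3) / 2,
#' scaled so the neighbour distance is 1.
#'
#' @param layout a `spot_layout`.
#' @return n x 2 matrix of coordinates.
#' @export
hex_coords <- function(layout) {
  cbind(x = layout$array_col / 2, y = layout$array_row * sqrt(3) / 2)
}

#' Moran's I spatial autocorrelation statistic
#'
#' I = (N / S) * sum_ij w_ij (x_i - xbar)(x_j - xbar) / sum_i (x_i - xbar)^2,
#' with S the sum of all weights. Positive I indicates spatially smooth
#' fields; the expectation under random arrangement is -1/(N-1).
#'
#' @param values numeric vector, one value per spatial unit.
#' @param weights a `spatial_weights` over the same units.
#' @return Moran's I (scalar).
#' @export
morans_i <- function(values, weights) {
  n <- weights$n
  if (length(values) != n) stop("geometry error: length(values) != n")
  x <- values - mean(values)
  ss <- sum(x^2)
  if (ss == 0) stop("undefined-statistic error: values have zero variance")
  # sum_ij w_ij x_i x_j with binary row-wise k-NN weights
  cross <- sum(x * vapply(weights$neighbors,
                          function(nb) sum(x[nb]), numeric(1)))
  (n / weights$total_weight) * cross / ss
}

#' P-value for Moran's I
#'
#' One-sided (positive autocorrelation). `analytic_z` uses the normality
#' approximation with E\[I\] = -1/(N-1) and the standard variance under
#' randomisation-free normality; `permutation` permutes values and reports
#' (1 + #\{I_perm >= I_obs\}) / (1 + n_perm).
#'
#' @param values,weights as in [morans_i()].
#' @param method `"analytic_z"` (default) or `"permutation"`.
#' @param n_perm permutation count (permutation method only).
#' @param seed integer seed for the permutation method.
#' @return list with `i` (the statistic) and `p`.
#' @export
morans_p <- function(values, weights, method = c("analytic_z", "permutation"),
                     n_perm = 999L, seed = 1L) {
  method <- match.arg(method)
  i_obs <- morans_i(values, weights)
  n <- weights$n
  if (method == "analytic_z") {
    mom <- weight_moments(weights)
    s0 <- mom$s0; s1 <- mom$s1; s2 <- mom$s2
    e_i <- -1 / (n - 1)
    var_i <- (n^2 * s1 - n * s2 + 3 * s0^2) / ((n^2 - 1) * s0^2) - e_i^2
    z <- (i_obs - e_i) / sqrt(var_i)
    p <- stats::pnorm(z, lower.tail = FALSE)
  } else {
    if (n_perm < 1L) stop("parameter error: n_perm must be >= 1")
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    exceed <- 0L
    for (b in seq_len(n_perm)) {
      ip <- morans_i(sample(values), weights)
      if (ip >= i_obs) exceed <- exceed + 1L
    }
    p <- (1 + exceed) / (1 + n_perm)
  }
  list(i = i_obs, p = p)
}

weights_matrix <- function(weights) {
  n <- weights$n
  w <- matrix(0, n, n)
  for (i in seq_len(n)) w[i, weights$neighbors[[i]]] <- 1
  w
}

# S0, S1, S2 of a binary row-wise k-NN weight matrix without materialising it:
# S1 = (1/2) sum_ij (w_ij + w_ji)^2 counts mutual unordered pairs as 4 and
# one-directional pairs as 1; S2 uses row degree k and in-degrees.
weight_moments <- function(weights) {
  n <- weights$n
  k <- weights$k
  edges <- cbind(rep(seq_len(n), each = k), unlist(weights$neighbors))
  key <- (edges[, 1] - 1) * n + edges[, 2]
  rev_key <- (edges[, 2] - 1) * n + edges[, 1]
  mutual_directed <- sum(key %in% rev_key)   # counts each mutual pair twice
  m <- mutual_directed / 2
  s_single <- n * k - mutual_directed        # one-directional ordered edges
  s1 <- 4 * m + s_single
  indeg <- tabulate(edges[, 2], nbins = n)
  s2 <- sum((k + indeg)^2)
  list(s0 = n * k, s1 = s1, s2 = s2)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

#' Score all genes on one slide
#'
#' Computes Moran's I and its p-value for every gene of a normalized counts
#' matrix on one slide.
#'
#' @param counts gene-by-spot normalized matrix.
#' @param layout the slide's `spot_layout` (in-tissue spots, column order of
#'   `counts`).
#' @param k neighbour count for the binary weights (default 15).
#' @param sample slide identifier recorded in the result.
#' @param method p-value method, see [morans_p()].
#' @return data.frame with columns `gene`, `i_statistic`, `p_value`, `sample`.
#'   Genes with zero variance get `NA` statistics.
#' @export
moran_scan <- function(counts, layout, k = 15L, sample = "sample1",
                       method = "analytic_z") {
  counts <- as.matrix(counts)
  layout <- layout[layout$in_tissue, , drop = FALSE]
  if (ncol(counts) != nrow(layout)) {
    stop("geometry error: counts columns != layout spots")
  }
  w <- knn_weights(hex_coords(layout), k = k)
  res <- lapply(rownames(counts), function(g) {
    x <- counts[g, ]
    if (stats::var(x) == 0) return(c(NA_real_, NA_real_))
    mp <- morans_p(x, w, method = method)
    c(mp$i, mp$p)
  })
  res <- do.call(rbind, res)
  data.frame(gene = rownames(counts), i_statistic = res[, 1],
             p_value = res[, 2], sample = sample,
             stringsAsFactors = FALSE)
}

#' Select spatially variable target genes
#'
#' Keeps genes whose median Moran's I across samples exceeds `i_cut` and
#' whose p-values satisfy the `p_mode` criterion: `"median"` (default)
#' requires the median p across samples < `p_cut`; `"all"` requires p <
#' `p_cut` in every sample the gene was scored in. Ordering is deterministic:
#' descending median I, then gene name.
#'
#' @param results data.frame of per-sample scores as returned by
#'   [moran_scan()] (possibly row-bound over samples).
#' @param p_cut p-value threshold (default 0.01).
#' @param i_cut Moran's I threshold, strict inequality (default 0.4).
#' @param p_mode `"median"` or `"all"`.
#' @return A `gene_panel`: data.frame with columns `gene`, `provenance`
#'   (here `"autocorrelation"`) and `median_i`.
#' @export
select_target_genes <- function(results, p_cut = 0.01, i_cut = 0.4,
                                p_mode = c("median", "all")) {
  p_mode <- match.arg(p_mode)
  results <- results[!is.na(results$i_statistic), , drop = FALSE]
  med_i <- tapply(results$i_statistic, results$gene, stats::median)
  p_ok <- if (p_mode == "median") {
    tapply(results$p_value, results$gene, stats::median) < p_cut
  } else {
    tapply(results$p_value, results$gene, function(p) all(p < p_cut))
  }
  keep <- names(med_i)[med_i > i_cut & p_ok[names(med_i)]]
  if (!length(keep)) {
    warning("empty selection: no gene passes i_cut = ", i_cut,
            ", p_cut = ", p_cut)
  }
  ord <- order(-med_i[keep], keep)
  panel <- data.frame(gene = keep[ord],
                      provenance = rep("autocorrelation", length(keep)),
                      median_i = as.numeric(med_i[keep][ord]),
                      stringsAsFactors = FALSE)
  class(panel) <- c("gene_panel", "data.frame")
  panel
}

#' Augment a gene panel with marker genes
#'
#' Unions lineage markers into the prediction targets. Markers already in the
#' panel are not duplicated; markers absent from the detected-gene universe
#' are dropped with a warning.
#'
#' @param panel a `gene_panel`.
#' @param markers character vector of marker gene names.
#' @param universe character vector of detected genes.
#' @return the augmented `gene_panel` (markers tagged `"marker"`, appended
#'   after the autocorrelation-selected genes in given order).
#' @export
augment_with_markers <- function(panel, markers, universe) {
  markers <- unique(markers)
  absent <- setdiff(markers, universe)
  if (length(absent)) {
    warning("marker(s) not detected, dropped: ",
            paste(absent, collapse = ", "))
  }
  add <- setdiff(intersect(markers, universe), panel$gene)
  if (length(add)) {
    panel <- rbind(panel,
                   data.frame(gene = add, provenance = "marker",
                              median_i = NA_real_,
                              stringsAsFactors = FALSE))
  }
  class(panel) <- c("gene_panel", "data.frame")
  panel
}

#' Write / read a gene panel as two-column TSV
#' @param panel a `gene_panel`.
#' @param path TSV path.
#' @return `path` (write) or a `gene_panel` (read).
#' @export
write_gene_panel <- function(panel, path) {
  utils::write.table(panel[, c("gene", "provenance")], path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_gene_panel
#' @export
read_gene_panel <- function(path) {
  panel <- utils::read.delim(path, stringsAsFactors = FALSE)
  panel$median_i <- rep(NA_real_, nrow(panel))
  class(panel) <- c("gene_panel", "data.frame")
  panel
}
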