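#' Synthetic slide configuration
#'
#' Defaults emulate a full 10x Visium capture area: a 78-row hexagonal
#' lattice with 64 spots per row (4,992 spots), a gene panel in which a
#' fraction of genes carries smooth spatial structure (Gaussian-kernel
#' smoothed log-intensity fields) and the rest are spatially unstructured,
#' one blob-shaped tumor region, and a paired image whose local intensity
#' around each spot is an affine function of a designated gene's expression.
#'
#' @param n_rows hex rows (default 78).
#' @param cols_per_row spots per row (default 64).
#' @param n_genes total genes (default 100).
#' @param smooth_fraction fraction of genes with spatial structure
#'   (default 0.1).
#' @param bandwidth Gaussian smoothing bandwidth in grid cells (default 3;
#'   0 degenerates to i.i.d. noise).
#' @param noise_sd per-spot log-intensity noise added to smooth fields
#'   (default 0.3).
#' @param base_log_mean log mean intensity of the Poisson counts (default
#'   log(5)).
#' @param field_sd amplitude of the smooth spatial fields on the log scale
#'   (default 1).
#' @param tumor_center,tumor_radius blob centre (grid row, col) and radius in
#'   grid cells; defaults centre of the grid and a quarter of its height.
#' @param image_px_per_spot pixel spacing between neighbouring spots
#'   (default 10).
#' @param image_noise_sd pixel texture noise (default 0.02).
#' @param seed RNG seed; every generator is a pure function of config + seed.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_rows = 78L, cols_per_row = 64L, n_genes = 100L,
                         smooth_fraction = 0.1, bandwidth = 3,
                         noise_sd = 0.3, base_log_mean = log(5),
                         field_sd = 1, tumor_center = NULL,
                         tumor_radius = NULL, image_px_per_spot = 10L,
                         image_noise_sd = 0.02, seed = 1L) {
  stopifnot(n_rows >= 1, cols_per_row >= 1, n_genes >= 1,
            smooth_fraction >= 0, smooth_fraction <= 1, bandwidth >= 0)
  if (is.null(tumor_center)) tumor_center <- c(n_rows / 2, cols_per_row / 2)
  if (is.null(tumor_radius)) tumor_radius <- n_rows / 4
  structure(list(n_rows = as.integer(n_rows),
                 cols_per_row = as.integer(cols_per_row),
                 n_genes = as.integer(n_genes),
                 smooth_fraction = smooth_fraction, bandwidth = bandwidth,
                 noise_sd = noise_sd, base_log_mean = base_log_mean,
                 field_sd = field_sd, tumor_center = tumor_center,
                 tumor_radius = tumor_radius,
                 image_px_per_spot = as.integer(image_px_per_spot),
                 image_noise_sd = image_noise_sd, seed = as.integer(seed)),
            class = "synth_config")
}

#' Generate a hexagonal spot layout
#'
#' Row r carries `cols_per_row` spots at array columns r %% 2, r %% 2 + 2,
#' ..., so row and column parity always agree; pixel centres lie on a
#' triangular lattice with constant nearest-neighbour distance
#' `image_px_per_spot`.
#'
#' @param cfg a [synth_config()].
#' @return a `spot_layout` with `n_rows * cols_per_row` spots.
#' @export
make_layout <- function(cfg) {
  rows <- rep(seq_len(cfg$n_rows) - 1L, each = cfg$cols_per_row)
  cols <- as.vector(vapply(seq_len(cfg$n_rows) - 1L, function(r) {
    as.integer(r %% 2L + 2L * (seq_len(cfg$cols_per_row) - 1L))
  }, integer(cfg$cols_per_row)))
  d <- cfg$image_px_per_spot
  margin <- 2L * d
  spot_layout(
    barcode = sprintf("spot-%05d", seq_along(rows)),
    array_row = rows, array_col = cols,
    pixel_x = margin + cols / 2 * d,
    pixel_y = margin + rows * sqrt(3) / 2 * d,
    in_tissue = TRUE
  )
}

gauss_kernel_1d <- function(bw) {
  if (bw <= 0) return(1)
  r <- max(1L, ceiling(3 * bw))
  k <- exp(-(seq(-r, r))^2 / (2 * bw^2))
  k / sum(k)
}

# separable truncated-Gaussian smoothing of a matrix (replicate-pad edges)
smooth_matrix <- function(m, bw) {
  if (bw <= 0) return(m)
  k <- gauss_kernel_1d(bw)
  r <- (length(k) - 1L) %/% 2L
  conv1 <- function(v) {
    vp <- c(rep(v[1], r), v, rep(v[length(v)], r))
    stats::filter(vp, k, sides = 2)[(r + 1):(r + length(v))]
  }
  m <- apply(m, 2L, conv1)
  t(apply(t(m), 2L, conv1))
}

#' Generate synthetic spot counts
#'
#' Smooth genes are Gaussian-kernel-smoothed white-noise log-intensity
#' fields (plus i.i.d. noise) exponentiated into Poisson rates; noise genes
#' are spatially unstructured. The designated smooth genes are recorded as
#' ground truth for selection benchmarks.
#'
#' @param cfg a [synth_config()].
#' @param layout the slide layout from [make_layout()].
#' @return list with `counts` (genes x spots integer matrix), `smooth_genes`
#'   (character) and `log_fields` (genes x spots latent log-intensities).
#' @export
make_expression <- function(cfg, layout) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed)
  asn <- map_spots_to_grid(layout)
  n <- nrow(layout)
  genes <- sprintf("gene%03d", seq_len(cfg$n_genes))
  n_smooth <- round(cfg$smooth_fraction * cfg$n_genes)
  smooth_genes <- genes[seq_len(n_smooth)]
  cells <- asn$cell_of[layout$barcode, , drop = FALSE]
  fields <- matrix(0, cfg$n_genes, n, dimnames = list(genes, layout$barcode))
  for (g in seq_len(cfg$n_genes)) {
    if (g <= n_smooth) {
      noise <- matrix(stats::rnorm(prod(asn$shape)), asn$shape[1],
                      asn$shape[2])
      sm <- smooth_matrix(noise, cfg$bandwidth)
      f <- sm[cells]
      f <- (f - mean(f)) / stats::sd(f) * cfg$field_sd
      fields[g, ] <- f + stats::rnorm(n, sd = cfg$noise_sd)
    } else {
      fields[g, ] <- stats::rnorm(n, sd = cfg$field_sd)
    }
  }
  lambda <- exp(cfg$base_log_mean + fields)
  counts <- matrix(stats::rpois(length(lambda), lambda), nrow(lambda),
                   dimnames = dimnames(fields))
  list(counts = counts, smooth_genes = smooth_genes, log_fields = fields)
}

#' Generate blob tumor labels
#'
#' Spots within `tumor_radius` of `tumor_center` (grid-cell coordinates) are
#' labelled tumor, the rest normal.
#'
#' @param cfg a [synth_config()].
#' @param layout the slide layout.
#' @return data.frame with columns `barcode`, `label`.
#' @export
make_tumor_labels <- function(cfg, layout) {
  asn <- map_spots_to_grid(layout)
  cells <- asn$cell_of[layout$barcode, , drop = FALSE]
  d2 <- (cells[, 1] - cfg$tumor_center[1])^2 +
    (cells[, 2] - cfg$tumor_center[2])^2
  data.frame(barcode = layout$barcode,
             label = ifelse(d2 <= cfg$tumor_radius^2, "tumor", "normal"),
             stringsAsFactors = FALSE)
}

#' Generate a paired synthetic H&E-like image
#'
#' Each spot's local square neighbourhood gets a mean intensity that is an
#' affine function of the designated gene's latent log-intensity (scaled to
#' \[0.2, 0.8\]) plus pixel texture noise, so patch-mean intensity correlates
#' with expression by construction (correlation 1 at zero noise).
#'
#' @param cfg a [synth_config()].
#' @param layout the slide layout.
#' @param expression result of [make_expression()].
#' @param gene driving gene (default: first smooth gene, or first gene).
#' @return list with `image` (H x W x 3 array in \[0, 1\]) and `gene`.
#' @export
make_image <- function(cfg, layout, expression, gene = NULL) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed + 1L)
  if (is.null(gene)) {
    gene <- if (length(expression$smooth_genes)) {
      expression$smooth_genes[1]
    } else rownames(expression$log_fields)[1]
  }
  v <- expression$log_fields[gene, layout$barcode]
  vr <- range(v)
  vn <- if (diff(vr) > 0) (v - vr[1]) / diff(vr) else rep(0.5, length(v))
  d <- cfg$image_px_per_spot
  h <- ceiling(max(layout$pixel_y) + 2 * d)
  w <- ceiling(max(layout$pixel_x) + 2 * d)
  base <- matrix(0.5, h, w)
  half <- d %/% 2L
  cx <- round(layout$pixel_x); cy <- round(layout$pixel_y)
  for (i in seq_along(v)) {
    rr <- max(cy[i] - half, 1L):min(cy[i] + half, h)
    cc <- max(cx[i] - half, 1L):min(cx[i] + half, w)
    base[rr, cc] <- 0.2 + 0.6 * vn[i]
  }
  if (cfg$image_noise_sd > 0) {
    base <- base + matrix(stats::rnorm(h * w, sd = cfg$image_noise_sd), h, w)
  }
  base <- pmin(pmax(base, 0), 1)
  img <- array(0, dim = c(h, w, 3L))
  img[, , 1] <- base
  img[, , 2] <- base * 0.75   # eosin-ish tint
  img[, , 3] <- base * 0.9
  list(image = img, gene = gene)
}

#' Generate a complete synthetic slide
#'
#' Convenience wrapper bundling layout, counts, tumor labels and image.
#'
#' @param cfg a [synth_config()].
#' @return list with `layout`, `counts`, `smooth_genes`, `log_fields`,
#'   `labels`, `image`, `image_gene`, `config`.
#' @export
make_synthetic_slide <- function(cfg = synth_config()) {
  layout <- make_layout(cfg)
  expr <- make_expression(cfg, layout)
  labels <- make_tumor_labels(cfg, layout)
  img <- make_image(cfg, layout, expr)
  list(layout = layout, counts = expr$counts,
       smooth_genes = expr$smooth_genes, log_fields = expr$log_fields,
       labels = labels, image = img$image, image_gene = img$gene,
       config = cfg)
}

#' Write a synthetic slide in the on-disk formats the readers consume
#'
#' Positions CSV, MatrixMarket counts trio, PNG image and a labels CSV.
#'
#' @param slide result of [make_synthetic_slide()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_synthetic_slide <- function(slide, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_tissue_positions(slide$layout, file.path(dir, "tissue_positions.csv"))
  write_counts_mtx(slide$counts, file.path(dir, "counts"))
  png::writePNG(slide$image, file.path(dir, "image.png"))
  utils::write.csv(slide$labels, file.path(dir, "labels.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}

smooth_field_grid <- function(h, w, bw, mean = 0, sd = 1) {
  noise <- matrix(stats::rnorm(h * w), h, w)
  f <- smooth_matrix(noise, bw)
  f <- (f - mean(f)) / stats::sd(f)
  mean + sd * f
}

#' Generate a synthetic survival cohort
#'
#' Per subject, a G x H x W expression grid whose per-gene spatial fields
#' fluctuate around subject-level means; the designated genes' means (the
#' grid pseudo-bulk, up to field noise) define the linear predictor
#' lp = sum(beta_g * mu_g). Survival times are exponential with rate
#' exp(lp); censoring is independent exponential with its rate solved
#' numerically so the expected censoring fraction matches
#' `censoring_rate`.
#'
#' @param n cohort size.
#' @param beta coefficient vector over genes (recycled/padded with zeros);
#'   scalar beta applies to the first gene. beta = log(3) is a hazard ratio
#'   of 3 per standard deviation of the gene score.
#' @param censoring_rate target censoring fraction (default 0.3).
#' @param seed RNG seed.
#' @param n_genes genes per grid (default 4).
#' @param shape grid height/width (default c(80, 64); must be divisible by
#'   32 for the application backbone).
#' @param bandwidth within-grid smoothing bandwidth (default 2).
#' @param field_sd within-grid field noise around the subject mean
#'   (default 0.5).
#' @return list with `grids`, `validity`, `time`, `event`, `lp`,
#'   `gene_names`.
#' @export
make_survival_cohort <- function(n, beta = log(3), censoring_rate = 0.3,
                                 seed = 1L, n_genes = 4L,
                                 shape = c(80L, 64L), bandwidth = 2,
                                 field_sd = 0.5) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  genes <- sprintf("gene%03d", seq_len(n_genes))
  b <- numeric(n_genes)
  b[seq_along(beta)] <- beta
  mu <- matrix(stats::rnorm(n * n_genes), n_genes, n)
  lp <- as.numeric(crossprod(mu, b))
  grids <- lapply(seq_len(n), function(i) {
    g <- array(0, dim = c(n_genes, shape[1], shape[2]),
               dimnames = list(genes, NULL, NULL))
    for (k in seq_len(n_genes)) {
      g[k, , ] <- smooth_field_grid(shape[1], shape[2], bandwidth,
                                    mean = mu[k, i], sd = field_sd)
    }
    g
  })
  time_event <- stats::rexp(n, rate = exp(lp))
  if (censoring_rate > 0) {
    f <- function(r) mean(1 - exp(-r * time_event)) - censoring_rate
    r <- stats::uniroot(f, c(1e-8, 1e8), tol = 1e-10)$root
    cens <- stats::rexp(n, rate = r)
  } else {
    cens <- rep(Inf, n)
  }
  event <- as.integer(time_event <= cens)
  list(grids = grids, validity = matrix(TRUE, shape[1], shape[2]),
       time = pmin(time_event, cens), event = event, lp = lp,
       gene_names = genes)
}

#' Generate a synthetic immunotherapy-response cohort
#'
#' Two classes of expression grids differing in the designated pathway
#' genes' subject-level means by `separation`; at separation 0 the classes
#' are indistinguishable.
#'
#' @param n cohort size.
#' @param class_balance responder fraction in (0, 1); 29/131 reproduces the
#'   published cohort imbalance.
#' @param separation mean shift of the pathway genes for responders.
#' @param seed RNG seed.
#' @param n_genes genes per grid (default 4; the first half are pathway
#'   genes).
#' @param shape grid height/width (default c(80, 64)).
#' @param bandwidth,field_sd within-grid field parameters.
#' @return list with `grids`, `labels` (factor non_responder/responder),
#'   `validity`, `gene_names`.
#' @export
make_icb_cohort <- function(n, class_balance = 0.5, separation = 2,
                            seed = 1L, n_genes = 4L, shape = c(80L, 64L),
                            bandwidth = 2, field_sd = 0.5) {
  stopifnot(class_balance > 0, class_balance < 1)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  genes <- sprintf("gene%03d", seq_len(n_genes))
  n_resp <- max(1L, min(n - 1L, round(n * class_balance)))
  y <- factor(c(rep("responder", n_resp),
                rep("non_responder", n - n_resp))[sample.int(n)],
              levels = c("non_responder", "responder"))
  pathway <- seq_len(max(1L, n_genes %/% 2L))
  grids <- lapply(seq_len(n), function(i) {
    g <- array(0, dim = c(n_genes, shape[1], shape[2]),
               dimnames = list(genes, NULL, NULL))
    shift <- if (y[i] == "responder") separation else 0
    for (k in seq_len(n_genes)) {
      mu <- stats::rnorm(1) + if (k %in% pathway) shift else 0
      g[k, , ] <- smooth_field_grid(shape[1], shape[2], bandwidth,
                                    mean = mu, sd = field_sd)
    }
    g
  })
  list(grids = grids, labels = y,
       validity = matrix(TRUE, shape[1], shape[2]), gene_names = genes)
}

#' Write a clinical table
#'
#' CSV with survival time, event indicator and any covariate columns, the
#' schema consumed by the survival pipeline.
#'
#' @param time,event outcome vectors.
#' @param covariates optional data.frame.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_clinical <- function(time, event, covariates = NULL, path) {
  df <- data.frame(time = time, event = event)
  if (!is.null(covariates)) df <- cbind(df, covariates)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
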