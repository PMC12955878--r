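# Small shared fixtures. All synthetic data is generated in code; reduced
# lattice geometries (e.g. 14 x 16, padded to 16 x 16) keep the suite fast
# while exercising the full pipeline.

tiny_cfg <- function(seed = 1L, ...) {
  args <- list(n_rows = 14L, cols_per_row = 16L, n_genes = 10L,
               smooth_fraction = 0.3, bandwidth = 2, seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(synth_config, args)
}

tiny_slide <- function(seed = 1L, ...) {
  make_synthetic_slide(tiny_cfg(seed = seed, ...))
}

# random small hex layout with a subset of spots out of tissue
random_layout <- function(n_rows = 6L, cols_per_row = 8L, seed = 1L,
                          frac_tissue = 0.8) {
  cfg <- synth_config(n_rows = n_rows, cols_per_row = cols_per_row,
                      n_genes = 2L, seed = seed)
  lay <- make_layout(cfg)
  set.seed(seed)
  lay$in_tissue <- runif(nrow(lay)) < frac_tissue
  lay
}

rand_array <- function(dims, seed = 1L) {
  set.seed(seed)
  array(rnorm(prod(dims)), dims)
}
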