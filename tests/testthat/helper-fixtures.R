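# Shared fixtures, memoized across test files within one run.

`%||%` <- function(a, b) if (is.null(a)) b else a

.fx <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fx[[key]])) .fx[[key]] <- force(expr)
  .fx[[key]]
}

# small labeled phantom dataset (6 tumors, modest diameters)
fx_dataset <- function() memo("ds6", make_paired_dataset(
  6, spec_ranges = list(diameter_mm = c(14, 20)), seed = 42))

# representative (sketch, CT) pairs at a given size, one per tumor
fx_pairs <- function(size = 32L) memo(paste0("pairs", size), {
  lapply(fx_dataset(), function(d)
    voi_to_pairs(resample_isotropic(crop_voi(d$volume)), FALSE, size = size)[[1]])
})

fx_ct <- function(size = 32L) lapply(fx_pairs(size), `[[`, "ct")

# tiny generator/discriminator configuration for fast tests
fx_cfg <- function(size = 32L, style = FALSE, base = 8L, latent = 32L)
  generator_config(image_size = size, depth = as.integer(log2(size)),
                   base_channels = base, use_style = style, latent_dim = latent)
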