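# Shared fixtures: phantoms are deterministic, so expensive pipeline runs are
# cached and reused across test files.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

default_phantom <- function(noise_sigma = 0, seed = 0L, tumor = NULL) {
  key <- sprintf("ph_%g_%d_%d", noise_sigma, seed, !is.null(tumor))
  cached(key, make_phantom(phantom_spec(noise_sigma = noise_sigma,
                                        seed = seed, tumor = tumor)))
}

# a smaller phantom for fast module-level pipeline tests
small_phantom <- function(noise_sigma = 0, seed = 0L, tumor = NULL) {
  key <- sprintf("phs_%g_%d_%d", noise_sigma, seed, !is.null(tumor))
  cached(key, make_phantom(phantom_spec(
    height = 128L, width = 128L,
    skull = ellipse_params(64, 64, 52, 44),
    noise_sigma = noise_sigma, seed = seed, tumor = tumor)))
}

# full-pipeline Dice against ground truth, cached per (sigma, seed)
pipeline_dice <- function(noise_sigma, seed) {
  key <- sprintf("dice_%g_%d", noise_sigma, seed)
  cached(key, {
    ph <- default_phantom(noise_sigma, seed)
    res <- segment_gm_wm(ph$slice)
    c(gm = dice(res$gm_mask, ph$truth$gm_mask),
      wm = dice(res$wm_mask, ph$truth$wm_mask),
      total = dice(res$gm_mask | res$wm_mask,
                   ph$truth$gm_mask | ph$truth$wm_mask))
  })
}

batch_dice <- function(noise_sigma, seeds = 0:9) {
  vapply(seeds, function(s) pipeline_dice(noise_sigma, s), numeric(3))
}
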