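# Shared fixtures, built in code. Phantoms used across test files are
# spatially small (the 508-band axis is kept where band accounting matters).

random_cube <- function(nr = 4, nc = 5, nb = 6, seed = 1,
                        wl = seq(900, by = 10, length.out = nb)) {
  set.seed(seed)
  hsi_cube(array(runif(nr * nc * nb), dim = c(nr, nc, nb)), wl)
}

small_phantom_cfg <- function(...) {
  phantom_config(n_rows = 64L, n_cols = 64L, ...)
}

quiet_cfg <- function(...) {
  small_phantom_cfg(noise_sd_core = 0, noise_sd_edge = 0,
                    illumination_rel_sd = 0, spatial_gradient = 0,
                    absorption_efficiency_rel_sd = 0, ...)
}

fast_train <- function(epochs = 30L, finetune_epochs = 20L, seed = 1L, ...) {
  train_config(epochs = epochs, finetune_epochs = finetune_epochs,
               seed = seed, ...)
}

# One moderate dataset shared by the regression / visualization tests.
.fixture_env <- new.env(parent = emptyenv())

shared_dataset <- function() {
  if (is.null(.fixture_env$ds)) {
    .fixture_env$ds <- generate_dataset(
      24, c(immature = 6L, semi_mature = 10L, mature = 8L),
      config = small_phantom_cfg(), seed = 101)
    .fixture_env$feats <- dataset_features(.fixture_env$ds)
  }
  list(ds = .fixture_env$ds, feats = .fixture_env$feats)
}

# A spectral SAE + RF trained on the shared dataset, for visualization tests.
shared_spectral_model <- function() {
  if (is.null(.fixture_env$model)) {
    sh <- shared_dataset()
    norm <- feature_normalize(sh$feats$spectral)
    sae <- fit_sae(norm$values, "453-350-200-60", targets = sh$feats$ssc,
                   cfg = fast_train(seed = 7))
    rf <- fit_rf(deep_features(sae, norm$values), sh$feats$ssc,
                 n_trees = 100, seed = 7)
    .fixture_env$model <- list(sae = sae, rf = rf, stats = norm$stats)
  }
  .fixture_env$model
}
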