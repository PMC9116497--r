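# Shared fixtures. Everything is generated in code; the expensive trained
# desk-scale network is built once per test run and cached for all tests
# that need it.

grid64 <- function() acoustic_grid(64L, 64L)

noiseless_config <- function(grid = grid64()) {
  sim_config(grid = grid, noise_level_mean = 0, noise_level_half_range = 0)
}

.fixture_cache <- new.env(parent = emptyenv())

# Desk-scale DL-RF model trained on vessel-constrained (group 3) data:
# 200 training images, 20 validation images, 64 x 64 pixels, base 8
# channels, 20 epochs. Cached across tests.
desk_model_rf <- function() {
  if (!is.null(.fixture_cache$model_rf)) return(.fixture_cache$model_rf)
  cfg <- sim_config(grid = grid64())
  train <- build_training_set(3, 200, cfg, seed = 101)
  val <- build_training_set(3, 20, cfg, seed = 202)
  model <- train_unet(train, val,
                      unet_spec(base_channels = 8L, representation = "RF"),
                      loss_config(beta = 1),
                      train_config(epochs = 20L, seed = 7L))
  .fixture_cache$model_rf <- model
  model
}
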