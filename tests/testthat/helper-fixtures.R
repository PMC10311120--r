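# Shared fixtures, built in code.

# Small scenes keep the unit tests fast; the acceptance tests use the
# full-size simulator defaults.
small_params <- function(seed = 1L, ...) {
  scene_params(image_size_px = c(128L, 128L), n_nuclei = 1L,
               nucleus_radius_nm_range = c(900, 1400),
               puncta_per_nucleus_range = c(4L, 7L), seed = seed, ...)
}

# A deterministic non-constant test image.
ramp_plane <- function(H = 32L, W = 32L, pixel_size_nm = 25) {
  image_plane(matrix(seq(0, 255, length.out = H * W), H, W),
              pixel_size_nm, modality = "EM")
}

# Build exact correspondences by pushing points through a known transform.
exact_correspondences <- function(t, pts) {
  out <- transform_points(t, pts)
  data.frame(x_mov = pts[, 1], y_mov = pts[, 2],
             x_fix = out[, 1], y_fix = out[, 2], score = 1)
}

# A small trained model, cached across test files (trained once per run).
.tiny_model_cache <- new.env(parent = emptyenv())
tiny_model <- function() {
  if (is.null(.tiny_model_cache$model)) {
    pairs <- make_training_set(8, small_params(seed = 400L), seed = 41L)
    .tiny_model_cache$model <- train_model(
      pairs, model_config(base_filters = 8L),
      train_config(epochs = 25L, patch_size_px = 64L, patches_per_pair = 6L,
                   seed = 7L))
  }
  .tiny_model_cache$model
}

expect_transform_equal <- function(est, truth, tol_t = 1e-9, tol_theta = 1e-9,
                                   tol_scale = 1e-9) {
  expect_lt(abs(est$theta_rad - truth$theta_rad), tol_theta)
  expect_lt(abs(est$scale - truth$scale), tol_scale)
  expect_lt(abs(est$tx_px - truth$tx_px), tol_t)
  expect_lt(abs(est$ty_px - truth$ty_px), tol_t)
}
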