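test_that("patch extraction is aligned, bounded, and deterministic", {
  pairs <- make_training_set(2, small_params(seed = 60L), seed = 61L)
  p1 <- extract_patches(pairs, 64, 10, seed = 3L)
  p2 <- extract_patches(pairs, 64, 10, seed = 3L)
  expect_length(p1, 20L)
  expect_identical(lapply(p1, `[[`, "corner"), lapply(p2, `[[`, "corner"))
  corners <- do.call(rbind, lapply(p1, `[[`, "corner"))
  expect_true(all(corners >= 0 & corners <= 64))   # 128 - 64
  # EM and chromatin cut at identical coordinates
  k <- p1[[4]]
  i0 <- k$corner[2] + 1; j0 <- k$corner[1] + 1
  expect_identical(k$em, pairs[[1]]$em$pixels[i0:(i0 + 63), j0:(j0 + 63)])

  # full-image patch: exactly one per pair
  full <- extract_patches(pairs, 128, 5, seed = 1L)
  expect_length(full, 2L)
  expect_identical(full[[1]]$em, pairs[[1]]$em$pixels)

  expect_error(extract_patches(pairs, 256, 1), "smaller than the patch")
})

test_that("the network learns the identity and constant maps", {
  set.seed(70)
  mats <- replicate(10, matrix(runif(32 * 32), 32), simplify = FALSE)
  pairs_id <- lapply(mats, function(m) list(em = m, chromatin = m))
  cfg_m <- model_config(depth = 2L, base_filters = 8L)
  cfg_t <- train_config(epochs = 20L, batch_size = 2L, patch_size_px = 32L,
                        patches_per_pair = 1L, learning_rate = 1e-2, seed = 2L)
  m_id <- train_model(pairs_id, cfg_m, cfg_t, preprocess_config("NONE"))
  h <- m_id$loss_history
  expect_identical(nrow(h), 20L)
  expect_lt(h$train_loss[20], 0.1 * h$train_loss[1])
  expect_lte(h$train_loss[20], h$train_loss[1])

  pairs_zero <- lapply(mats, function(m) list(em = m, chromatin = m * 0))
  # constant-zero targets need no normalization of the target
  m_zero <- train_model(pairs_zero, cfg_m,
                        train_config(epochs = 10L, patch_size_px = 32L,
                                     patches_per_pair = 1L, learning_rate = 3e-3,
                                     seed = 2L, loss = "MSE"),
                        preprocess_config("NONE"), normalize_target = FALSE)
  pred <- predict_chromatin(m_zero, image_plane(mats[[1]], 25, "EM"))
  expect_lt(mean(abs(pred$pixels)), 0.05)
})

test_that("training is seeded-reproducible and beats the mean-image baseline", {
  pairs <- make_training_set(4, small_params(seed = 80L), seed = 81L)
  cfg_m <- model_config(base_filters = 8L)
  cfg_short <- train_config(epochs = 3L, patch_size_px = 64L,
                            patches_per_pair = 2L, seed = 11L)
  m_a <- train_model(pairs, cfg_m, cfg_short)
  m_b <- train_model(pairs, cfg_m, cfg_short)
  expect_equal(m_a$loss_history, m_b$loss_history, tolerance = 1e-12)

  cfg_t <- train_config(epochs = 30L, patch_size_px = 64L, patches_per_pair = 2L,
                        seed = 11L)
  m1 <- train_model(pairs, cfg_m, cfg_t)

  # trivial-predictor bound: final loss not worse than predicting the
  # mean target patch (same training subset and patch sampling as the run)
  seeds <- clemsim:::derive_seeds(11L, 3L)
  val_idx <- clemsim:::with_seed(seeds[1], sample.int(4L, 1L))
  patches <- extract_patches(lapply(pairs[-val_idx], function(p) list(
    em = preprocess(p$em)$pixels,
    chromatin = percentile_normalize(p$chromatin)$pixels)),
    64, 2, seed = seeds[2])
  targets <- vapply(patches, function(p) p$chromatin, matrix(0, 64, 64))
  mean_img <- apply(targets, c(1, 2), mean)
  baseline <- mean(abs(sweep(targets, c(1, 2), mean_img)))
  expect_lte(tail(m1$loss_history$train_loss, 1), baseline)
})

test_that("prediction preserves geometry, is deterministic, and tiles cleanly", {
  m <- tiny_model()
  sc <- sample_scene(small_params(seed = 90L))
  em <- render_em(sc)
  p1 <- predict_chromatin(m, em)
  p2 <- predict_chromatin(m, em)
  expect_identical(p1$pixels, p2$pixels)
  expect_identical(dim(p1$pixels), dim(em$pixels))
  expect_identical(p1$pixel_size_nm, em$pixel_size_nm)
  expect_identical(p1$modality, "PREDICTED")

  # image smaller than the tile: single-tile path, shape preserved
  small <- image_plane(em$pixels[1:100, 1:90], 25, "EM")
  ps <- predict_chromatin(m, small, tile_px = 128L)
  expect_identical(dim(ps$pixels), c(100L, 90L))

  # tiled vs single-tile prediction on a 256x256 input: seams below 1e-4
  sc2 <- sample_scene(scene_params(seed = 91L))
  em2 <- render_em(sc2)
  whole <- predict_chromatin(m, em2)
  tiled <- predict_chromatin(m, em2, tile_px = 128L, overlap_px = 32L)
  expect_lt(max(abs(whole$pixels - tiled$pixels)), 1e-4)
})

test_that("model artifacts round-trip through save/load", {
  m <- tiny_model()
  dir <- withr::local_tempdir()
  save_model(m, dir)
  expect_true(file.exists(file.path(dir, "model.json")))
  expect_true(file.exists(file.path(dir, "weights.txt")))
  m2 <- load_model(dir)
  expect_equal(m2$layers, m$layers, tolerance = 0)
  expect_equal(m2$train_cfg$epochs, m$train_cfg$epochs)
  em <- render_em(sample_scene(small_params(seed = 92L)))
  expect_identical(predict_chromatin(m, em)$pixels,
                   predict_chromatin(m2, em)$pixels)
  expect_error(load_model(withr::local_tempdir()), "model.json")
})

test_that("training validates its inputs", {
  pairs <- make_training_set(2, small_params(seed = 95L), seed = 96L)
  expect_error(train_model(pairs[1]), "at least 2")
  expect_error(train_model(pairs, model_config(depth = 3L),
                           train_config(patch_size_px = 60L)),
               "divisible")
})
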