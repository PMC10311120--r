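test_that("residual errors measure per-axis displacement in nm", {
  pts <- rbind(c(10, 20), c(100, 40), c(60, 110))
  t0 <- similarity_transform(0.2, 1.01, 3, -4)
  expect_equal(unname(residual_error_nm(t0, t0, pts, 25)), c(0, 0))

  # a pure +2 px x-offset is 50 nm at 25 nm/px, at any points
  t_shift <- compose_transforms(similarity_transform(0, 1, 2, 0), t0)
  expect_equal(unname(residual_error_nm(t_shift, t0, pts, 25)), c(50, 0),
               tolerance = 1e-9)

  # 1-degree rotation about the center: arc displacements computed directly
  ctr <- c(63.5, 63.5)
  t_rot <- transform_about_center(pi / 180, 1, ctr)
  d <- transform_points(t_rot, pts) - pts
  expected <- c(mean(abs(d[, 1])), mean(abs(d[, 2]))) * 25
  expect_equal(unname(residual_error_nm(t_rot, identity_transform(), pts, 25)),
               expected, tolerance = 1e-9)

  expect_error(residual_error_nm(t0, t0, pts[0, , drop = FALSE], 25),
               "at least one")
})

test_that("perturbations are constructed and applied exactly", {
  sc <- sample_scene(small_params(seed = 50L))
  img <- render_fluorescence(sc)
  shape <- dim(img$pixels)

  p_al <- perturbation("ALIGNED", shape, 25)
  expect_identical(perturb_pair(img, p_al)$pixels, img$pixels)

  # 3125 nm at 25 nm/px: an exact 125 px array shift
  p_sx <- perturbation("SHIFT_X", shape, 25)
  expect_equal(p_sx$transform$tx_px, 125)
  sh <- perturb_pair(img, p_sx)
  expect_identical(sh$pixels[, 126:128], img$pixels[, 1:3])

  # ROT_180 is an exact involution
  p180 <- perturbation("ROT_180", shape, 25)
  once <- perturb_pair(img, p180)
  twice <- perturb_pair(once, p180)
  expect_identical(twice$pixels, img$pixels)
  expect_false(identical(once$pixels, img$pixels))

  # ROT_90 about the center of a square image permutes pixels losslessly
  p90 <- perturbation("ROT_90", shape, 25)
  r90 <- perturb_pair(img, p90)
  expect_identical(sort(as.numeric(r90$pixels)), sort(as.numeric(img$pixels)))

  expect_error(perturbation("CUSTOM", shape, 25), "similarity_transform")
})

test_that("evaluate_pair with a perfect predictor meets the half-pixel bound", {
  sc <- sample_scene(scene_params(seed = 51L))
  em <- render_em(sc)
  aligned <- render_fluorescence(sc, FALSE)
  oracle <- oracle_model(render_fluorescence(sc, FALSE, noise = FALSE))
  puncta <- as.matrix(sc$puncta[, c("x_px", "y_px")])

  for (lab in c("ALIGNED", "SHIFT_X")) {
    rec <- evaluate_pair(em, aligned, oracle,
                         perturbation(lab, dim(em$pixels), 25),
                         puncta_px = puncta, image_id = lab)
    expect_true(rec$success)
    expect_lt(rec$err_x_nm, 12.5)   # 0.5 px at 25 nm/px
    expect_lt(rec$err_y_nm, 12.5)
  }

  # a useless constant "prediction" cannot succeed
  flat <- oracle_model(image_plane(matrix(1, nrow(em$pixels), ncol(em$pixels)),
                                   25, "FLUO"))
  rec_flat <- evaluate_pair(em, aligned, flat,
                            perturbation("ALIGNED", dim(em$pixels), 25),
                            puncta_px = puncta)
  expect_false(rec_flat$success)
})

test_that("the benchmark has the right cardinality and is reproducible", {
  params <- small_params()
  r1 <- run_benchmark("oracle", n_scenes = 4, params = params, seed = 52L)
  expect_identical(nrow(r1$records), 16L)
  expect_identical(sort(unique(r1$records$perturbation)),
                   sort(c("ALIGNED", "SHIFT_X", "ROT_90", "ROT_180")))
  expect_equal(r1$success_rate, mean(r1$records$success))

  r2 <- run_benchmark("oracle", n_scenes = 4, params = params, seed = 52L)
  expect_identical(as.data.frame(r1$records), as.data.frame(r2$records))

  # broom-style accessors
  expect_identical(tidy(r1), r1$records)
  g <- glance(r1)
  expect_identical(nrow(g), 1L)
  expect_equal(g$success_rate, r1$success_rate)

  # report writers
  dir <- withr::local_tempdir()
  wide <- write_benchmark(r1, file.path(dir, "b.csv"), file.path(dir, "b.json"))
  expect_identical(nrow(wide), 4L)     # one row per scene
  expect_identical(ncol(wide), 9L)     # id + 4 perturbations x (X, Y)
  js <- jsonlite::read_json(file.path(dir, "b.json"))
  expect_equal(js$success_rate, r1$success_rate)

  p <- autoplot(r1)
  expect_s3_class(p, "ggplot")
})
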