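test_that("LoG blob detection localizes Gaussian spots to sub-pixel accuracy", {
  g <- clemsim:::coord_grids(128, 128)
  spot <- function(x0, y0, sigma) exp(-((g$x - x0)^2 + (g$y - y0)^2) / (2 * sigma^2))
  img <- spot(40, 60, 3)
  kp <- detect_blobs(img)
  expect_identical(nrow(kp), 1L)
  expect_lt(sqrt((kp$x_px - 40)^2 + (kp$y_px - 60)^2), 0.5)
  # reported scale approximates the blob radius sigma * sqrt(2)
  expect_gt(kp$scale_px, 3 * sqrt(2) / 1.5)
  expect_lt(kp$scale_px, 3 * sqrt(2) * 1.5)

  # three well-separated blobs give exactly three keypoints, each matching a
  # local-maxima scan of the image
  img3 <- spot(30, 30, 2.5) + spot(90, 40, 3.5) + 0.8 * spot(60, 100, 3)
  kp3 <- detect_blobs(img3)
  expect_identical(nrow(kp3), 3L)
  truth <- rbind(c(30, 30), c(90, 40), c(60, 100))
  for (r in seq_len(3)) {
    d <- sqrt((truth[, 1] - kp3$x_px[r])^2 + (truth[, 2] - kp3$y_px[r])^2)
    expect_lt(min(d), 0.5)
  }

  # pure noise with a high threshold yields nothing; constant image likewise
  set.seed(4)
  noise <- matrix(rnorm(128 * 128, sd = 0.01), 128)
  expect_identical(nrow(detect_blobs(noise, register_config(blob_threshold = 0.5))), 0L)
  expect_identical(nrow(detect_blobs(matrix(1, 64, 64))), 0L)
})

test_that("keypoint matching is mutual, ratio-tested, and deterministic", {
  mk <- function(xy, D) {
    kp <- data.frame(x_px = xy[, 1], y_px = xy[, 2],
                     scale_px = 3, response = 1)
    attr(kp, "descriptors") <- D
    kp
  }
  set.seed(6)
  D <- matrix(rnorm(8 * 10), 8, 10)
  D <- D / sqrt(rowSums(D^2))
  xy <- matrix(runif(16, 0, 100), 8, 2)
  a <- mk(xy, D)
  # identical lists match one-to-one
  m <- match_keypoints(a, a)
  expect_identical(nrow(m), 8L)
  expect_equal(m$x_mov, m$x_fix)

  # a random permutation is recovered (oracle: brute-force distances)
  perm <- sample(8)
  b <- mk(xy[perm, , drop = FALSE], D[perm, , drop = FALSE])
  m2 <- match_keypoints(a, b)
  expect_identical(nrow(m2), 8L)
  reord <- match(paste(m2$x_mov, m2$y_mov), paste(xy[, 1], xy[, 2]))
  expect_equal(cbind(m2$x_fix, m2$y_fix), xy[reord, , drop = FALSE],
               ignore_attr = TRUE)

  # duplicated descriptor in the fixed list: ambiguous, dropped
  one <- mk(rbind(c(1, 1)), D[1, , drop = FALSE])
  two_same <- mk(rbind(c(5, 5), c(50, 50)), D[c(1, 1), , drop = FALSE])
  expect_identical(nrow(match_keypoints(one, two_same)), 0L)

  # empty inputs give an empty set
  expect_identical(nrow(match_keypoints(clemsim:::empty_keypoints(), a)), 0L)
})

test_that("closed-form similarity fit recovers exact transforms", {
  # two exact pairs determine the transform to 1e-9
  t_true <- similarity_transform(30 * pi / 180, 1.1, 5, -2)
  cs <- exact_correspondences(t_true, rbind(c(0, 0), c(10, 0)))
  expect_transform_equal(fit_similarity(cs), t_true)

  # identity on repeated identity pairs
  pts <- matrix(runif(10, 0, 100), 5, 2)
  expect_transform_equal(fit_similarity(exact_correspondences(identity_transform(), pts)),
                         identity_transform())

  # 10 noiseless pairs under a 90-degree rotation + 125 px shift: exact,
  # residuals at machine precision
  t90 <- similarity_transform(pi / 2, 1, 125, 0)
  set.seed(9)
  pts10 <- matrix(runif(20, 0, 200), 10, 2)
  cs10 <- exact_correspondences(t90, pts10)
  est <- fit_similarity(cs10)
  expect_transform_equal(est, t90)
  res <- transform_points(est, pts10) - cbind(cs10$x_fix, cs10$y_fix)
  expect_lt(sum(res^2), 1e-12)

  expect_error(fit_similarity(cs10[1, , drop = FALSE]), "at least 2")
  same <- data.frame(x_mov = c(1, 1), y_mov = c(2, 2), x_fix = c(0, 5), y_fix = c(0, 5))
  expect_error(fit_similarity(same), "degenerate")

  # a mirrored correspondence set is refused, not silently mis-fit
  mir <- data.frame(x_mov = c(0, 10, 0), y_mov = c(0, 0, 10),
                    x_fix = c(0, 10, 0), y_fix = c(0, 0, -10))
  expect_error(fit_similarity(mir), "REFLECTION_REQUIRED")
})

test_that("RANSAC rejects outliers and matches the plain fit on clean data", {
  t_true <- similarity_transform(0.3, 1.05, 22, -13)
  set.seed(12)
  pts <- matrix(runif(20, 0, 200), 10, 2)
  clean <- exact_correspondences(t_true, pts)
  rr <- ransac_similarity(clean, register_config(seed = 1L))
  expect_true(all(rr$inliers))
  expect_transform_equal(rr$transform, fit_similarity(clean), 1e-9, 1e-12, 1e-12)

  outliers <- data.frame(x_mov = runif(10, 0, 200), y_mov = runif(10, 0, 200),
                         x_fix = runif(10, 0, 200), y_fix = runif(10, 0, 200),
                         score = 1)
  mixed <- rbind(clean, outliers)
  rr2 <- ransac_similarity(mixed, register_config(seed = 7L))
  expect_gte(sum(rr2$inliers), 10L)
  expect_lt(abs(rr2$transform$tx_px - t_true$tx_px), 0.1)
  expect_lt(abs(rr2$transform$ty_px - t_true$ty_px), 0.1)
  expect_lt(abs(rr2$transform$theta_rad - t_true$theta_rad), 0.1 * pi / 180)

  expect_error(ransac_similarity(clean[1, , drop = FALSE]), "at least 2")
  expect_error(ransac_similarity(outliers[1:4, ],
                                 register_config(seed = 2L, inlier_tol_px = 1e-6)),
               "NO_CONSENSUS")
})

test_that("normalized cross-correlation matches direct evaluation", {
  set.seed(1)
  A <- matrix(rnorm(1024), 32)
  expect_equal(ncc(A, A), 1.0, tolerance = 1e-12)
  expect_equal(ncc(A, -A), -1.0, tolerance = 1e-12)
  a <- matrix(c(1, 2, 3, 4, 2, 2, 1, 0, 5, 1, 2, 2, 0, 1, 3, 4), 4)
  b <- matrix(c(2, 1, 3, 3, 1, 2, 2, 1, 4, 2, 1, 3, 1, 0, 4, 5), 4)
  direct <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(ncc(a, b), direct, tolerance = 1e-12)
  expect_error(ncc(A, matrix(2, 32, 32)), "constant")
})

test_that("exhaustive search recovers translations exactly and rotations on-grid", {
  s <- sample_scene(small_params(seed = 31L))
  f <- render_fluorescence(s, noise = FALSE)$pixels

  t_id <- exhaustive_similarity_search(f, f, theta_grid_deg = c(-2, 0, 2))
  expect_lt(abs(t_id$theta_rad), 1e-9)
  expect_lt(max(abs(c(t_id$tx_px, t_id$ty_px))), 0.5)

  # integer shift: content moved by (17, -9), mapping recovered exactly at
  # the discrete correlation peak (oracle: the constructed shift)
  shift <- similarity_transform(0, 1, 17, -9)
  m <- apply_transform(f, shift)
  t_sh <- exhaustive_similarity_search(m, f, theta_grid_deg = 0)
  expect_equal(c(t_sh$tx_px, t_sh$ty_px), c(-17, 9), tolerance = 1e-9)

  # rotation by 90 degrees about the center is selected from the grid
  rot <- transform_about_center(pi / 2, 1, image_center(f))
  m90 <- apply_transform(f, rot, interp = "NEAREST")
  t_rot <- exhaustive_similarity_search(m90, f,
                                        theta_grid_deg = seq(-180, 170, by = 10))
  expect_equal(t_rot$theta_rad * 180 / pi, -90, tolerance = 1e-6)

  expect_error(exhaustive_similarity_search(f, f, theta_grid_deg = numeric(0)),
               "empty grids")
})

test_that("apply_transform resamples correctly in both modes", {
  s <- sample_scene(small_params(seed = 32L))
  img <- render_fluorescence(s, noise = FALSE)

  out <- apply_transform(img, identity_transform(), interp = "NEAREST")
  expect_identical(out$pixels, img$pixels)

  sh <- similarity_transform(0, 1, 5, 3)
  out_sh <- apply_transform(img, sh, interp = "NEAREST")
  expect_identical(out_sh$pixels[4:128, 6:128], img$pixels[1:125, 1:123])
  expect_true(all(out_sh$pixels[1:3, ] == 0))

  # warp round trip on smooth content: interior error below 1% of range
  t <- similarity_transform(0.2, 1.03, 4.5, -2.2)
  fwd <- apply_transform(img, t)
  back <- apply_transform(fwd, invert_transform(t))
  interior <- 20:108
  err <- abs(back$pixels[interior, interior] - img$pixels[interior, interior])
  expect_lt(mean(err), 0.01 * diff(range(img$pixels)))

  # bilinear warping at unit scale conserves interior-supported intensity
  blob <- matrix(0, 128, 128)
  g <- clemsim:::coord_grids(128, 128)
  blob <- exp(-((g$x - 60)^2 + (g$y - 70)^2) / 50)
  w <- apply_transform(blob, similarity_transform(0.4, 1, 7.3, -4.1))
  expect_lt(abs(sum(w) - sum(blob)) / sum(blob), 0.02)

  expect_error(apply_transform(img, t, out_shape = c(0, 10)), "out_shape")
})

test_that("register_planes runs the full pipeline with honest statuses", {
  s <- sample_scene(small_params(seed = 33L))
  fl <- percentile_normalize(render_fluorescence(s, noise = FALSE))

  # self-registration: near-identity, status OK
  reg <- register_planes(fl, fl)
  expect_identical(reg$status, "OK")
  expect_lt(abs(reg$transform$theta_rad) * 180 / pi, 0.5)
  expect_lt(abs(reg$transform$scale - 1), 0.01)
  expect_lt(max(abs(c(reg$transform$tx_px, reg$transform$ty_px))), 0.5)
  expect_gte(reg$score_after, reg$score_before)

  # the reference perturbation: 125 px shift in x (3125 nm at 25 nm/px)
  sh <- similarity_transform(0, 1, 125, 0)
  chrom <- render_fluorescence(sample_scene(scene_params(seed = 34L)), noise = FALSE)
  moving <- percentile_normalize(apply_transform(chrom, sh))
  fixed <- percentile_normalize(chrom)
  reg2 <- register_planes(moving, fixed)
  expect_identical(reg2$status, "OK")
  expect_lt(abs(reg2$transform$tx_px - (-125)), 0.5)
  expect_lt(abs(reg2$transform$ty_px), 0.5)

  # featureless images cannot be registered
  flat <- image_plane(matrix(1, 64, 64), 25, "FLUO")
  reg3 <- register_planes(flat, flat)
  expect_identical(reg3$status, "LOW_FEATURES")
  # registration failure (constant fixed image) reports status, never raises
  flat128 <- image_plane(matrix(1, 128, 128), 25, "FLUO")
  reg4 <- register_planes(fl, flat128)
  expect_identical(reg4$status, "LOW_FEATURES")
  expect_error(register_planes(fl, image_plane(matrix(1, 32, 32), 25, "FLUO")),
               "shape")
})

test_that("registration recovers random misalignments (parameter recovery)", {
  for (seed in c(41L, 42L, 43L)) {
    s <- sample_scene(small_params(seed = seed))
    img <- render_fluorescence(s, noise = FALSE)
    t <- transform_about_center((((seed * 37) %% 40) - 20) * pi / 180,
                                1 + (seed %% 5 - 2) / 100,
                                image_center(img),
                                shift = c(seed %% 11 - 5, seed %% 7 - 3))
    moving <- percentile_normalize(apply_transform(img, t))
    reg <- register_planes(moving, percentile_normalize(img))
    rec <- compose_transforms(reg$transform, t)   # should be identity
    pts <- as.matrix(s$puncta[, c("x_px", "y_px")])
    d <- transform_points(rec, pts) - pts
    expect_lt(mean(abs(d[, 1])), 0.5)
    expect_lt(mean(abs(d[, 2])), 0.5)
    expect_lt(abs(rec$theta_rad) * 180 / pi, 0.5)
    expect_lt(abs(rec$scale - 1), 0.01)
  }
})
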