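test_that("scene sampling is deterministic and honors the puncta minimum", {
  p <- small_params(seed = 21L)
  s1 <- sample_scene(p); s2 <- sample_scene(p)
  expect_identical(s1$puncta, s2$puncta)
  expect_identical(s1$nuclei, s2$nuclei)
  expect_identical(unclass(s1$true_transform), unclass(s2$true_transform))
  expect_gte(nrow(s1$puncta), 3L)
  expect_error(scene_params(puncta_per_nucleus_range = c(1L, 5L)), "at least 3")

  # puncta do not overlap
  d <- as.matrix(dist(s1$puncta[, c("x_px", "y_px")]))
  rad_px <- s1$puncta$radius_nm / p$pixel_size_nm
  lim <- outer(rad_px, rad_px, "+")
  diag(d) <- Inf
  expect_true(all(d > lim | !is.finite(d)))
})

test_that("zero-width misalignment ranges give the identity transform", {
  p <- small_params(seed = 3L,
                    misalignment_ranges = list(theta_deg = c(0, 0),
                                               scale = c(1, 1),
                                               shift_nm = c(0, 0)))
  s <- sample_scene(p)
  expect_transform_equal(s$true_transform, identity_transform(),
                         1e-9, 1e-12, 1e-12)
})

test_that("EM and fluorescence renders are deterministic with correct polarity", {
  s <- sample_scene(small_params(seed = 9L))
  em1 <- render_em(s); em2 <- render_em(s)
  expect_identical(em1$pixels, em2$pixels)
  fl1 <- render_fluorescence(s); fl2 <- render_fluorescence(s)
  expect_identical(fl1$pixels, fl2$pixels)
  expect_identical(em1$modality, "EM")
  expect_identical(fl1$modality, "FLUO")

  # noiseless polarity at every punctum: EM below local background,
  # fluorescence above it
  em0 <- render_em(s, noise = FALSE)
  fl0 <- render_fluorescence(s, noise = FALSE)
  idx <- cbind(round(s$puncta$y_px) + 1, round(s$puncta$x_px) + 1)
  expect_true(all(em0$pixels[idx] < 0.45))       # nucleoplasm level
  expect_true(all(fl0$pixels[idx] > s$params$fluo_background + 0.3))
})

test_that("rendered punctum centroids match the ground-truth coordinates", {
  s <- sample_scene(small_params(seed = 14L))
  em0 <- render_em(s, noise = FALSE)
  g <- clemsim:::coord_grids(128, 128)
  rad_all <- s$puncta$radius_nm / s$params$pixel_size_nm
  dmat <- as.matrix(dist(s$puncta[, c("x_px", "y_px")])); diag(dmat) <- Inf
  for (i in seq_len(nrow(s$puncta))) {
    # isolated puncta only: a neighbor inside the window would bias the
    # centroid of the window, not of the disk
    if (min(dmat[i, ] - rad_all) < rad_all[i] + 4) next
    x0 <- s$puncta$x_px[i]; y0 <- s$puncta$y_px[i]
    r_px <- s$puncta$radius_nm[i] / s$params$pixel_size_nm
    win <- sqrt((g$x - x0)^2 + (g$y - y0)^2) <= r_px + 3
    # inverted dark disk; the 0.40 floor excludes nucleoplasm texture
    w <- pmax(0.40 - em0$pixels, 0) * win
    cx <- sum(w * g$x) / sum(w); cy <- sum(w * g$y) / sum(w)
    expect_lt(sqrt((cx - x0)^2 + (cy - y0)^2), 0.5)
  }

  # noiseless fluorescence centroids: aligned render sits on the EM-frame
  # coordinates, misaligned render is displaced by the true transform
  fl0 <- render_fluorescence(s, apply_misalignment = FALSE, noise = FALSE)
  flm <- render_fluorescence(s, apply_misalignment = TRUE, noise = FALSE)
  sigma_px <- s$params$fluo_psf_sigma_nm / s$params$pixel_size_nm
  centroid_at <- function(img, x0, y0) {
    win <- sqrt((g$x - x0)^2 + (g$y - y0)^2) <= 4 * sigma_px
    w <- pmax(img - s$params$fluo_background, 0) * win
    c(sum(w * g$x), sum(w * g$y)) / sum(w)
  }
  mapped <- transform_points(s$true_transform,
                             as.matrix(s$puncta[, c("x_px", "y_px")]))
  for (i in seq_len(nrow(s$puncta))) {
    c_al <- centroid_at(fl0$pixels, s$puncta$x_px[i], s$puncta$y_px[i])
    expect_lt(max(abs(c_al - c(s$puncta$x_px[i], s$puncta$y_px[i]))), 0.25)
    if (all(mapped[i, ] > 8) && all(mapped[i, ] < 119)) {
      c_mis <- centroid_at(flm$pixels, mapped[i, 1], mapped[i, 2])
      expect_lt(max(abs(c_mis - mapped[i, ])), 0.25)
    }
  }
})

test_that("noiseless fluorescence equals the analytic sum-of-Gaussians field", {
  p <- small_params(seed = 17L, fluo_background = 0)
  s <- sample_scene(p)
  fl0 <- render_fluorescence(s, noise = FALSE)
  sigma_px <- p$fluo_psf_sigma_nm / p$pixel_size_nm
  g <- clemsim:::coord_grids(128, 128)
  analytic <- matrix(0, 128, 128)
  for (i in seq_len(nrow(s$puncta)))
    analytic <- analytic + s$puncta$intensity[i] *
      exp(-((g$x - s$puncta$x_px[i])^2 + (g$y - s$puncta$y_px[i])^2) /
            (2 * sigma_px^2))
  expect_gt(cor(as.numeric(fl0$pixels), as.numeric(analytic)), 0.99)
})

test_that("the true transform round-trips puncta to 1e-9 px", {
  for (seed in c(1L, 5L, 23L)) {
    s <- sample_scene(small_params(seed = seed))
    pts <- as.matrix(s$puncta[, c("x_px", "y_px")])
    back <- transform_points(invert_transform(s$true_transform),
                             transform_points(s$true_transform, pts))
    expect_lt(max(abs(back - pts)), 1e-9)
  }
})

test_that("training sets are aligned, reproducible, and validated", {
  expect_error(make_training_set(0), "n_pairs")
  ts1 <- make_training_set(30, small_params(), seed = 5L)
  ts2 <- make_training_set(30, small_params(), seed = 5L)
  expect_length(ts1, 30L)
  expect_identical(ts1[[7]]$em$pixels, ts2[[7]]$em$pixels)
  expect_identical(ts1[[30]]$chromatin$pixels, ts2[[30]]$chromatin$pixels)
  shapes <- vapply(ts1, function(p) dim(p$em$pixels), integer(2))
  expect_true(all(shapes == 128L))
  # alignment: each pair's noiseless chromatin peaks at EM-frame puncta
  s <- ts1[[3]]$scene
  fl0 <- render_fluorescence(s, apply_misalignment = FALSE, noise = FALSE)
  idx <- cbind(round(s$puncta$y_px) + 1, round(s$puncta$x_px) + 1)
  expect_true(all(fl0$pixels[idx] > 0.5))
})

test_that("write_scene produces the full file set", {
  dir <- withr::local_tempdir()
  s <- sample_scene(small_params(seed = 30L))
  paths <- write_scene(s, dir)
  expect_true(all(file.exists(paths)))
  tr <- read_transform_xml(paths[["transform"]])
  expect_equal(tr$scale, s$true_transform$scale, tolerance = 1e-9)
  pt <- utils::read.csv(paths[["puncta"]])
  expect_identical(nrow(pt), nrow(s$puncta))
  em_back <- read_image(paths[["em"]], modality = "EM")
  expect_equal(em_back$pixel_size_nm, 25, tolerance = 1e-6)
})
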