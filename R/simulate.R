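#' Parameters of a synthetic correlative scene
#'
#' The simulator emulates the situation the registration workflow is built
#' for: resin-section nuclei whose heterochromatin puncta are electron-dense
#' (dark) in the EM image and Hoechst-bright in the fluorescence channel,
#' with the two modalities related by an unknown global similarity
#' transform. Correlation needs at least three puncta in the field of view,
#' so the minimum puncta count per nucleus is 3.
#'
#' Defaults: 256 x 256 px at 25 nm/px (a 6.4 um field, so the standard
#' 3125 nm evaluation shift is exactly 125 px), two nuclei with 3-6 puncta
#' each, punctum radii 100-250 nm, a SIM-scale PSF (sigma 60 nm), and a
#' modest misalignment range (rotation within 15 degrees, scale within 2%,
#' shift within 625 nm) typical of manually placed serial sections.
#'
#' @param image_size_px integer (H, W) of both rendered modalities.
#' @param pixel_size_nm physical pixel size, nm/px.
#' @param n_nuclei number of nuclei in the field.
#' @param puncta_per_nucleus_range integer (min, max) puncta per nucleus;
#'   min must be >= 3.
#' @param punctum_radius_nm_range punctum radius range, nm.
#' @param nucleus_radius_nm_range nucleus semi-axis range, nm.
#' @param em_noise_sd sd of additive Gaussian noise on the EM render.
#' @param fluo_psf_sigma_nm Gaussian PSF sigma of the fluorescence render, nm.
#' @param fluo_background constant fluorescence background level.
#' @param fluo_noise list with `gaussian_sd` (read noise) and
#'   `poisson_scaling` (photons per intensity unit; 0 disables shot noise).
#' @param misalignment_ranges list with `theta_deg`, `scale`, `shift_nm`
#'   ranges (each length-2) from which the true EM-to-fluorescence
#'   misalignment is drawn uniformly, about the image center.
#' @param seed integer seed; scenes are pure functions of (params, seed).
#' @return A list of class `scene_params`.
#' @export
scene_params <- function(image_size_px = c(256L, 256L),
                         pixel_size_nm = 25,
                         n_nuclei = 2L,
                         puncta_per_nucleus_range = c(3L, 6L),
                         punctum_radius_nm_range = c(100, 250),
                         nucleus_radius_nm_range = c(1250, 2250),
                         em_noise_sd = 0.03,
                         fluo_psf_sigma_nm = 60,
                         fluo_background = 0.05,
                         fluo_noise = list(gaussian_sd = 0.01, poisson_scaling = 200),
                         misalignment_ranges = list(theta_deg = c(-15, 15),
                                                    scale = c(0.98, 1.02),
                                                    shift_nm = c(-625, 625)),
                         seed = 1L) {
  stopifnot(length(image_size_px) == 2L, all(image_size_px >= 32),
            pixel_size_nm > 0, n_nuclei >= 1L,
            length(puncta_per_nucleus_range) == 2L,
            diff(punctum_radius_nm_range) >= 0,
            diff(nucleus_radius_nm_range) >= 0,
            em_noise_sd >= 0, fluo_psf_sigma_nm > 0, fluo_background >= 0)
  if (puncta_per_nucleus_range[1] < 3L)
    stop("scene_params: at least 3 puncta per nucleus are required ",
         "(similarity registration needs >= 3 landmarks in the field of view)")
  if (puncta_per_nucleus_range[1] > puncta_per_nucleus_range[2])
    stop("scene_params: puncta_per_nucleus_range must be ordered")
  for (nm in c("theta_deg", "scale", "shift_nm")) {
    r <- misalignment_ranges[[nm]]
    if (is.null(r) || length(r) != 2L || r[1] > r[2])
      stop("scene_params: misalignment_ranges$", nm, " must be an ordered range")
  }
  structure(list(image_size_px = as.integer(image_size_px),
                 pixel_size_nm = as.numeric(pixel_size_nm),
                 n_nuclei = as.integer(n_nuclei),
                 puncta_per_nucleus_range = as.integer(puncta_per_nucleus_range),
                 punctum_radius_nm_range = as.numeric(punctum_radius_nm_range),
                 nucleus_radius_nm_range = as.numeric(nucleus_radius_nm_range),
                 em_noise_sd = as.numeric(em_noise_sd),
                 fluo_psf_sigma_nm = as.numeric(fluo_psf_sigma_nm),
                 fluo_background = as.numeric(fluo_background),
                 fluo_noise = fluo_noise,
                 misalignment_ranges = misalignment_ranges,
                 seed = as.integer(seed)),
            class = "scene_params")
}

#' Sample a synthetic scene (ground truth) from scene parameters
#'
#' Draws nuclei (ellipses), non-overlapping heterochromatin puncta inside
#' them, and the true EM-to-fluorescence misalignment. Everything is
#' deterministic given `params$seed`. Puncta are kept in the central part
#' of each nucleus and nuclei in the central part of the field, so they
#' remain informative under the benchmark's large perturbations.
#'
#' @param params a [scene_params()] object.
#' @return A list of class `synthetic_scene` with elements `params`,
#'   `nuclei` (data frame), `puncta` (data frame with `x_px`, `y_px`,
#'   `radius_nm`, `intensity`), `true_transform` (EM frame to fluorescence
#'   frame), and internal render seeds.
#' @export
sample_scene <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  H <- params$image_size_px[1]; W <- params$image_size_px[2]
  ps <- params$pixel_size_nm
  with_seed(params$seed, {
    nuc_r_px <- params$nucleus_radius_nm_range / ps
    nuclei <- data.frame(
      cx = stats::runif(params$n_nuclei, 0.30 * W, 0.70 * W),
      cy = stats::runif(params$n_nuclei, 0.30 * H, 0.70 * H),
      a  = stats::runif(params$n_nuclei, nuc_r_px[1], nuc_r_px[2]),
      b  = stats::runif(params$n_nuclei, nuc_r_px[1], nuc_r_px[2]),
      phi = stats::runif(params$n_nuclei, 0, pi))
    # clamp semi-axes so nuclei stay inside the field
    nuclei$a <- pmin(nuclei$a, 0.45 * min(H, W))
    nuclei$b <- pmin(nuclei$b, 0.45 * min(H, W))

    puncta <- list()
    for (n in seq_len(params$n_nuclei)) {
      k <- sample(params$puncta_per_nucleus_range[1]:params$puncta_per_nucleus_range[2], 1L)
      placed <- 0L; tries <- 0L
      while (placed < k) {
        tries <- tries + 1L
        if (tries > 400L)
          stop("sample_scene: could not place ", k, " non-overlapping puncta; ",
               "use a larger image or larger nuclei")
        r_nm <- stats::runif(1, params$punctum_radius_nm_range[1],
                             params$punctum_radius_nm_range[2])
        r_px <- r_nm / ps
        # uniform in the inner 80% of the ellipse
        u <- sqrt(stats::runif(1)) * 0.8; ang <- stats::runif(1, 0, 2 * pi)
        ex <- u * nuclei$a[n] * cos(ang); ey <- u * nuclei$b[n] * sin(ang)
        x <- nuclei$cx[n] + ex * cos(nuclei$phi[n]) - ey * sin(nuclei$phi[n])
        y <- nuclei$cy[n] + ex * sin(nuclei$phi[n]) + ey * cos(nuclei$phi[n])
        ok <- TRUE
        for (p in puncta) {
          if (sqrt((p$x_px - x)^2 + (p$y_px - y)^2) <= (p$radius_nm / ps + r_px)) {
            ok <- FALSE; break
          }
        }
        if (!ok) next
        puncta[[length(puncta) + 1L]] <- list(
          x_px = x, y_px = y, radius_nm = r_nm,
          intensity = stats::runif(1, 0.6, 1.0))
        placed <- placed + 1L
      }
    }
    puncta <- do.call(rbind.data.frame, puncta)

    mr <- params$misalignment_ranges
    theta <- stats::runif(1, mr$theta_deg[1], mr$theta_deg[2]) * pi / 180
    sc <- stats::runif(1, mr$scale[1], mr$scale[2])
    shift_px <- stats::runif(2, mr$shift_nm[1], mr$shift_nm[2]) / ps
    true_transform <- transform_about_center(theta, sc,
                                             center = c((W - 1) / 2, (H - 1) / 2),
                                             shift = shift_px)
    render_seeds <- sample.int(2^31 - 2, 4L)
    structure(list(params = params, nuclei = nuclei, puncta = puncta,
                   true_transform = true_transform,
                   render_seeds = list(em_texture = render_seeds[1],
                                       em_noise = render_seeds[2],
                                       fluo_noise = render_seeds[3],
                                       coi = render_seeds[4])),
              class = "synthetic_scene")
  })
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene> %d x %d px, %d nuclei, %d puncta, seed %d\n",
              x$params$image_size_px[1], x$params$image_size_px[2],
              nrow(x$nuclei), nrow(x$puncta), x$params$seed))
  print(x$true_transform)
  invisible(x)
}

# signed ellipse "radius" field: q < 1 inside, > 1 outside
ellipse_field <- function(grid, cx, cy, a, b, phi) {
  dx <- grid$x - cx; dy <- grid$y - cy
  u <- dx * cos(phi) + dy * sin(phi)
  v <- -dx * sin(phi) + dy * cos(phi)
  (u / a)^2 + (v / b)^2
}

# linear smoothstep from 1 (q <= lo) to 0 (q >= hi)
soft_inside <- function(q, lo, hi) pmin(1, pmax(0, (hi - q) / (hi - lo)))

#' Render the EM modality of a scene
#'
#' Mid-gray cytoplasm with smooth low-frequency texture, slightly darker
#' nucleoplasm, and heterochromatin puncta as dark soft-edged disks
#' (electron-dense chromatin), plus additive Gaussian noise. Deterministic
#' given the scene; rendering twice gives identical pixels.
#'
#' @param scene a `synthetic_scene`.
#' @param noise if `FALSE`, omit the additive noise (noiseless render,
#'   used by the evaluation oracles).
#' @return An `image_plane` with modality `"EM"`.
#' @export
render_em <- function(scene, noise = TRUE) {
  stopifnot(inherits(scene, "synthetic_scene"))
  p <- scene$params
  H <- p$image_size_px[1]; W <- p$image_size_px[2]
  g <- coord_grids(H, W)
  img <- matrix(0.55, H, W)
  tex <- with_seed(scene$render_seeds$em_texture,
                   gaussian_blur(matrix(stats::rnorm(H * W), H, W), 6))
  img <- img + tex / stats::sd(tex) * 0.02
  for (n in seq_len(nrow(scene$nuclei))) {
    q <- ellipse_field(g, scene$nuclei$cx[n], scene$nuclei$cy[n],
                       scene$nuclei$a[n], scene$nuclei$b[n], scene$nuclei$phi[n])
    img <- img - 0.10 * soft_inside(q, 0.94, 1.06)
  }
  for (i in seq_len(nrow(scene$puncta))) {
    r_px <- scene$puncta$radius_nm[i] / p$pixel_size_nm
    d <- sqrt((g$x - scene$puncta$x_px[i])^2 + (g$y - scene$puncta$y_px[i])^2)
    w <- soft_inside(d / r_px, 1 - 1.2 / r_px, 1 + 1.2 / r_px)
    img <- img - 0.35 * scene$puncta$intensity[i] * w
  }
  if (noise && p$em_noise_sd > 0)
    img <- img + with_seed(scene$render_seeds$em_noise,
                           matrix(stats::rnorm(H * W, sd = p$em_noise_sd), H, W))
  image_plane(img, p$pixel_size_nm, modality = "EM", channel_name = "em")
}

# sum-of-Gaussians field at given spot positions (the analytic fluorescence model)
gaussian_spot_field <- function(H, W, xs, ys, amps, sigma_px, background = 0) {
  g <- coord_grids(H, W)
  img <- matrix(background, H, W)
  for (i in seq_along(xs)) {
    img <- img + amps[i] *
      exp(-((g$x - xs[i])^2 + (g$y - ys[i])^2) / (2 * sigma_px^2))
  }
  img
}

#' Render the fluorescence (chromatin) modality of a scene
#'
#' Puncta appear as bright Gaussian spots (the Hoechst chromatin signal
#' seen through a SIM-scale PSF) over a constant background, with scaled
#' Poisson shot noise plus Gaussian read noise. When `apply_misalignment`
#' is `TRUE`, spot positions are mapped through the scene's true transform
#' (the fluorescence frame the microscope actually delivered); when
#' `FALSE` the render is aligned to the EM frame (ground-truth chromatin,
#' as used for network training).
#'
#' @param scene a `synthetic_scene`.
#' @param apply_misalignment map puncta through the true transform?
#' @param noise if `FALSE`, return the noiseless analytic field.
#' @param channel channel label of the returned plane.
#' @return An `image_plane` with modality `"FLUO"`.
#' @export
render_fluorescence <- function(scene, apply_misalignment = FALSE, noise = TRUE,
                                channel = "chromatin") {
  stopifnot(inherits(scene, "synthetic_scene"))
  p <- scene$params
  H <- p$image_size_px[1]; W <- p$image_size_px[2]
  pos <- cbind(scene$puncta$x_px, scene$puncta$y_px)
  if (apply_misalignment) pos <- transform_points(scene$true_transform, pos)
  sigma_px <- p$fluo_psf_sigma_nm / p$pixel_size_nm
  img <- gaussian_spot_field(H, W, pos[, 1], pos[, 2], scene$puncta$intensity,
                             sigma_px, p$fluo_background)
  if (noise) {
    img <- with_seed(scene$render_seeds$fluo_noise, {
      K <- p$fluo_noise$poisson_scaling
      out <- if (!is.null(K) && K > 0)
        matrix(stats::rpois(H * W, pmax(img, 0) * K) / K, H, W) else img
      gs <- p$fluo_noise$gaussian_sd
      if (!is.null(gs) && gs > 0)
        out <- out + matrix(stats::rnorm(H * W, sd = gs), H, W)
      out
    })
  }
  image_plane(img, p$pixel_size_nm, modality = "FLUO", channel_name = channel)
}

#' Render a "channel of interest" for a scene
#'
#' A second fluorescence channel (e.g. an immunolabel) with a few spots at
#' positions unrelated to the chromatin puncta, misaligned by the same true
#' transform. It carries no registration information itself: exactly the
#' situation where the chromatin-based transform must be re-applied.
#'
#' @inheritParams render_fluorescence
#' @param n_spots number of labeled spots.
#' @return An `image_plane` with modality `"FLUO"`.
#' @export
render_channel_of_interest <- function(scene, apply_misalignment = TRUE,
                                       noise = TRUE, n_spots = 5L) {
  stopifnot(inherits(scene, "synthetic_scene"))
  p <- scene$params
  H <- p$image_size_px[1]; W <- p$image_size_px[2]
  spots <- with_seed(scene$render_seeds$coi, {
    n <- sample(seq_len(nrow(scene$nuclei)), n_spots, replace = TRUE)
    u <- sqrt(stats::runif(n_spots)) * 0.9
    ang <- stats::runif(n_spots, 0, 2 * pi)
    ex <- u * scene$nuclei$a[n] * cos(ang); ey <- u * scene$nuclei$b[n] * sin(ang)
    cbind(scene$nuclei$cx[n] + ex * cos(scene$nuclei$phi[n]) - ey * sin(scene$nuclei$phi[n]),
          scene$nuclei$cy[n] + ex * sin(scene$nuclei$phi[n]) + ey * cos(scene$nuclei$phi[n]),
          stats::runif(n_spots, 0.5, 1.0))
  })
  pos <- spots[, 1:2, drop = FALSE]
  if (apply_misalignment) pos <- transform_points(scene$true_transform, pos)
  sigma_px <- p$fluo_psf_sigma_nm / p$pixel_size_nm
  img <- gaussian_spot_field(H, W, pos[, 1], pos[, 2], spots[, 3],
                             sigma_px, p$fluo_background)
  if (noise) {
    img <- with_seed(scene$render_seeds$coi + 1, {
      K <- p$fluo_noise$poisson_scaling
      out <- if (!is.null(K) && K > 0)
        matrix(stats::rpois(H * W, pmax(img, 0) * K) / K, H, W) else img
      gs <- p$fluo_noise$gaussian_sd
      if (!is.null(gs) && gs > 0) out <- out + matrix(stats::rnorm(H * W, sd = gs), H, W)
      out
    })
  }
  image_plane(img, p$pixel_size_nm, modality = "FLUO",
              channel_name = "channel_of_interest")
}

#' Generate an aligned EM / chromatin training set
#'
#' Renders `n_pairs` independent scenes (seeds derived deterministically
#' from `seed`) and returns the aligned pairs used to train the
#' chromatin-prediction network. 30-40 pairs are a good working size for a
#' new experiment.
#'
#' @param n_pairs number of pairs (>= 1).
#' @param params [scene_params()] shared by all scenes (the per-scene seed
#'   field is replaced by derived seeds).
#' @param seed master seed.
#' @return A list of `n_pairs` elements, each a list with `em`,
#'   `chromatin` (aligned `image_plane`s) and `scene`.
#' @export
make_training_set <- function(n_pairs, params = scene_params(), seed = 1L) {
  if (!is.numeric(n_pairs) || n_pairs < 1L)
    stop("make_training_set: n_pairs must be >= 1")
  seeds <- derive_seeds(seed, n_pairs)
  lapply(seq_len(n_pairs), function(i) {
    pi_ <- params; pi_$seed <- seeds[i]
    sc <- sample_scene(pi_)
    list(em = render_em(sc),
         chromatin = render_fluorescence(sc, apply_misalignment = FALSE),
         scene = sc)
  })
}

#' Write a simulated scene to a directory
#'
#' Writes the EM image, aligned and misaligned chromatin, an extra channel
#' of interest, the ground-truth transform XML, and the puncta table (CSV)
#' for one scene. This is the command-line `simulate` entry point.
#'
#' @param scene a `synthetic_scene`.
#' @param dir output directory (created if missing).
#' @return Named character vector of written paths, invisibly.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(em = file.path(dir, "em.tif"),
             chromatin_aligned = file.path(dir, "chromatin_aligned.tif"),
             chromatin = file.path(dir, "chromatin.tif"),
             channel_of_interest = file.path(dir, "channel_of_interest.tif"),
             transform = file.path(dir, "true_transform.xml"),
             puncta = file.path(dir, "puncta.csv"))
  write_image(render_em(scene), paths[["em"]])
  write_image(render_fluorescence(scene, apply_misalignment = FALSE),
              paths[["chromatin_aligned"]])
  write_image(render_fluorescence(scene, apply_misalignment = TRUE),
              paths[["chromatin"]])
  write_image(render_channel_of_interest(scene), paths[["channel_of_interest"]])
  write_transform_xml(
    as_transform_record(scene$true_transform, scene$params$pixel_size_nm,
                        moving_name = "em_frame", fixed_name = "fluo_frame"),
    paths[["transform"]])
  utils::write.csv(scene$puncta, paths[["puncta"]], row.names = FALSE)
  invisible(paths)
}
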