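#' Registration configuration
#'
#' The measured chromatin image is aligned to the predicted chromatin image
#' through a feature pipeline tuned to punctate signals: multiscale
#' Laplacian-of-Gaussian blob detection (heterochromatin puncta are the
#' implicit fiducials), rotation-invariant ring descriptors with ratio-test
#' matching, RANSAC over 2-point minimal samples, and an optional local
#' correlation refinement. When feature matching cannot produce a
#' consensus (few or ambiguous puncta), an exhaustive correlation search
#' over a rotation/scale grid serves as fallback.
#'
#' @param detector feature detector; only `"LOG_BLOBS"`.
#' @param n_scales number of LoG scales (log-spaced).
#' @param sigma_min_px,sigma_max_px LoG scale range in pixels.
#' @param blob_threshold minimum scale-normalized LoG response.
#' @param match_ratio Lowe-style ratio-test threshold in (0, 1).
#' @param ransac_iters number of RANSAC hypotheses.
#' @param inlier_tol_px residual tolerance (px) for RANSAC consensus.
#' @param min_inliers minimum consensus size (>= 3).
#' @param refine `"NCC_LOCAL"` (bounded local optimization of the
#'   correlation score over the 4 transform parameters) or `"NONE"`.
#' @param fallback `"EXHAUSTIVE"` (grid search when features fail) or
#'   `"NONE"`.
#' @param fallback_theta_step_deg rotation grid step of the fallback.
#' @param fallback_scale_grid scale grid of the fallback.
#' @param seed RANSAC sampling seed.
#' @return A list of class `register_config`.
#' @export
register_config <- function(detector = "LOG_BLOBS", n_scales = 6L,
                            sigma_min_px = 1.5, sigma_max_px = 8,
                            blob_threshold = 0.08,
                            match_ratio = 0.8, ransac_iters = 2000L,
                            inlier_tol_px = 3.0, min_inliers = 3L,
                            refine = c("NCC_LOCAL", "NONE"),
                            fallback = c("EXHAUSTIVE", "NONE"),
                            fallback_theta_step_deg = 2,
                            fallback_scale_grid = 1.0,
                            seed = 42L) {
  refine <- match.arg(refine); fallback <- match.arg(fallback)
  stopifnot(identical(detector, "LOG_BLOBS"), n_scales >= 1,
            sigma_min_px > 0, sigma_max_px >= sigma_min_px,
            match_ratio > 0, match_ratio < 1,
            ransac_iters >= 1, inlier_tol_px > 0, min_inliers >= 3)
  structure(list(detector = detector, n_scales = as.integer(n_scales),
                 sigma_min_px = sigma_min_px, sigma_max_px = sigma_max_px,
                 blob_threshold = blob_threshold, match_ratio = match_ratio,
                 ransac_iters = as.integer(ransac_iters),
                 inlier_tol_px = inlier_tol_px,
                 min_inliers = as.integer(min_inliers),
                 refine = refine, fallback = fallback,
                 fallback_theta_step_deg = fallback_theta_step_deg,
                 fallback_scale_grid = fallback_scale_grid,
                 seed = as.integer(seed)),
            class = "register_config")
}

# --- blob detection ---------------------------------------------------------

# discrete Laplacian with replicate borders
laplacian <- function(m) {
  p <- pad_replicate(m, 1L)
  H <- nrow(m); W <- ncol(m)
  p[1:H + 1, 1:W] + p[1:H + 1, 1:W + 2] +
    p[1:H, 1:W + 1] + p[1:H + 2, 1:W + 1] - 4 * m
}

#' Detect bright blobs (heterochromatin puncta) in an image
#'
#' Multiscale scale-normalized Laplacian-of-Gaussian detection of bright
#' blobs: local maxima of `-sigma^2 * Laplacian(G_sigma * I)` across
#' position and scale, above `blob_threshold`, localized to sub-pixel
#' accuracy by a quadratic fit. The reported `scale_px` is `sigma * sqrt(2)`,
#' an estimate of the blob radius. Keypoints carry a rotation-invariant
#' descriptor (intensity means over concentric rings, normalized to zero
#' mean and unit length) and are sorted by response, strongest first.
#'
#' @param img an `image_plane` or matrix (preprocessed, bright puncta).
#' @param cfg a [register_config()].
#' @return A data frame with columns `x_px`, `y_px`, `scale_px`,
#'   `response`, plus a `descriptors` attribute (one row per keypoint).
#'   Constant images yield zero rows.
#' @export
detect_blobs <- function(img, cfg = register_config()) {
  m <- if (inherits(img, "image_plane")) img$pixels else img
  if (diff(range(m)) == 0) return(empty_keypoints())
  sigmas <- exp(seq(log(cfg$sigma_min_px), log(cfg$sigma_max_px),
                    length.out = cfg$n_scales))
  H <- nrow(m); W <- ncol(m)
  resp <- array(0, c(H, W, length(sigmas)))
  for (k in seq_along(sigmas))
    resp[, , k] <- -sigmas[k]^2 * laplacian(gaussian_blur(m, sigmas[k]))

  kps <- list()
  for (k in seq_along(sigmas)) {
    r <- resp[, , k]
    # strict spatial maximum over the 8-neighborhood, away from borders
    p <- matrix(-Inf, H + 2, W + 2); p[2:(H + 1), 2:(W + 1)] <- r
    is_max <- r > cfg$blob_threshold
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      is_max <- is_max & (r > p[1:H + 1 + di, 1:W + 1 + dj])
    }
    is_max[c(1, H), ] <- FALSE; is_max[, c(1, W)] <- FALSE
    # maximum across adjacent scales at the same pixel
    if (k > 1) is_max <- is_max & (r >= resp[, , k - 1])
    if (k < length(sigmas)) is_max <- is_max & (r >= resp[, , k + 1])
    idx <- which(is_max, arr.ind = TRUE)
    if (nrow(idx) == 0) next
    for (n in seq_len(nrow(idx))) {
      i <- as.integer(idx[n, 1]); j <- as.integer(idx[n, 2])
      # sub-pixel quadratic fit per axis
      dy <- quad_offset(r[i - 1, j], r[i, j], r[i + 1, j])
      dx <- quad_offset(r[i, j - 1], r[i, j], r[i, j + 1])
      kps[[length(kps) + 1L]] <- c(x = (j - 1L) + dx, y = (i - 1L) + dy,
                                   sigma = sigmas[k], response = r[i, j])
      names(kps[[length(kps)]]) <- c("x", "y", "sigma", "response")
    }
  }
  if (!length(kps)) return(empty_keypoints())
  kp <- do.call(rbind, kps)
  kp <- kp[order(-kp[, "response"]), , drop = FALSE]
  # merge duplicate detections across scales (within 2 px): keep strongest
  keep <- rep(TRUE, nrow(kp))
  for (i in seq_len(nrow(kp))) {
    if (!keep[i]) next
    if (i < nrow(kp)) {
      d2 <- (kp[(i + 1):nrow(kp), "x"] - kp[i, "x"])^2 +
            (kp[(i + 1):nrow(kp), "y"] - kp[i, "y"])^2
      keep[(i + 1):nrow(kp)][d2 < 4] <- FALSE
    }
  }
  kp <- kp[keep, , drop = FALSE]
  out <- data.frame(x_px = kp[, "x"], y_px = kp[, "y"],
                    scale_px = kp[, "sigma"] * sqrt(2),
                    response = kp[, "response"])
  ring <- ring_descriptors(m, out$x_px, out$y_px, kp[, "sigma"])
  attr(out, "descriptors") <- cbind(ring, neighbor_descriptors(out$x_px, out$y_px))
  attr(out, "descriptors") <- attr(out, "descriptors") /
    pmax(sqrt(rowSums(attr(out, "descriptors")^2)), 1e-12)
  out
}

# Rotation- and scale-invariant geometric context: log distances to the
# k nearest other keypoints, normalized by the mean pairwise distance of
# the whole set. Distinguishes look-alike puncta by their constellation.
neighbor_descriptors <- function(xs, ys, k = 3L) {
  n <- length(xs)
  if (n < 2) return(matrix(0, n, k))
  d <- as.matrix(stats::dist(cbind(xs, ys)))
  dbar <- mean(d[upper.tri(d)])
  if (dbar <= 0) return(matrix(0, n, k))
  D <- matrix(0, n, k)
  for (i in seq_len(n)) {
    nd <- sort(d[i, -i])[seq_len(min(k, n - 1))]
    D[i, seq_along(nd)] <- log(nd / dbar)
  }
  D
}

empty_keypoints <- function() {
  out <- data.frame(x_px = numeric(0), y_px = numeric(0),
                    scale_px = numeric(0), response = numeric(0))
  attr(out, "descriptors") <- matrix(numeric(0), 0, 8)
  out
}

quad_offset <- function(a, b, c) {
  den <- a - 2 * b + c
  if (den >= 0) return(0)          # not a proper maximum; stay on the grid
  off <- 0.5 * (a - c) / den
  max(-0.5, min(0.5, off))
}

# Rotation-invariant descriptor: mean intensity over 8 concentric rings of
# radius proportional to the detection scale, zero-meaned, unit-normalized.
ring_descriptors <- function(m, xs, ys, sigmas, n_rings = 8L, n_angles = 16L) {
  if (!length(xs)) return(matrix(numeric(0), 0, n_rings))
  ang <- seq(0, 2 * pi, length.out = n_angles + 1L)[-(n_angles + 1L)]
  D <- matrix(0, length(xs), n_rings)
  for (i in seq_along(xs)) {
    for (j in seq_len(n_rings)) {
      rad <- (j - 0.5) * 0.6 * sigmas[i]
      v <- bilinear_sample(m, xs[i] + rad * cos(ang), ys[i] + rad * sin(ang))
      D[i, j] <- mean(as.numeric(v))
    }
    D[i, ] <- D[i, ] - mean(D[i, ])
    nrm <- sqrt(sum(D[i, ]^2))
    if (nrm > 0) D[i, ] <- D[i, ] / nrm
  }
  D
}

# --- matching ---------------------------------------------------------------

#' Match keypoints between moving and fixed images
#'
#' Mutual-nearest-neighbor matching in descriptor space with a Lowe-style
#' ratio test: a match is kept only if the best descriptor distance is at
#' most `match_ratio` times the second best (ambiguous matches between
#' look-alike puncta are dropped). Deterministic.
#'
#' @param moving_kps,fixed_kps keypoint frames from [detect_blobs()].
#' @param match_ratio ratio-test threshold.
#' @return A correspondence data frame with columns `x_mov`, `y_mov`,
#'   `x_fix`, `y_fix`, `score` (possibly zero rows).
#' @export
match_keypoints <- function(moving_kps, fixed_kps, match_ratio = 0.8) {
  empty <- data.frame(x_mov = numeric(0), y_mov = numeric(0),
                      x_fix = numeric(0), y_fix = numeric(0), score = numeric(0))
  nm <- nrow(moving_kps); nf <- nrow(fixed_kps)
  if (nm == 0 || nf == 0) return(empty)
  Dm <- attr(moving_kps, "descriptors"); Df <- attr(fixed_kps, "descriptors")
  if (ncol(Dm) != ncol(Df)) stop("match_keypoints: descriptor lengths differ")
  # all-pairs Euclidean distances
  d2 <- outer(rowSums(Dm^2), rowSums(Df^2), "+") - 2 * Dm %*% t(Df)
  d2[d2 < 0] <- 0
  nn_f_of_m <- apply(d2, 1, which.min)
  nn_m_of_f <- apply(d2, 2, which.min)
  rows <- list()
  for (i in seq_len(nm)) {
    j <- nn_f_of_m[i]
    if (nn_m_of_f[j] != i) next                       # not mutual
    if (nf >= 2) {
      d_sorted <- sort(d2[i, ])[1:2]
      # strict Lowe test: equal first and second distances are ambiguous
      if (!(sqrt(d_sorted[1]) < match_ratio * sqrt(d_sorted[2]))) next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      x_mov = moving_kps$x_px[i], y_mov = moving_kps$y_px[i],
      x_fix = fixed_kps$x_px[j], y_fix = fixed_kps$y_px[j],
      score = 1 / (1 + sqrt(d2[i, j])))
  }
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}

# --- similarity fitting -----------------------------------------------------

#' Least-squares similarity fit from point correspondences
#'
#' Closed-form fit of rotation, isotropic scale and translation minimizing
#' the sum of squared residuals, via the complex-number formulation: with
#' centered moving points `z` and fixed points `w`, the optimal rotation
#' and scale are `a = sum(w * Conj(z)) / sum(|z|^2)`, giving
#' `scale = |a|`, `theta = Arg(a)`. Reflections are not part of the model;
#' if a reflected fit would be strictly better the fit aborts with a
#' `REFLECTION_REQUIRED` error rather than silently returning a poor
#' rotation.
#'
#' @param correspondences data frame with `x_mov`, `y_mov`, `x_fix`,
#'   `y_fix` (as produced by [match_keypoints()]), at least 2 rows.
#' @return A `similarity_transform` mapping moving to fixed coordinates.
#' @export
fit_similarity <- function(correspondences) {
  cs <- correspondences
  if (is.null(cs) || nrow(cs) < 2)
    stop("fit_similarity: at least 2 correspondences are required")
  z <- complex(real = cs$x_mov, imaginary = cs$y_mov)
  w <- complex(real = cs$x_fix, imaginary = cs$y_fix)
  zc <- z - mean(z); wc <- w - mean(w)
  den <- sum(Mod(zc)^2)
  if (den == 0)
    stop("fit_similarity: degenerate correspondences (all moving points coincide)")
  num_direct <- sum(wc * Conj(zc))
  num_reflected <- sum(wc * zc)
  if (Mod(num_reflected) > Mod(num_direct) * (1 + 1e-12))
    stop("REFLECTION_REQUIRED: the best-fitting map is a reflection, which ",
         "is outside the similarity model (flipped section?)")
  a <- num_direct / den
  if (Mod(a) == 0) stop("fit_similarity: degenerate fit (zero scale)")
  b <- mean(w) - a * mean(z)
  similarity_transform(Arg(a), Mod(a), Re(b), Im(b))
}

#' Robust similarity estimation with RANSAC
#'
#' Repeatedly fits the similarity on minimal samples of 2 correspondences,
#' scores consensus as residuals at most `inlier_tol_px`, and refits on
#' the best consensus set (ties broken by lower inlier RMS residual).
#' Deterministic given `cfg$seed`. Fails with a `NO_CONSENSUS` error when
#' the best consensus is smaller than `cfg$min_inliers`.
#'
#' @param correspondences correspondence data frame (>= 2 rows).
#' @param cfg a [register_config()].
#' @return A list with `transform` (refit on all inliers) and `inliers`
#'   (logical mask over the correspondences).
#' @export
ransac_similarity <- function(correspondences, cfg = register_config()) {
  cs <- correspondences
  if (is.null(cs) || nrow(cs) < 2)
    stop("ransac_similarity: at least 2 correspondences are required")
  n <- nrow(cs)
  mov <- cbind(cs$x_mov, cs$y_mov); fix <- cbind(cs$x_fix, cs$y_fix)
  resid_of <- function(t) {
    d <- transform_points(t, mov) - fix
    sqrt(rowSums(d^2))
  }
  best <- NULL
  with_seed(cfg$seed, {
    for (it in seq_len(cfg$ransac_iters)) {
      s <- sample.int(n, 2L)
      if (all(mov[s[1], ] == mov[s[2], ])) next
      t_hyp <- tryCatch(fit_similarity(cs[s, , drop = FALSE]),
                        error = function(e) NULL)
      if (is.null(t_hyp)) next
      r <- resid_of(t_hyp)
      inl <- r <= cfg$inlier_tol_px
      k <- sum(inl)
      if (k < 2) next
      rms <- sqrt(mean(r[inl]^2))
      if (is.null(best) || k > best$k || (k == best$k && rms < best$rms))
        best <- list(k = k, rms = rms, inliers = inl, resid = r)
    }
  })
  if (is.null(best) || best$k < cfg$min_inliers)
    stop("NO_CONSENSUS: RANSAC consensus of ",
         if (is.null(best)) 0 else best$k, " is below min_inliers = ",
         cfg$min_inliers)
  # Tighten the tolerance to the robust residual scale of the winning
  # hypothesis before the final refit, so an outlier that happens to fall
  # just inside the raw tolerance cannot bias the least-squares solution.
  s_rob <- 1.4826 * stats::median(best$resid[best$inliers])
  tol_fin <- min(cfg$inlier_tol_px, max(6 * s_rob, 1e-6))
  inl <- best$resid <= tol_fin
  if (sum(inl) < cfg$min_inliers) inl <- best$inliers
  t_fin <- fit_similarity(cs[inl, , drop = FALSE])
  # consensus re-evaluated once under the refit transform
  inl2 <- resid_of(t_fin) <= tol_fin
  if (sum(inl2) >= cfg$min_inliers) {
    t_fin <- fit_similarity(cs[inl2, , drop = FALSE])
    inl <- inl2
  }
  list(transform = t_fin, inliers = inl)
}

# --- correlation scoring and exhaustive search ------------------------------

#' Zero-normalized cross-correlation between two images
#'
#' @param img_a,img_b `image_plane`s or matrices of identical shape.
#' @param mask optional logical matrix restricting the score to valid
#'   (non-padded) pixels.
#' @return A single number in `[-1, 1]`.
#' @export
ncc <- function(img_a, img_b, mask = NULL) {
  a <- if (inherits(img_a, "image_plane")) img_a$pixels else img_a
  b <- if (inherits(img_b, "image_plane")) img_b$pixels else img_b
  if (!identical(dim(a), dim(b))) stop("ncc: images must have the same shape")
  ncc_values(a, b, mask)
}

# FFT cross-correlation of zero-meaned, zero-padded images.
# Returns the displacement (dx, dy) of b relative to a (b shifted by
# (dx, dy) best matches a): the integer correlation peak plus a quadratic
# sub-pixel correction (reported separately in the "int" attribute).
xcorr_peak <- function(a, b, fft_a = NULL) {
  H <- nrow(a); W <- ncol(a)
  Hp <- 2 * H; Wp <- 2 * W
  if (is.null(fft_a)) {
    pa <- matrix(0, Hp, Wp); pa[1:H, 1:W] <- a - mean(a)
    fft_a <- stats::fft(pa)
  }
  pb <- matrix(0, Hp, Wp)
  pb[1:H, 1:W] <- b - mean(b)
  cc <- Re(stats::fft(fft_a * Conj(stats::fft(pb)), inverse = TRUE))
  peak <- which.max(cc)
  pi_ <- (peak - 1) %% Hp; pj <- (peak - 1) %/% Hp
  wrap <- function(v, N) ifelse(v > N / 2, v - N, v)
  dy <- wrap(pi_, Hp); dx <- wrap(pj, Wp)
  at <- function(i, j) cc[(i %% Hp) + 1, (j %% Wp) + 1]
  sub_y <- quad_offset(at(pi_ - 1, pj), at(pi_, pj), at(pi_ + 1, pj))
  sub_x <- quad_offset(at(pi_, pj - 1), at(pi_, pj), at(pi_, pj + 1))
  out <- c(dx = dx + sub_x, dy = dy + sub_y)
  attr(out, "int") <- c(dx = dx, dy = dy)
  out
}

# NCC between a and b shifted by integer (dx, dy), over the overlap.
ncc_at_shift <- function(a, b, dx, dy) {
  H <- nrow(a); W <- ncol(a)
  xs_a <- max(1, 1 + dx):min(W, W + dx)
  ys_a <- max(1, 1 + dy):min(H, H + dy)
  if (length(xs_a) < 4 || length(ys_a) < 4) return(-Inf)
  sub_a <- a[ys_a, xs_a, drop = FALSE]
  sub_b <- b[ys_a - dy, xs_a - dx, drop = FALSE]
  tryCatch(ncc_values(sub_a, sub_b), error = function(e) -Inf)
}

#' Exhaustive similarity search by rotation/scale grid + correlation peak
#'
#' For every (theta, scale) on the grids, the moving image is rotated and
#' scaled about its center, the translation is found at the
#' cross-correlation peak (sub-pixel by quadratic fit), and the candidate
#' is scored by normalized cross-correlation; the best-scoring transform
#' is returned. Slower than feature matching but free of any assumption
#' about descriptor quality, which makes it both the fallback inside
#' [register_planes()] and an independent oracle for it.
#'
#' @param moving,fixed `image_plane`s or matrices of identical shape.
#' @param theta_grid_deg rotation grid, degrees.
#' @param scale_grid scale grid.
#' @return A `similarity_transform` (moving to fixed) with attributes
#'   `score` (NCC at the optimum) and `grid_step_deg`.
#' @export
exhaustive_similarity_search <- function(moving, fixed,
                                         theta_grid_deg = seq(-180, 178, by = 2),
                                         scale_grid = 1.0) {
  if (!length(theta_grid_deg) || !length(scale_grid))
    stop("exhaustive_similarity_search: empty grids")
  m <- if (inherits(moving, "image_plane")) moving$pixels else moving
  f <- if (inherits(fixed, "image_plane")) fixed$pixels else fixed
  if (!identical(dim(m), dim(f)))
    stop("exhaustive_similarity_search: images must have the same shape")
  center <- c((ncol(m) - 1) / 2, (nrow(m) - 1) / 2)
  pf <- matrix(0, 2 * nrow(f), 2 * ncol(f))
  pf[1:nrow(f), 1:ncol(f)] <- f - mean(f)
  fft_f <- stats::fft(pf)
  best <- NULL
  for (s in scale_grid) for (th in theta_grid_deg) {
    t_rot <- transform_about_center(th * pi / 180, s, center)
    m_rot <- apply_transform(m, t_rot)
    d <- xcorr_peak(f, m_rot, fft_a = fft_f)
    sc <- ncc_at_shift(f, m_rot, round(d[["dx"]]), round(d[["dy"]]))
    if (is.null(best) || sc > best$score)
      best <- list(score = sc, theta = th, scale = s, d = d,
                   m_rot = m_rot, t_rot = t_rot)
  }
  # accept the sub-pixel correction only if it actually improves the score
  # over the integer peak (for an exact integer shift it cannot, and the
  # integer displacement is then returned exactly)
  d_int <- attr(best$d, "int")
  cand <- list(c(d_int[["dx"]], d_int[["dy"]]),
               c(best$d[["dx"]], best$d[["dy"]]))
  score_d <- vapply(cand, function(dd) {
    w <- apply_transform(best$m_rot, similarity_transform(0, 1, dd[1], dd[2]))
    mask <- valid_mask_of(w)
    if (sum(mask) < 16) return(-Inf)
    tryCatch(ncc_values(f, w, mask), error = function(e) -Inf)
  }, numeric(1))
  d_best <- cand[[which.max(score_d)]]
  t_best <- compose_transforms(
    similarity_transform(0, 1, d_best[1], d_best[2]), best$t_rot)
  attr(t_best, "score") <- max(score_d)
  attr(t_best, "grid_step_deg") <-
    if (length(theta_grid_deg) > 1) diff(theta_grid_deg[1:2]) else 0
  t_best
}

# --- full registration pipeline ---------------------------------------------

#' Register a moving image to a fixed image
#'
#' The complete similarity-registration pipeline: blob detection in both
#' images, descriptor matching, RANSAC, optional local correlation
#' refinement, and an exhaustive grid-search fallback when the feature
#' stage cannot reach a consensus. Registration failure never raises; it
#' is reported in the `status` field (`OK`, `LOW_FEATURES`,
#' `NO_CONSENSUS`, `DEGRADED`), together with the correlation score
#' before and after alignment.
#'
#' @param moving,fixed preprocessed `image_plane`s of identical shape
#'   (moving = measured chromatin, fixed = predicted chromatin).
#' @param cfg a [register_config()].
#' @return A list of class `registration_result` with `transform`
#'   (moving to fixed), `n_inliers`, `score_before`, `score_after`,
#'   `status`, and `method` (`"features"` or `"exhaustive"`).
#' @export
register_planes <- function(moving, fixed, cfg = register_config()) {
  m <- if (inherits(moving, "image_plane")) moving$pixels else moving
  f <- if (inherits(fixed, "image_plane")) fixed$pixels else fixed
  if (!identical(dim(m), dim(f)))
    stop("register_planes: images must have the same shape")
  score_before <- tryCatch(ncc_values(f, m), error = function(e) NA_real_)
  if (diff(range(m)) == 0 || diff(range(f)) == 0)
    return(registration_result(identity_transform(), 0L, score_before,
                               NA_real_, "LOW_FEATURES", "none"))

  kp_m <- detect_blobs(m, cfg); kp_f <- detect_blobs(f, cfg)
  candidate <- NULL; n_inliers <- 0L; method <- "none"; feature_failed <- FALSE
  if (nrow(kp_m) >= 2 && nrow(kp_f) >= 2) {
    matches <- match_keypoints(kp_m, kp_f, cfg$match_ratio)
    if (nrow(matches) >= max(2L, cfg$min_inliers)) {
      rr <- tryCatch(ransac_similarity(matches, cfg), error = function(e) NULL)
      if (!is.null(rr)) {
        candidate <- rr$transform; n_inliers <- sum(rr$inliers)
        method <- "features"
      } else feature_failed <- TRUE
    } else feature_failed <- TRUE
  } else feature_failed <- TRUE

  if (is.null(candidate) && cfg$fallback == "EXHAUSTIVE") {
    # coarse grid search on a downsampled pyramid level, then lifted back
    lev <- 0L; md <- m; fd <- f
    while (max(dim(md)) > 128) { md <- downsample2(md); fd <- downsample2(fd); lev <- lev + 1L }
    cand_ds <- exhaustive_similarity_search(
      md, fd, theta_grid_deg = seq(-180, 180 - cfg$fallback_theta_step_deg,
                                   by = cfg$fallback_theta_step_deg),
      scale_grid = cfg$fallback_scale_grid)
    candidate <- lift_transform(cand_ds, lev)
    method <- "exhaustive"
  }
  if (!is.null(candidate) && nrow(kp_m) >= 2 && nrow(kp_f) >= 2) {
    # landmark polish: project moving blobs, pair with nearest fixed blobs,
    # refit in closed form (sub-pixel accuracy beyond any search grid)
    refit <- refine_with_landmarks(candidate, kp_m, kp_f, cfg$inlier_tol_px)
    if (!is.null(refit$transform) && refit$n >= max(3L, cfg$min_inliers)) {
      candidate <- refit$transform
      if (method == "exhaustive") n_inliers <- refit$n
    }
  }
  if (is.null(candidate)) {
    status <- if (nrow(kp_m) < cfg$min_inliers || nrow(kp_f) < cfg$min_inliers)
      "LOW_FEATURES" else "NO_CONSENSUS"
    return(registration_result(identity_transform(), 0L, score_before,
                               NA_real_, status, "none"))
  }

  score_of <- function(t) {
    w <- apply_transform(m, t)
    mask <- valid_mask_of(w)
    if (sum(mask) < 16) return(-Inf)
    tryCatch(ncc_values(f, w, mask), error = function(e) -Inf)
  }
  sc_cand <- score_of(candidate)
  if (cfg$refine == "NCC_LOCAL") {
    # bounded local optimization of the correlation score over the four
    # transform parameters, on a coarse pixel subgrid for speed; accepted
    # only if it actually improves the full-resolution score
    sub <- function(mm) mm[seq(1, nrow(mm), by = 2), seq(1, ncol(mm), by = 2)]
    score_sub <- function(t) {
      w <- apply_transform(m, t)
      mask <- sub(valid_mask_of(w))
      if (sum(mask) < 16) return(-Inf)
      tryCatch(ncc_values(sub(f), sub(if (inherits(w, "image_plane")) w$pixels else w),
                          mask), error = function(e) -Inf)
    }
    par0 <- c(candidate$theta_rad, log(candidate$scale),
              candidate$tx_px, candidate$ty_px)
    obj <- function(p) -score_sub(similarity_transform(p[1], exp(p[2]), p[3], p[4]))
    opt <- tryCatch(
      stats::optim(par0, obj, method = "Nelder-Mead",
                   control = list(maxit = 120, reltol = 1e-8,
                                  parscale = c(0.01, 0.005, 0.5, 0.5))),
      error = function(e) NULL)
    if (!is.null(opt)) {
      t_ref <- similarity_transform(opt$par[1], exp(opt$par[2]),
                                    opt$par[3], opt$par[4])
      sc_ref <- score_of(t_ref)
      if (sc_ref > sc_cand) { candidate <- t_ref; sc_cand <- sc_ref }
    }
  }

  score_after <- sc_cand
  status <- if (n_inliers >= max(3L, cfg$min_inliers) &&
                is.finite(score_after) && !is.na(score_before) &&
                score_after >= score_before) "OK"
  else if (n_inliers < max(3L, cfg$min_inliers)) "LOW_FEATURES"
  else "DEGRADED"
  registration_result(candidate, n_inliers, score_before, score_after,
                      status, method)
}

# 2x2 mean downsampling (trailing odd row/col dropped)
downsample2 <- function(m) {
  H <- 2L * (nrow(m) %/% 2L); W <- 2L * (ncol(m) %/% 2L)
  m <- m[1:H, 1:W, drop = FALSE]
  0.25 * (m[seq(1, H, 2), seq(1, W, 2)] + m[seq(2, H, 2), seq(1, W, 2)] +
          m[seq(1, H, 2), seq(2, W, 2)] + m[seq(2, H, 2), seq(2, W, 2)])
}

# Lift a transform estimated on a 2^lev-downsampled grid to full resolution.
# Downsampled pixel centers sit at p_full = 2 * p_ds + 0.5 per level.
lift_transform <- function(t, lev) {
  if (lev == 0L) return(t)
  up <- similarity_transform(0, 2, 0.5, 0.5)
  out <- t
  for (i in seq_len(lev))
    out <- compose_transforms(up, compose_transforms(out, invert_transform(up)))
  out
}

# One/two rounds of: project moving keypoints through the candidate, pair
# each with the nearest fixed keypoint within tolerance (greedy one-to-one),
# refit the similarity on the pairs.
refine_with_landmarks <- function(candidate, kp_m, kp_f, tol_px, rounds = 2L) {
  best <- list(transform = NULL, n = 0L)
  t_cur <- candidate
  fixp <- cbind(kp_f$x_px, kp_f$y_px)
  movp <- cbind(kp_m$x_px, kp_m$y_px)
  for (r in seq_len(rounds)) {
    proj <- transform_points(t_cur, movp)
    d <- sqrt(pmax(outer(rowSums(proj^2), rowSums(fixp^2), "+") -
                     2 * proj %*% t(fixp), 0))
    pairs <- list(); used <- rep(FALSE, nrow(fixp))
    for (i in order(apply(d, 1, min))) {
      j <- which.min(ifelse(used, Inf, d[i, ]))
      if (!is.finite(d[i, j]) || d[i, j] > tol_px) next
      used[j] <- TRUE
      pairs[[length(pairs) + 1L]] <- c(movp[i, ], fixp[j, ])
    }
    if (length(pairs) < 2) break
    cs <- as.data.frame(do.call(rbind, pairs))
    names(cs) <- c("x_mov", "y_mov", "x_fix", "y_fix")
    t_new <- tryCatch(fit_similarity(cs), error = function(e) NULL)
    if (is.null(t_new)) break
    t_cur <- t_new
    best <- list(transform = t_cur, n = nrow(cs))
  }
  best
}

registration_result <- function(transform, n_inliers, score_before,
                                score_after, status, method) {
  structure(list(transform = transform, n_inliers = as.integer(n_inliers),
                 score_before = score_before, score_after = score_after,
                 status = status, method = method),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("<registration_result> status %s (%s), %d inliers, NCC %.4f -> %.4f\n",
              x$status, x$method, x$n_inliers,
              if (is.na(x$score_before)) NA else x$score_before,
              if (is.na(x$score_after)) NA else x$score_after))
  print(x$transform)
  invisible(x)
}
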