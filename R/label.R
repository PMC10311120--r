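#' Network architecture configuration
#'
#' A plain 2D U-Net regressor with skip connections and a linear output:
#' `depth` resolution levels (one 3x3 convolution + ReLU each, 2x2 mean
#' pooling), a bottleneck convolution, and a mirrored decoder with
#' nearest-neighbor upsampling and skip concatenation. Depth 3 with a
#' batch size of 8 is the reference configuration for chromatin
#' prediction; inputs must be divisible by `pool^depth` (prediction pads
#' internally).
#'
#' @param depth number of pooling steps (>= 1, default 3).
#' @param base_filters channels at the finest level (doubled per level).
#' @param kernel_size convolution kernel (fixed 3).
#' @param pool pooling factor (fixed 2).
#' @param final_activation output activation; `"linear"` only.
#' @return A list of class `model_config`.
#' @export
model_config <- function(depth = 3L, base_filters = 16L, kernel_size = 3L,
                         pool = 2L, final_activation = "linear") {
  stopifnot(depth >= 1, base_filters >= 1,
            kernel_size == 3L, pool == 2L,
            identical(final_activation, "linear"))
  structure(list(depth = as.integer(depth), base_filters = as.integer(base_filters),
                 kernel_size = 3L, pool = 2L, final_activation = "linear"),
            class = "model_config")
}

#' Training configuration
#'
#' The reference schedule is 150 epochs at batch size 8; tests and the
#' built-in benchmark use a reduced desk-scale preset (64-px patches,
#' around 30 epochs) that trains in minutes on one CPU. The L1 (MAE) loss
#' is the default for this model family; a single seed drives patch
#' sampling, weight initialization and shuffling.
#'
#' @param epochs training epochs (>= 1, reference default 150).
#' @param batch_size patches per gradient step (reference default 8).
#' @param patch_size_px square patch edge; must be divisible by
#'   `pool^depth`.
#' @param patches_per_pair random patches drawn from each image pair.
#' @param learning_rate Adam learning rate.
#' @param loss `"MAE"` or `"MSE"`.
#' @param validation_fraction fraction of pairs held out for validation.
#' @param seed integer seed.
#' @return A list of class `train_config`.
#' @export
train_config <- function(epochs = 150L, batch_size = 8L, patch_size_px = 64L,
                         patches_per_pair = 4L, learning_rate = 1e-3,
                         loss = c("MAE", "MSE"), validation_fraction = 0.1,
                         seed = 1L) {
  loss <- match.arg(loss)
  stopifnot(epochs >= 1, batch_size >= 1, patch_size_px >= 8,
            patches_per_pair >= 1, learning_rate > 0,
            validation_fraction > 0, validation_fraction < 1)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 patch_size_px = as.integer(patch_size_px),
                 patches_per_pair = as.integer(patches_per_pair),
                 learning_rate = learning_rate, loss = loss,
                 validation_fraction = validation_fraction,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Extract aligned training patches from image pairs
#'
#' Samples square patches at identical coordinates in the EM image and the
#' aligned chromatin image of each pair, fully inside the images,
#' deterministically for a given seed. If a patch spans the whole image,
#' exactly one (full-image) patch is taken per pair.
#'
#' @param pairs list of pairs; each element has `$em` and `$chromatin`
#'   (`image_plane`s or plain matrices of identical shape).
#' @param patch_size square patch edge, px.
#' @param patches_per_pair number of patches per pair.
#' @param seed integer seed.
#' @return A list of lists with `em`, `chromatin` (matrices) and `corner`
#'   (0-based (x, y) of the top-left pixel).
#' @export
extract_patches <- function(pairs, patch_size, patches_per_pair, seed = 1L) {
  px_of <- function(x) if (inherits(x, "image_plane")) x$pixels else x
  with_seed(seed, {
    out <- list()
    for (p in pairs) {
      em <- px_of(p$em); ch <- px_of(p$chromatin)
      if (!identical(dim(em), dim(ch)))
        stop("extract_patches: pair images have different shapes")
      H <- nrow(em); W <- ncol(em)
      if (H < patch_size || W < patch_size)
        stop("extract_patches: image (", H, "x", W,
             ") is smaller than the patch size (", patch_size, ")")
      if (H == patch_size && W == patch_size) {
        out[[length(out) + 1L]] <- list(em = em, chromatin = ch, corner = c(0, 0))
        next
      }
      for (k in seq_len(patches_per_pair)) {
        i0 <- sample.int(H - patch_size + 1L, 1L)
        j0 <- sample.int(W - patch_size + 1L, 1L)
        rows <- i0:(i0 + patch_size - 1L); cols <- j0:(j0 + patch_size - 1L)
        out[[length(out) + 1L]] <- list(em = em[rows, cols],
                                        chromatin = ch[rows, cols],
                                        corner = c(j0 - 1L, i0 - 1L))
      }
    }
    out
  })
}

#' Train the chromatin-prediction network
#'
#' Trains the U-Net to regress the aligned fluorescent chromatin image
#' from the (preprocessed) EM image on randomly sampled patches. The
#' preprocessing configuration is embedded in the returned model and
#' re-applied at prediction time, so there is no train/predict skew.
#' Chromatin targets are percentile-normalized with the same percentiles,
#' so predictions are in normalized fluorescence units.
#'
#' @param pairs list of aligned pairs (elements with `$em`, `$chromatin`),
#'   e.g. from [make_training_set()]; at least 2 (one pair is held out for
#'   validation at the default split).
#' @param model_cfg a [model_config()].
#' @param train_cfg a [train_config()].
#' @param preprocess_cfg a [preprocess_config()] applied to every EM image.
#' @param normalize_target percentile-normalize the chromatin targets
#'   (default; disable for targets already on a fixed scale).
#' @param verbose print per-epoch losses?
#' @return A list of class `clem_model` with the trained weights, all
#'   configs, and `loss_history` (data frame: epoch, train_loss, val_loss).
#' @export
train_model <- function(pairs, model_cfg = model_config(),
                        train_cfg = train_config(),
                        preprocess_cfg = preprocess_config(),
                        normalize_target = TRUE, verbose = FALSE) {
  if (length(pairs) < 2L)
    stop("train_model: at least 2 aligned pairs are required ",
         "(one is held out for validation)")
  if (train_cfg$patch_size_px %% model_cfg$pool^model_cfg$depth != 0L)
    stop("train_model: patch_size_px must be divisible by pool^depth = ",
         model_cfg$pool^model_cfg$depth)
  prep <- function(p) list(
    em = preprocess(as_plane(p$em, "EM"), preprocess_cfg)$pixels,
    chromatin = if (normalize_target)
      percentile_normalize(as_plane(p$chromatin, "FLUO"),
                           preprocess_cfg$p_low, preprocess_cfg$p_high)$pixels
    else as_plane(p$chromatin, "FLUO")$pixels)
  pairs_pp <- lapply(pairs, prep)

  seeds <- derive_seeds(train_cfg$seed, 3L)
  n_val <- max(1L, round(train_cfg$validation_fraction * length(pairs_pp)))
  val_idx <- with_seed(seeds[1], sample.int(length(pairs_pp), n_val))
  train_patches <- extract_patches(pairs_pp[-val_idx], train_cfg$patch_size_px,
                                   train_cfg$patches_per_pair, seed = seeds[2])
  val_patches <- extract_patches(pairs_pp[val_idx], train_cfg$patch_size_px,
                                 train_cfg$patches_per_pair, seed = seeds[2] + 1L)
  if (!length(train_patches)) stop("train_model: empty training set")

  ps <- train_cfg$patch_size_px
  as_col <- function(m) matrix(as.numeric(m), ps * ps, 1L)
  Xtr <- lapply(train_patches, function(p) as_col(p$em))
  Ytr <- lapply(train_patches, function(p) as_col(p$chromatin))
  Xva <- lapply(val_patches, function(p) as_col(p$em))
  Yva <- lapply(val_patches, function(p) as_col(p$chromatin))

  cache <- new.env(parent = emptyenv())
  layers <- with_seed(seeds[3], unet_init(model_cfg))
  state <- adam_init(layers)
  t_step <- 0L
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_loss = numeric(0))
  epoch_seeds <- derive_seeds(seeds[3] + 1L, train_cfg$epochs)
  Xva_all <- do.call(rbind, Xva); Yva_all <- do.call(rbind, Yva)
  for (ep in seq_len(train_cfg$epochs)) {
    ord <- with_seed(epoch_seeds[ep], sample.int(length(Xtr)))
    ep_losses <- numeric(0)
    for (b0 in seq(1L, length(ord), by = train_cfg$batch_size)) {
      idx <- ord[b0:min(b0 + train_cfg$batch_size - 1L, length(ord))]
      Xb <- do.call(rbind, Xtr[idx]); Yb <- do.call(rbind, Ytr[idx])
      fw <- unet_fwd(Xb, ps, ps, layers, model_cfg$depth, cache,
                     keep = TRUE, nb = length(idx))
      lg <- loss_and_grad(fw$pred, Yb, train_cfg$loss)
      g <- unet_bwd(lg$grad, fw, ps, ps, layers, model_cfg$depth, cache)
      t_step <- t_step + 1L
      upd <- adam_step(layers, g, state, train_cfg$learning_rate, t_step)
      layers <- upd$layers; state <- upd$state
      ep_losses <- c(ep_losses, lg$loss)
    }
    fw_val <- unet_fwd(Xva_all, ps, ps, layers, model_cfg$depth, cache,
                       nb = length(Xva))
    val_loss <- loss_and_grad(fw_val$pred, Yva_all, train_cfg$loss)$loss
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = mean(ep_losses),
                                   val_loss = val_loss))
    if (verbose)
      message(sprintf("epoch %3d  train %.5f  val %.5f", ep,
                      mean(ep_losses), val_loss))
  }
  structure(list(model_cfg = model_cfg, train_cfg = train_cfg,
                 preprocess_cfg = preprocess_cfg, layers = layers,
                 loss_history = hist, n_pairs = length(pairs)),
            class = "clem_model")
}

accumulate_grads <- function(a, g) {
  for (nm in names(g)) {
    a[[nm]]$dW <- a[[nm]]$dW + g[[nm]]$dW
    a[[nm]]$db <- a[[nm]]$db + g[[nm]]$db
  }
  a
}

as_plane <- function(x, modality) {
  if (inherits(x, "image_plane")) x
  else image_plane(x, pixel_size_nm = 1, modality = modality)
}

#' @export
print.clem_model <- function(x, ...) {
  h <- x$loss_history
  cat(sprintf(paste0("<clem_model> U-Net depth %d, %d base filters; trained %d",
                     " epochs on %d pairs (final train %.5f, val %.5f)\n"),
              x$model_cfg$depth, x$model_cfg$base_filters, nrow(h), x$n_pairs,
              h$train_loss[nrow(h)], h$val_loss[nrow(h)]))
  invisible(x)
}

#' Predict the virtual chromatin image from an EM image
#'
#' Applies the model's embedded preprocessing to the EM image and runs the
#' network, tiling large images with overlapping tiles whose interiors are
#' stitched (overlap margins are discarded), so tiled and single-tile
#' predictions agree away from tile borders. Inference is deterministic.
#'
#' @param model a `clem_model` from [train_model()] (or an oracle stand-in,
#'   see [oracle_model()]).
#' @param em the EM `image_plane`.
#' @param tile_px tile edge (multiple of 8); `NULL` processes the whole
#'   image as one tile.
#' @param overlap_px overlap between neighboring tiles (multiple of 16).
#' @param ... unused.
#' @return An `image_plane` with modality `"PREDICTED"`, same shape and
#'   pixel size as the input.
#' @export
predict_chromatin <- function(model, em, tile_px = NULL, overlap_px = 32L, ...) {
  UseMethod("predict_chromatin")
}

#' @export
predict_chromatin.clem_model <- function(model, em, tile_px = NULL,
                                         overlap_px = 32L, ...) {
  stopifnot(inherits(em, "image_plane"))
  grid <- model$model_cfg$pool^model_cfg_depth(model)
  img <- preprocess(em, model$preprocess_cfg)$pixels
  H <- nrow(img); W <- ncol(img)
  cache <- new.env(parent = emptyenv())
  run <- function(m) {
    fw <- unet_fwd(matrix(as.numeric(m), nrow(m) * ncol(m), 1L),
                   nrow(m), ncol(m), model$layers, model$model_cfg$depth, cache)
    matrix(fw$pred, nrow(m), ncol(m))
  }
  # pad to a multiple of the pooling grid (reflect)
  Hp <- grid * ceiling(H / grid); Wp <- grid * ceiling(W / grid)
  imgp <- reflect_pad_to(img, Hp, Wp)

  if (is.null(tile_px) || (tile_px >= Hp && tile_px >= Wp)) {
    out <- run(imgp)[1:H, 1:W, drop = FALSE]
    return(predicted_plane(out, em))
  }
  tile_px <- as.integer(tile_px)
  if (tile_px %% grid != 0L)
    stop("predict_chromatin: tile_px must be a multiple of ", grid)
  overlap_px <- max(grid * 2L, as.integer(round(overlap_px / (2L * grid)) * 2L * grid))
  stride <- tile_px - overlap_px
  if (stride <= 0L) stop("predict_chromatin: overlap must be smaller than tile")
  margin <- overlap_px %/% 2L
  # receptive-field radius of the net; each tile is run with this much real
  # image context (grid-aligned) so stitched interiors equal the untiled pass
  rf <- 3L * model$model_cfg$pool^model$model_cfg$depth - 2L
  ctx <- grid * as.integer(ceiling(rf / grid))
  out <- matrix(0, Hp, Wp)
  origins <- function(total) {
    o <- seq(0L, max(0L, total - tile_px), by = stride)
    if (o[length(o)] + tile_px < total) o <- c(o, total - tile_px)
    unique(pmin(o, total - tile_px))
  }
  for (oy in origins(Hp)) for (ox in origins(Wp)) {
    y0 <- max(0L, oy - ctx); y1 <- min(Hp, oy + tile_px + ctx)
    x0 <- max(0L, ox - ctx); x1 <- min(Wp, ox + tile_px + ctx)
    tl_full <- run(imgp[(y0 + 1):y1, (x0 + 1):x1, drop = FALSE])
    tl <- tl_full[(oy - y0 + 1):(oy - y0 + tile_px),
                  (ox - x0 + 1):(ox - x0 + tile_px), drop = FALSE]
    ky <- if (oy == 0L) 1L else margin + 1L
    kx <- if (ox == 0L) 1L else margin + 1L
    ey <- if (oy + tile_px >= Hp) tile_px else tile_px - margin
    ex <- if (ox + tile_px >= Wp) tile_px else tile_px - margin
    out[(oy + ky):(oy + ey), (ox + kx):(ox + ex)] <-
      tl[ky:ey, kx:ex, drop = FALSE]
  }
  predicted_plane(out[1:H, 1:W, drop = FALSE], em)
}

model_cfg_depth <- function(model) model$model_cfg$depth

predicted_plane <- function(px, em) {
  image_plane(px, em$pixel_size_nm, modality = "PREDICTED",
              channel_name = "chromatin_predicted")
}

reflect_pad_to <- function(m, Hp, Wp) {
  H <- nrow(m); W <- ncol(m)
  if (Hp > H) {
    extra <- min(Hp - H, H - 1L)
    m <- rbind(m, m[seq(H - 1L, by = -1L, length.out = extra), , drop = FALSE])
    if (nrow(m) < Hp) m <- rbind(m, m[rep(nrow(m), Hp - nrow(m)), , drop = FALSE])
  }
  if (Wp > W) {
    extra <- min(Wp - W, W - 1L)
    m <- cbind(m, m[, seq(W - 1L, by = -1L, length.out = extra), drop = FALSE])
    if (ncol(m) < Wp) m <- cbind(m, m[, rep(ncol(m), Wp - ncol(m)), drop = FALSE])
  }
  m
}

# --- oracle model -----------------------------------------------------------

#' A perfect-predictor stand-in model
#'
#' Wraps a known ground-truth chromatin image and returns it for any EM
#' input of the same shape. Used by the evaluation protocol to separate
#' registration error from prediction error (the registration benchmark
#' with this model measures the registration stage alone).
#'
#' @param chromatin the ground-truth chromatin `image_plane`.
#' @return An object of class `clem_oracle`.
#' @export
oracle_model <- function(chromatin) {
  stopifnot(inherits(chromatin, "image_plane"))
  structure(list(chromatin = chromatin), class = "clem_oracle")
}

#' @export
predict_chromatin.clem_oracle <- function(model, em, tile_px = NULL,
                                          overlap_px = 32L, ...) {
  stopifnot(identical(dim(em$pixels), dim(model$chromatin$pixels)))
  image_plane(model$chromatin$pixels, em$pixel_size_nm,
              modality = "PREDICTED", channel_name = "chromatin_predicted")
}

# --- model persistence ------------------------------------------------------

#' Save / load a trained model
#'
#' The model artifact is a directory with a JSON sidecar (`model.json`:
#' architecture, training and preprocessing configuration, loss history,
#' tensor manifest) and a plain-text weight file (`weights.txt`, one value
#' per line at full double precision).
#'
#' @param model a `clem_model`.
#' @param dir artifact directory (created if needed).
#' @return `save_model` returns `dir` invisibly; `load_model` returns the
#'   `clem_model`.
#' @export
save_model <- function(model, dir) {
  stopifnot(inherits(model, "clem_model"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- lapply(model$layers, function(l)
    list(w_dim = dim(l$W), b_len = length(l$b)))
  meta <- list(model_cfg = unclass(model$model_cfg),
               train_cfg = unclass(model$train_cfg),
               preprocess_cfg = unclass(model$preprocess_cfg),
               loss_history = model$loss_history,
               n_pairs = model$n_pairs,
               manifest = manifest)
  jsonlite::write_json(meta, file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA)
  vals <- unlist(lapply(model$layers, function(l) c(as.numeric(l$W), l$b)))
  writeLines(sprintf("%.17g", vals), file.path(dir, "weights.txt"))
  invisible(dir)
}

#' @rdname save_model
#' @param dir artifact directory.
#' @export
load_model <- function(dir) {
  meta_path <- file.path(dir, "model.json")
  if (!file.exists(meta_path)) stop("load_model: no model.json in ", dir)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  vals <- as.numeric(readLines(file.path(dir, "weights.txt")))
  layers <- list(); off <- 0L
  for (nm in names(meta$manifest)) {
    mm <- meta$manifest[[nm]]
    nw <- prod(mm$w_dim)
    W <- matrix(vals[(off + 1):(off + nw)], mm$w_dim[1], mm$w_dim[2]); off <- off + nw
    b <- vals[(off + 1):(off + mm$b_len)]; off <- off + mm$b_len
    layers[[nm]] <- list(W = W, b = b)
  }
  structure(list(model_cfg = do.call(model_config, as.list(meta$model_cfg)),
                 train_cfg = do.call(train_config, as.list(meta$train_cfg)),
                 preprocess_cfg = do.call(preprocess_config,
                                          as.list(meta$preprocess_cfg)),
                 layers = layers,
                 loss_history = as.data.frame(meta$loss_history),
                 n_pairs = meta$n_pairs),
            class = "clem_model")
}
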