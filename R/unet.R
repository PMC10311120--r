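# Native U-Net internals.
#
# A compact 2D U-Net for image-to-image regression, implemented directly on
# BLAS matrix products: activations are (H*W) x C matrices, 3x3 convolutions
# are im2col gathers followed by one matmul, pooling/upsampling are index
# maps. Sizes here are small (64-px training patches, <= 128 filters), where
# this formulation is fast and has no external dependencies.
#
# Layout per resolution level i (1-based, finest first), depth d:
#   encoder:  conv3x3(base * 2^(i-1)) + ReLU, then 2x2 mean-pool
#   bottleneck: conv3x3(base * 2^d) + ReLU
#   decoder:  nearest 2x upsample, concat skip, conv3x3(base * 2^(i-1)) + ReLU
#   head:     conv1x1 linear -> 1 channel

# ---- index plans (cached per spatial size) ---------------------------------

# Plans carry a batch dimension nb: a batch of nb images is stacked
# image-major into a (nb*H*W) x C activation matrix, and every index map is
# replicated with per-image offsets, so one gather + one matmul process the
# whole batch (padding never leaks between images).

conv_plan <- function(H, W, nb = 1L) {
  Hp <- H + 2L; Wp <- W + 2L
  interior1 <- as.vector(outer(2:(H + 1L), 2:(W + 1L),
                               function(i, j) (j - 1L) * Hp + i))
  boff <- rep((0:(nb - 1L)) * (Hp * Wp), each = H * W)
  interior <- rep(interior1, nb) + boff
  offs <- expand.grid(di = -1:1, dj = -1:1)
  taps <- matrix(0L, length(interior), 9L)
  for (k in seq_len(9L))
    taps[, k] <- as.integer(interior + offs$di[k] + offs$dj[k] * Hp)
  list(H = H, W = W, nb = nb, Hp = Hp, Wp = Wp,
       interior = as.integer(interior), taps = taps)
}

pool_plan <- function(H, W, nb = 1L) {
  stopifnot(H %% 2L == 0L, W %% 2L == 0L)
  h <- H %/% 2L; w <- W %/% 2L
  base1 <- as.vector(outer(seq(1L, H, 2L), seq(1L, W, 2L),
                           function(i, j) (j - 1L) * H + i))
  boff_c <- rep((0:(nb - 1L)) * (H * W), each = h * w)
  base <- rep(base1, nb) + boff_c
  fine_i <- rep(seq_len(H), times = W)
  fine_j <- rep(seq_len(W), each = H)
  up1 <- (((fine_j + 1L) %/% 2L - 1L) * h) + (fine_i + 1L) %/% 2L
  up_idx <- rep(up1, nb) + rep((0:(nb - 1L)) * (h * w), each = H * W)
  list(h = h, w = w, nb = nb,
       i00 = base, i10 = base + 1L, i01 = base + H, i11 = base + H + 1L,
       up_idx = up_idx)
}

get_plan <- function(cache, key, maker) {
  if (is.null(cache[[key]])) cache[[key]] <- maker()
  cache[[key]]
}

# ---- conv layer ------------------------------------------------------------

im2col <- function(X, plan) {
  C <- ncol(X)
  P <- matrix(0, plan$Hp * plan$Wp * plan$nb, C)
  P[plan$interior, ] <- X
  im2col_gather(P, plan$taps)
}

col2im_grad <- function(dcol, plan, C) {
  col2im_scatter(dcol, plan$taps, plan$Hp * plan$Wp * plan$nb, plan$interior)
}

conv_fwd <- function(X, layer, plan, relu = TRUE) {
  col <- im2col(X, plan)
  Y <- col %*% layer$W
  Y <- sweep(Y, 2L, layer$b, "+")
  pre <- NULL
  if (relu) { pre <- Y > 0; Y <- Y * pre }
  list(Y = Y, col = col, pre = pre)
}

conv_bwd <- function(dY, fwd, layer, plan, C_in) {
  if (!is.null(fwd$pre)) dY <- dY * fwd$pre
  dW <- crossprod(fwd$col, dY)
  db <- colSums(dY)
  dcol <- tcrossprod(dY, layer$W)
  dX <- col2im_grad(dcol, plan, C_in)
  list(dX = dX, dW = dW, db = db)
}

# ---- net construction ------------------------------------------------------

he_init <- function(n_in, n_out) {
  matrix(stats::rnorm(n_in * n_out, sd = sqrt(2 / n_in)), n_in, n_out)
}

unet_init <- function(model_cfg) {
  d <- model_cfg$depth; base <- model_cfg$base_filters
  f <- base * 2^(0:(d))            # level channels + bottleneck
  layers <- list()
  c_prev <- 1L
  for (i in seq_len(d)) {
    layers[[paste0("enc", i)]] <- list(W = he_init(9L * c_prev, f[i]),
                                       b = rep(0, f[i]))
    c_prev <- f[i]
  }
  layers$bottleneck <- list(W = he_init(9L * c_prev, f[d + 1]), b = rep(0, f[d + 1]))
  c_up <- f[d + 1]
  for (i in rev(seq_len(d))) {
    c_in <- c_up + f[i]            # upsampled + skip concat
    layers[[paste0("dec", i)]] <- list(W = he_init(9L * c_in, f[i]), b = rep(0, f[i]))
    c_up <- f[i]
  }
  layers$head <- list(W = he_init(f[1], 1L), b = 0)
  layers
}

# Forward pass of a stacked batch (X: (nb*H*W) x 1, image-major), returning
# predictions and, if `keep` is TRUE, all intermediates for backprop.
unet_fwd <- function(X, H, W, layers, depth, cache, keep = FALSE, nb = 1L) {
  plan_c <- function(h, w) get_plan(cache, paste0("c", h, "x", w, "b", nb),
                                    function() conv_plan(h, w, nb))
  plan_p <- function(h, w) get_plan(cache, paste0("p", h, "x", w, "b", nb),
                                    function() pool_plan(h, w, nb))
  sizes <- list(); enc <- list()
  h <- H; w <- W
  cur <- X
  for (i in seq_len(depth)) {
    e <- conv_fwd(cur, layers[[paste0("enc", i)]], plan_c(h, w))
    pp <- plan_p(h, w)
    cur <- 0.25 * (e$Y[pp$i00, , drop = FALSE] + e$Y[pp$i10, , drop = FALSE] +
                   e$Y[pp$i01, , drop = FALSE] + e$Y[pp$i11, , drop = FALSE])
    enc[[i]] <- e
    sizes[[i]] <- c(h, w)
    h <- h %/% 2L; w <- w %/% 2L
  }
  bot <- conv_fwd(cur, layers$bottleneck, plan_c(h, w))
  cur <- bot$Y
  dec <- list()
  for (i in rev(seq_len(depth))) {
    hw <- sizes[[i]]
    pp <- plan_p(hw[1], hw[2])
    up <- cur[pp$up_idx, , drop = FALSE]
    cat_in <- cbind(up, enc[[i]]$Y)
    dd <- conv_fwd(cat_in, layers[[paste0("dec", i)]], plan_c(hw[1], hw[2]))
    dec[[i]] <- list(fwd = dd, n_up = ncol(up))
    cur <- dd$Y
  }
  pred <- sweep(cur %*% layers$head$W, 2L, layers$head$b, "+")
  if (!keep) return(list(pred = pred))
  list(pred = pred, enc = enc, bot = bot, dec = dec, sizes = sizes,
       head_in = cur, X = X, nb = nb)
}

unet_bwd <- function(dpred, fw, H, W, layers, depth, cache) {
  nb <- fw$nb
  plan_c <- function(h, w) get_plan(cache, paste0("c", h, "x", w, "b", nb),
                                    function() conv_plan(h, w, nb))
  plan_p <- function(h, w) get_plan(cache, paste0("p", h, "x", w, "b", nb),
                                    function() pool_plan(h, w, nb))
  grads <- list()
  grads$head <- list(dW = crossprod(fw$head_in, dpred), db = sum(dpred))
  cur <- tcrossprod(dpred, layers$head$W)
  skip_grads <- vector("list", depth)
  for (i in seq_len(depth)) {       # decoder, finest first
    hw <- fw$sizes[[i]]
    c_in <- ncol(fw$dec[[i]]$fwd$col) / 9L
    bb <- conv_bwd(cur, fw$dec[[i]]$fwd, layers[[paste0("dec", i)]],
                   plan_c(hw[1], hw[2]), c_in)
    grads[[paste0("dec", i)]] <- list(dW = bb$dW, db = bb$db)
    n_up <- fw$dec[[i]]$n_up
    d_up <- bb$dX[, seq_len(n_up), drop = FALSE]
    skip_grads[[i]] <- bb$dX[, (n_up + 1L):ncol(bb$dX), drop = FALSE]
    # upsample backward: sum the 2x2 fine block into each coarse pixel
    cur <- rowsum(d_up, plan_p(hw[1], hw[2])$up_idx)
  }
  h <- fw$sizes[[depth]][1] %/% 2L; w <- fw$sizes[[depth]][2] %/% 2L
  c_in_b <- ncol(fw$bot$col) / 9L
  bb <- conv_bwd(cur, fw$bot, layers$bottleneck, plan_c(h, w), c_in_b)
  grads$bottleneck <- list(dW = bb$dW, db = bb$db)
  cur <- bb$dX
  for (i in rev(seq_len(depth))) {  # encoder, coarsest first
    hw <- fw$sizes[[i]]
    pp <- plan_p(hw[1], hw[2])
    dpool <- matrix(0, hw[1] * hw[2] * nb, ncol(cur))
    dpool[pp$i00, ] <- 0.25 * cur; dpool[pp$i10, ] <- 0.25 * cur
    dpool[pp$i01, ] <- 0.25 * cur; dpool[pp$i11, ] <- 0.25 * cur
    dY <- dpool + skip_grads[[i]]
    c_in <- ncol(fw$enc[[i]]$col) / 9L
    bb <- conv_bwd(dY, fw$enc[[i]], layers[[paste0("enc", i)]],
                   plan_c(hw[1], hw[2]), c_in)
    grads[[paste0("enc", i)]] <- list(dW = bb$dW, db = bb$db)
    cur <- bb$dX
  }
  grads
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(layers) {
  lapply(layers, function(l) list(mW = l$W * 0, vW = l$W * 0,
                                  mb = l$b * 0, vb = l$b * 0))
}

adam_step <- function(layers, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^t; bc2 <- 1 - beta2^t
  for (nm in names(layers)) {
    g <- grads[[nm]]; s <- state[[nm]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$dW
    s$vW <- beta2 * s$vW + (1 - beta2) * g$dW^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$db
    s$vb <- beta2 * s$vb + (1 - beta2) * g$db^2
    layers[[nm]]$W <- layers[[nm]]$W - lr * (s$mW / bc1) / (sqrt(s$vW / bc2) + eps)
    layers[[nm]]$b <- layers[[nm]]$b - lr * (s$mb / bc1) / (sqrt(s$vb / bc2) + eps)
    state[[nm]] <- s
  }
  list(layers = layers, state = state)
}

# mean loss and gradient for one batch (lists of (H*W) x 1 targets/preds)
loss_and_grad <- function(pred, target, loss = "MAE") {
  n <- length(pred)
  if (loss == "MAE") {
    list(loss = mean(abs(pred - target)),
         grad = sign(pred - target) / n)
  } else {
    list(loss = mean((pred - target)^2),
         grad = 2 * (pred - target) / n)
  }
}
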