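# Image resampling under a similarity transform.

# Vectorized bilinear sampling of matrix m at 0-based (x, y); out-of-range
# samples return `fill` and are flagged in the "valid" attribute.
bilinear_sample <- function(m, x, y, fill = 0) {
  H <- nrow(m); W <- ncol(m)
  valid <- x >= -1e-9 & y >= -1e-9 & x <= W - 1 + 1e-9 & y <= H - 1 + 1e-9
  # clamp the base cell so points exactly on the far border interpolate
  # from the last cell (fx/fy = 1) instead of reading out of bounds
  x0 <- pmin(pmax(floor(x), 0), W - 2); y0 <- pmin(pmax(floor(y), 0), H - 2)
  fx <- pmin(pmax(x - x0, 0), 1); fy <- pmin(pmax(y - y0, 0), 1)
  i00 <- x0 * H + y0 + 1
  v <- (1 - fx) * (1 - fy) * m[i00] +
       fx * (1 - fy) * m[i00 + H] +
       (1 - fx) * fy * m[i00 + 1] +
       fx * fy * m[i00 + H + 1]
  v[!valid] <- fill
  attr(v, "valid") <- valid
  v
}

nearest_sample <- function(m, x, y, fill = 0) {
  H <- nrow(m); W <- ncol(m)
  xi <- round(x); yi <- round(y)
  valid <- xi >= 0 & yi >= 0 & xi <= W - 1 & yi <= H - 1
  xi <- pmin(pmax(xi, 0), W - 1); yi <- pmin(pmax(yi, 0), H - 1)
  v <- m[xi * H + yi + 1]
  v[!valid] <- fill
  attr(v, "valid") <- valid
  v
}

#' Warp an image with a similarity transform
#'
#' Resamples `img` into the frame the transform maps into: for each output
#' pixel `p`, the value is sampled from the source at `t^-1(p)`
#' (inverse mapping), so `apply_transform(moving, t)` places the moving
#' image in the fixed frame when `t` maps moving to fixed coordinates.
#' Output pixels whose source location falls outside the image are filled
#' with 0 and marked invalid in the attached `valid_mask` attribute (used
#' by the correlation scorer to ignore padding).
#'
#' @param img an `image_plane` (or plain matrix).
#' @param t a `similarity_transform` mapping source to output coordinates.
#' @param out_shape integer (H, W) of the output; default the input shape.
#' @param interp `"BILINEAR"` (default) or `"NEAREST"`.
#' @return An `image_plane` (or matrix) with a `valid_mask` attribute.
#' @export
apply_transform <- function(img, t, out_shape = NULL,
                            interp = c("BILINEAR", "NEAREST")) {
  interp <- match.arg(interp)
  stopifnot(inherits(t, "similarity_transform"))
  is_plane <- inherits(img, "image_plane")
  m <- if (is_plane) img$pixels else img
  if (is.null(out_shape)) out_shape <- dim(m)
  if (length(out_shape) != 2L || any(out_shape < 1))
    stop("apply_transform: invalid out_shape")
  H <- as.integer(out_shape[1]); W <- as.integer(out_shape[2])
  g <- coord_grids(H, W)
  src <- transform_points(invert_transform(t), cbind(as.numeric(g$x), as.numeric(g$y)))
  v <- if (interp == "BILINEAR") bilinear_sample(m, src[, 1], src[, 2])
       else nearest_sample(m, src[, 1], src[, 2])
  out <- matrix(as.numeric(v), H, W)
  mask <- matrix(attr(v, "valid"), H, W)
  if (is_plane) {
    res <- image_plane(out, img$pixel_size_nm, img$modality, img$channel_name)
    attr(res, "valid_mask") <- mask
    res
  } else {
    attr(out, "valid_mask") <- mask
    out
  }
}

# valid mask of a warp result (all TRUE when absent)
valid_mask_of <- function(x) {
  m <- attr(x, "valid_mask")
  if (is.null(m)) {
    d <- if (inherits(x, "image_plane")) dim(x$pixels) else dim(x)
    m <- matrix(TRUE, d[1], d[2])
  }
  m
}
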