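#' Preprocessing configuration
#'
#' EM images from different sessions differ widely in contrast, and the
#' chromatin-prediction network is trained on harmonized inputs, so the
#' same preprocessing must be applied at training and at prediction time
#' (the trained model embeds its config for exactly that reason).
#' Global histogram equalization followed by percentile normalization is
#' the default; equalization alone gave the best contrast harmonization
#' for EM data in our experience, and the trailing normalization fixes the
#' numeric range the network sees.
#'
#' @param mode one of `"NONE"`, `"PERCENTILE_NORMALIZE"`, `"HIST_EQUALIZE"`,
#'   `"EQUALIZE_THEN_NORMALIZE"`.
#' @param p_low,p_high percentiles in `[0, 100]`, `p_low < p_high`.
#' @param n_bins number of histogram bins (>= 2) for equalization.
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(mode = "EQUALIZE_THEN_NORMALIZE",
                              p_low = 1.0, p_high = 99.8, n_bins = 256L) {
  valid <- c("NONE", "PERCENTILE_NORMALIZE", "HIST_EQUALIZE", "EQUALIZE_THEN_NORMALIZE")
  if (!is.character(mode) || length(mode) != 1L || !(mode %in% valid))
    stop("preprocess_config: invalid mode '", paste(mode, collapse = ","),
         "'; must be one of ", paste(valid, collapse = ", "))
  if (!(p_low >= 0 && p_high <= 100 && p_low < p_high))
    stop("preprocess_config: need 0 <= p_low < p_high <= 100")
  if (n_bins < 2L) stop("preprocess_config: n_bins must be >= 2")
  structure(list(mode = mode, p_low = as.numeric(p_low),
                 p_high = as.numeric(p_high), n_bins = as.integer(n_bins)),
            class = "preprocess_config")
}

#' Percentile-based intensity normalization
#'
#' Maps the `p_low` percentile of the input to 0 and the `p_high`
#' percentile to 1 by an affine rescaling
#' `(v - q_low) / (q_high - q_low)`; values outside `[0, 1]` are kept
#' (no clipping), so the transform is strictly affine and invertible.
#' Percentiles use linear interpolation between order statistics
#' (`stats::quantile` type 7).
#'
#' @param img an `image_plane`.
#' @param p_low,p_high percentiles in `[0, 100]`.
#' @return A normalized `image_plane` (same shape and pixel size).
#' @export
percentile_normalize <- function(img, p_low = 1.0, p_high = 99.8) {
  stopifnot(inherits(img, "image_plane"))
  if (!(p_low < p_high)) stop("percentile_normalize: need p_low < p_high")
  q <- stats::quantile(img$pixels, c(p_low, p_high) / 100, names = FALSE, type = 7)
  if (q[2] <= q[1])
    stop("percentile_normalize: image is constant over the requested ",
         "percentile range (q_low == q_high); cannot normalize")
  with_pixels(img, (img$pixels - q[1]) / (q[2] - q[1]))
}

#' Global histogram equalization
#'
#' Flattens the intensity histogram: each output value is the empirical
#' CDF of the pixel's input bin, scaled to `[0, 1]` (a pixel in the top
#' bin maps to exactly 1). Bins are `n_bins` equal-width intervals over
#' the input range, so the result is invariant under affine input
#' rescaling and monotone in the input.
#'
#' @param img an `image_plane`; must not be constant.
#' @param n_bins number of bins (default 256, the usual 8-bit convention).
#' @return An equalized `image_plane` with values in `[0, 1]`.
#' @export
equalize_histogram <- function(img, n_bins = 256L) {
  stopifnot(inherits(img, "image_plane"))
  px <- img$pixels
  r <- range(px)
  if (r[2] <= r[1])
    stop("equalize_histogram: image is constant; equalization is undefined")
  # bin index 1..n_bins by equal-width intervals over [min, max]
  idx <- pmin(floor((px - r[1]) / (r[2] - r[1]) * n_bins) + 1L, n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  cdf <- cumsum(counts) / length(px)
  with_pixels(img, matrix(cdf[idx], nrow(px), ncol(px)))
}

#' Apply a preprocessing configuration to an image
#'
#' Dispatches on `cfg$mode`; `EQUALIZE_THEN_NORMALIZE` equalizes first and
#' then percentile-normalizes the result, `NONE` returns the input
#' unchanged.
#'
#' @param img an `image_plane`.
#' @param cfg a [preprocess_config()].
#' @return The preprocessed `image_plane`.
#' @export
preprocess <- function(img, cfg = preprocess_config()) {
  stopifnot(inherits(img, "image_plane"))
  if (!inherits(cfg, "preprocess_config")) {
    if (is.list(cfg)) cfg <- do.call(preprocess_config, cfg)
    else stop("preprocess: 'cfg' must be a preprocess_config")
  }
  switch(cfg$mode,
    NONE = img,
    PERCENTILE_NORMALIZE = percentile_normalize(img, cfg$p_low, cfg$p_high),
    HIST_EQUALIZE = equalize_histogram(img, cfg$n_bins),
    EQUALIZE_THEN_NORMALIZE =
      percentile_normalize(equalize_histogram(img, cfg$n_bins), cfg$p_low, cfg$p_high))
}
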