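#' A single image plane with physical pixel size
#'
#' The unit of exchange between all pipeline stages: a 2D grid of finite
#' real intensities plus the physical edge length of one pixel in
#' nanometres and a modality tag. Registration errors are reported in nm,
#' so the pixel size is mandatory; there is no default.
#'
#' @param pixels numeric matrix (rows = y, columns = x) of finite values.
#' @param pixel_size_nm physical pixel size, nm per pixel, > 0.
#' @param modality one of `"EM"`, `"FLUO"`, `"PREDICTED"`.
#' @param channel_name free-text channel label.
#' @return An object of class `image_plane`.
#' @examples
#' p <- image_plane(matrix(runif(32 * 32), 32), pixel_size_nm = 25, modality = "EM")
#' dim(p$pixels)
#' @export
image_plane <- function(pixels, pixel_size_nm, modality = c("EM", "FLUO", "PREDICTED"),
                        channel_name = "") {
  modality <- match.arg(modality)
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("image_plane: 'pixels' must be a numeric matrix")
  if (nrow(pixels) < 16L || ncol(pixels) < 16L)
    stop("image_plane: image must be at least 16 x 16 pixels")
  if (!all(is.finite(pixels)))
    stop("image_plane: all intensities must be finite")
  if (!is.numeric(pixel_size_nm) || length(pixel_size_nm) != 1L ||
      !is.finite(pixel_size_nm) || pixel_size_nm <= 0)
    stop("image_plane: 'pixel_size_nm' must be a single positive number")
  structure(
    list(pixels = unname(`storage.mode<-`(pixels, "double")),
         pixel_size_nm = as.numeric(pixel_size_nm),
         modality = modality, channel_name = as.character(channel_name)),
    class = "image_plane")
}

#' @export
print.image_plane <- function(x, ...) {
  cat(sprintf("<image_plane> %d x %d px, %.3g nm/px, %s%s, range [%.4g, %.4g]\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_nm, x$modality,
              if (nzchar(x$channel_name)) paste0(" (", x$channel_name, ")") else "",
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.image_plane <- function(x) dim(x$pixels)

# Replace the pixel grid, keeping metadata.
with_pixels <- function(img, pixels, modality = img$modality) {
  image_plane(pixels, img$pixel_size_nm, modality, img$channel_name)
}

# --- TIFF reading / writing -------------------------------------------------

#' Read a grayscale TIFF as one or more image planes
#'
#' Intensities are loaded exactly as stored (8/16-bit integers keep their
#' integer values; 32-bit float data is kept as is); nothing is rescaled.
#' The pixel size is taken from the TIFF X/Y resolution tags (px per inch
#' or cm) or, if the file carries none, from `pixel_size_nm_override`; a
#' file without either is an error because downstream error reporting is
#' in nanometres.
#'
#' @param path path to a single-plane or multi-plane grayscale TIFF.
#' @param pixel_size_nm_override pixel size in nm to use when the file has
#'   no resolution metadata (also overrides any metadata when given).
#' @param modality,channel_name metadata attached to the returned plane(s).
#' @return An `image_plane`, or a list of them for a multi-plane file.
#' @export
read_image <- function(path, pixel_size_nm_override = NULL,
                       modality = "FLUO", channel_name = "") {
  if (!file.exists(path)) stop("read_image: no such file: ", path)
  planes <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  make_plane <- function(arr) {
    if (length(dim(arr)) == 3L) {
      if (dim(arr)[3] == 1L) {
        a <- attributes(arr); arr <- arr[, , 1L]
        for (nm in setdiff(names(a), c("dim", "dimnames"))) attr(arr, nm) <- a[[nm]]
      } else stop("read_image: '", path, "' is not grayscale (", dim(arr)[3],
                " samples per pixel); convert to single-channel first")
    }
    # readTIFF maps integer samples to [0,1] by v / (2^bits - 1); undo it so
    # stored camera counts come back unrescaled. 32-bit data is float, kept
    # as is unless it carries this package's range annotation (see
    # write_image), in which case the original intensity range is restored.
    bits <- attr(arr, "bits.per.sample")
    if (!is.null(bits) && bits %in% c(8L, 16L)) {
      arr[] <- round(arr * (2^bits - 1))
    } else {
      desc <- attr(arr, "description")
      if (!is.null(desc) && grepl("clemsim_range=", desc)) {
        rng <- as.numeric(strsplit(sub(".*clemsim_range=([^;]*).*", "\\1", desc),
                                   ":")[[1]])
        if (length(rng) == 2L && all(is.finite(rng)))
          arr[] <- arr * (rng[2] - rng[1]) + rng[1]
      }
    }
    ps <- pixel_size_from_tags(arr)
    if (!is.null(pixel_size_nm_override)) ps <- as.numeric(pixel_size_nm_override)
    if (is.null(ps))
      stop("read_image: '", path, "' has no resolution metadata; pass an ",
           "explicit 'pixel_size_nm_override' (nm per pixel)")
    image_plane(matrix(as.numeric(arr), nrow(arr), ncol(arr)), ps,
                modality = modality, channel_name = channel_name)
  }
  out <- lapply(planes, make_plane)
  if (length(out) == 1L) out[[1L]] else out
}

# nm/px from the x.resolution (+ unit) attributes readTIFF(info=TRUE) attaches.
pixel_size_from_tags <- function(arr) {
  xres <- attr(arr, "x.resolution")
  if (is.null(xres) || !is.finite(xres) || xres <= 0) return(NULL)
  unit <- attr(arr, "resolution.unit")
  if (is.null(unit) || is.na(unit)) unit <- "inch"  # TIFF default
  unit_nm <- switch(unit, inch = 2.54e7, cm = 1e7, NULL)
  if (is.null(unit_nm)) return(NULL)                # "none": not a length
  unit_nm / xres
}

#' Write an image plane as a TIFF with pixel-size metadata
#'
#' Integer-valued data in the 16-bit range (camera counts) is stored as
#' 16-bit TIFF and round-trips exactly. Real-valued data is stored as
#' 32-bit float scaled to [0, 1], with the original intensity range
#' recorded in the ImageDescription tag so [read_image()] restores it
#' (to single precision, about 7 significant digits). The pixel size is
#' embedded as TIFF X/Y resolution tags in px/cm.
#'
#' @param img an `image_plane`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  stopifnot(inherits(img, "image_plane"))
  px <- img$pixels
  is_int16 <- all(px == round(px)) && min(px) >= 0 && max(px) <= 65535
  if (is_int16) {
    tiff::writeTIFF(px / 65535, path, bits.per.sample = 16L,
                    compression = "none", reduce = FALSE)
    tiff_set_resolution(path, px_per_cm = 1e7 / img$pixel_size_nm)
  } else {
    rng <- range(px)
    norm <- if (rng[2] > rng[1]) (px - rng[1]) / (rng[2] - rng[1]) else px * 0
    tiff::writeTIFF(norm, path, bits.per.sample = 32L,
                    compression = "none", reduce = FALSE)
    tiff_set_resolution(path, px_per_cm = 1e7 / img$pixel_size_nm,
                        description = sprintf("clemsim_range=%.17g:%.17g",
                                              rng[1], rng[2]))
  }
  invisible(path)
}

# --- RGB overlay ------------------------------------------------------------

#' Write a CLEM overlay image
#'
#' Renders the EM image as a grayscale base and superimposes each
#' fluorescence channel additively in a distinct tint. Every channel
#' (including the EM base) is min-max scaled to [0, 1] before compositing,
#' so the overlay is for visual inspection only.
#'
#' @param em the EM `image_plane` (grayscale base).
#' @param channels list of `image_plane`s to tint and superimpose (may be
#'   empty).
#' @param path output path; `.png` writes PNG, anything else 8-bit RGB TIFF.
#' @param colors character vector of tint colors recycled over channels.
#' @return `path`, invisibly.
#' @export
write_overlay <- function(em, channels = list(), path,
                          colors = c("magenta", "green", "cyan", "yellow")) {
  stopifnot(inherits(em, "image_plane"))
  if (inherits(channels, "image_plane")) channels <- list(channels)
  for (ch in channels) {
    if (!identical(dim(ch$pixels), dim(em$pixels)))
      stop("write_overlay: channel shape ", paste(dim(ch$pixels), collapse = "x"),
           " does not match EM shape ", paste(dim(em$pixels), collapse = "x"))
  }
  rescale01 <- function(m) {
    r <- range(m)
    if (r[2] > r[1]) (m - r[1]) / (r[2] - r[1]) else m * 0
  }
  base <- rescale01(em$pixels)
  rgb_arr <- array(rep(base, 3L), c(dim(base), 3L))
  if (length(channels)) {
    cols <- grDevices::col2rgb(rep_len(colors, length(channels))) / 255
    for (i in seq_along(channels)) {
      ch01 <- rescale01(channels[[i]]$pixels)
      for (k in 1:3) rgb_arr[, , k] <- rgb_arr[, , k] + cols[k, i] * ch01
    }
  }
  rgb_arr <- pmin(pmax(rgb_arr, 0), 1)
  if (grepl("\\.png$", path, ignore.case = TRUE)) png::writePNG(rgb_arr, path)
  else tiff::writeTIFF(rgb_arr, path, bits.per.sample = 8L)
  invisible(path)
}
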