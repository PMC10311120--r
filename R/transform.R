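#' 2D similarity transforms
#'
#' A similarity transform maps a point `p = (x, y)` (pixel units, x = column
#' increasing rightward, y = row increasing downward, 0-based, pixel centers)
#' to `p' = scale * R(theta) %*% p + t`. It has four degrees of freedom:
#' rotation `theta` (radians), isotropic `scale`, and translation
#' `(tx, ty)` in pixels. Reflections are excluded: this is the transform
#' class used to align serial-section fluorescence to EM.
#'
#' Stored transforms map MOVING (measured fluorescence) coordinates into
#' FIXED (EM / predicted chromatin) coordinates; warping a moving image uses
#' the inverse mapping.
#'
#' @param theta_rad rotation angle in radians.
#' @param scale isotropic scale factor, must be > 0.
#' @param tx_px,ty_px translation in pixels.
#' @return An object of class `similarity_transform`.
#' @examples
#' t1 <- similarity_transform(pi / 2, 1, 5, -2)
#' transform_points(t1, cbind(1, 0))   # rotates (1,0) to (0,1), then shifts
#' @export
similarity_transform <- function(theta_rad = 0, scale = 1, tx_px = 0, ty_px = 0) {
  stopifnot(is.numeric(theta_rad), length(theta_rad) == 1L, is.finite(theta_rad))
  stopifnot(is.numeric(scale), length(scale) == 1L, is.finite(scale))
  if (scale <= 0) stop("similarity_transform: 'scale' must be > 0")
  stopifnot(is.finite(tx_px), is.finite(ty_px))
  structure(
    list(theta_rad = as.numeric(theta_rad), scale = as.numeric(scale),
         tx_px = as.numeric(tx_px), ty_px = as.numeric(ty_px)),
    class = "similarity_transform")
}

#' @export
print.similarity_transform <- function(x, ...) {
  cat(sprintf("<similarity_transform> theta = %.6f deg, scale = %.6f, t = (%.4f, %.4f) px\n",
              x$theta_rad * 180 / pi, x$scale, x$tx_px, x$ty_px))
  invisible(x)
}

#' @export
#' @rdname similarity_transform
identity_transform <- function() similarity_transform(0, 1, 0, 0)

#' Rotation matrix of a similarity transform
#' @param t a `similarity_transform`.
#' @return 2x2 rotation matrix (no scale).
#' @keywords internal
rotation_matrix <- function(t) {
  c0 <- cos(t$theta_rad); s0 <- sin(t$theta_rad)
  matrix(c(c0, s0, -s0, c0), 2, 2)
}

#' Apply a similarity transform to points
#'
#' @param t a `similarity_transform`.
#' @param pts n x 2 matrix of (x, y) pixel coordinates.
#' @return n x 2 matrix of mapped coordinates.
#' @export
transform_points <- function(t, pts) {
  stopifnot(inherits(t, "similarity_transform"))
  pts <- matrix(as.numeric(pts), ncol = 2)
  out <- t$scale * (pts %*% t(rotation_matrix(t)))
  out[, 1] <- out[, 1] + t$tx_px
  out[, 2] <- out[, 2] + t$ty_px
  out
}

#' Compose and invert similarity transforms
#'
#' `compose_transforms(t1, t2)` returns the transform mapping
#' `p -> t1(t2(p))`; `invert_transform(t)` returns the transform with
#' `compose_transforms(t, invert_transform(t))` equal to the identity.
#' Similarity transforms are closed under both operations.
#'
#' @param t1,t2,t `similarity_transform` objects.
#' @return A `similarity_transform`.
#' @export
compose_transforms <- function(t1, t2) {
  stopifnot(inherits(t1, "similarity_transform"), inherits(t2, "similarity_transform"))
  R1 <- rotation_matrix(t1)
  t_new <- t1$scale * (R1 %*% c(t2$tx_px, t2$ty_px)) + c(t1$tx_px, t1$ty_px)
  similarity_transform(t1$theta_rad + t2$theta_rad, t1$scale * t2$scale,
                       t_new[1], t_new[2])
}

#' @rdname compose_transforms
#' @export
invert_transform <- function(t) {
  stopifnot(inherits(t, "similarity_transform"))
  Rinv <- matrix(c(cos(-t$theta_rad), sin(-t$theta_rad),
                   -sin(-t$theta_rad), cos(-t$theta_rad)), 2, 2)
  t_new <- -(1 / t$scale) * (Rinv %*% c(t$tx_px, t$ty_px))
  similarity_transform(-t$theta_rad, 1 / t$scale, t_new[1], t_new[2])
}

#' Build a similarity transform that rotates/scales about a given center
#'
#' Rotations in this workflow (known perturbations, exhaustive search) are
#' physically meaningful about the image center; stored transforms are
#' origin-anchored. This converts: `p' = s R (p - c) + c + shift`.
#'
#' @param theta_rad rotation angle (radians).
#' @param scale isotropic scale.
#' @param center length-2 (x, y) center of rotation in pixels.
#' @param shift length-2 extra translation (pixels), applied after.
#' @return A `similarity_transform` (origin-anchored).
#' @export
transform_about_center <- function(theta_rad, scale, center, shift = c(0, 0)) {
  stopifnot(length(center) == 2L, length(shift) == 2L)
  R <- matrix(c(cos(theta_rad), sin(theta_rad), -sin(theta_rad), cos(theta_rad)), 2, 2)
  t_new <- as.numeric(center) + as.numeric(shift) - scale * (R %*% as.numeric(center))
  similarity_transform(theta_rad, scale, t_new[1], t_new[2])
}

#' Geometric center of an image in pixel coordinates
#'
#' With 0-based pixel-center coordinates an H x W image has its center at
#' `((W - 1) / 2, (H - 1) / 2)`.
#' @param img an `image_plane` or a matrix.
#' @return length-2 numeric (x, y).
#' @export
image_center <- function(img) {
  d <- if (inherits(img, "image_plane")) dim(img$pixels) else dim(img)
  c((d[2] - 1) / 2, (d[1] - 1) / 2)
}

# --- transform XML serialization -------------------------------------------

#' Read and write the transform-parameter XML file
#'
#' The recovered registration transform is written to a small XML file so it
#' can be archived next to the correlated images and re-applied later. The
#' schema is a single element:
#' `<similarity_transform theta_deg="..." scale="..." tx_px="..." ty_px="..."
#'   pixel_size_nm="..." moving="..." fixed="..."/>`
#' with numeric attributes at full double precision; a write/read round trip
#' reproduces every value to better than 1e-9 relative.
#'
#' @param record a named list with fields `theta_deg`, `scale`, `tx_px`,
#'   `ty_px`, `pixel_size_nm`, `moving_name`, `fixed_name` (see
#'   [transform_record()]).
#' @param path file path of the XML file.
#' @return `read_transform_xml` returns a transform record (named list);
#'   `write_transform_xml` returns `path`, invisibly.
#' @export
write_transform_xml <- function(record, path) {
  record <- validate_transform_record(record)
  doc <- xml2::xml_new_root("similarity_transform")
  num <- function(v) sprintf("%.17g", v)
  xml2::xml_set_attrs(doc, c(
    theta_deg = num(record$theta_deg),
    scale = num(record$scale),
    tx_px = num(record$tx_px),
    ty_px = num(record$ty_px),
    pixel_size_nm = num(record$pixel_size_nm),
    moving = record$moving_name,
    fixed = record$fixed_name))
  xml2::write_xml(doc, path)
  invisible(path)
}

#' @rdname write_transform_xml
#' @export
read_transform_xml <- function(path) {
  if (!file.exists(path)) stop("read_transform_xml: no such file: ", path)
  doc <- xml2::read_xml(path)
  if (xml2::xml_name(doc) != "similarity_transform")
    stop("read_transform_xml: root element is not <similarity_transform>")
  need_num <- c("theta_deg", "scale", "tx_px", "ty_px", "pixel_size_nm")
  vals <- lapply(need_num, function(a) {
    v <- xml2::xml_attr(doc, a)
    if (is.na(v)) stop("read_transform_xml: missing required attribute '", a, "'")
    as.numeric(v)
  })
  names(vals) <- need_num
  transform_record(theta_deg = vals$theta_deg, scale = vals$scale,
                   tx_px = vals$tx_px, ty_px = vals$ty_px,
                   pixel_size_nm = vals$pixel_size_nm,
                   moving_name = xml2::xml_attr(doc, "moving", default = ""),
                   fixed_name = xml2::xml_attr(doc, "fixed", default = ""))
}

#' Construct a transform record (the XML payload)
#'
#' @param theta_deg rotation in degrees.
#' @param scale isotropic scale.
#' @param tx_px,ty_px translation, pixels.
#' @param pixel_size_nm physical pixel size (nm per pixel) of the fixed frame.
#' @param moving_name,fixed_name free-text labels of the two images.
#' @return A named list of class `transform_record`.
#' @export
transform_record <- function(theta_deg, scale, tx_px, ty_px, pixel_size_nm,
                             moving_name = "moving", fixed_name = "fixed") {
  validate_transform_record(structure(
    list(theta_deg = as.numeric(theta_deg), scale = as.numeric(scale),
         tx_px = as.numeric(tx_px), ty_px = as.numeric(ty_px),
         pixel_size_nm = as.numeric(pixel_size_nm),
         moving_name = as.character(moving_name),
         fixed_name = as.character(fixed_name)),
    class = "transform_record"))
}

validate_transform_record <- function(record) {
  need <- c("theta_deg", "scale", "tx_px", "ty_px", "pixel_size_nm")
  for (f in need) {
    v <- record[[f]]
    if (is.null(v) || !is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("transform_record: field '", f, "' must be a finite number")
  }
  if (record$scale <= 0) stop("transform_record: scale must be > 0")
  if (record$pixel_size_nm <= 0) stop("transform_record: pixel_size_nm must be > 0")
  record
}

#' Convert between a transform and its XML record
#' @param t a `similarity_transform`.
#' @param pixel_size_nm pixel size of the fixed frame, nm.
#' @param moving_name,fixed_name labels stored in the record.
#' @return a `transform_record` / a `similarity_transform`.
#' @export
as_transform_record <- function(t, pixel_size_nm, moving_name = "moving",
                                fixed_name = "fixed") {
  transform_record(theta_deg = t$theta_rad * 180 / pi, scale = t$scale,
                   tx_px = t$tx_px, ty_px = t$ty_px,
                   pixel_size_nm = pixel_size_nm,
                   moving_name = moving_name, fixed_name = fixed_name)
}

#' @rdname as_transform_record
#' @param record a `transform_record`.
#' @export
record_to_transform <- function(record) {
  similarity_transform(record$theta_deg * pi / 180, record$scale,
                       record$tx_px, record$ty_px)
}
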