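#' Known perturbations for the registration benchmark
#'
#' The benchmark perturbs a ground-truth-aligned chromatin image by a known
#' transform and asks the workflow to recover it. The standard set mirrors
#' the evaluation protocol: `ALIGNED` (identity), `SHIFT_X` (a 3125 nm
#' shift along x), and rotations by 90 and 180 degrees about the image
#' center. `CUSTOM` wraps an arbitrary similarity transform.
#'
#' @param label one of `"ALIGNED"`, `"SHIFT_X"`, `"ROT_90"`, `"ROT_180"`,
#'   `"CUSTOM"`.
#' @param image_shape integer (H, W) the perturbation will act on.
#' @param pixel_size_nm pixel size, nm (converts the shift to pixels).
#' @param shift_nm shift used by `SHIFT_X` (default 3125 nm).
#' @param transform a `similarity_transform` for `CUSTOM`.
#' @return A list of class `perturbation` with `label` and `transform`
#'   (origin-anchored, built about the image center).
#' @export
perturbation <- function(label, image_shape, pixel_size_nm,
                         shift_nm = 3125, transform = NULL) {
  label <- match.arg(label, c("ALIGNED", "SHIFT_X", "ROT_90", "ROT_180", "CUSTOM"))
  ctr <- c((image_shape[2] - 1) / 2, (image_shape[1] - 1) / 2)
  tr <- switch(label,
    ALIGNED = identity_transform(),
    SHIFT_X = similarity_transform(0, 1, shift_nm / pixel_size_nm, 0),
    ROT_90 = transform_about_center(pi / 2, 1, ctr),
    ROT_180 = transform_about_center(pi, 1, ctr),
    CUSTOM = {
      if (!inherits(transform, "similarity_transform"))
        stop("perturbation: CUSTOM requires a similarity_transform")
      transform
    })
  structure(list(label = label, transform = tr), class = "perturbation")
}

#' Apply a known perturbation to an aligned chromatin image
#'
#' Warps the image by the perturbation transform. Pure 90/180-degree
#' rotations about the center of a square image and integer translations
#' are applied with nearest-neighbor resampling, which is lossless for
#' these cases (a double 180-degree application reproduces the input
#' exactly); anything else uses bilinear interpolation.
#'
#' @param aligned_chromatin an `image_plane`.
#' @param pert a [perturbation()].
#' @return The perturbed `image_plane`.
#' @export
perturb_pair <- function(aligned_chromatin, pert) {
  stopifnot(inherits(pert, "perturbation"))
  t <- pert$transform
  if (pert$label == "ALIGNED") return(aligned_chromatin)
  is_exact <- abs(t$scale - 1) < 1e-12 &&
    abs((t$theta_rad / (pi / 2)) - round(t$theta_rad / (pi / 2))) < 1e-12 &&
    abs(t$tx_px - round(t$tx_px)) < 1e-12 && abs(t$ty_px - round(t$ty_px)) < 1e-12
  apply_transform(aligned_chromatin, t,
                  interp = if (is_exact) "NEAREST" else "BILINEAR")
}

#' Per-axis registration error in nanometres
#'
#' Evaluates the estimated and the true mapping at a set of landmark
#' points (typically the scene's puncta) and returns the mean absolute
#' displacement per axis, converted to nm. Zero iff the two transforms
#' agree at every evaluation point.
#'
#' @param estimated,truth `similarity_transform`s.
#' @param eval_points n x 2 matrix of (x, y) pixel coordinates, n >= 1.
#' @param pixel_size_nm pixel size, nm.
#' @return Named numeric `c(err_x_nm, err_y_nm)`.
#' @export
residual_error_nm <- function(estimated, truth, eval_points, pixel_size_nm) {
  pts <- matrix(as.numeric(eval_points), ncol = 2)
  if (nrow(pts) < 1) stop("residual_error_nm: at least one evaluation point needed")
  d <- transform_points(estimated, pts) - transform_points(truth, pts)
  c(err_x_nm = mean(abs(d[, 1])) * pixel_size_nm,
    err_y_nm = mean(abs(d[, 2])) * pixel_size_nm)
}

#' Evaluate one perturbed pair through the full workflow
#'
#' Predicts the chromatin image from the EM image, perturbs the aligned
#' chromatin by the known transform, registers the perturbed image to the
#' prediction, and composes the recovered transform with the perturbation:
#' for a perfect registration the composition is the identity. Residual
#' errors are measured at the supplied landmark coordinates and a success
#' flag is set if both per-axis errors stay at or below the threshold and
#' the registration reported `OK`.
#'
#' @param em EM `image_plane`.
#' @param aligned_chromatin measured chromatin, aligned to the EM frame.
#' @param model a `clem_model` or [oracle_model()].
#' @param pert a [perturbation()].
#' @param reg_cfg a [register_config()].
#' @param success_threshold_nm success cut-off on max(err_x, err_y), nm.
#' @param puncta_px n x 2 landmark coordinates (px) for error evaluation.
#' @param image_id identifier copied into the record.
#' @return A one-row data frame (an evaluation record) with columns
#'   `image_id`, `perturbation`, `err_x_nm`, `err_y_nm`, `success`,
#'   `ncc_after`, `status`.
#' @export
evaluate_pair <- function(em, aligned_chromatin, model, pert,
                          reg_cfg = register_config(),
                          success_threshold_nm = 250,
                          puncta_px, image_id = "image") {
  predicted <- predict_chromatin(model, em)
  moving <- perturb_pair(aligned_chromatin, pert)
  # a degenerate (constant) prediction cannot be normalized; hand it to the
  # registration as-is so it reports LOW_FEATURES instead of raising
  norm_or_raw <- function(p) tryCatch(percentile_normalize(p),
                                      error = function(e) p)
  reg <- register_planes(norm_or_raw(moving), norm_or_raw(predicted), reg_cfg)
  est_end_to_end <- compose_transforms(reg$transform, pert$transform)
  errs <- residual_error_nm(est_end_to_end, identity_transform(),
                            puncta_px, em$pixel_size_nm)
  success <- reg$status == "OK" &&
    max(errs) <= success_threshold_nm
  data.frame(image_id = image_id, perturbation = pert$label,
             err_x_nm = unname(errs[1]), err_y_nm = unname(errs[2]),
             success = success,
             ncc_after = if (is.na(reg$score_after)) NA_real_ else reg$score_after,
             status = reg$status, stringsAsFactors = FALSE)
}

#' Run the full registration benchmark
#'
#' Renders `n_scenes` independent synthetic scenes, applies each
#' perturbation to the aligned chromatin image, runs the complete
#' predict-and-register workflow, and collects one record per scene and
#' perturbation, mirroring the known-perturbation evaluation protocol.
#' Fully reproducible from (model, seed, configs).
#'
#' @param model a `clem_model`, or the string `"oracle"` to use the
#'   ground-truth chromatin as a perfect prediction (isolates the
#'   registration stage).
#' @param n_scenes number of held-out scenes.
#' @param params [scene_params()] for the scenes (per-scene seeds are
#'   derived from `seed`).
#' @param perturbations character vector of perturbation labels.
#' @param reg_cfg a [register_config()].
#' @param success_threshold_nm success cut-off, nm.
#' @param seed master seed for the scenes.
#' @return A list of class `benchmark_report`: `records` (tibble),
#'   `success_rate`, and the configuration snapshot.
#' @export
run_benchmark <- function(model, n_scenes = 10L, params = scene_params(),
                          perturbations = c("ALIGNED", "SHIFT_X",
                                            "ROT_90", "ROT_180"),
                          reg_cfg = register_config(),
                          success_threshold_nm = 250, seed = 2024L) {
  seeds <- derive_seeds(seed, n_scenes)
  records <- list()
  for (i in seq_len(n_scenes)) {
    pi_ <- params; pi_$seed <- seeds[i]
    sc <- sample_scene(pi_)
    em <- render_em(sc)
    aligned <- render_fluorescence(sc, apply_misalignment = FALSE)
    mdl <- if (identical(model, "oracle"))
      oracle_model(render_fluorescence(sc, FALSE, noise = FALSE)) else model
    puncta <- as.matrix(sc$puncta[, c("x_px", "y_px")])
    for (lab in perturbations) {
      pert <- perturbation(lab, dim(em$pixels), em$pixel_size_nm)
      records[[length(records) + 1L]] <- evaluate_pair(
        em, aligned, mdl, pert, reg_cfg, success_threshold_nm, puncta,
        image_id = sprintf("scene_%02d", i))
    }
  }
  records <- tibble::as_tibble(do.call(rbind, records))
  structure(list(records = records,
                 success_rate = mean(records$success),
                 success_threshold_nm = success_threshold_nm,
                 n_scenes = n_scenes, perturbations = perturbations,
                 seed = seed, params = params, reg_cfg = reg_cfg),
            class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat(sprintf("<benchmark_report> %d scenes x %d perturbations, success rate %.2f (threshold %g nm)\n",
              x$n_scenes, length(x$perturbations), x$success_rate,
              x$success_threshold_nm))
  agg <- stats::aggregate(cbind(err_x_nm, err_y_nm) ~ perturbation,
                          data = x$records, FUN = stats::median)
  print(agg, row.names = FALSE)
  invisible(x)
}

#' Tidy a benchmark report into one record per row
#' @param x a `benchmark_report`.
#' @param ... unused.
#' @return The records tibble.
#' @export
tidy.benchmark_report <- function(x, ...) x$records

#' One-row summary of a benchmark report
#' @param x a `benchmark_report`.
#' @param ... unused.
#' @return A one-row tibble with success rate and median errors.
#' @export
glance.benchmark_report <- function(x, ...) {
  tibble::tibble(n_records = nrow(x$records),
                 success_rate = x$success_rate,
                 median_err_x_nm = stats::median(x$records$err_x_nm),
                 median_err_y_nm = stats::median(x$records$err_y_nm),
                 threshold_nm = x$success_threshold_nm)
}

#' Plot per-perturbation registration errors
#' @param object a `benchmark_report`.
#' @param ... unused.
#' @return A ggplot object (requires ggplot2).
#' @export
autoplot.benchmark_report <- function(object, ...) {
  rec <- object$records
  long <- rbind(
    data.frame(perturbation = rec$perturbation, axis = "x", err_nm = rec$err_x_nm),
    data.frame(perturbation = rec$perturbation, axis = "y", err_nm = rec$err_y_nm))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$perturbation, y = .data$err_nm,
                                     fill = .data$axis)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::geom_hline(yintercept = object$success_threshold_nm,
                        linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "absolute error [nm]",
                  title = "Registration error by known perturbation") +
    ggplot2::theme_minimal()
}

#' Write a benchmark report as CSV (records) and JSON (summary)
#'
#' The CSV mirrors the benchmark table layout: one row per scene, one
#' column pair (X, Y error in nm) per perturbation.
#'
#' @param report a `benchmark_report`.
#' @param csv_path,json_path output paths (either may be `NULL` to skip).
#' @return Invisibly, the wide data frame written to CSV.
#' @export
write_benchmark <- function(report, csv_path = NULL, json_path = NULL) {
  rec <- report$records
  wide <- stats::reshape(
    as.data.frame(rec[, c("image_id", "perturbation", "err_x_nm", "err_y_nm")]),
    direction = "wide", idvar = "image_id", timevar = "perturbation")
  if (!is.null(csv_path)) utils::write.csv(wide, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(list(success_rate = report$success_rate,
                              success_threshold_nm = report$success_threshold_nm,
                              n_scenes = report$n_scenes,
                              perturbations = report$perturbations),
                         json_path, auto_unbox = TRUE, digits = NA)
  invisible(wide)
}
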