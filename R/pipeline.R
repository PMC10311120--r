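#' Pipeline configuration
#'
#' One configuration object for the whole workflow, loadable from a YAML
#' (or JSON) file with sections `preprocess`, `model`, `train`,
#' `register`, `evaluate`, `io`, and `seed`. Unknown keys are rejected so
#' typos fail loudly; every run logs the fully resolved configuration.
#'
#' @param preprocess a [preprocess_config()] or list of its arguments.
#' @param model a [model_config()] or argument list.
#' @param train a [train_config()] or argument list.
#' @param register a [register_config()] or argument list.
#' @param evaluate list with `threshold_nm` and `perturbations`.
#' @param io list with `out_dir` and `overwrite`.
#' @param seed integer master seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(preprocess = preprocess_config(),
                            model = model_config(),
                            train = train_config(),
                            register = register_config(),
                            evaluate = list(threshold_nm = 250,
                                            perturbations = c("ALIGNED", "SHIFT_X",
                                                              "ROT_90", "ROT_180")),
                            io = list(out_dir = "clemsim_out", overwrite = FALSE),
                            seed = 1L) {
  as_cfg <- function(x, ctor, cls) {
    if (inherits(x, cls)) return(x)
    if (is.list(x)) return(do.call(ctor, x))
    stop("pipeline_config: cannot interpret section as ", cls)
  }
  structure(list(preprocess = as_cfg(preprocess, preprocess_config, "preprocess_config"),
                 model = as_cfg(model, model_config, "model_config"),
                 train = as_cfg(train, train_config, "train_config"),
                 register = as_cfg(register, register_config, "register_config"),
                 evaluate = evaluate, io = io, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration file
#'
#' @param path YAML or JSON file; missing sections fall back to defaults,
#'   unknown sections or keys are an error.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("read_pipeline_config: no such file: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- c("preprocess", "model", "train", "register", "evaluate", "io", "seed")
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("read_pipeline_config: unknown section(s): ", paste(bad, collapse = ", "))
  check_keys <- function(sec, ctor) {
    if (is.null(raw[[sec]])) return(NULL)
    allowed <- names(formals(ctor))
    bad <- setdiff(names(raw[[sec]]), allowed)
    if (length(bad))
      stop("read_pipeline_config: unknown key(s) in '", sec, "': ",
           paste(bad, collapse = ", "))
    raw[[sec]]
  }
  args <- list()
  for (sec in c("preprocess", "model", "train", "register")) {
    ctor <- switch(sec, preprocess = preprocess_config, model = model_config,
                   train = train_config, register = register_config)
    v <- check_keys(sec, ctor)
    if (!is.null(v)) args[[sec]] <- v
  }
  if (!is.null(raw$evaluate)) args$evaluate <- raw$evaluate
  if (!is.null(raw$io)) args$io <- raw$io
  if (!is.null(raw$seed)) args$seed <- raw$seed
  do.call(pipeline_config, args)
}

resolved_config_string <- function(cfg) {
  yaml::as.yaml(rapply(unclass(cfg), function(x) x, how = "replace"))
}

#' Run the full CLEM registration workflow on one image set
#'
#' The end-user entry point: predicts the virtual chromatin image from the
#' EM image, registers the measured chromatin channel to the prediction,
#' applies the recovered transform to every channel of interest, and
#' writes the predicted chromatin, the warped channels, an RGB overlay,
#' the transform XML and a JSON report into `out_dir`.
#'
#' @param em_path path to the EM TIFF.
#' @param chromatin_path path to the measured chromatin TIFF (moving).
#' @param channel_paths character vector of additional channel TIFFs to
#'   warp with the recovered transform (may be empty).
#' @param model_path model artifact directory (see [save_model()]).
#' @param config a `pipeline_config` (or path to one).
#' @param out_dir output directory; refuses to overwrite unless
#'   `config$io$overwrite` is set.
#' @param pixel_size_nm optional override when the TIFFs carry no
#'   resolution metadata.
#' @return Invisibly, a list with the `registration_result`, the output
#'   paths, and the exit status (0 = OK, 2 = registration not OK).
#' @export
run_pipeline <- function(em_path, chromatin_path, channel_paths = character(),
                         model_path, config = pipeline_config(),
                         out_dir = NULL, pixel_size_nm = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  for (p in c(em_path, chromatin_path, channel_paths))
    if (!file.exists(p)) stop("run_pipeline: missing input: ", p)
  if (!dir.exists(model_path)) stop("run_pipeline: missing model: ", model_path)
  if (is.null(out_dir)) out_dir <- config$io$out_dir
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0 &&
      !isTRUE(config$io$overwrite))
    stop("run_pipeline: output directory '", out_dir,
         "' exists and is not empty; set io$overwrite to proceed")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  log_file <- file.path(out_dir, "run.log")
  logf <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S "), sprintf(...))
    message(msg)
    cat(msg, "\n", file = log_file, append = TRUE)
  }
  logf("clemsim %s", as.character(utils::packageVersion("clemsim")))
  cat("resolved config:\n", resolved_config_string(config),
      file = log_file, append = TRUE)

  model <- load_model(model_path)
  em <- read_image(em_path, pixel_size_nm, modality = "EM", channel_name = "em")
  chromatin <- read_image(chromatin_path, pixel_size_nm,
                          modality = "FLUO", channel_name = "chromatin")
  channels <- lapply(channel_paths, read_image,
                     pixel_size_nm_override = pixel_size_nm)

  logf("predicting chromatin from EM (%d x %d px)", nrow(em$pixels), ncol(em$pixels))
  predicted <- predict_chromatin(model, em)
  write_image(predicted, file.path(out_dir, "chromatin_predicted.tif"))

  logf("registering measured chromatin to prediction")
  reg <- register_planes(percentile_normalize(chromatin),
                         percentile_normalize(predicted), config$register)
  logf("registration status %s (%d inliers, NCC %.3f -> %.3f)",
       reg$status, reg$n_inliers, reg$score_before,
       ifelse(is.na(reg$score_after), NaN, reg$score_after))

  warped_chromatin <- apply_transform(chromatin, reg$transform,
                                      out_shape = dim(em$pixels))
  write_image(warped_chromatin, file.path(out_dir, "chromatin_registered.tif"))
  warped_channels <- list()
  for (i in seq_along(channels)) {
    w <- apply_transform(channels[[i]], reg$transform, out_shape = dim(em$pixels))
    out_name <- sprintf("channel_%02d_registered.tif", i)
    write_image(w, file.path(out_dir, out_name))
    warped_channels[[i]] <- w
  }
  write_overlay(em, c(list(warped_chromatin), warped_channels),
                file.path(out_dir, "overlay.png"))
  write_transform_xml(
    as_transform_record(reg$transform, em$pixel_size_nm,
                        moving_name = basename(chromatin_path),
                        fixed_name = basename(em_path)),
    file.path(out_dir, "transform.xml"))
  report <- list(status = reg$status, n_inliers = reg$n_inliers,
                 score_before = reg$score_before, score_after = reg$score_after,
                 degraded = reg$status != "OK",
                 transform = unclass(reg$transform))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  status <- if (reg$status == "OK") 0L else 2L
  logf("done (exit status %d)", status)
  invisible(list(registration = reg, out_dir = out_dir, exit_status = status))
}
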