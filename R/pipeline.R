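#' Pipeline configuration
#'
#' Assembles the fully-resolved configuration of an end-to-end synthetic
#' run: simulate a survey, calibrate every frame against its in-frame
#' chart, superimpose both conditions to the landmark consensus, and
#' compare colour homogeneity. All randomness derives from \code{seed};
#' a run is bit-reproducible from its configuration alone.
#'
#' @param out_dir output directory for the run.
#' @param seed master seed.
#' @param n_images frames per condition (default 15).
#' @param severity illuminant severity in [0, 1] (default 0.5).
#' @param jitter_px geometric perturbation scale (default 0.5).
#' @param height,width scene dimensions (default 256 x 320).
#' @param n_points sampled homogeneity points (default 300).
#' @param window sampling window side (default 8).
#' @param lambda calibration smoothing (default 0, exact interpolation).
#' @param roi homogeneity ROI \code{c(r0, c0, r1, c1)} or NULL for the
#'   central half of the canvas (25 per cent inset per side, clear of the
#'   chart corner).
#' @param lut optional LUT resolution for calibration application.
#' @param scaling include scale in the Procrustes consensus (default TRUE).
#' @return list of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(out_dir, seed = 1, n_images = 15, severity = 0.5,
                            jitter_px = 0.5, height = 256, width = 320,
                            n_points = 300, window = 8, lambda = 0,
                            roi = NULL, lut = NULL, scaling = TRUE) {
  if (is.null(roi))
    roi <- c(round(height * 0.25), round(width * 0.25),
             round(height * 0.75), round(width * 0.75))
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 n_images = n_images, severity = severity,
                 jitter_px = jitter_px, height = height, width = width,
                 n_points = n_points, window = window, lambda = lambda,
                 roi = roi, lut = lut, scaling = scaling),
            class = "pipeline_config")
}

# tiny FNV-style hash of the serialized config, for the run log
config_hash <- function(config) {
  s <- utf8ToInt(jsonlite::toJSON(unclass(config), digits = NA, auto_unbox = TRUE))
  h <- 216613626
  for (b in s) h <- ((h * 16777619) + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run the full synthetic calibration pipeline
#'
#' Executes simulate, calibrate, superimpose and evaluate in sequence,
#' writing every stage's products under \code{config$out_dir}: raw and
#' calibrated frames (8-bit LZW TIFF), superimposed frames, the landmark
#' file and chart annotation, per-point results CSV, a JSON summary, a
#' plain-text report, the resolved configuration and a log. Stage
#' boundaries go through the written 8-bit files, as they would between
#' separate tool invocations.
#'
#' @param config a \code{"pipeline_config"}.
#' @return (invisibly) list with the \code{"homogeneity_comparison"}
#'   result, the consensus, the scene truth and the output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dirs <- file.path(out, c("raw", "calibrated", "superimposed/calibrated",
                           "superimposed/non-calibrated"))
  for (d2 in dirs) dir.create(d2, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character()
  note <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    message("[orthocal] ", line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }
  note("orthocal %s, config hash %s, master seed %d",
       as.character(utils::packageVersion("orthocal")), config_hash(config),
       config$seed)

  ids <- sprintf("frame%02d", seq_len(config$n_images))

  # --- simulate -------------------------------------------------------
  truth <- stage("simulate", {
    base <- make_base_scene(substream_seed(config$seed, "scene"),
                            config$height, config$width)
    truth <- render_survey(base, config$n_images, config$severity,
                           config$jitter_px,
                           master_seed = substream_seed(config$seed, "survey"))
    for (i in seq_along(truth$frames))
      write_rgb_image(truth$frames[[i]], file.path(out, "raw", paste0(ids[i], ".tif")))
    write_landmarks(truth$landmarks, file.path(out, "landmarks.txt"))
    write_annotation_json(truth$chart, file.path(out, "chart_annotation.json"))
    note("simulate: %d frames at severity %g, jitter %g px",
         config$n_images, config$severity, config$jitter_px)
    truth
  })

  # --- calibrate ------------------------------------------------------
  stage("calibrate", {
    annotation <- read_annotation_json(file.path(out, "chart_annotation.json"))
    for (id in ids) {
      img <- read_rgb_image(file.path(out, "raw", paste0(id, ".tif")))
      model <- fit_color_calibration(measure_patches(img, annotation),
                                     lambda = config$lambda)
      cal <- apply_color_calibration(model, img, lut_resolution = config$lut)
      write_rgb_image(cal, file.path(out, "calibrated", paste0(id, ".tif")))
    }
    note("calibrate: fitted and applied 3D TPS per frame (lambda %g)",
         config$lambda)
  })

  # --- superimpose ----------------------------------------------------
  sup <- stage("superimpose", {
    lmk <- read_landmarks(file.path(out, "landmarks.txt"))
    consensus <- procrustes_consensus(lmk[ids], scaling = config$scaling)
    unwarp_dir <- function(indir, outdir) {
      stack <- list()
      for (id in ids) {
        img <- read_rgb_image(file.path(out, indir, paste0(id, ".tif")))
        u <- unwarp_to_consensus(img, lmk[[id]], consensus)
        attr(u, "id") <- id
        write_rgb_image(u, file.path(out, outdir, paste0(id, ".tif")))
        stack[[id]] <- u
      }
      stack
    }
    cal_stack <- unwarp_dir("calibrated", "superimposed/calibrated")
    raw_stack <- unwarp_dir("raw", "superimposed/non-calibrated")
    note("superimpose: consensus over %d landmark sets (%d iterations)",
         length(ids), consensus$iterations)
    list(consensus = consensus, cal = cal_stack, raw = raw_stack)
  })

  # --- evaluate -------------------------------------------------------
  result <- stage("evaluate", {
    res <- compare_conditions(sup$cal, sup$raw, roi = config$roi,
                              n = config$n_points,
                              seed = substream_seed(config$seed, "sampling"),
                              window = config$window)
    write_homogeneity_results(res, file.path(out, "rms_sd.csv"),
                              file.path(out, "summary.json"))
    note("evaluate: %d points, p = %.4g", config$n_points,
         res$test$p_two_sided)
    res
  })

  jsonlite::write_json(unclass(config), file.path(out, "config.json"),
                       digits = NA, auto_unbox = TRUE)
  report <- c(utils::capture.output(print(result)),
              "",
              sprintf("Run directory: %s", out))
  writeLines(report, file.path(out, "report.txt"))
  writeLines(log_lines, file.path(out, "log.txt"))
  invisible(list(result = result, consensus = sup$consensus, truth = truth,
                 out_dir = out))
}
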