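#' @include AllClasses.R AllGenerics.R synthetic-gel.R gel-io.R profile-detection.R band-quantification.R detection-eval.R agreement-stats.R
NULL

#' Read a pipeline configuration from YAML
#'
#' Recognised fields: \code{simulator} (GelSimConfig fields or a path to a
#' simulator YAML), \code{n_images}, \code{images}, \code{annotations},
#' \code{detections}, \code{out} (paths), \code{profile} (profileParams
#' fields), \code{iou_threshold}, \code{conf_threshold}, \code{pairs}
#' (CSV path for agreement), \code{seed}.
#'
#' @param path YAML file.
#' @return Named list.
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}

.logLines <- function(out_dir, lines) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cat(lines, file = file.path(out_dir, "pipeline.log"), sep = "\n", append = TRUE)
}

.stem <- function(p) tools::file_path_sans_ext(basename(p))

.readBoxesFor <- function(det_path, width, height) {
  if (grepl("\\.json$", det_path, ignore.case = TRUE)) {
    readDetectionsJSON(det_path)
  } else {
    readYoloAnnotations(det_path, width, height)
  }
}

#' Run one pipeline stage
#'
#' Composes the toolkit stages behind a single entry point with a config
#' list and deterministic seeding. Every stage writes its artifacts under
#' \code{config$out} (or the stage's natural directory) and appends the
#' parameters and output file hashes to \code{pipeline.log}.
#'
#' Stages: \code{simulate} renders an annotated synthetic batch;
#' \code{detect} runs the profile-analysis baseline over the images (an
#' external detector's output can instead be dropped into
#' \code{config$detections}); \code{quantify} turns images + detections into
#' per-image content results; \code{evaluate} scores detections against
#' annotations (mAP50, confusion matrix); \code{agree} compares paired
#' method/reference values.
#'
#' @param config list as from [readPipelineConfig()].
#' @param command one of "simulate", "detect", "quantify", "evaluate",
#'   "agree".
#' @return Invisibly, a list of produced artifact paths and result objects.
#' @export
runPipeline <- function(config,
                        command = c("simulate", "detect", "quantify",
                                    "evaluate", "agree")) {
  command <- match.arg(command)
  out_dir <- config$out %||% "."
  artifacts <- character(0)
  results <- list()

  if (command == "simulate") {
    sim_cfg <- config$simulator
    cfg <- if (is.character(sim_cfg)) {
      readGelSimConfig(sim_cfg)
    } else {
      bands <- if (!is.null(sim_cfg$bands)) {
        lapply(sim_cfg$bands, function(b) {
          bandSpec(b$class_label, b$pI, b$amplitude %||% 120, b$sigma_y %||% 5,
                   b$fraction %||% NA_real_)
        })
      } else defaultHbBands()
      sim_cfg$bands <- NULL
      do.call(gelSimConfig, c(sim_cfg %||% list(), list(bands = bands)))
    }
    if (!is.null(config$seed)) cfg@seed <- as.numeric(config$seed)
    n <- config$n_images %||% 1
    img_dir <- config$images %||% file.path(out_dir, "images")
    manifest <- generateDataset(cfg, n, img_dir)
    artifacts <- list.files(img_dir, full.names = TRUE)
    results$manifest <- manifest
  } else if (command == "detect") {
    img_dir <- config$images
    det_dir <- config$detections %||% file.path(out_dir, "detections")
    dir.create(det_dir, recursive = TRUE, showWarnings = FALSE)
    imgs <- list.files(img_dir, pattern = "\\.(png|tif|tiff)$", full.names = TRUE)
    if (!length(imgs)) stop("no images found in: ", img_dir)
    params <- do.call(profileParams, config$profile %||% list())
    for (p in imgs) {
      img <- readGelImage(p)
      det <- profileDetect(img, params)
      dst <- file.path(det_dir, paste0(.stem(p), ".txt"))
      writeYoloAnnotations(det, imageWidth(img), imageHeight(img), dst)
      artifacts <- c(artifacts, dst)
    }
  } else if (command == "quantify") {
    img_dir <- config$images
    det_dir <- config$detections
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    imgs <- list.files(img_dir, pattern = "\\.(png|tif|tiff)$", full.names = TRUE)
    if (!length(imgs)) stop("no images found in: ", img_dir)
    for (p in imgs) {
      img <- readGelImage(p)
      cand <- file.path(det_dir, paste0(.stem(p), c(".json", ".txt")))
      det_path <- cand[file.exists(cand)][1]
      if (is.na(det_path)) stop("no detections for image: ", basename(p))
      det <- .readBoxesFor(det_path, imageWidth(img), imageHeight(img))
      q <- quantifyBands(img, det)
      dst <- file.path(out_dir, paste0(.stem(p), "_quant.json"))
      writeQuantJSON(q, dst)
      artifacts <- c(artifacts, dst)
      results[[.stem(p)]] <- q
    }
  } else if (command == "evaluate") {
    gt_dir <- config$annotations
    det_dir <- config$detections
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    gt_files <- list.files(gt_dir, pattern = "\\.txt$", full.names = TRUE)
    if (!length(gt_files)) stop("no annotation files in: ", gt_dir)
    wh <- config$image_size %||% c(640, 640)
    gt_all <- list(); pred_all <- list()
    for (i in seq_along(gt_files)) {
      stem <- .stem(gt_files[[i]])
      pred_path <- file.path(det_dir, paste0(stem, ".txt"))
      if (!file.exists(pred_path)) stop("no detections for: ", stem)
      off <- (i - 1) * 1e5  # images are disjoint: offset so cross-image IoU = 0
      shift <- function(bs) {
        b <- boxFrame(bs)
        b$x_min <- b$x_min + off; b$x_max <- b$x_max + off
        new("BandBoxSet", boxes = b)
      }
      gt_all[[i]] <- shift(readYoloAnnotations(gt_files[[i]], wh[[1]], wh[[2]]))
      pred_all[[i]] <- shift(readYoloAnnotations(pred_path, wh[[1]], wh[[2]]))
    }
    gt <- do.call(concatBoxes, gt_all)
    pred <- do.call(concatBoxes, pred_all)
    ev <- evaluateDetections(gt, pred, config$iou_threshold %||% 0.5,
                             config$conf_threshold %||% 0.25)
    dst <- file.path(out_dir, "eval.json")
    jsonlite::write_json(list(map50 = ev@map50,
                              per_class_ap = as.list(ev@per_class_ap),
                              confusion = ev@confusion),
                         dst, auto_unbox = TRUE, digits = NA)
    artifacts <- dst
    results$eval <- ev
  } else if (command == "agree") {
    pairs <- utils::read.csv(config$pairs)
    need <- c("method_value", "reference_value")
    if (!all(need %in% names(pairs))) {
      stop("pairs CSV must have columns: id, method_value, reference_value")
    }
    st <- agreementStats(pairs$method_value, pairs$reference_value)
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    dst <- file.path(out_dir, "agree.json")
    jsonlite::write_json(as.list(as.data.frame(st)), dst, auto_unbox = TRUE,
                         digits = NA)
    artifacts <- dst
    results$agree <- st
  }

  hashes <- tools::md5sum(artifacts[file.exists(artifacts)])
  .logLines(out_dir, c(
    sprintf("stage=%s seed=%s", command, format(config$seed %||% NA)),
    sprintf("param %s=%s", names(unlist(config)), unlist(config)),
    sprintf("artifact %s md5=%s", names(hashes), hashes)))
  invisible(list(artifacts = artifacts, results = results))
}

#' Human-readable summary report
#'
#' Formats quantification (contents as percentages to one decimal),
#' evaluation and agreement results as a deterministic text block.
#'
#' @param quant a \linkS4class{QuantResult}, or NULL.
#' @param eval an \linkS4class{EvalResult}, or NULL.
#' @param agree an \linkS4class{AgreementStats}, or NULL.
#' @return Character vector of report lines (invisibly printable with
#'   \code{cat(..., sep = "\n")}).
#' @export
reportResults <- function(quant = NULL, eval = NULL, agree = NULL) {
  if (is.null(quant) && is.null(eval) && is.null(agree)) {
    stop("nothing to report")
  }
  lines <- character(0)
  if (!is.null(quant)) {
    lines <- c(lines, "== Band quantification ==",
               sprintf("background threshold: %.3f (%s)",
                       quant@background_threshold, quant@background_mode))
    if (quant@determined) {
      for (cl in names(quant@fractions)) {
        lines <- c(lines, sprintf("%-9s intensity %14.1f  content %5.1f%%", cl,
                                  quant@band_intensities[[cl]],
                                  100 * quant@fractions[[cl]]))
      }
      lines <- c(lines, sprintf("Hb A2 status: %s", quant@hba2_status))
    } else {
      lines <- c(lines, "undetermined: no Hb band signal")
    }
  }
  if (!is.null(eval)) {
    lines <- c(lines, "== Detection evaluation ==",
               sprintf("mAP50: %.4f", eval@map50),
               vapply(names(eval@per_class_ap), function(cl) {
                 sprintf("AP50 %-9s %.4f", cl, eval@per_class_ap[[cl]])
               }, character(1)))
  }
  if (!is.null(agree)) {
    lines <- c(lines, "== Method agreement ==",
               sprintf("slope %.4f intercept %.4f r %.4f r^2 %.4f",
                       agree@slope, agree@intercept, agree@r, agree@r_squared),
               sprintf("Bland-Altman mean %.4f SD %.4f LoA [%.4f, %.4f]",
                       agree@mean_diff, agree@sd_diff, agree@loa_low,
                       agree@loa_high))
  }
  lines
}
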