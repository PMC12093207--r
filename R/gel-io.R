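#' @include AllClasses.R
NULL

#' Default annotation class map
#'
#' Fixed class-id order used in YOLO-txt files: gel=0, bubble=1, HbA1c_A0=2,
#' MetHb=3, HbF=4, HbA2=5, pI_marker=6 (the marker id is used only by the
#' profile-analysis baseline).
#'
#' @return Named integer vector, label -> id.
#' @export
yoloClassMap <- function() {
  setNames(0:6, c("gel", "bubble", "HbA1c_A0", "MetHb", "HbF", "HbA2", "pI_marker"))
}

#' @param path YAML file with a \code{classes: {label: id}} mapping.
#' @rdname yoloClassMap
#' @export
readClassMap <- function(path) {
  y <- yaml::read_yaml(path)
  m <- unlist(y$classes %||% y)
  setNames(as.integer(m), names(m))
}

#' @param class_map named integer vector, label -> id.
#' @rdname yoloClassMap
#' @export
writeClassMap <- function(class_map, path) {
  yaml::write_yaml(list(classes = as.list(class_map)), path)
  invisible(path)
}

#' Read an 8-bit grayscale gel image
#'
#' Reads PNG or TIFF. Multi-channel inputs are converted to luminance
#' (0.299 R + 0.587 G + 0.114 B) with a warning; an alpha channel is dropped.
#'
#' @param path image file (.png, .tif or .tiff).
#' @return A \linkS4class{GelImage}.
#' @export
readGelImage <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format '", ext, "' for: ", path))
  if (length(dim(arr)) == 3L) {
    nc <- dim(arr)[3]
    if (nc >= 3L) {
      warning("multi-channel image converted to luminance: ", path)
      arr <- 0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
    } else {
      arr <- arr[, , 1]
    }
  }
  GelImage(round(arr * 255))
}

#' Write an 8-bit grayscale gel image
#'
#' Lossless single-channel output; the format follows the file extension
#' (PNG or TIFF).
#'
#' @param image a \linkS4class{GelImage}.
#' @param path destination path (.png, .tif or .tiff).
#' @return Invisibly, \code{path}.
#' @export
writeGelImage <- function(image, path) {
  stopifnot(is(image, "GelImage"))
  v <- gelPixels(image) / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(v, path),
    tif = ,
    tiff = tiff::writeTIFF(v, path, bits.per.sample = 8L, compression = "none"),
    stop("unsupported image format '", ext, "' for: ", path))
  invisible(path)
}

# round half away from zero: the convention common YOLO tooling uses when
# mapping normalized coordinates back to pixels
.roundHalfAway <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Read YOLO-txt band annotations
#'
#' Parses the LabelImg/YOLO dialect: one box per line,
#' \code{"class x_center y_center width height [confidence]"}, all
#' coordinates normalized to the image size. Pixel boxes are recovered as
#' \code{x_min = round((xc - w/2) * width)} etc. (round half away from zero),
#' in 0-based half-open coordinates.
#'
#' @param path annotation file.
#' @param width,height image size in pixels.
#' @param class_map named integer vector label -> id (default [yoloClassMap()]).
#' @return A \linkS4class{BandBoxSet}.
#' @export
readYoloAnnotations <- function(path, width, height, class_map = yoloClassMap()) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(bandBoxSet())
  rows <- vector("list", length(lines))
  id2label <- setNames(names(class_map), as.character(class_map))
  for (i in seq_along(lines)) {
    f <- strsplit(trimws(lines[[i]]), "\\s+")[[1]]
    if (!length(f) %in% c(5L, 6L)) {
      stop(sprintf("%s line %d: expected 5 or 6 fields, got %d", path, i, length(f)))
    }
    num <- suppressWarnings(as.numeric(f))
    if (anyNA(num)) stop(sprintf("%s line %d: non-numeric field", path, i))
    lab <- unname(id2label[as.character(as.integer(num[[1]]))])
    if (is.na(lab)) {
      stop(sprintf("%s line %d: class id %d not in class map", path, i, as.integer(num[[1]])))
    }
    if (any(num[2:5] < 0 | num[2:5] > 1)) {
      stop(sprintf("%s line %d: normalized coordinates outside [0, 1]", path, i))
    }
    xc <- num[[2]]; yc <- num[[3]]; w <- num[[4]]; h <- num[[5]]
    rows[[i]] <- data.frame(
      class_label = lab,
      x_min = .roundHalfAway((xc - w / 2) * width),
      y_min = .roundHalfAway((yc - h / 2) * height),
      x_max = .roundHalfAway((xc + w / 2) * width),
      y_max = .roundHalfAway((yc + h / 2) * height),
      confidence = if (length(f) == 6L) num[[6]] else NA_real_,
      stringsAsFactors = FALSE)
  }
  new("BandBoxSet", boxes = do.call(rbind, rows))
}

#' Write YOLO-txt band annotations
#'
#' Inverse of [readYoloAnnotations()]: boxes are normalized to the image
#' size; a confidence column is appended when present. Round-trips recover
#' pixel boxes within one pixel.
#'
#' @param boxes a \linkS4class{BandBoxSet}.
#' @param width,height image size in pixels.
#' @param path destination file.
#' @param class_map named integer vector label -> id.
#' @return Invisibly, \code{path}.
#' @export
writeYoloAnnotations <- function(boxes, width, height, path,
                                 class_map = yoloClassMap()) {
  b <- boxFrame(boxes)
  if (nrow(b) && (min(b$x_min) < 0 || min(b$y_min) < 0 ||
                  max(b$x_max) > width || max(b$y_max) > height)) {
    stop("box outside image bounds")
  }
  lines <- character(nrow(b))
  for (i in seq_len(nrow(b))) {
    id <- unname(class_map[b$class_label[[i]]])
    if (is.na(id)) stop("class not in class map: ", b$class_label[[i]])
    xc <- (b$x_min[[i]] + b$x_max[[i]]) / 2 / width
    yc <- (b$y_min[[i]] + b$y_max[[i]]) / 2 / height
    w <- (b$x_max[[i]] - b$x_min[[i]]) / width
    h <- (b$y_max[[i]] - b$y_min[[i]]) / height
    lines[[i]] <- if (is.na(b$confidence[[i]])) {
      sprintf("%d %.6f %.6f %.6f %.6f", id, xc, yc, w, h)
    } else {
      sprintf("%d %.6f %.6f %.6f %.6f %.6f", id, xc, yc, w, h, b$confidence[[i]])
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read detector output from JSON
#'
#' Adapter for external object-detector results: a JSON array of objects
#' with fields \code{class}, \code{x_min}, \code{y_min}, \code{x_max},
#' \code{y_max} and \code{confidence}.
#'
#' @param path JSON file.
#' @return A \linkS4class{BandBoxSet}.
#' @export
readDetectionsJSON <- function(path) {
  if (!file.exists(path)) stop("detections file not found: ", path)
  recs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!length(recs)) return(bandBoxSet())
  need <- c("class", "x_min", "y_min", "x_max", "y_max", "confidence")
  rows <- lapply(seq_along(recs), function(i) {
    r <- recs[[i]]
    missing <- setdiff(need, names(r))
    if (length(missing)) {
      stop(sprintf("%s record %d: missing field(s) %s", path, i,
                   paste(missing, collapse = ", ")))
    }
    if (r$confidence < 0 || r$confidence > 1) {
      stop(sprintf("%s record %d: confidence %.3f outside [0, 1]", path, i,
                   r$confidence))
    }
    data.frame(class_label = r$class, x_min = r$x_min, y_min = r$y_min,
               x_max = r$x_max, y_max = r$y_max, confidence = r$confidence,
               stringsAsFactors = FALSE)
  })
  new("BandBoxSet", boxes = do.call(rbind, rows))
}

#' @param boxes a \linkS4class{BandBoxSet} with confidences.
#' @rdname readDetectionsJSON
#' @export
writeDetectionsJSON <- function(boxes, path) {
  b <- boxFrame(boxes)
  recs <- lapply(seq_len(nrow(b)), function(i) {
    list(class = b$class_label[[i]], x_min = b$x_min[[i]], y_min = b$y_min[[i]],
         x_max = b$x_max[[i]], y_max = b$y_max[[i]],
         confidence = if (is.na(b$confidence[[i]])) 1.0 else b$confidence[[i]])
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
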