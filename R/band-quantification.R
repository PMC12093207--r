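#' @include AllClasses.R AllGenerics.R profile-detection.R
NULL

#' Invert an 8-bit gel image
#'
#' Bands are imaged as dark stripes on a light background (absorbance at
#' 405 nm); quantification works on the inverted image where band signal is
#' positive: v -> 255 - v.
#'
#' @param image a \linkS4class{GelImage}.
#' @return The inverted \linkS4class{GelImage}.
#' @export
invertGray <- function(image) GelImage(255 - gelPixels(image))

# logical mask (TRUE inside) for a set of boxes, 0-based half-open coords
.boxMask <- function(boxes_df, height, width) {
  mask <- matrix(FALSE, height, width)
  for (i in seq_len(nrow(boxes_df))) {
    b <- boxes_df[i, ]
    if (b$x_min < 0 || b$y_min < 0 || b$x_max > width || b$y_max > height) {
      stop("box outside image bounds")
    }
    mask[(b$y_min + 1):b$y_max, (b$x_min + 1):b$x_max] <- TRUE
  }
  mask
}

.splitBoxes <- function(detections) {
  b <- if (is(detections, "BandBoxSet")) boxFrame(detections) else detections
  list(gel = b[b$class_label == "gel", , drop = FALSE],
       bubble = b[b$class_label == "bubble", , drop = FALSE],
       band = b[b$class_label %in% hbClasses(), , drop = FALSE],
       marker = b[b$class_label == "pI_marker", , drop = FALSE])
}

#' Estimate the background threshold
#'
#' The threshold is the mean inverted intensity of the gel background: the
#' gel-box region (the whole image when no gel box was detected, flagged as
#' whole-image mode) minus all band, marker and bubble boxes.
#'
#' @param image an inverted \linkS4class{GelImage}, or an already-inverted
#'   numeric matrix (pre-quantization pipelines).
#' @param detections a \linkS4class{BandBoxSet} holding the gel box (if
#'   any), band boxes and bubble boxes.
#' @return Numeric threshold with attribute \code{background_mode}
#'   ("gel-box" or "whole-image").
#' @export
estimateBackgroundThreshold <- function(image, detections) {
  m <- .pixelMatrix(image)
  H <- nrow(m); W <- ncol(m)
  sp <- .splitBoxes(detections)
  region <- if (nrow(sp$gel)) .boxMask(sp$gel, H, W) else matrix(TRUE, H, W)
  mode <- if (nrow(sp$gel)) "gel-box" else "whole-image"
  excl <- rbind(sp$band, sp$marker, sp$bubble)
  if (nrow(excl)) region <- region & !.boxMask(excl, H, W)
  if (!any(region)) {
    stop("background region is empty; drop the gel box to fall back to the ",
         "whole-image background")
  }
  structure(mean(m[region]), background_mode = mode)
}

#' Subtract the background threshold
#'
#' v -> max(v - threshold, 0) per pixel, so uniform-background pixels map to
#' (approximately) zero and band baselines are unified. Returns a plain
#' non-negative real matrix: quantification continues on unquantized signal.
#'
#' @param image an inverted \linkS4class{GelImage} or numeric matrix.
#' @param threshold non-negative background level (inverted scale).
#' @return Numeric matrix of background-subtracted signal.
#' @export
subtractBackground <- function(image, threshold) {
  if (threshold < 0) stop("threshold must be non-negative")
  pmax(.pixelMatrix(image) - as.numeric(threshold), 0)
}

#' Integrate band intensities inside detection boxes
#'
#' Sums background-subtracted signal per band box and aggregates by class.
#' Pixels inside a bubble box are excluded. A pixel covered by two or more
#' band boxes is counted once, for the box whose vertical centre is nearest
#' (ties go to the upper box) — the rule that generalises merging Hb A1c
#' with Hb A0 to avoid double-counting overlapping boxes.
#'
#' @param signal numeric matrix of background-subtracted signal.
#' @param band_boxes \linkS4class{BandBoxSet} (or data.frame) of Hb-class
#'   boxes.
#' @param bubble_boxes optional boxes whose pixels are excluded.
#' @return Named numeric: summed intensity per class.
#' @export
integrateBands <- function(signal, band_boxes, bubble_boxes = NULL) {
  b <- if (is(band_boxes, "BandBoxSet")) boxFrame(band_boxes) else band_boxes
  H <- nrow(signal); W <- ncol(signal)
  if (!nrow(b)) return(setNames(numeric(0), character(0)))
  owner <- matrix(0L, H, W)
  owner_dist <- matrix(Inf, H, W)
  owner_yc <- matrix(Inf, H, W)
  for (i in seq_len(nrow(b))) {
    if (b$x_min[[i]] < 0 || b$y_min[[i]] < 0 || b$x_max[[i]] > W || b$y_max[[i]] > H) {
      stop("band box outside image bounds")
    }
    rows <- (b$y_min[[i]] + 1):b$y_max[[i]]
    cols <- (b$x_min[[i]] + 1):b$x_max[[i]]
    yc <- (b$y_min[[i]] + b$y_max[[i]]) / 2
    d <- abs((rows - 0.5) - yc)
    for (ri in seq_along(rows)) {
      r <- rows[[ri]]
      take <- d[[ri]] < owner_dist[r, cols] |
        (d[[ri]] == owner_dist[r, cols] & yc < owner_yc[r, cols])
      if (any(take)) {
        cc <- cols[take]
        owner[r, cc] <- i
        owner_dist[r, cc] <- d[[ri]]
        owner_yc[r, cc] <- yc
      }
    }
  }
  if (!is.null(bubble_boxes)) {
    bb <- if (is(bubble_boxes, "BandBoxSet")) boxFrame(bubble_boxes) else bubble_boxes
    if (nrow(bb)) owner[.boxMask(bb, H, W)] <- 0L
  }
  per_box <- vapply(seq_len(nrow(b)), function(i) sum(signal[owner == i]), numeric(1))
  out <- tapply(per_box, b$class_label, sum)
  setNames(as.numeric(out), names(out))
}

#' Relative band contents
#'
#' The content of a band is its integrated intensity divided by the summed
#' intensity of all detected bands.
#'
#' @param intensities named non-negative numeric, per-class intensities.
#' @return Named fractions summing to 1, with attribute
#'   \code{determined = TRUE}; when all intensities are zero, NA fractions
#'   with \code{determined = FALSE} (no division is attempted).
#' @export
computeFractions <- function(intensities) {
  if (any(intensities < 0)) stop("intensities must be non-negative")
  tot <- sum(intensities)
  if (!length(intensities) || tot == 0) {
    return(structure(setNames(rep(NA_real_, length(intensities)),
                              names(intensities)), determined = FALSE))
  }
  structure(intensities / tot, determined = TRUE)
}

#' Hb A2 abnormality call
#'
#' A sample is called abnormal when the Hb A2 share of all detected Hb is at
#' least 3.5% (boundary inclusive), normal below; undetermined when no Hb A2
#' band was detected or the fractions are undetermined.
#'
#' @param fractions named fractions as returned by [computeFractions()].
#' @return "normal", "abnormal" or "undetermined".
#' @export
classifyHbA2 <- function(fractions) {
  if (!"HbA2" %in% names(fractions)) return("undetermined")
  f <- fractions[["HbA2"]]
  if (is.na(f)) return("undetermined")
  if (f >= 0.035) "abnormal" else "normal"
}

#' Quantify band contents from an image and detections
#'
#' The end-to-end box densitometry pipeline: invert the grayscale, estimate
#' the background threshold from the inter-band gel region, subtract it,
#' integrate signal inside each Hb-class box (bubbles excluded, overlaps
#' uniquely assigned), normalise to relative contents and apply the Hb A2
#' rule. pI-marker boxes never enter the content denominator; Hb A1c and
#' Hb A0 circulate as the single merged class "HbA1c_A0".
#'
#' @param image a \linkS4class{GelImage} (raw, not inverted).
#' @param detections a \linkS4class{BandBoxSet}: Hb band boxes plus optional
#'   gel, bubble and pI-marker boxes.
#' @return A \linkS4class{QuantResult}.
#' @export
quantifyBands <- function(image, detections) {
  sp <- .splitBoxes(detections)
  inv <- invertGray(image)
  if (!nrow(sp$band)) {
    thr <- tryCatch(estimateBackgroundThreshold(inv, detections), error = function(e) 0)
    return(new("QuantResult",
               background_threshold = as.numeric(thr),
               band_intensities = setNames(numeric(0), character(0)),
               fractions = setNames(numeric(0), character(0)),
               hba2_status = "undetermined",
               background_mode = attr(thr, "background_mode") %||% "whole-image",
               determined = FALSE))
  }
  thr <- estimateBackgroundThreshold(inv, detections)
  signal <- subtractBackground(inv, as.numeric(thr))
  intens <- integrateBands(signal, sp$band, sp$bubble)
  frac <- computeFractions(intens)
  determined <- isTRUE(attr(frac, "determined"))
  new("QuantResult",
      background_threshold = as.numeric(thr),
      band_intensities = intens,
      fractions = if (determined) {
        setNames(as.numeric(frac), names(frac))
      } else setNames(numeric(0), character(0)),
      hba2_status = if (determined) classifyHbA2(frac) else "undetermined",
      background_mode = attr(thr, "background_mode"),
      determined = determined)
}

#' Serialise a QuantResult to JSON
#' @param quant a \linkS4class{QuantResult}.
#' @param path destination file.
#' @return Invisibly, \code{path}.
#' @export
writeQuantJSON <- function(quant, path) {
  jsonlite::write_json(list(
    background_threshold = quant@background_threshold,
    background_mode = quant@background_mode,
    determined = quant@determined,
    band_intensities = as.list(quant@band_intensities),
    fractions = as.list(quant@fractions),
    hba2_status = quant@hba2_status
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
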