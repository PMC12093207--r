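#' @import methods
NULL

#' Band class vocabulary
#'
#' The six annotation classes used on hemoglobin IEF gel images, plus the
#' pI-marker class used only by the profile-analysis baseline. Hb A1c and
#' Hb A0 focus at nearly the same position and are merged into a single class
#' so that overlapping boxes are never double counted.
#'
#' @return Character vector of class labels.
#' @export
gelClasses <- function() {
  c("gel", "bubble", "HbA1c_A0", "MetHb", "HbF", "HbA2", "pI_marker")
}

#' @rdname gelClasses
#' @export
hbClasses <- function() c("HbA1c_A0", "MetHb", "HbF", "HbA2")

#' GelImage: an 8-bit grayscale gel image
#'
#' A thin wrapper around an integer-valued intensity matrix. Rows index the
#' vertical (y, migration/pI) axis, columns the horizontal (x, lane) axis;
#' y increases downward as in image coordinates. All values lie in [0, 255].
#'
#' @slot pixels numeric matrix of 8-bit intensities (row = y, column = x).
#' @export
setClass("GelImage", representation(pixels = "matrix"), validity = function(object) {
  p <- object@pixels
  if (!is.numeric(p)) return("pixels must be numeric")
  if (nrow(p) < 1L || ncol(p) < 1L) return("image must have height >= 1 and width >= 1")
  if (anyNA(p)) return("pixels must not contain NA")
  if (min(p) < 0 || max(p) > 255) return("pixel values must lie in [0, 255]")
  if (any(p != round(p))) return("pixel values must be integral (8-bit)")
  TRUE
})

#' Construct a GelImage
#'
#' @param pixels numeric matrix of intensities in [0, 255] (row = y).
#' @return A \linkS4class{GelImage}.
#' @export
GelImage <- function(pixels) {
  new("GelImage", pixels = matrix(as.numeric(pixels), nrow = nrow(pixels)))
}

#' BandBoxSet: classed, optionally confidence-scored boxes
#'
#' Axis-aligned pixel bounding boxes in 0-based, half-open coordinates
#' \code{[x_min, x_max) x [y_min, y_max)}. Ground-truth boxes carry
#' \code{NA} confidence; detector outputs carry a confidence in [0, 1].
#'
#' @slot boxes data.frame with columns class_label, x_min, y_min, x_max,
#'   y_max, confidence.
#' @export
setClass("BandBoxSet", representation(boxes = "data.frame"), validity = function(object) {
  b <- object@boxes
  need <- c("class_label", "x_min", "y_min", "x_max", "y_max", "confidence")
  if (!all(need %in% names(b))) {
    return(paste("missing columns:", paste(setdiff(need, names(b)), collapse = ", ")))
  }
  if (nrow(b) == 0L) return(TRUE)
  if (!all(b$class_label %in% gelClasses())) {
    return(paste("unknown class label(s):",
                 paste(unique(setdiff(b$class_label, gelClasses())), collapse = ", ")))
  }
  if (any(b$x_min >= b$x_max) || any(b$y_min >= b$y_max)) {
    return("boxes must satisfy x_min < x_max and y_min < y_max")
  }
  conf <- b$confidence[!is.na(b$confidence)]
  if (length(conf) && (min(conf) < 0 || max(conf) > 1)) {
    return("confidence must lie in [0, 1]")
  }
  TRUE
})

#' Construct a BandBoxSet
#'
#' @param class_label character vector of class labels (see [gelClasses()]).
#' @param x_min,y_min,x_max,y_max box bounds, 0-based half-open pixels.
#' @param confidence detector confidence in [0, 1], or \code{NA} for ground
#'   truth (recycled).
#' @return A \linkS4class{BandBoxSet}.
#' @export
bandBoxSet <- function(class_label = character(), x_min = numeric(),
                       y_min = numeric(), x_max = numeric(), y_max = numeric(),
                       confidence = NA_real_) {
  n <- length(class_label)
  df <- data.frame(
    class_label = as.character(class_label),
    x_min = as.numeric(x_min), y_min = as.numeric(y_min),
    x_max = as.numeric(x_max), y_max = as.numeric(y_max),
    confidence = rep_len(as.numeric(confidence), n),
    stringsAsFactors = FALSE
  )
  new("BandBoxSet", boxes = df)
}

#' Concatenate BandBoxSets
#' @param ... BandBoxSet objects.
#' @return A single \linkS4class{BandBoxSet}.
#' @export
concatBoxes <- function(...) {
  dfs <- lapply(list(...), function(b) b@boxes)
  new("BandBoxSet", boxes = do.call(rbind, dfs))
}

#' BandSpec: one simulated band
#'
#' @slot class_label character, one of the Hb classes or "pI_marker".
#' @slot pI numeric, isoelectric point in pH units.
#' @slot amplitude numeric, darkening depth below background (8-bit units).
#' @slot sigma_y numeric, Gaussian spread along the migration axis (pixels).
#' @slot fraction numeric, target share of total Hb signal (NA = derive from
#'   amplitude and sigma_y).
#' @export
setClass("BandSpec",
  representation(class_label = "character", pI = "numeric",
                 amplitude = "numeric", sigma_y = "numeric",
                 fraction = "numeric"),
  validity = function(object) {
    if (!object@class_label %in% c(hbClasses(), "pI_marker")) {
      return("class_label must be an Hb class or 'pI_marker'")
    }
    if (object@amplitude <= 0) return("amplitude must be positive")
    if (object@sigma_y <= 0) return("sigma_y must be positive")
    if (!is.na(object@fraction) && (object@fraction < 0 || object@fraction > 1)) {
      return("fraction must lie in [0, 1]")
    }
    TRUE
  })

#' Construct a BandSpec
#' @param class_label band class (Hb class or "pI_marker").
#' @param pI isoelectric point (pH units), inside the gradient range.
#' @param amplitude darkening depth relative to background, 8-bit units.
#' @param sigma_y Gaussian axial spread in pixels.
#' @param fraction target share of total Hb signal, or NA.
#' @return A \linkS4class{BandSpec}.
#' @export
bandSpec <- function(class_label, pI, amplitude = 120, sigma_y = 5, fraction = NA_real_) {
  new("BandSpec", class_label = class_label, pI = as.numeric(pI),
      amplitude = as.numeric(amplitude), sigma_y = as.numeric(sigma_y),
      fraction = as.numeric(fraction))
}

#' GelSimConfig: simulator configuration
#'
#' Describes the geometry of an mIEF chip image (lanes running vertically,
#' dark bands on a light background across a pH 5.2-7.8 gradient along y)
#' and the imaging perturbations applied: a linear illumination ramp,
#' Gaussian sensor noise, lane curvature, bubbles in the cooling liquid, and
#' a global exposure scale.
#'
#' @export
setClass("GelSimConfig",
  representation(image_width = "numeric", image_height = "numeric",
                 n_lanes = "numeric", lane_width = "numeric",
                 pH_low = "numeric", pH_high = "numeric",
                 bands = "list", background_level = "numeric",
                 illumination_gradient = "numeric", noise_sigma = "numeric",
                 lane_curvature = "numeric", bubble_count = "numeric",
                 exposure_scale = "numeric", seed = "numeric"),
  validity = function(object) {
    if (object@pH_low >= object@pH_high) return("pH_low must be < pH_high")
    if (object@background_level < 0 || object@background_level > 255) {
      return("background_level must lie in [0, 255]")
    }
    if (object@noise_sigma < 0) return("noise_sigma must be >= 0")
    if (object@n_lanes < 1) return("n_lanes must be >= 1")
    if (object@exposure_scale <= 0) return("exposure_scale must be positive")
    if (object@lane_width * object@n_lanes > object@image_width) {
      return("lanes do not fit in image width")
    }
    for (b in object@bands) {
      if (!is(b, "BandSpec")) return("bands must be a list of BandSpec")
      if (b@pI < object@pH_low || b@pI > object@pH_high) {
        return(sprintf("band '%s' pI %.2f outside gradient [%.2f, %.2f]",
                       b@class_label, b@pI, object@pH_low, object@pH_high))
      }
    }
    TRUE
  })

#' GroundTruth: annotations emitted with a simulated gel
#'
#' @slot boxes \linkS4class{BandBoxSet} of gel, band, marker and bubble boxes.
#' @slot true_fractions named numeric, clean-signal share per Hb class.
#' @slot pi_map numeric length-2 (intercept, slope): pH = intercept + slope*y.
#' @slot lane_centers numeric, x pixel centers of the simulated lanes.
#' @export
setClass("GroundTruth",
  representation(boxes = "BandBoxSet", true_fractions = "numeric",
                 pi_map = "numeric", lane_centers = "numeric"),
  validity = function(object) {
    fr <- object@true_fractions
    if (length(fr) && abs(sum(fr) - 1) > 1e-9) {
      return("true fractions must sum to 1")
    }
    TRUE
  })

#' IntensityProfile: a 1-D projection of a gel image
#'
#' @slot values numeric, non-negative mean inverted intensities.
#' @slot axis character, "x" or "y" (the axis indexed by the profile).
#' @slot origin numeric, pixel offset of element 1 in image coordinates.
#' @export
setClass("IntensityProfile",
  representation(values = "numeric", axis = "character", origin = "numeric"),
  validity = function(object) {
    if (length(object@values) < 1L) return("profile must have length >= 1")
    if (any(object@values < -1e-9)) return("profile values must be >= 0")
    if (!object@axis %in% c("x", "y")) return("axis must be 'x' or 'y'")
    TRUE
  })

#' PiCalibration: piecewise-linear y -> pI mapping
#'
#' Built from pI-marker anchor points; linear interpolation between anchors
#' and linear extrapolation from the two nearest anchors outside the range.
#'
#' @slot anchors data.frame with columns y (pixels) and pI (pH units),
#'   strictly monotone in y.
#' @export
setClass("PiCalibration", representation(anchors = "data.frame"),
  validity = function(object) {
    a <- object@anchors
    if (!all(c("y", "pI") %in% names(a))) return("anchors need columns y and pI")
    if (nrow(a) < 2L) return("need >= 2 anchors")
    if (any(diff(a$y) <= 0)) return("anchor y values must be strictly increasing")
    TRUE
  })

#' QuantResult: per-band intensities and relative contents
#'
#' @slot background_threshold numeric, mean inverted background intensity.
#' @slot band_intensities named numeric, summed background-subtracted signal.
#' @slot fractions named numeric, relative content per Hb class.
#' @slot hba2_status character: "normal", "abnormal" or "undetermined".
#' @slot background_mode character: "gel-box" or "whole-image".
#' @slot determined logical, FALSE when no Hb signal was quantifiable.
#' @export
setClass("QuantResult",
  representation(background_threshold = "numeric", band_intensities = "numeric",
                 fractions = "numeric", hba2_status = "character",
                 background_mode = "character", determined = "logical"),
  validity = function(object) {
    if (any(object@band_intensities < 0)) return("intensities must be >= 0")
    if (object@determined && length(object@fractions) &&
        abs(sum(object@fractions) - 1) > 1e-9) {
      return("fractions must sum to 1 when determined")
    }
    if (!object@hba2_status %in% c("normal", "abnormal", "undetermined")) {
      return("invalid hba2_status")
    }
    TRUE
  })

#' EvalResult: detection-quality metrics
#'
#' @slot per_class_ap named numeric, average precision per GT-present class.
#' @slot map50 numeric, mean of per-class AP at IoU 0.5.
#' @slot pr_curves named list of data.frames (recall, precision, confidence).
#' @slot confusion integer matrix over classes plus "background"
#'   (rows = ground truth, columns = prediction).
#' @export
setClass("EvalResult",
  representation(per_class_ap = "numeric", map50 = "numeric",
                 pr_curves = "list", confusion = "matrix"),
  validity = function(object) {
    ap <- object@per_class_ap
    if (length(ap) && (min(ap) < -1e-12 || max(ap) > 1 + 1e-12)) {
      return("AP values must lie in [0, 1]")
    }
    TRUE
  })

#' AgreementStats: regression and Bland-Altman method comparison
#'
#' @slot slope,intercept OLS coefficients of method on reference.
#' @slot r,r_squared Pearson correlation and its square.
#' @slot mean_diff,sd_diff mean and sample SD (n-1) of method - reference.
#' @slot loa_low,loa_high limits of agreement mean_diff +/- 1.96 sd_diff.
#' @slot frac_within_loa share of differences inside the limits.
#' @slot n number of pairs.
#' @export
setClass("AgreementStats",
  representation(slope = "numeric", intercept = "numeric", r = "numeric",
                 r_squared = "numeric", mean_diff = "numeric",
                 sd_diff = "numeric", loa_low = "numeric", loa_high = "numeric",
                 frac_within_loa = "numeric", n = "numeric"),
  validity = function(object) {
    if (!is.na(object@r) && abs(object@r) > 1 + 1e-12) return("|r| must be <= 1")
    if (object@loa_low > object@mean_diff || object@loa_high < object@mean_diff) {
      return("limits of agreement must bracket the mean difference")
    }
    TRUE
  })
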