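#' @include AllClasses.R
NULL

#' Accessors for gel-analysis objects
#'
#' Small accessor generics following Bioconductor conventions: user code
#' reads slots through these rather than with \code{@}.
#'
#' @param x an object defined by this package.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("gelPixels", function(x) standardGeneric("gelPixels"))
#' @rdname accessors
#' @export
setGeneric("imageWidth", function(x) standardGeneric("imageWidth"))
#' @rdname accessors
#' @export
setGeneric("imageHeight", function(x) standardGeneric("imageHeight"))
#' @rdname accessors
#' @export
setGeneric("boxFrame", function(x) standardGeneric("boxFrame"))
#' @rdname accessors
#' @export
setGeneric("trueFractions", function(x) standardGeneric("trueFractions"))
#' @rdname accessors
#' @export
setGeneric("gtBoxes", function(x) standardGeneric("gtBoxes"))
#' @rdname accessors
#' @export
setGeneric("piMap", function(x) standardGeneric("piMap"))
#' @rdname accessors
#' @export
setGeneric("profileValues", function(x) standardGeneric("profileValues"))
#' @rdname accessors
#' @export
setGeneric("profileOrigin", function(x) standardGeneric("profileOrigin"))
#' @rdname accessors
#' @export
setGeneric("bandIntensities", function(x) standardGeneric("bandIntensities"))
#' @rdname accessors
#' @export
setGeneric("bandFractions", function(x) standardGeneric("bandFractions"))
#' @rdname accessors
#' @export
setGeneric("hba2Status", function(x) standardGeneric("hba2Status"))
#' @rdname accessors
#' @export
setGeneric("backgroundThreshold", function(x) standardGeneric("backgroundThreshold"))
#' @rdname accessors
#' @export
setGeneric("perClassAP", function(x) standardGeneric("perClassAP"))
#' @rdname accessors
#' @export
setGeneric("map50", function(x) standardGeneric("map50"))
#' @rdname accessors
#' @export
setGeneric("prCurves", function(x) standardGeneric("prCurves"))
#' @rdname accessors
#' @export
setGeneric("confusionCounts", function(x) standardGeneric("confusionCounts"))

# ---- GelImage ----

#' @rdname accessors
#' @export
setMethod("gelPixels", "GelImage", function(x) x@pixels)
#' @rdname accessors
#' @export
setMethod("imageWidth", "GelImage", function(x) ncol(x@pixels))
#' @rdname accessors
#' @export
setMethod("imageHeight", "GelImage", function(x) nrow(x@pixels))

setMethod("show", "GelImage", function(object) {
  p <- object@pixels
  cat(sprintf("GelImage: %d x %d px (8-bit), intensity range [%d, %d]\n",
              ncol(p), nrow(p), as.integer(min(p)), as.integer(max(p))))
})

# ---- BandBoxSet ----

#' @rdname accessors
#' @export
setMethod("boxFrame", "BandBoxSet", function(x) x@boxes)

#' @param x a BandBoxSet.
#' @rdname bandBoxSet
#' @export
setMethod("length", "BandBoxSet", function(x) nrow(x@boxes))

#' @param i row index.
#' @param j,...,drop ignored (present for generic compatibility).
#' @rdname bandBoxSet
#' @export
setMethod("[", "BandBoxSet", function(x, i, j, ..., drop = FALSE) {
  new("BandBoxSet", boxes = x@boxes[i, , drop = FALSE])
})

#' @rdname bandBoxSet
#' @export
setMethod("as.data.frame", "BandBoxSet", function(x, ...) x@boxes)

setMethod("show", "BandBoxSet", function(object) {
  b <- object@boxes
  cat(sprintf("BandBoxSet with %d box(es)\n", nrow(b)))
  if (nrow(b)) {
    tab <- table(b$class_label)
    cat("  classes:", paste(sprintf("%s(%d)", names(tab), tab), collapse = ", "), "\n")
    if (any(!is.na(b$confidence))) {
      cat(sprintf("  confidence range: [%.3f, %.3f]\n",
                  min(b$confidence, na.rm = TRUE), max(b$confidence, na.rm = TRUE)))
    }
  }
})

# ---- GroundTruth ----

#' @rdname accessors
#' @export
setMethod("gtBoxes", "GroundTruth", function(x) x@boxes)
#' @rdname accessors
#' @export
setMethod("trueFractions", "GroundTruth", function(x) x@true_fractions)
#' @rdname accessors
#' @export
setMethod("piMap", "GroundTruth", function(x) x@pi_map)

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %d box(es); pH = %.4f + %.5f * y\n",
              length(object@boxes), object@pi_map[1], object@pi_map[2]))
  if (length(object@true_fractions)) {
    cat("  true fractions:",
        paste(sprintf("%s=%.3f", names(object@true_fractions),
                      object@true_fractions), collapse = ", "), "\n")
  }
})

# ---- IntensityProfile ----

#' @rdname accessors
#' @export
setMethod("profileValues", "IntensityProfile", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("profileOrigin", "IntensityProfile", function(x) x@origin)

#' @param x an IntensityProfile.
#' @rdname projectProfile
#' @export
setMethod("length", "IntensityProfile", function(x) length(x@values))

setMethod("show", "IntensityProfile", function(object) {
  cat(sprintf("IntensityProfile along %s: %d elements from pixel %d, max %.2f\n",
              object@axis, length(object@values), as.integer(object@origin),
              max(object@values)))
})

# ---- QuantResult ----

#' @rdname accessors
#' @export
setMethod("bandIntensities", "QuantResult", function(x) x@band_intensities)
#' @rdname accessors
#' @export
setMethod("bandFractions", "QuantResult", function(x) x@fractions)
#' @rdname accessors
#' @export
setMethod("hba2Status", "QuantResult", function(x) x@hba2_status)
#' @rdname accessors
#' @export
setMethod("backgroundThreshold", "QuantResult", function(x) x@background_threshold)

setMethod("show", "QuantResult", function(object) {
  cat("QuantResult\n")
  cat(sprintf("  background threshold (inverted scale): %.3f [%s]\n",
              object@background_threshold, object@background_mode))
  if (!object@determined) {
    cat("  undetermined: no Hb band signal\n")
    return(invisible(NULL))
  }
  for (cl in names(object@fractions)) {
    cat(sprintf("  %-9s intensity %12.1f  content %5.1f%%\n", cl,
                object@band_intensities[[cl]], 100 * object@fractions[[cl]]))
  }
  cat(sprintf("  Hb A2 status: %s\n", object@hba2_status))
})

# ---- EvalResult ----

#' @rdname accessors
#' @export
setMethod("perClassAP", "EvalResult", function(x) x@per_class_ap)
#' @rdname accessors
#' @export
setMethod("map50", "EvalResult", function(x) x@map50)
#' @rdname accessors
#' @export
setMethod("prCurves", "EvalResult", function(x) x@pr_curves)
#' @rdname accessors
#' @export
setMethod("confusionCounts", "EvalResult", function(x) x@confusion)

setMethod("show", "EvalResult", function(object) {
  cat(sprintf("EvalResult: mAP50 = %.4f over %d class(es)\n",
              object@map50, length(object@per_class_ap)))
  for (cl in names(object@per_class_ap)) {
    cat(sprintf("  AP50 %-9s %.4f\n", cl, object@per_class_ap[[cl]]))
  }
})

# ---- AgreementStats ----

setMethod("show", "AgreementStats", function(object) {
  cat(sprintf("AgreementStats (n = %d pairs)\n", as.integer(object@n)))
  cat(sprintf("  OLS: slope %.4f, intercept %.4f; r %.4f, r^2 %.4f\n",
              object@slope, object@intercept, object@r, object@r_squared))
  cat(sprintf("  Bland-Altman: mean diff %.4f, SD %.4f, LoA [%.4f, %.4f], %.0f%% within\n",
              object@mean_diff, object@sd_diff, object@loa_low, object@loa_high,
              100 * object@frac_within_loa))
})

#' @param x an AgreementStats object.
#' @param ... ignored.
#' @rdname agreementStats
#' @export
setMethod("as.data.frame", "AgreementStats", function(x, ...) {
  data.frame(slope = x@slope, intercept = x@intercept, r = x@r,
             r_squared = x@r_squared, mean_diff = x@mean_diff,
             sd_diff = x@sd_diff, loa_low = x@loa_low, loa_high = x@loa_high,
             frac_within_loa = x@frac_within_loa, n = x@n)
})
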