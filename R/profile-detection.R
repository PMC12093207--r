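#' @include AllClasses.R AllGenerics.R
NULL

.pixelMatrix <- function(x, invert = FALSE) {
  if (is(x, "GelImage")) {
    p <- gelPixels(x)
    if (invert) 255 - p else p
  } else if (is.matrix(x)) {
    x  # plain matrices are taken as already-inverted signal
  } else {
    stop("expected a GelImage or a numeric matrix")
  }
}

#' Project a gel image onto one axis
#'
#' Computes the mean inverted intensity per row (\code{axis = "y"}, the
#' migration/pI axis) or per column (\code{axis = "x"}) inside an optional
#' region. Inversion (255 - v) makes dark bands positive peaks. A plain
#' numeric matrix is treated as already-inverted signal and projected as-is.
#'
#' @param image a \linkS4class{GelImage} (or already-inverted numeric matrix).
#' @param axis "y" or "x".
#' @param region optional \linkS4class{BandBoxSet} with a single box
#'   restricting the projection.
#' @return An \linkS4class{IntensityProfile}.
#' @export
projectProfile <- function(image, axis = c("y", "x"), region = NULL) {
  axis <- match.arg(axis)
  m <- .pixelMatrix(image, invert = TRUE)
  x0 <- 0; y0 <- 0
  if (!is.null(region)) {
    b <- if (is(region, "BandBoxSet")) boxFrame(region) else as.data.frame(region)
    if (nrow(b) != 1L) stop("region must contain exactly one box")
    if (b$x_min < 0 || b$y_min < 0 || b$x_max > ncol(m) || b$y_max > nrow(m)) {
      stop("region outside image")
    }
    m <- m[(b$y_min + 1):b$y_max, (b$x_min + 1):b$x_max, drop = FALSE]
    x0 <- b$x_min; y0 <- b$y_min
  }
  if (!length(m)) stop("empty projection region")
  if (axis == "y") {
    new("IntensityProfile", values = unname(rowMeans(m)), axis = "y", origin = y0)
  } else {
    new("IntensityProfile", values = unname(colMeans(m)), axis = "x", origin = x0)
  }
}

# 1-D grayscale erosion/dilation with a centred flat window; windows shrink
# at the profile ends
.rollExtreme <- function(v, window, fun) {
  n <- length(v)
  h <- (window - 1) %/% 2
  out <- numeric(n)
  for (i in seq_len(n)) {
    out[[i]] <- fun(v[max(1, i - h):min(n, i + h)])
  }
  out
}

#' Baseline-correct an intensity profile
#'
#' Subtracts a morphological-opening baseline (rolling minimum followed by
#' rolling maximum over a flat window). Peaks narrower than the window sit on
#' a baseline that follows slow background drift; the corrected profile is
#' non-negative, and the correction is idempotent.
#'
#' @param profile an \linkS4class{IntensityProfile}.
#' @param window structuring-element width in pixels (odd widths are
#'   symmetric); must not exceed the profile length.
#' @return A baseline-corrected \linkS4class{IntensityProfile}.
#' @export
correctBaseline <- function(profile, window = 51) {
  v <- profileValues(profile)
  if (window < 1 || window > length(v)) {
    stop("window must lie in [1, profile length]")
  }
  eroded <- .rollExtreme(v, window, min)
  baseline <- .rollExtreme(eroded, window, max)
  new("IntensityProfile", values = pmax(v - baseline, 0),
      axis = profile@axis, origin = profile@origin)
}

#' Detect peaks in a baseline-corrected profile
#'
#' Local maxima with prominence at least \code{min_prominence} times the
#' profile maximum, separated by at least \code{min_distance} pixels (kept in
#' decreasing height order when closer). Peak bounds extend outward from the
#' mode to the nearest local minimum, or to where the profile falls below 1%
#' of the peak height — whichever comes first; on quantized profiles the
#' inter-band floor is a flat zero run, which the 1% rule treats as the
#' bound.
#'
#' @param profile an \linkS4class{IntensityProfile} (baseline-corrected).
#' @param min_prominence required prominence as a fraction of the profile
#'   maximum (default 0.05).
#' @param min_distance minimum separation between kept peaks, pixels.
#' @return data.frame with columns center, left, right (0-based image
#'   pixels, \code{[left, right)} half-open), height, prominence.
#' @export
detectPeaks <- function(profile, min_prominence = 0.05, min_distance = 3) {
  v <- profileValues(profile)
  n <- length(v)
  empty <- data.frame(center = numeric(0), left = numeric(0), right = numeric(0),
                      height = numeric(0), prominence = numeric(0))
  if (max(v) <= 0) return(empty)

  # candidate maxima; plateau maxima take the centre index of the plateau
  cand <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (v[[i]] > v[[i - 1L]]) {
      j <- i
      while (j < n && v[[j + 1L]] == v[[j]]) j <- j + 1L
      if (j < n && v[[j + 1L]] < v[[j]]) {
        cand <- c(cand, as.integer((i + j) %/% 2))
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (!length(cand)) return(empty)

  # prominence: height above the higher of the two key saddles (lowest point
  # between the peak and the nearest higher peak, or the profile end)
  prom <- vapply(cand, function(p) {
    hp <- v[[p]]
    left_min <- hp
    k <- p
    while (k > 1L && v[[k - 1L]] <= hp) {
      k <- k - 1L
      left_min <- min(left_min, v[[k]])
    }
    if (k == 1L && v[[k]] <= hp) left_min <- min(left_min, v[[k]])
    right_min <- hp
    k <- p
    while (k < n && v[[k + 1L]] <= hp) {
      k <- k + 1L
      right_min <- min(right_min, v[[k]])
    }
    hp - max(left_min, right_min)
  }, numeric(1))

  keep <- prom >= min_prominence * max(v)
  cand <- cand[keep]; prom <- prom[keep]
  if (!length(cand)) return(empty)

  # enforce min_distance, keeping taller peaks first
  ord <- order(v[cand], decreasing = TRUE)
  kept <- integer(0)
  for (idx in ord) {
    if (!length(kept) || all(abs(cand[kept] - cand[[idx]]) >= min_distance)) {
      kept <- c(kept, idx)
    }
  }
  kept <- sort(kept)
  cand <- cand[kept]; prom <- prom[kept]

  bounds <- t(vapply(cand, function(p) {
    floor_v <- 0.01 * v[[p]]
    l <- p
    while (l > 1L && v[[l - 1L]] <= v[[l]] && v[[l - 1L]] > floor_v) l <- l - 1L
    if (l > 1L && v[[l - 1L]] <= floor_v) l <- l - 1L
    r <- p
    while (r < n && v[[r + 1L]] <= v[[r]] && v[[r + 1L]] > floor_v) r <- r + 1L
    if (r < n && v[[r + 1L]] <= floor_v) r <- r + 1L
    c(l, r)
  }, numeric(2)))

  org <- profile@origin
  data.frame(center = org + cand - 1, left = org + bounds[, 1] - 1,
             right = org + bounds[, 2], height = v[cand], prominence = prom)
}

#' Segment the lanes of a gel image
#'
#' Projects the inverted image onto the x axis, removes slow background with
#' a morphological opening, and takes contiguous supra-threshold runs as
#' lanes. When no lane contrast is detectable the whole image is returned as
#' a single region with \code{whole_image = TRUE} (quantification can still
#' proceed; band localisation then works on the full-width profile).
#'
#' @param image a \linkS4class{GelImage}.
#' @param n_lanes_hint optional expected lane count; when more runs are
#'   found, the strongest \code{n_lanes_hint} are kept.
#' @param window baseline window for the x projection (default an eighth of
#'   the image width, at least 31 px).
#' @param threshold run threshold as a fraction of the corrected-projection
#'   maximum.
#' @return List with \code{regions} (data.frame x_min, x_max, 0-based
#'   half-open) and \code{whole_image} flag.
#' @export
segmentLanes <- function(image, n_lanes_hint = NULL, window = NULL,
                         threshold = 0.25) {
  m <- .pixelMatrix(image, invert = TRUE)
  W <- ncol(m)
  prof <- projectProfile(image, axis = "x")
  if (is.null(window)) {
    # the opening window must exceed the lane bump width so lanes survive
    # baseline removal; scale it from the expected pitch when hinted
    window <- if (!is.null(n_lanes_hint)) {
      2 * ceiling(0.75 * W / n_lanes_hint) + 1
    } else {
      max(31, 2 * (W %/% 8) + 1)
    }
  }
  window <- min(window, W)
  corr <- correctBaseline(prof, window)
  cv <- profileValues(corr)
  if (max(cv) < 1) {  # < 1 intensity unit of lane contrast: degraded mode
    return(list(regions = data.frame(x_min = 0, x_max = W), whole_image = TRUE))
  }
  above <- cv >= threshold * max(cv)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- data.frame(x_min = starts[r$values] - 1, x_max = ends[r$values])
  if (!nrow(runs)) {
    return(list(regions = data.frame(x_min = 0, x_max = W), whole_image = TRUE))
  }
  if (!is.null(n_lanes_hint) && nrow(runs) > n_lanes_hint) {
    strength <- vapply(seq_len(nrow(runs)), function(i) {
      sum(cv[(runs$x_min[[i]] + 1):runs$x_max[[i]]])
    }, numeric(1))
    keep <- sort(order(strength, decreasing = TRUE)[seq_len(n_lanes_hint)])
    runs <- runs[keep, , drop = FALSE]
  }
  rownames(runs) <- NULL
  list(regions = runs, whole_image = FALSE)
}

#' Build a pI calibration from marker positions
#'
#' @param markers data.frame (or 2-column matrix) with columns y (pixels)
#'   and pI, one row per pI-marker band; at least two distinct positions.
#' @return A \linkS4class{PiCalibration}.
#' @export
calibratePi <- function(markers) {
  m <- as.data.frame(markers)
  names(m)[1:2] <- c("y", "pI")
  m <- m[order(m$y), , drop = FALSE]
  if (nrow(m) < 2L || anyDuplicated(m$y)) {
    stop("marker-free mode: calibration unavailable (need >= 2 distinct markers)")
  }
  rownames(m) <- NULL
  new("PiCalibration", anchors = m[, c("y", "pI")])
}

#' Map y positions to pI through a calibration
#'
#' Piecewise-linear interpolation between anchors; outside the anchor range
#' the nearest segment is extended linearly.
#'
#' @param calibration a \linkS4class{PiCalibration}.
#' @param y numeric vector of y pixel positions.
#' @return Numeric vector of pI values.
#' @export
predictPi <- function(calibration, y) {
  a <- calibration@anchors
  n <- nrow(a)
  vapply(y, function(yi) {
    if (yi <= a$y[[1]]) {
      seg <- 1L
    } else if (yi >= a$y[[n]]) {
      seg <- n - 1L
    } else {
      seg <- findInterval(yi, a$y, rightmost.closed = TRUE)
    }
    sl <- (a$pI[[seg + 1L]] - a$pI[[seg]]) / (a$y[[seg + 1L]] - a$y[[seg]])
    a$pI[[seg]] + sl * (yi - a$y[[seg]])
  }, numeric(1))
}

#' Default parameters for the profile-analysis detector
#'
#' @param window baseline-correction window (pixels).
#' @param min_prominence peak prominence threshold, fraction of profile max.
#' @param min_distance minimum peak separation (pixels).
#' @param n_lanes_hint expected lane count, or NULL.
#' @param markers optional data.frame (y, pI) of located pI markers; with
#'   two or more markers band classes are assigned by calibrated pI, else by
#'   the fixed migration-order template.
#' @param class_template Hb classes in top-to-bottom migration order.
#' @param class_pi nominal pI per class, used with markers.
#' @return Parameter list for [profileDetect()].
#' @export
profileParams <- function(window = 51, min_prominence = 0.05, min_distance = 3,
                          n_lanes_hint = NULL, markers = NULL,
                          class_template = c("HbA1c_A0", "HbF", "MetHb", "HbA2"),
                          class_pi = c(HbA1c_A0 = 6.80, HbF = 7.10,
                                       MetHb = 7.35, HbA2 = 7.60,
                                       pI_marker_low = 5.40, pI_marker_high = 7.75)) {
  list(window = window, min_prominence = min_prominence,
       min_distance = min_distance, n_lanes_hint = n_lanes_hint,
       markers = markers, class_template = class_template, class_pi = class_pi)
}

#' Detect bands with the classical profile-analysis pipeline
#'
#' Per lane: project onto the migration axis, correct the baseline, detect
#' peaks, and emit one box per peak spanning the lane width and the peak
#' bounds. Classes are assigned by calibrated pI windows when marker
#' positions are supplied, else by the fixed top-to-bottom migration-order
#' template. Box confidence is the peak height normalised by the tallest
#' peak in the image, so detections can be ranked on a PR curve.
#'
#' @param image a \linkS4class{GelImage}.
#' @param params parameter list from [profileParams()].
#' @return A \linkS4class{BandBoxSet} of detections.
#' @export
profileDetect <- function(image, params = profileParams()) {
  lanes <- segmentLanes(image, n_lanes_hint = params$n_lanes_hint)
  H <- imageHeight(image)
  rows <- list()
  for (li in seq_len(nrow(lanes$regions))) {
    reg <- lanes$regions[li, ]
    lane_box <- bandBoxSet("gel", reg$x_min, 0, reg$x_max, H)
    prof <- projectProfile(image, axis = "y", region = lane_box)
    corr <- correctBaseline(prof, min(params$window, length(prof)))
    peaks <- detectPeaks(corr, params$min_prominence, params$min_distance)
    if (!nrow(peaks)) next
    peaks <- peaks[order(peaks$center), , drop = FALSE]

    if (!is.null(params$markers) && nrow(as.data.frame(params$markers)) >= 2) {
      cal <- calibratePi(params$markers)
      pis <- predictPi(cal, peaks$center + 0.5)
      cls <- vapply(pis, function(p) {
        ref <- params$class_pi
        lab <- names(ref)[which.min(abs(ref - p))]
        if (startsWith(lab, "pI_marker")) "pI_marker" else lab
      }, character(1))
    } else {
      tmpl <- params$class_template
      cls <- tmpl[pmin(seq_len(nrow(peaks)), length(tmpl))]
    }
    rows[[length(rows) + 1L]] <- data.frame(
      class_label = cls, x_min = reg$x_min, y_min = peaks$left,
      x_max = reg$x_max, y_max = peaks$right, confidence = peaks$height,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(bandBoxSet())
  df <- do.call(rbind, rows)
  df$confidence <- df$confidence / max(df$confidence)
  new("BandBoxSet", boxes = df)
}
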