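#' @include AllClasses.R AllGenerics.R
NULL

#' Default hemoglobin band layout
#'
#' Four Hb bands in their IEF migration order (lowest pI focuses nearest the
#' acidic end of the gradient, which is rendered at the top of the image):
#' merged Hb A1c/A0, Hb F, MetHb, Hb A2. The default relative contents
#' (0.80/0.05/0.10/0.05) describe a sample whose Hb A2 share sits above the
#' 3.5% screening cutoff so both sides of the decision rule are exercised.
#'
#' @param fractions named or positional numeric of length 4 summing to 1,
#'   shares for HbA1c_A0, HbF, MetHb, HbA2 in that order.
#' @return List of \linkS4class{BandSpec}.
#' @export
defaultHbBands <- function(fractions = c(0.80, 0.05, 0.10, 0.05)) {
  stopifnot(length(fractions) == 4L, abs(sum(fractions) - 1) < 1e-9)
  list(
    bandSpec("HbA1c_A0", pI = 6.80, amplitude = 150, sigma_y = 5, fraction = fractions[[1]]),
    bandSpec("HbF",      pI = 7.10, amplitude = 120, sigma_y = 4, fraction = fractions[[2]]),
    bandSpec("MetHb",    pI = 7.35, amplitude = 120, sigma_y = 4, fraction = fractions[[3]]),
    bandSpec("HbA2",     pI = 7.60, amplitude = 120, sigma_y = 4, fraction = fractions[[4]])
  )
}

#' pI marker bands near the gradient ends
#' @return List of \linkS4class{BandSpec} with class "pI_marker".
#' @export
defaultPiMarkers <- function() {
  list(
    bandSpec("pI_marker", pI = 5.40, amplitude = 80, sigma_y = 3),
    bandSpec("pI_marker", pI = 7.75, amplitude = 80, sigma_y = 3)
  )
}

#' Construct a simulator configuration
#'
#' Defaults emulate the mIEF chip imagery the toolkit targets: a 640 x 640
#' 8-bit frame holding 12 vertical micro separation columns, dark Hb bands on
#' a light background, and a carrier-ampholyte gradient spanning pH 5.2-7.8
#' along the vertical (migration) axis.
#'
#' @param image_width,image_height frame size in pixels.
#' @param n_lanes number of separation lanes (default 12).
#' @param lane_width lane width in pixels.
#' @param pH_low,pH_high ampholyte gradient range (default 5.2-7.8).
#' @param bands list of \linkS4class{BandSpec}; when every Hb band carries a
#'   fraction, band amplitudes are rescaled so the clean signal masses match
#'   those fractions exactly.
#' @param background_level light-background intensity (8-bit units).
#' @param illumination_gradient linear ramp coefficient (intensity per pixel
#'   along x, centred so the mean background stays at background_level).
#' @param noise_sigma Gaussian sensor noise SD (8-bit units).
#' @param lane_curvature maximum horizontal lane displacement in pixels.
#' @param bubble_count number of bubbles to render inside lanes.
#' @param exposure_scale global multiplicative exposure factor.
#' @param seed RNG seed; identical config + seed gives byte-identical output.
#' @return A \linkS4class{GelSimConfig}.
#' @export
gelSimConfig <- function(image_width = 640, image_height = 640, n_lanes = 12,
                         lane_width = 30, pH_low = 5.2, pH_high = 7.8,
                         bands = defaultHbBands(), background_level = 200,
                         illumination_gradient = 0, noise_sigma = 0,
                         lane_curvature = 0, bubble_count = 0,
                         exposure_scale = 1, seed = 1L) {
  new("GelSimConfig", image_width = as.numeric(image_width),
      image_height = as.numeric(image_height), n_lanes = as.numeric(n_lanes),
      lane_width = as.numeric(lane_width), pH_low = as.numeric(pH_low),
      pH_high = as.numeric(pH_high), bands = bands,
      background_level = as.numeric(background_level),
      illumination_gradient = as.numeric(illumination_gradient),
      noise_sigma = as.numeric(noise_sigma),
      lane_curvature = as.numeric(lane_curvature),
      bubble_count = as.numeric(bubble_count),
      exposure_scale = as.numeric(exposure_scale), seed = as.numeric(seed))
}

#' Read / write a simulator configuration as YAML
#' @param path file path.
#' @return \code{readGelSimConfig}: a \linkS4class{GelSimConfig}.
#' @export
readGelSimConfig <- function(path) {
  y <- yaml::read_yaml(path)
  bands <- lapply(y$bands, function(b) {
    bandSpec(b$class_label, b$pI, b$amplitude %||% 120, b$sigma_y %||% 5,
             b$fraction %||% NA_real_)
  })
  y$bands <- NULL
  do.call(gelSimConfig, c(y, list(bands = bands)))
}

#' @param config a \linkS4class{GelSimConfig}.
#' @rdname readGelSimConfig
#' @export
writeGelSimConfig <- function(config, path) {
  slots <- setdiff(slotNames("GelSimConfig"), "bands")
  y <- lapply(slots, function(s) slot(config, s))
  names(y) <- slots
  y$bands <- lapply(config@bands, function(b) {
    list(class_label = b@class_label, pI = b@pI, amplitude = b@amplitude,
         sigma_y = b@sigma_y, fraction = if (is.na(b@fraction)) NULL else b@fraction)
  })
  yaml::write_yaml(y, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Gel-region geometry shared by the renderer and the ground truth: lanes are
# evenly pitched across the width; the pH gradient spans 90% of the height.
.gelGeometry <- function(config) {
  W <- config@image_width; H <- config@image_height
  pitch <- W / config@n_lanes
  centers <- (seq_len(config@n_lanes) - 0.5) * pitch
  gel_top <- round(0.05 * H); gel_bottom <- round(0.95 * H)
  slope <- (config@pH_high - config@pH_low) / (gel_bottom - gel_top)
  intercept <- config@pH_low - slope * gel_top
  list(lane_centers = centers, gel_top = gel_top, gel_bottom = gel_bottom,
       pi_map = c(intercept = intercept, slope = slope))
}

# Axial Gaussian sampled at row centres (y = i - 0.5 in 0-based pixel units
# for R row i); soft top-hat across the lane with a raised-cosine edge.
.bandYProfile <- function(H, y0, sigma) {
  yc <- seq_len(H) - 0.5
  exp(-((yc - y0)^2) / (2 * sigma^2))
}

.laneXProfile <- function(W, cx, half_width, edge = 1.5) {
  xc <- seq_len(W) - 0.5
  u <- abs(xc - cx)
  w <- numeric(W)
  w[u <= half_width - edge] <- 1
  ramp <- u > half_width - edge & u < half_width
  w[ramp] <- 0.5 * (1 + cos(pi * (u[ramp] - (half_width - edge)) / edge))
  w
}

# Rescale band amplitudes so discrete clean masses match requested fractions;
# the x-profile is identical for all bands in a lane so only the axial sums
# matter. The largest-amplitude request is preserved.
.resolveAmplitudes <- function(config, geom) {
  bands <- config@bands
  hb <- vapply(bands, function(b) b@class_label %in% hbClasses(), logical(1))
  fr <- vapply(bands, function(b) b@fraction, numeric(1))
  amp <- vapply(bands, function(b) b@amplitude, numeric(1))
  if (any(hb) && all(!is.na(fr[hb]))) {
    if (abs(sum(fr[hb]) - 1) > 1e-9) {
      stop("Hb band fractions must sum to 1 (got ", sum(fr[hb]), ")")
    }
    H <- config@image_height
    g <- vapply(bands, function(b) {
      y0 <- (b@pI - geom$pi_map[["intercept"]]) / geom$pi_map[["slope"]]
      sum(.bandYProfile(H, y0, b@sigma_y))
    }, numeric(1))
    # amplitude_i = k * fraction_i / g_i, k chosen so the tallest resulting
    # band keeps the largest requested amplitude
    raw <- fr[hb] / g[hb]
    amp[hb] <- max(amp[hb]) / max(raw) * raw
  }
  amp
}

#' Generate one annotated synthetic gel image
#'
#' Renders each configured band into every lane as a separable profile
#' (Gaussian along the migration axis, soft-edged top-hat across the lane),
#' then applies lane curvature, a linear illumination ramp, bubbles, exposure
#' scaling, Gaussian noise, clipping to [0, 255] and round-half-to-even
#' quantization. Ground-truth boxes have half-height 3 sigma_y, covering more
#' than 99% of each band's clean signal mass.
#'
#' @param config a \linkS4class{GelSimConfig}.
#' @return List with elements \code{image} (\linkS4class{GelImage}),
#'   \code{truth} (\linkS4class{GroundTruth}) and \code{clean_signal}
#'   (list of per-band noiseless signal matrices, for diagnostics).
#' @export
generateGel <- function(config) {
  validObject(config)
  geom <- .gelGeometry(config)
  W <- config@image_width; H <- config@image_height
  hw <- config@lane_width / 2
  amp <- .resolveAmplitudes(config, geom)

  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(config@seed))

  # Per-row lane-centre displacement shared by all lanes
  dx <- config@lane_curvature * sin(pi * (seq_len(H) - 0.5) / H)

  band_signal <- vector("list", length(config@bands))
  boxes <- list()
  gt_frac <- setNames(numeric(0), character(0))
  masses <- setNames(numeric(length(config@bands)),
                     vapply(config@bands, function(b) b@class_label, character(1)))

  for (bi in seq_along(config@bands)) {
    b <- config@bands[[bi]]
    y0 <- (b@pI - geom$pi_map[["intercept"]]) / geom$pi_map[["slope"]]
    gy <- .bandYProfile(H, y0, b@sigma_y)
    S <- matrix(0, H, W)
    y_lo <- max(0, floor(y0 - 3 * b@sigma_y))
    y_hi <- min(H, ceiling(y0 + 3 * b@sigma_y))
    rows_in_box <- (y_lo + 1):y_hi
    for (li in seq_len(config@n_lanes)) {
      cx0 <- geom$lane_centers[[li]]
      if (config@lane_curvature == 0) {
        wx <- .laneXProfile(W, cx0, hw)
        S <- S + amp[[bi]] * outer(gy, wx)
      } else {
        for (r in seq_len(H)) {
          if (gy[[r]] > 1e-12) {
            S[r, ] <- S[r, ] + amp[[bi]] * gy[[r]] * .laneXProfile(W, cx0 + dx[[r]], hw)
          }
        }
      }
      shift <- if (config@lane_curvature == 0) c(0, 0) else range(dx[rows_in_box])
      boxes[[length(boxes) + 1L]] <- data.frame(
        class_label = b@class_label,
        x_min = max(0, floor(cx0 + shift[[1]] - hw)),
        y_min = y_lo,
        x_max = min(W, ceiling(cx0 + shift[[2]] + hw)),
        y_max = y_hi,
        confidence = NA_real_, stringsAsFactors = FALSE)
    }
    band_signal[[bi]] <- S
    masses[[bi]] <- sum(S)
  }

  hb_idx <- vapply(config@bands, function(b) b@class_label %in% hbClasses(), logical(1))
  if (any(hb_idx)) {
    hb_mass <- tapply(masses[hb_idx], names(masses)[hb_idx], sum)
    gt_frac <- hb_mass / sum(hb_mass)
    gt_frac <- setNames(as.numeric(gt_frac), names(hb_mass))
    # renormalise exactly against accumulated floating error
    gt_frac <- gt_frac / sum(gt_frac)
  }

  S_total <- Reduce(`+`, band_signal, matrix(0, H, W))

  # Illumination ramp centred on the frame, then bubbles, exposure and noise
  xc <- seq_len(W) - 0.5
  illum <- config@illumination_gradient * (xc - (W - 1) / 2)
  base <- matrix(rep(config@background_level + illum, each = H), H, W)

  bubble <- matrix(0, H, W)
  if (config@bubble_count > 0) {
    for (k in seq_len(config@bubble_count)) {
      lane <- sample.int(config@n_lanes, 1L)
      bx <- geom$lane_centers[[lane]] + stats::runif(1, -hw / 2, hw / 2)
      by <- stats::runif(1, geom$gel_top + 10, geom$gel_bottom - 10)
      rx <- stats::runif(1, 3, 8); ry <- stats::runif(1, 3, 8)
      cols <- max(1, floor(bx - 1.3 * rx)):min(W, ceiling(bx + 1.3 * rx))
      rows <- max(1, floor(by - 1.3 * ry)):min(H, ceiling(by + 1.3 * ry))
      for (r in rows) {
        d <- sqrt(((cols - 0.5 - bx) / rx)^2 + ((r - 0.5 - by) / ry)^2)
        inside <- d <= 1
        rim <- d > 1 & d <= 1.25
        bubble[r, cols[inside]] <- bubble[r, cols[inside]] + 30   # bright body
        bubble[r, cols[rim]] <- bubble[r, cols[rim]] - 25         # dark rim
      }
      boxes[[length(boxes) + 1L]] <- data.frame(
        class_label = "bubble",
        x_min = max(0, floor(bx - 1.25 * rx)), y_min = max(0, floor(by - 1.25 * ry)),
        x_max = min(W, ceiling(bx + 1.25 * rx)), y_max = min(H, ceiling(by + 1.25 * ry)),
        confidence = NA_real_, stringsAsFactors = FALSE)
    }
  }

  F_clean <- config@exposure_scale * (base - S_total + bubble)
  n_clip <- sum(F_clean < 0 | F_clean > 255)
  if (n_clip > 0) {
    warning(sprintf("%d pixel(s) clipped to [0, 255] during rendering", n_clip))
  }
  F_img <- F_clean
  if (config@noise_sigma > 0) {
    F_img <- F_img + matrix(stats::rnorm(H * W, sd = config@noise_sigma), H, W)
  }
  pix <- round(pmin(pmax(F_img, 0), 255))  # round() is round-half-to-even

  gel_box <- data.frame(
    class_label = "gel",
    x_min = max(0, floor(min(geom$lane_centers) - hw - 4)),
    y_min = geom$gel_top,
    x_max = min(W, ceiling(max(geom$lane_centers) + hw + 4)),
    y_max = geom$gel_bottom,
    confidence = NA_real_, stringsAsFactors = FALSE)

  all_boxes <- do.call(rbind, c(list(gel_box), boxes))
  truth <- new("GroundTruth", boxes = new("BandBoxSet", boxes = all_boxes),
               true_fractions = gt_frac, pi_map = geom$pi_map,
               lane_centers = geom$lane_centers)
  names(band_signal) <- vapply(config@bands, function(b) b@class_label, character(1))
  list(image = GelImage(pix), truth = truth, clean_signal = band_signal)
}

#' Generate a batch of annotated gels on disk
#'
#' Writes \code{n_images} PNG images with YOLO-txt annotation files and a
#' manifest CSV listing the true per-class fractions. Per-image seeds are
#' derived deterministically from \code{config@seed}, so a re-run reproduces
#' the batch byte for byte.
#'
#' @param config a \linkS4class{GelSimConfig}.
#' @param n_images number of images to generate.
#' @param out_dir output directory (created if missing).
#' @return Invisibly, the manifest data.frame (columns image, class,
#'   true_fraction), also written to \code{out_dir/manifest.csv}.
#' @export
generateDataset <- function(config, n_images, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir)
  }
  manifest <- list()
  for (i in seq_len(n_images)) {
    cfg_i <- config
    cfg_i@seed <- config@seed + i - 1
    sim <- generateGel(cfg_i)
    img_name <- sprintf("gel_%03d.png", i)
    writeGelImage(sim$image, file.path(out_dir, img_name))
    writeYoloAnnotations(gtBoxes(sim$truth), imageWidth(sim$image),
                         imageHeight(sim$image),
                         file.path(out_dir, sprintf("gel_%03d.txt", i)))
    fr <- trueFractions(sim$truth)
    manifest[[i]] <- data.frame(image = img_name, class = names(fr),
                                true_fraction = as.numeric(fr),
                                stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, manifest)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
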