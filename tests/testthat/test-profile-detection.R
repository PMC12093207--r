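gaussianProfile <- function(n, centers, heights, sigma) {
  x <- seq_len(n) - 1
  v <- numeric(n)
  for (i in seq_along(centers)) {
    v <- v + heights[[i]] * exp(-((x - centers[[i]])^2) / (2 * sigma[[i]]^2))
  }
  new("IntensityProfile", values = v, axis = "y", origin = 0)
}

test_that("projection reduces images to mean inverted row/column intensities", {
  img <- GelImage(matrix(200, 50, 40))
  expect_equal(profileValues(projectProfile(img, "y")), rep(55, 50))

  m <- matrix(255, 50, 40); m[20, ] <- 0  # one dark row
  prof <- projectProfile(GelImage(m), "y")
  expect_equal(which.max(profileValues(prof)), 20)

  reg <- bandBoxSet("gel", 10, 5, 30, 45)
  prof_r <- projectProfile(GelImage(m), "y", reg)
  expect_equal(length(prof_r), 40)
  expect_equal(profileOrigin(prof_r), 5)
  expect_equal(which.max(profileValues(prof_r)) - 1 + profileOrigin(prof_r), 19)
  expect_error(projectProfile(GelImage(m), "y", bandBoxSet("gel", 10, 5, 50, 45)),
               "outside image")
})

test_that("projection maxima on a simulated lane sit at the band centres", {
  cfg <- smallGelConfig(n_lanes = 1, bands = list(
    bandSpec("HbA1c_A0", pI = 6.3, amplitude = 120, sigma_y = 5, fraction = 0.5),
    bandSpec("HbA2", pI = 7.4, amplitude = 120, sigma_y = 5, fraction = 0.5)))
  sim <- generateGel(cfg)
  prof <- correctBaseline(projectProfile(sim$image, "y"), 51)
  pk <- detectPeaks(prof, 0.2, 10)
  b <- boxFrame(hbOnly(gtBoxes(sim$truth)))
  expect_equal(nrow(pk), 2)
  expect_lte(max(abs(sort(pk$center) - sort((b$y_min + b$y_max) / 2))), 1)
})

test_that("morphological-opening baseline correction behaves as specified", {
  flat <- new("IntensityProfile", values = rep(7, 100), axis = "y", origin = 0)
  expect_equal(profileValues(correctBaseline(flat, 21)), rep(0, 100))

  # linear ramp plus one narrow peak: off-peak residual under 5% of height
  x <- 0:199
  ramp <- 10 + 0.05 * x
  peak <- 40 * exp(-((x - 100)^2) / (2 * 4^2))
  prof <- new("IntensityProfile", values = ramp + peak, axis = "y", origin = 0)
  corr <- profileValues(correctBaseline(prof, 41))
  off <- abs(x - 100) > 25
  expect_lte(max(corr[off]), 0.05 * 40)
  expect_gte(max(corr), 0.9 * 40)

  # idempotence
  once <- correctBaseline(prof, 41)
  twice <- correctBaseline(once, 41)
  expect_equal(profileValues(twice), profileValues(once), tolerance = 1e-9)

  expect_error(correctBaseline(prof, 0), "window")
  expect_error(correctBaseline(prof, 500), "window")
})

test_that("peak detection finds modes, respects prominence and distance", {
  single <- gaussianProfile(200, 80, 10, 5)
  pk <- detectPeaks(single)
  expect_equal(nrow(pk), 1)
  expect_lte(abs(pk$center - 80), 1)
  expect_true(pk$left <= pk$center && pk$center < pk$right)

  two <- gaussianProfile(300, c(100, 200), c(10, 8), c(6, 6))  # 5+ sigma apart
  expect_equal(nrow(detectPeaks(two)), 2)

  zero <- new("IntensityProfile", values = rep(0, 50), axis = "y", origin = 0)
  expect_equal(nrow(detectPeaks(zero)), 0)
})

test_that("peak count is monotone non-increasing in the prominence threshold", {
  set.seed(5)
  for (rep in 1:10) {
    n_pk <- sample(2:6, 1)
    prof <- gaussianProfile(400, sort(sample(30:370, n_pk)),
                            stats::runif(n_pk, 1, 10), rep(4, n_pk))
    counts <- vapply(c(0.01, 0.05, 0.1, 0.25, 0.5, 0.9),
                     function(p) nrow(detectPeaks(prof, p)), numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("lane segmentation finds lanes and degrades gracefully", {
  sim <- generateGel(smallGelConfig(n_lanes = 3, seed = 2))
  seg <- segmentLanes(sim$image, n_lanes_hint = 3)
  expect_false(seg$whole_image)
  expect_equal(nrow(seg$regions), 3)
  centers <- (seg$regions$x_min + seg$regions$x_max) / 2
  expect_lte(max(abs(centers - sim$truth@lane_centers)), 2)

  flat <- GelImage(matrix(180, 100, 100))
  seg2 <- segmentLanes(flat)
  expect_true(seg2$whole_image)
  expect_equal(seg2$regions, data.frame(x_min = 0, x_max = 100))

  sim12 <- generateGel(gelSimConfig(noise_sigma = 2, seed = 3))
  seg12 <- segmentLanes(sim12$image, n_lanes_hint = 12)
  expect_equal(nrow(seg12$regions), 12)
})

test_that("pI calibration interpolates anchors and extrapolates linearly", {
  cal <- calibratePi(data.frame(y = c(0, 100), pI = c(5.2, 7.8)))
  expect_equal(predictPi(cal, 50), 6.5)
  expect_equal(predictPi(cal, c(0, 100)), c(5.2, 7.8))

  cal3 <- calibratePi(data.frame(y = c(0, 50, 100), pI = c(5.2, 6.0, 7.8)))
  expect_equal(predictPi(cal3, 75), 6.9)
  expect_equal(predictPi(cal3, 50), 6.0)
  # linear extrapolation beyond the anchors uses the nearest segment
  expect_equal(predictPi(cal3, 125), 7.8 + 25 * (7.8 - 6.0) / 50)

  expect_error(calibratePi(data.frame(y = 10, pI = 6)), "marker-free")
  expect_error(calibratePi(data.frame(y = c(10, 10), pI = c(6, 7))), "marker-free")

  # monotone y in, monotone pI out
  ys <- seq(-20, 140, by = 7)
  expect_true(all(diff(predictPi(cal3, ys)) > 0))
})

test_that("the profile baseline recovers clean bands with correct classes", {
  sim <- generateGel(smallGelConfig(n_lanes = 1, seed = 4))
  det <- profileDetect(sim$image, profileParams(n_lanes_hint = 1))
  gt <- hbOnly(gtBoxes(sim$truth))
  expect_equal(length(det), 4)
  m <- matchDetections(gt, det, 0.5)
  expect_equal(nrow(m$matches), 4)
  expect_true(all(m$matches$iou >= 0.5))
  # template class assignment matches the simulated migration order
  db <- boxFrame(det)[order(boxFrame(det)$y_min), ]
  expect_equal(db$class_label, c("HbA1c_A0", "HbF", "MetHb", "HbA2"))

  blank <- GelImage(matrix(200, 200, 60))
  expect_length(profileDetect(blank), 0)
})

test_that("marker-calibrated classification matches the ground truth", {
  cfg <- smallGelConfig(n_lanes = 1, seed = 6,
                        bands = c(defaultHbBands(), defaultPiMarkers()))
  sim <- generateGel(cfg)
  mk <- boxFrame(gtBoxes(sim$truth))
  mk <- mk[mk$class_label == "pI_marker", ]
  markers <- data.frame(y = (mk$y_min + mk$y_max) / 2, pI = c(5.40, 7.75))
  det <- profileDetect(sim$image, profileParams(n_lanes_hint = 1, markers = markers))
  db <- boxFrame(det)
  expect_setequal(db$class_label[db$class_label != "pI_marker"], hbClasses())
  expect_equal(sum(db$class_label == "pI_marker"), 2)
  db_hb <- db[db$class_label %in% hbClasses(), ]
  expect_equal(db_hb$class_label[order(db_hb$y_min)],
               c("HbA1c_A0", "HbF", "MetHb", "HbA2"))
})
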