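test_that("gray inversion is the 8-bit involution", {
  img <- GelImage(matrix(c(0, 255, 128, 7), 2, 2))
  inv <- invertGray(img)
  expect_equal(gelPixels(inv), matrix(c(255, 0, 127, 248), 2, 2))
  expect_equal(gelPixels(invertGray(inv)), gelPixels(img))
})

test_that("the background threshold is the mean inverted inter-band intensity", {
  m <- matrix(10, 40, 40)
  bands <- bandBoxSet("HbA2", 5, 10, 35, 20)
  m[11:20, 6:35] <- 200
  expect_equal(as.numeric(estimateBackgroundThreshold(m, bands)), 10)
  # mean shift: adding a constant moves the threshold by exactly that much
  expect_equal(as.numeric(estimateBackgroundThreshold(m + 5, bands)), 15)

  # checkerboard background, no exclusions: brute-force pixel mean
  chk <- matrix(0, 20, 20)
  chk[(row(chk) + col(chk)) %% 2 == 0] <- 20
  expect_equal(as.numeric(estimateBackgroundThreshold(chk, bandBoxSet())),
               mean(chk))
  expect_equal(as.numeric(estimateBackgroundThreshold(chk, bandBoxSet())), 10)

  # gel box restricts the region; fully covered background errors
  gel <- bandBoxSet("gel", 0, 0, 40, 40)
  both <- concatBoxes(gel, bands)
  thr <- estimateBackgroundThreshold(m, both)
  expect_equal(attr(thr, "background_mode"), "gel-box")
  cover <- concatBoxes(gel, bandBoxSet("HbA2", 0, 0, 40, 40))
  expect_error(estimateBackgroundThreshold(m, cover), "whole-image")
})

test_that("background subtraction clamps at zero", {
  m <- matrix(10, 5, 5)
  expect_equal(subtractBackground(m, 10), matrix(0, 5, 5))
  expect_equal(subtractBackground(m, 0), m)
  expect_equal(subtractBackground(matrix(8, 1, 1), 10), matrix(0, 1, 1))
  expect_error(subtractBackground(m, -1), "non-negative")
})

test_that("band integration sums box pixels with unique overlap assignment", {
  sig <- matrix(4, 30, 30)
  one <- bandBoxSet("HbA2", 10, 10, 15, 15)
  expect_equal(integrateBands(sig, one), c(HbA2 = 100))

  # two 5x5 boxes overlapping in a 2x5 strip: every pixel counted once and
  # the strip goes to the box with the nearer vertical centre
  a <- bandBoxSet("HbF", 10, 10, 15, 15)
  b <- bandBoxSet("HbA2", 10, 13, 15, 18)
  got <- integrateBands(sig, concatBoxes(a, b))
  expect_equal(sum(got), 4 * (25 + 25 - 10))
  # brute-force oracle: pixel rows 13:14 (0-based) are closer to a's centre
  # (12.5) for row 13 ... assign per |row_centre - box_centre|, tie to upper
  oracle <- c(HbF = 0, HbA2 = 0)
  for (y in 10:17) {
    for (x in 10:14) {
      in_a <- y >= 10 && y < 15; in_b <- y >= 13 && y < 18
      owner <- if (in_a && in_b) {
        da <- abs(y + 0.5 - 12.5); db <- abs(y + 0.5 - 15.5)
        if (da < db || (da == db && 12.5 < 15.5)) "HbF" else "HbA2"
      } else if (in_a) "HbF" else "HbA2"
      oracle[owner] <- oracle[owner] + 4
    }
  }
  expect_equal(got[names(oracle)], oracle)

  # a band fully covered by a bubble integrates to zero
  bubble <- bandBoxSet("bubble", 9, 9, 16, 16)
  expect_equal(unname(integrateBands(sig, one, bubble)), 0)
  expect_error(integrateBands(sig, bandBoxSet("HbA2", 10, 10, 40, 15)),
               "outside image")
})

test_that("fractions normalise intensities and flag the all-zero case", {
  expect_equal(as.numeric(computeFractions(c(A = 300, B = 100))), c(0.75, 0.25),
               ignore_attr = TRUE)
  expect_equal(as.numeric(computeFractions(c(A = 7))), 1, ignore_attr = TRUE)
  expect_equal(as.numeric(computeFractions(c(A = 1, B = 1, C = 2))),
               c(0.25, 0.25, 0.5), ignore_attr = TRUE)
  z <- computeFractions(c(A = 0, B = 0))
  expect_false(attr(z, "determined"))
  expect_true(all(is.na(z)))
  expect_error(computeFractions(c(A = -1)), "non-negative")
})

test_that("the Hb A2 rule is inclusive at 3.5%", {
  expect_equal(classifyHbA2(c(HbA1c_A0 = 0.964, HbA2 = 0.036)), "abnormal")
  expect_equal(classifyHbA2(c(HbA1c_A0 = 0.966, HbA2 = 0.034)), "normal")
  expect_equal(classifyHbA2(c(HbA1c_A0 = 0.965, HbA2 = 0.035)), "abnormal")
  expect_equal(classifyHbA2(c(HbA1c_A0 = 1)), "undetermined")
})

test_that("quantification recovers simulated contents from GT boxes", {
  for (seed in 1:3) {
    sim <- generateGel(smallGelConfig(noise_sigma = 2, seed = seed))
    q <- quantifyBands(sim$image, gtBoxes(sim$truth))
    tf <- trueFractions(sim$truth)
    expect_equal(sum(bandFractions(q)), 1, tolerance = 1e-9)
    expect_lte(max(abs(bandFractions(q)[names(tf)] - tf)), 0.01)
    expect_equal(hba2Status(q), "abnormal")  # simulated Hb A2 share is 5%
    expect_equal(q@background_mode, "gel-box")
  }
})

test_that("uniform illumination offsets cancel through the threshold", {
  sim <- generateGel(smallGelConfig())
  inv <- 255 - gelPixels(sim$image)  # pre-quantization signal chain
  boxes <- gtBoxes(sim$truth)
  sp <- boxFrame(boxes)
  quantFromInverted <- function(m) {
    thr <- estimateBackgroundThreshold(m, boxes)
    sig <- subtractBackground(m, as.numeric(thr))
    computeFractions(integrateBands(sig, sp[sp$class_label %in% hbClasses(), ],
                                    sp[sp$class_label == "bubble", ]))
  }
  f0 <- quantFromInverted(inv)
  f_off <- quantFromInverted(inv + 20)
  expect_lte(max(abs(f_off - f0)), 1e-6)
})

test_that("positive scaling of the subtracted signal leaves fractions unchanged", {
  sim <- generateGel(smallGelConfig(noise_sigma = 1, seed = 9))
  inv <- 255 - gelPixels(sim$image)
  boxes <- gtBoxes(sim$truth)
  sp <- boxFrame(boxes)
  thr <- as.numeric(estimateBackgroundThreshold(inv, boxes))
  sig <- subtractBackground(inv, thr)
  hb <- sp[sp$class_label %in% hbClasses(), ]
  f1 <- computeFractions(integrateBands(sig, hb))
  f3 <- computeFractions(integrateBands(3.7 * sig, hb))
  expect_equal(as.numeric(f1), as.numeric(f3), tolerance = 1e-12)
})

test_that("bubbles overlapping a band are excluded from its integral", {
  cfg <- smallGelConfig(noise_sigma = 1, bubble_count = 3, seed = 12)
  sim <- generateGel(cfg)
  q <- quantifyBands(sim$image, gtBoxes(sim$truth))
  tf <- trueFractions(sim$truth)
  expect_lte(max(abs(bandFractions(q)[names(tf)] - tf)), 0.02)
})

test_that("quantification without Hb boxes is a flagged undetermined result", {
  sim <- generateGel(smallGelConfig())
  q <- quantifyBands(sim$image, bandBoxSet())
  expect_false(q@determined)
  expect_equal(hba2Status(q), "undetermined")
  expect_length(bandFractions(q), 0)
})

test_that("pI marker boxes stay out of the content denominator", {
  cfg <- smallGelConfig(bands = c(defaultHbBands(), defaultPiMarkers()))
  sim <- generateGel(cfg)
  q <- quantifyBands(sim$image, gtBoxes(sim$truth))
  expect_setequal(names(bandFractions(q)), hbClasses())
  expect_equal(sum(bandFractions(q)), 1, tolerance = 1e-9)
})
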