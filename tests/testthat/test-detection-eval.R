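test_that("IoU follows the half-open area convention", {
  a <- c(0, 0, 10, 10)
  expect_equal(boxIoU(a, a), 1)
  expect_equal(boxIoU(a, c(20, 20, 30, 30)), 0)
  expect_equal(boxIoU(a, c(5, 0, 15, 10)), 50 / 150)
  expect_equal(boxIoU(bandBoxSet("HbA2", 0, 0, 10, 10),
                      bandBoxSet("HbA2", 5, 0, 15, 10)), 1 / 3)
})

test_that("CIoU adds centre-distance and aspect penalties to IoU", {
  a <- c(0, 0, 10, 10)
  same <- boxCIoU(a, a)
  expect_equal(same$ciou, 1)
  expect_equal(same$loss, 0)

  far <- boxCIoU(a, c(100, 100, 110, 110))  # same shape, far apart
  expect_lt(far$ciou, 0)

  # concentric, same aspect ratio: rho = 0 and v = 0, so CIoU equals IoU
  inner <- c(2.5, 2.5, 7.5, 7.5)
  expect_equal(boxCIoU(a, inner)$ciou, boxIoU(a, inner))
  expect_equal(boxIoU(a, inner), 25 / 100)

  expect_error(boxCIoU(a, c(0, 0, 0, 10)), "degenerate")
})

test_that("the loss combiner weights components 1 : 7.5 : 1.5", {
  expect_equal(combineLoss(0, 0, 0), 0)
  expect_equal(combineLoss(1, 1, 1), 10)
  expect_equal(combineLoss(0.4, 0.2, 0.1), 2.05)
  # linearity: exact finite-difference sensitivities
  h <- 0.25
  expect_identical((combineLoss(1, 1 + h, 1) - combineLoss(1, 1, 1)) / h, 7.5)
  expect_identical((combineLoss(1, 1, 1 + h) - combineLoss(1, 1, 1)) / h, 1.5)
  expect_identical((combineLoss(1 + h, 1, 1) - combineLoss(1, 1, 1)) / h, 1)
  expect_error(combineLoss(-1, 0, 0))
})

test_that("matching is greedy, confidence-ordered and one-to-one", {
  gt <- bandBoxSet(c("HbA2", "HbF"), c(0, 50), c(0, 0), c(10, 60), c(10, 10))
  perfect <- bandBoxSet(c("HbA2", "HbF"), c(0, 50), c(0, 0), c(10, 60),
                        c(10, 10), c(0.9, 0.8))
  m <- matchDetections(gt, perfect)
  expect_equal(nrow(m$matches), 2)
  expect_length(m$unmatched_gt, 0)
  expect_length(m$unmatched_pred, 0)

  # two predictions on one GT: only the more confident one matches
  two <- bandBoxSet(c("HbA2", "HbA2"), c(0, 1), c(0, 0), c(10, 11), c(10, 10),
                    c(0.6, 0.95))
  m2 <- matchDetections(gt, two)
  expect_equal(m2$matches$pred_idx, 2)  # the 0.95 one
  expect_equal(m2$unmatched_pred, 1)
  expect_equal(m2$unmatched_gt, 2)

  # class labels partition the matching
  wrong <- bandBoxSet("HbF", 0, 0, 10, 10, 0.9)
  m3 <- matchDetections(gt, wrong)
  expect_equal(nrow(m3$matches), 0)
})

test_that("AP reproduces hand-enumerated PR areas", {
  gt <- bandBoxSet("HbA2", 0, 0, 10, 10)
  # perfect single detection
  expect_equal(averagePrecision(gt, bandBoxSet("HbA2", 0, 0, 10, 10, 0.9),
                                "HbA2")$ap, 1)
  # one matching (IoU 0.6) then one non-matching (IoU ~0.2) prediction:
  # PR points (1, 1) then (1, 0.5) -> envelope area 1
  preds <- bandBoxSet(c("HbA2", "HbA2"), c(0, 8), c(0, 0), c(10, 18),
                      c(8, 10), c(0.9, 0.8))
  expect_equal(boxIoU(gt[1], preds[1]), 80 / 100)
  res <- averagePrecision(gt, preds, "HbA2")
  expect_equal(res$ap, 1)
  expect_equal(res$pr$recall, c(1, 1))
  expect_equal(res$pr$precision, c(1, 0.5))
  # no predictions
  expect_equal(averagePrecision(gt, bandBoxSet(), "HbA2")$ap, 0)
  expect_error(averagePrecision(bandBoxSet(), preds, "HbA2"), "no ground truth")
})

test_that("AP is invariant under monotone confidence transforms", {
  set.seed(21)
  inst <- randomDetectionInstance()
  pred <- inst$pred
  ap1 <- averagePrecision(asBoxSet(inst$gt), asBoxSet(pred), "HbA2")$ap
  pred$confidence <- plogis(5 * pred$confidence - 2)  # strictly monotone
  ap2 <- averagePrecision(asBoxSet(inst$gt), asBoxSet(pred), "HbA2")$ap
  expect_equal(ap1, ap2)
})

test_that("greedy matcher and AP agree exactly with brute-force oracles", {
  set.seed(77)
  for (i in 1:60) {
    inst <- randomDetectionInstance()
    if (!nrow(inst$pred)) next
    gt <- asBoxSet(inst$gt); pred <- asBoxSet(inst$pred)
    # per-class TP/FP labels against the independently coded greedy rule
    for (cl in unique(inst$gt$class_label)) {
      p_cl <- inst$pred[inst$pred$class_label == cl, , drop = FALSE]
      if (!nrow(p_cl)) next
      want_tp <- oracleGreedy(inst$gt[inst$gt$class_label == cl, , drop = FALSE],
                              p_cl, 0.5)$tp
      m <- matchDetections(gt, pred, 0.5)
      idx_cl <- which(boxFrame(pred)$class_label == cl)
      got_tp <- idx_cl %in% m$matches$pred_idx
      expect_identical(got_tp, want_tp)
    }
    ev <- evaluateDetections(gt, pred, 0.5)
    expect_identical(map50(ev), oracleMap50(inst$gt, inst$pred, 0.5))
  }
})

test_that("mAP50 is 1 on perfect detections and 0 on empty predictions", {
  sim <- generateGel(smallGelConfig())
  gt <- hbOnly(gtBoxes(sim$truth))
  b <- boxFrame(gt); b$confidence <- seq(0.9, 0.5, length.out = nrow(b))
  perfect <- new("BandBoxSet", boxes = b)
  ev <- evaluateDetections(gt, perfect)
  expect_identical(map50(ev), 1)
  expect_true(all(perClassAP(ev) == 1))

  ev0 <- evaluateDetections(gt, bandBoxSet())
  expect_identical(map50(ev0), 0)
  expect_error(evaluateDetections(bandBoxSet(), perfect), "empty ground truth")

  # one class perfect, one with no predictions: the mean is 0.5
  gt2 <- bandBoxSet(c("HbA2", "HbF"), c(0, 50), c(0, 0), c(10, 60), c(10, 10))
  pred2 <- bandBoxSet("HbA2", 0, 0, 10, 10, 0.9)
  expect_equal(map50(evaluateDetections(gt2, pred2)), 0.5)
})

test_that("the confusion matrix routes matches, misses and false alarms", {
  gt <- bandBoxSet(c("HbA2", "MetHb"), c(0, 50), c(0, 0), c(10, 60), c(10, 10))
  perfect <- bandBoxSet(c("HbA2", "MetHb"), c(0, 50), c(0, 0), c(10, 60),
                        c(10, 10), c(0.9, 0.8))
  M <- detectionConfusion(gt, perfect)
  expect_equal(M["HbA2", "HbA2"], 1L)
  expect_equal(M["MetHb", "MetHb"], 1L)
  expect_equal(sum(M), 2L)

  # a missed GT lands in the background column
  M2 <- detectionConfusion(gt, bandBoxSet("HbA2", 0, 0, 10, 10, 0.9))
  expect_equal(M2["MetHb", "background"], 1L)

  # cross-class overlap: the matched pair increments the off-diagonal cell
  wrong <- bandBoxSet("HbF", 0, 0, 10, 10, 0.9)
  M3 <- detectionConfusion(gt, wrong)
  expect_equal(M3["HbA2", "HbF"], 1L)
  expect_equal(M3["MetHb", "background"], 1L)
  expect_equal(M3["background", "HbF"], 0L)

  # predictions under the confidence threshold are dropped
  weak <- bandBoxSet("HbA2", 0, 0, 10, 10, 0.1)
  M4 <- detectionConfusion(gt, weak, conf_threshold = 0.25)
  expect_equal(sum(M4[, setdiff(colnames(M4), "background")]), 0L)
})
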