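# Shared fixtures and independent oracles for the suite.

# A small, fast gel: 3 lanes, 4 Hb bands at the default 0.80/0.05/0.10/0.05
# contents. Everything downstream of the simulator is tested against it.
smallGelConfig <- function(noise_sigma = 0, seed = 1L, n_lanes = 3,
                           bands = defaultHbBands(), ...) {
  gelSimConfig(image_width = 60 * n_lanes, image_height = 480,
               n_lanes = n_lanes, lane_width = 30, bands = bands,
               noise_sigma = noise_sigma, seed = seed, ...)
}

hbOnly <- function(boxset) {
  boxset[which(boxFrame(boxset)$class_label %in% hbClasses())]
}

# --- independent detection-metric oracles (pixel enumeration + threshold
# enumeration); deliberately naive, shared with scripts/acceptance.R through
# duplication so neither depends on package internals ---

oracleIoU <- function(a, b) {
  ax <- seq(a[[1]], a[[3]] - 1); ay <- seq(a[[2]], a[[4]] - 1)
  bx <- seq(b[[1]], b[[3]] - 1); by <- seq(b[[2]], b[[4]] - 1)
  inter <- length(intersect(ax, bx)) * length(intersect(ay, by))
  inter / (length(ax) * length(ay) + length(bx) * length(by) - inter)
}

# greedy rule re-stated from scratch: descending confidence, best IoU >= thr,
# ties to the lower GT index, one-to-one
oracleGreedy <- function(gt_df, pred_df, iou_threshold) {
  taken <- rep(FALSE, nrow(gt_df))
  tp <- rep(FALSE, nrow(pred_df))
  for (pi in order(-pred_df$confidence)) {
    best <- 0L; best_iou <- -1
    for (gi in seq_len(nrow(gt_df))) {
      if (taken[[gi]]) next
      iou <- oracleIoU(as.numeric(pred_df[pi, c("x_min", "y_min", "x_max", "y_max")]),
                       as.numeric(gt_df[gi, c("x_min", "y_min", "x_max", "y_max")]))
      if (iou >= iou_threshold && iou > best_iou + 1e-12) {
        best <- gi; best_iou <- iou
      }
    }
    if (best > 0L) { taken[[best]] <- TRUE; tp[[pi]] <- TRUE }
  }
  list(tp = tp, gt_matched = taken)
}

# AP by enumerating every confidence threshold, computing one PR point per
# threshold, and integrating the precision envelope
oracleAP <- function(gt_df, pred_df, class, iou_threshold = 0.5) {
  g <- gt_df[gt_df$class_label == class, , drop = FALSE]
  p <- pred_df[pred_df$class_label == class, , drop = FALSE]
  if (!nrow(g)) stop("no GT for class")
  if (!nrow(p)) return(0)
  pts <- lapply(sort(unique(p$confidence), decreasing = TRUE), function(t) {
    sub <- p[p$confidence >= t, , drop = FALSE]
    tp <- sum(oracleGreedy(g, sub, iou_threshold)$tp)
    c(recall = tp / nrow(g), precision = tp / nrow(sub))
  })
  pts <- do.call(rbind, pts)
  env <- rev(cummax(rev(pts[, "precision"])))
  sum(diff(c(0, pts[, "recall"])) * env)
}

oracleMap50 <- function(gt_df, pred_df, iou_threshold = 0.5) {
  cls <- unique(gt_df$class_label)
  mean(vapply(cls, function(cl) oracleAP(gt_df, pred_df, cl, iou_threshold),
              numeric(1)))
}

# random detection instance: <= max_boxes GT boxes per class and a noisy
# prediction set (jittered copies, drops, spurious boxes), distinct
# confidences so rank order is unambiguous
randomDetectionInstance <- function(classes = c("HbA1c_A0", "HbA2"),
                                    max_boxes = 6, size = 100) {
  gt <- list(); pred <- list()
  for (cl in classes) {
    n <- sample.int(max_boxes, 1)
    for (i in seq_len(n)) {
      x0 <- sample.int(size - 20, 1); y0 <- sample.int(size - 20, 1)
      w <- sample(5:15, 1); h <- sample(5:15, 1)
      gt[[length(gt) + 1L]] <- data.frame(class_label = cl, x_min = x0, y_min = y0,
                                          x_max = x0 + w, y_max = y0 + h,
                                          confidence = NA_real_)
      if (stats::runif(1) < 0.85) {  # jittered detection
        dx <- sample(-3:3, 1); dy <- sample(-3:3, 1)
        pred[[length(pred) + 1L]] <- data.frame(class_label = cl,
          x_min = x0 + dx, y_min = y0 + dy, x_max = x0 + w + dx,
          y_max = y0 + h + dy, confidence = stats::runif(1))
      }
    }
    if (stats::runif(1) < 0.5) {  # spurious detection
      x0 <- sample.int(size - 20, 1); y0 <- sample.int(size - 20, 1)
      pred[[length(pred) + 1L]] <- data.frame(class_label = cl, x_min = x0,
        y_min = y0, x_max = x0 + 8, y_max = y0 + 8, confidence = stats::runif(1))
    }
  }
  list(gt = do.call(rbind, gt),
       pred = if (length(pred)) do.call(rbind, pred) else
         data.frame(class_label = character(0), x_min = numeric(0),
                    y_min = numeric(0), x_max = numeric(0), y_max = numeric(0),
                    confidence = numeric(0)))
}

asBoxSet <- function(df) {
  if (!nrow(df)) return(bandBoxSet())
  bandBoxSet(df$class_label, df$x_min, df$y_min, df$x_max, df$y_max,
             df$confidence)
}
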