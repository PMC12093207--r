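#' @include AllClasses.R AllGenerics.R
NULL

.asBoxMatrix <- function(x) {
  if (is(x, "BandBoxSet")) {
    b <- boxFrame(x)
    cbind(b$x_min, b$y_min, b$x_max, b$y_max)
  } else if (is.numeric(x) && length(x) == 4L) {
    matrix(x, nrow = 1)
  } else {
    stop("expected a BandBoxSet or a numeric (x_min, y_min, x_max, y_max)")
  }
}

.iou1 <- function(a, b) {
  ix <- max(0, min(a[[3]], b[[3]]) - max(a[[1]], b[[1]]))
  iy <- max(0, min(a[[4]], b[[4]]) - max(a[[2]], b[[2]]))
  inter <- ix * iy
  union <- (a[[3]] - a[[1]]) * (a[[4]] - a[[2]]) +
    (b[[3]] - b[[1]]) * (b[[4]] - b[[2]]) - inter
  inter / union
}

#' Intersection over union of two boxes
#'
#' Areas use the half-open pixel convention; disjoint boxes give 0.
#'
#' @param a,b numeric (x_min, y_min, x_max, y_max) or single-box
#'   \linkS4class{BandBoxSet}s.
#' @return IoU in [0, 1].
#' @export
boxIoU <- function(a, b) {
  .iou1(as.numeric(.asBoxMatrix(a)[1, ]), as.numeric(.asBoxMatrix(b)[1, ]))
}

#' Complete IoU (CIoU) of two boxes
#'
#' IoU minus a normalised centre-distance penalty and an aspect-ratio
#' penalty: \code{CIoU = IoU - rho^2/c^2 - alpha * v}, with rho the distance
#' between box centres, c the diagonal of the smallest enclosing box,
#' \code{v = (4/pi^2) (atan(w_a/h_a) - atan(w_b/h_b))^2} and
#' \code{alpha = v / ((1 - IoU) + v)}. The associated loss is 1 - CIoU.
#'
#' @param a,b boxes as in [boxIoU()].
#' @return List with elements \code{ciou} and \code{loss}.
#' @export
boxCIoU <- function(a, b) {
  a <- as.numeric(.asBoxMatrix(a)[1, ]); b <- as.numeric(.asBoxMatrix(b)[1, ])
  wa <- a[[3]] - a[[1]]; ha <- a[[4]] - a[[2]]
  wb <- b[[3]] - b[[1]]; hb <- b[[4]] - b[[2]]
  if (wa <= 0 || ha <= 0 || wb <= 0 || hb <= 0) stop("degenerate zero-area box")
  iou <- .iou1(a, b)
  rho2 <- ((a[[1]] + a[[3]]) / 2 - (b[[1]] + b[[3]]) / 2)^2 +
    ((a[[2]] + a[[4]]) / 2 - (b[[2]] + b[[4]]) / 2)^2
  cw <- max(a[[3]], b[[3]]) - min(a[[1]], b[[1]])
  ch <- max(a[[4]], b[[4]]) - min(a[[2]], b[[2]])
  c2 <- cw^2 + ch^2
  v <- (4 / pi^2) * (atan(wa / ha) - atan(wb / hb))^2
  alpha <- if (v == 0) 0 else v / ((1 - iou) + v)
  ciou <- iou - rho2 / c2 - alpha * v
  list(ciou = ciou, loss = 1 - ciou)
}

#' Combine detector loss components
#'
#' The total detection loss is the weighted sum of its classification and
#' localisation components: \code{BCE + 7.5 * CIoU loss + 1.5 * DFL}. The
#' component values are taken as given scalars; only the combination is
#' computed here.
#'
#' @param bce binary cross-entropy classification loss.
#' @param ciou_loss complete-IoU localisation loss.
#' @param dfl distribution focal loss.
#' @return The combined loss.
#' @export
combineLoss <- function(bce, ciou_loss, dfl) {
  stopifnot(is.finite(bce), is.finite(ciou_loss), is.finite(dfl),
            bce >= 0, ciou_loss >= 0, dfl >= 0)
  bce + 7.5 * ciou_loss + 1.5 * dfl
}

# Greedy one-to-one matching: predictions in descending confidence (ties:
# original order), each taking the unmatched GT with highest IoU >= the
# threshold; IoU ties break to the lower GT index.
.greedyMatch <- function(gt_mat, pred_mat, pred_conf, iou_threshold) {
  n_gt <- nrow(gt_mat); n_pred <- nrow(pred_mat)
  gt_taken <- rep(FALSE, n_gt)
  match_gt <- rep(NA_integer_, n_pred)
  match_iou <- rep(NA_real_, n_pred)
  ord <- order(-pred_conf)
  for (pi in ord) {
    best <- NA_integer_; best_iou <- -1
    for (gi in seq_len(n_gt)) {
      if (gt_taken[[gi]]) next
      iou <- .iou1(pred_mat[pi, ], gt_mat[gi, ])
      if (iou >= iou_threshold && iou > best_iou + 1e-12) {
        best <- gi; best_iou <- iou
      }
    }
    if (!is.na(best)) {
      gt_taken[[best]] <- TRUE
      match_gt[[pi]] <- best
      match_iou[[pi]] <- best_iou
    }
  }
  list(match_gt = match_gt, match_iou = match_iou, gt_taken = gt_taken)
}

#' Match detections to ground truth
#'
#' Greedy one-to-one matching per class: predictions in descending
#' confidence take the highest-IoU unmatched ground-truth box of the same
#' class with IoU at least \code{iou_threshold}; IoU ties break to the lower
#' GT index.
#'
#' @param gt ground-truth \linkS4class{BandBoxSet}.
#' @param pred predicted \linkS4class{BandBoxSet} with confidences.
#' @param iou_threshold match threshold (default 0.5).
#' @return List with \code{matches} (data.frame pred_idx, gt_idx, iou, in
#'   original row indices), \code{unmatched_gt} and \code{unmatched_pred}.
#' @export
matchDetections <- function(gt, pred, iou_threshold = 0.5) {
  gb <- boxFrame(gt); pb <- boxFrame(pred)
  matches <- list(); un_gt <- integer(0); un_pred <- integer(0)
  for (cl in union(gb$class_label, pb$class_label)) {
    gi <- which(gb$class_label == cl); pi <- which(pb$class_label == cl)
    if (!length(pi)) { un_gt <- c(un_gt, gi); next }
    if (!length(gi)) { un_pred <- c(un_pred, pi); next }
    m <- .greedyMatch(.asBoxMatrix(gt[gi]), .asBoxMatrix(pred[pi]),
                      pb$confidence[pi], iou_threshold)
    hit <- which(!is.na(m$match_gt))
    if (length(hit)) {
      matches[[length(matches) + 1L]] <- data.frame(
        pred_idx = pi[hit], gt_idx = gi[m$match_gt[hit]], iou = m$match_iou[hit])
    }
    un_gt <- c(un_gt, gi[!m$gt_taken])
    un_pred <- c(un_pred, pi[is.na(m$match_gt)])
  }
  list(matches = if (length(matches)) do.call(rbind, matches) else
         data.frame(pred_idx = integer(0), gt_idx = integer(0), iou = numeric(0)),
       unmatched_gt = sort(un_gt), unmatched_pred = sort(un_pred))
}

#' Average precision for one class
#'
#' Confidence-ranked precision-recall with all-point interpolation: the
#' area under the precision envelope
#' \code{p_env(r) = max(precision at recall >= r)}.
#'
#' @param gt,pred \linkS4class{BandBoxSet}s (all classes; filtered here).
#' @param class the class to evaluate; must have at least one GT box.
#' @param iou_threshold match threshold (default 0.5, i.e. AP50).
#' @return List with \code{ap} and \code{pr} (data.frame recall, precision,
#'   confidence, one row per ranked prediction).
#' @export
averagePrecision <- function(gt, pred, class, iou_threshold = 0.5) {
  gb <- boxFrame(gt); pb <- boxFrame(pred)
  gi <- which(gb$class_label == class)
  pi <- which(pb$class_label == class)
  if (!length(gi)) stop("AP undefined: no ground truth of class ", class)
  empty_pr <- data.frame(recall = numeric(0), precision = numeric(0),
                         confidence = numeric(0))
  if (!length(pi)) return(list(ap = 0, pr = empty_pr))
  m <- .greedyMatch(.asBoxMatrix(gt[gi]), .asBoxMatrix(pred[pi]),
                    pb$confidence[pi], iou_threshold)
  ord <- order(-pb$confidence[pi])
  tp <- !is.na(m$match_gt)[ord]
  cum_tp <- cumsum(tp)
  cum_fp <- cumsum(!tp)
  recall <- cum_tp / length(gi)
  precision <- cum_tp / (cum_tp + cum_fp)
  env <- rev(cummax(rev(precision)))
  ap <- sum(diff(c(0, recall)) * env)
  list(ap = ap, pr = data.frame(recall = recall, precision = precision,
                                confidence = pb$confidence[pi][ord]))
}

#' Confusion matrix over classes plus background
#'
#' Predictions below \code{conf_threshold} are dropped; the rest are matched
#' one-to-one to ground truth greedily by descending confidence with IoU at
#' least \code{iou_threshold}, irrespective of class. A matched pair
#' increments (gt_class, pred_class); an unmatched GT box counts against
#' background in its row, an unmatched prediction against background in its
#' column.
#'
#' @param gt,pred \linkS4class{BandBoxSet}s.
#' @param iou_threshold match threshold (default 0.5).
#' @param conf_threshold minimum confidence for a prediction to count
#'   (default 0.25).
#' @param classes class vocabulary ordering the matrix.
#' @return Integer matrix, rows = ground truth, columns = prediction.
#' @export
detectionConfusion <- function(gt, pred, iou_threshold = 0.5,
                               conf_threshold = 0.25, classes = gelClasses()) {
  gb <- boxFrame(gt)
  pred <- pred[which(boxFrame(pred)$confidence >= conf_threshold)]
  pb <- boxFrame(pred)
  labs <- c(classes, "background")
  M <- matrix(0L, length(labs), length(labs), dimnames = list(gt = labs, pred = labs))
  if (nrow(pb)) {
    m <- .greedyMatch(.asBoxMatrix(gt), .asBoxMatrix(pred), pb$confidence,
                      iou_threshold)
  } else {
    m <- list(match_gt = integer(0), gt_taken = rep(FALSE, nrow(gb)))
  }
  for (pi in seq_len(nrow(pb))) {
    if (is.na(m$match_gt[[pi]])) {
      M["background", pb$class_label[[pi]]] <- M["background", pb$class_label[[pi]]] + 1L
    } else {
      g <- gb$class_label[[m$match_gt[[pi]]]]
      M[g, pb$class_label[[pi]]] <- M[g, pb$class_label[[pi]]] + 1L
    }
  }
  for (gi in which(!m$gt_taken)) {
    M[gb$class_label[[gi]], "background"] <- M[gb$class_label[[gi]], "background"] + 1L
  }
  M
}

#' Evaluate detections: per-class AP, mAP50 and confusion matrix
#'
#' AP is computed per class present in the ground truth (classes without GT
#' instances are excluded from the mean) at the given IoU threshold; mAP50
#' is their mean at IoU 0.5.
#'
#' @param gt ground-truth \linkS4class{BandBoxSet} (non-empty).
#' @param pred predicted \linkS4class{BandBoxSet} with confidences.
#' @param iou_threshold match threshold (default 0.5).
#' @param conf_threshold confidence cutoff for the confusion matrix only;
#'   PR curves always use all predictions.
#' @return An \linkS4class{EvalResult}.
#' @export
evaluateDetections <- function(gt, pred, iou_threshold = 0.5,
                               conf_threshold = 0.25) {
  gb <- boxFrame(gt)
  if (!nrow(gb)) stop("empty ground truth")
  classes <- intersect(gelClasses(), unique(gb$class_label))
  aps <- setNames(numeric(length(classes)), classes)
  curves <- setNames(vector("list", length(classes)), classes)
  for (cl in classes) {
    res <- averagePrecision(gt, pred, cl, iou_threshold)
    aps[[cl]] <- res$ap
    curves[[cl]] <- res$pr
  }
  new("EvalResult", per_class_ap = aps, map50 = mean(aps), pr_curves = curves,
      confusion = detectionConfusion(gt, pred, iou_threshold, conf_threshold))
}
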