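#' Segmentation overlap and boundary metrics
#'
#' Exact pixel-level metrics for binary lesion segmentation: Dice
#' coefficient, confusion matrix, mean intersection-over-union, accuracy,
#' sensitivity, specificity, and the (max-form) Hausdorff distance
#' between mask boundaries, in pixel units.
#'
#' @name metrics
NULL

check_mask_pair <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth))) {
    stop("prediction and ground truth have different shapes")
  }
  if (!all(pred %in% c(0, 1)) || !all(truth %in% c(0, 1))) {
    stop("masks must be binary (values 0/1)")
  }
}

#' Dice similarity coefficient
#'
#' `2|P intersect G| / (|P| + |G|)` between a predicted and a reference
#' binary mask. When both masks are empty there is no region to compare;
#' by declared policy the function returns 1 (perfect agreement on the
#' absence of a lesion) with a warning.
#'
#' @param pred,truth Binary masks (0/1) of identical shape.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice <- function(pred, truth) {
  check_mask_pair(pred, truth)
  sp <- sum(pred)
  sg <- sum(truth)
  if (sp + sg == 0) {
    warning("both masks empty: Dice defined as 1 by policy")
    return(1)
  }
  2 * sum(pred * truth) / (sp + sg)
}

#' Pixel confusion matrix
#'
#' Counts `p[i, j]` of pixels with true class `i` predicted as class `j`.
#' For binary masks the classes are background (0) and lesion (1), so
#' `TP = p[2,2]`, `TN = p[1,1]`, `FP = p[1,2]`, `FN = p[2,1]`.
#'
#' @param pred,truth Integer class masks of identical shape.
#' @param n_classes Number of classes k+1 (default: inferred).
#' @return An `n_classes x n_classes` matrix of counts (rows = truth).
#' @export
confusion_matrix <- function(pred, truth, n_classes = NULL) {
  if (!identical(dim(pred), dim(truth))) {
    stop("prediction and ground truth have different shapes")
  }
  if (is.null(n_classes)) n_classes <- max(pred, truth) + 1
  cm <- table(factor(as.vector(truth), levels = 0:(n_classes - 1)),
              factor(as.vector(pred), levels = 0:(n_classes - 1)))
  m <- matrix(as.numeric(cm), n_classes, n_classes)
  dimnames(m) <- list(truth = 0:(n_classes - 1), pred = 0:(n_classes - 1))
  m
}

#' Mean intersection-over-union
#'
#' Average over classes of `p_ii / (sum_j p_ij + sum_j p_ji - p_ii)`.
#' Classes absent from both prediction and ground truth are excluded
#' from the average (their IoU is undefined).
#'
#' @param cm A confusion matrix from [confusion_matrix()], or a predicted
#'   mask (then `truth` must be given).
#' @param truth Optional ground-truth mask.
#' @return Mean IoU in `[0, 1]`.
#' @export
miou <- function(cm, truth = NULL) {
  if (!is.null(truth)) cm <- confusion_matrix(cm, truth, n_classes = 2)
  if (!is.matrix(cm) || nrow(cm) != ncol(cm) || nrow(cm) < 2) {
    stop("`cm` must be a square confusion matrix with >= 2 classes")
  }
  diagv <- diag(cm)
  denom <- rowSums(cm) + colSums(cm) - diagv
  present <- denom > 0
  if (!any(present)) stop("empty confusion matrix")
  mean(diagv[present] / denom[present])
}

#' Accuracy, sensitivity and specificity from a binary confusion matrix
#'
#' `accuracy = (TP+TN)/total`, `sensitivity = TP/(TP+FN)` (lesion pixels
#' recovered), `specificity = TN/(TN+FP)` (background pixels correctly
#' excluded). Undefined ratios (zero denominator) are returned as `NaN`
#' with a warning, never silently.
#'
#' @param cm A 2x2 confusion matrix ([confusion_matrix()]), or a
#'   predicted binary mask (then `truth` must be given).
#' @param truth Optional ground-truth mask.
#' @return Named numeric vector `c(accuracy, sensitivity, specificity)`.
#' @export
accuracy_sensitivity_specificity <- function(cm, truth = NULL) {
  if (!is.null(truth)) cm <- confusion_matrix(cm, truth, n_classes = 2)
  stopifnot(identical(dim(cm), c(2L, 2L)) || identical(dim(cm), c(2, 2)))
  tn <- cm[1, 1]; fp <- cm[1, 2]; fn <- cm[2, 1]; tp <- cm[2, 2]
  acc <- (tp + tn) / sum(cm)
  sens <- if (tp + fn > 0) tp / (tp + fn) else {
    warning("sensitivity undefined: no positive pixels in ground truth")
    NaN
  }
  spec <- if (tn + fp > 0) tn / (tn + fp) else {
    warning("specificity undefined: no negative pixels in ground truth")
    NaN
  }
  c(accuracy = acc, sensitivity = sens, specificity = spec)
}

#' Boundary pixels of a binary mask
#'
#' Boundary = mask minus its 4-connected erosion: a foreground pixel is
#' on the boundary if any of its 4-neighbours (or the image border)
#' is background.
#'
#' @param mask Binary matrix.
#' @return A two-column matrix of (row, col) coordinates.
#' @export
boundary_points <- function(mask) {
  stopifnot(is.matrix(mask))
  m <- mask > 0
  pad <- matrix(FALSE, nrow(m) + 2, ncol(m) + 2)
  pad[2:(nrow(m) + 1), 2:(ncol(m) + 1)] <- m
  core <- pad[2:(nrow(m) + 1), 2:(ncol(m) + 1)] &
    pad[1:nrow(m), 2:(ncol(m) + 1)] & pad[3:(nrow(m) + 2), 2:(ncol(m) + 1)] &
    pad[2:(nrow(m) + 1), 1:ncol(m)] & pad[2:(nrow(m) + 1), 3:(ncol(m) + 2)]
  which(m & !core, arr.ind = TRUE)
}

#' Hausdorff distance between two point sets
#'
#' Symmetric Hausdorff distance
#' `max(sup_a inf_b d(a,b), sup_b inf_a d(a,b))` with Euclidean `d`, in
#' pixel units. Inputs may be binary masks (boundaries are extracted with
#' [boundary_points()]) or (row, col) coordinate matrices.
#'
#' @param A,B Binary masks or two-column coordinate matrices.
#' @return Nonnegative distance in pixels.
#' @export
hausdorff_distance <- function(A, B) {
  # two-column matrices are coordinate sets; anything else must be a
  # binary mask whose boundary is extracted
  to_points <- function(x) {
    if (!is.matrix(x)) stop("inputs must be matrices")
    if (ncol(x) == 2) return(x)
    if (!all(x %in% c(0, 1))) {
      stop("inputs must be binary masks or (row,col) coordinate matrices")
    }
    boundary_points(x)
  }
  pa <- to_points(A)
  pb <- to_points(B)
  if (nrow(pa) == 0 || nrow(pb) == 0) {
    stop("Hausdorff distance undefined for an empty point set")
  }
  d2 <- outer(pa[, 1], pb[, 1], "-")^2 + outer(pa[, 2], pb[, 2], "-")^2
  max(sqrt(max(apply(d2, 1, min))), sqrt(max(apply(d2, 2, min))))
}

#' Pooled pixelwise ROC curve and AUC
#'
#' Pools all pixels of the given score maps and labels, computes the
#' true/false positive rate at every distinct score threshold, and the
#' area under the curve by trapezoidal integration — equal to the
#' concordance probability with ties counted 1/2.
#'
#' @param scores Numeric vector/array(s) of lesion probabilities in
#'   `[0,1]`, or a list of arrays (pooled).
#' @param labels Binary labels of matching total length, or list.
#' @return A list with `curve` (tibble: threshold, fpr, tpr) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  s <- as.numeric(unlist(scores))
  l <- as.numeric(unlist(labels))
  stopifnot(length(s) == length(l))
  if (!all(l %in% c(0, 1))) stop("labels must be binary")
  np <- sum(l == 1)
  nn <- sum(l == 0)
  if (np == 0 || nn == 0) {
    stop("ROC undefined: need at least one positive and one negative pixel")
  }
  ord <- order(s, decreasing = TRUE)
  s <- s[ord]
  l <- l[ord]
  tp <- cumsum(l)
  fp <- cumsum(1 - l)
  last <- cumsum(rle(s)$lengths) # collapse tied scores
  curve <- tibble::tibble(
    threshold = c(Inf, s[last]),
    fpr = c(0, fp[last] / nn),
    tpr = c(0, tp[last] / np)
  )
  auc <- sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) +
                                  utils::tail(curve$tpr, -1)) / 2)
  structure(list(curve = curve, auc = auc), class = "us_roc")
}

#' @export
print.us_roc <- function(x, ...) {
  cat(sprintf("<us_roc> pooled pixelwise ROC: %d thresholds, AUC = %.4f\n",
              nrow(x$curve) - 1, x$auc))
  invisible(x)
}

#' Evaluate predicted masks against ground truth
#'
#' Computes the full metric battery for a set of predicted/reference
#' binary mask pairs: per-image Dice, IoU (lesion), mIoU (background +
#' lesion), accuracy, sensitivity, specificity, and Hausdorff distance,
#' plus macro (image-averaged) and pooled (all pixels as one image)
#' aggregates. Images where prediction or truth has an empty boundary are
#' excluded from the Hausdorff average and counted in `glance()`.
#'
#' @param pred List of predicted binary masks (or `(H,W,N)` array).
#' @param truth List of reference binary masks (or `(H,W,N)` array).
#' @param ids Optional character ids.
#' @return An object of class `us_eval`: a list with `per_image` (tibble),
#'   `macro`, `pooled` (named vectors), and `hausdorff_excluded` (count).
#' @export
evaluate_masks <- function(pred, truth, ids = NULL) {
  pred <- as_mask_list(pred)
  truth <- as_mask_list(truth)
  stopifnot(length(pred) == length(truth))
  n <- length(pred)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  rows <- vector("list", n)
  pooled_cm <- matrix(0, 2, 2)
  hd_excluded <- 0L
  for (i in seq_len(n)) {
    p <- pred[[i]]
    g <- truth[[i]]
    cm <- confusion_matrix(p, g, n_classes = 2)
    pooled_cm <- pooled_cm + cm
    ass <- suppressWarnings(accuracy_sensitivity_specificity(cm))
    dc <- suppressWarnings(dice(p, g))
    iou_fg <- {
      den <- sum(p) + sum(g) - sum(p * g)
      if (den > 0) sum(p * g) / den else NA_real_
    }
    hd <- if (sum(p) == 0 || sum(g) == 0) {
      hd_excluded <- hd_excluded + 1L
      NA_real_
    } else {
      hausdorff_distance(p, g)
    }
    rows[[i]] <- tibble::tibble(
      id = ids[i], dice = dc, iou = iou_fg, miou = miou(cm),
      accuracy = ass["accuracy"], sensitivity = ass["sensitivity"],
      specificity = ass["specificity"], hausdorff = hd
    )
  }
  per_image <- dplyr::bind_rows(rows)
  macro <- c(
    dice = mean(per_image$dice), miou = mean(per_image$miou),
    accuracy = mean(per_image$accuracy),
    sensitivity = mean(per_image$sensitivity, na.rm = TRUE),
    specificity = mean(per_image$specificity, na.rm = TRUE),
    hausdorff = mean(per_image$hausdorff, na.rm = TRUE)
  )
  pooled_ass <- suppressWarnings(accuracy_sensitivity_specificity(pooled_cm))
  pooled <- c(
    dice = 2 * pooled_cm[2, 2] /
      (2 * pooled_cm[2, 2] + pooled_cm[1, 2] + pooled_cm[2, 1]),
    miou = miou(pooled_cm), pooled_ass
  )
  structure(list(per_image = per_image, macro = macro, pooled = pooled,
                 hausdorff_excluded = hd_excluded),
            class = "us_eval")
}

as_mask_list <- function(x) {
  if (is.list(x)) return(x)
  if (is.array(x) && length(dim(x)) == 3) {
    return(lapply(seq_len(dim(x)[3]), function(i) x[, , i]))
  }
  if (is.matrix(x)) return(list(x))
  stop("expected a list of masks or an (H,W,N) array")
}

#' @export
print.us_eval <- function(x, ...) {
  cat(sprintf("<us_eval> %d images (macro averages):\n",
              nrow(x$per_image)))
  m <- x$macro
  cat(sprintf(
    "  Dice %.4f | mIoU %.4f | acc %.4f | sens %.4f | spec %.4f | HD %.2f px\n",
    m["dice"], m["miou"], m["accuracy"], m["sensitivity"], m["specificity"],
    m["hausdorff"]))
  if (x$hausdorff_excluded > 0) {
    cat(sprintf("  (%d image(s) excluded from Hausdorff average)\n",
                x$hausdorff_excluded))
  }
  invisible(x)
}
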