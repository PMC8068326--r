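#' Evaluation metrics for grading and segmentation
#'
#' One-vs-rest micro- and macro-averaged ROC-AUC for the 3-class grading
#' stage; intersection-over-union (Jaccard), Dice/F1, accuracy, precision,
#' sensitivity and specificity for the epithelium/stroma segmentation
#' stage; Cohen's kappa for inter-rater agreement; and mean +/- sigma
#' aggregation across cross-validation folds.
#'
#' @name metrics
NULL

.check_scores <- function(scores, truth) {
  scores <- as.matrix(scores)
  if (!is.numeric(scores) || !all(is.finite(scores))) {
    stop("scores must be a finite numeric matrix", call. = FALSE)
  }
  truth <- as.integer(truth)
  if (length(truth) != nrow(scores)) {
    stop("one truth label per score row required", call. = FALSE)
  }
  if (any(truth < 1L) || any(truth > ncol(scores))) {
    stop("truth labels must index score columns (1..K)", call. = FALSE)
  }
  list(scores = scores, truth = truth)
}

# ROC points of a binary problem, thresholds swept from +Inf downwards;
# tied scores enter as one diagonal segment. Returns (fpr, tpr) including
# the (0,0) and (1,1) endpoints.
.binary_roc <- function(scores, positive) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  p <- positive[ord]
  last <- which(c(diff(s) != 0, TRUE))  # last index of each tie group
  tp <- cumsum(p)[last]
  fp <- cumsum(!p)[last]
  P <- sum(p)
  N <- sum(!p)
  list(fpr = c(0, fp / N), tpr = c(0, tp / P))
}

.trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' Micro-averaged one-vs-rest ROC-AUC
#'
#' Expands the K-class problem into K one-vs-rest binary problems, pools
#' the true/false positive counts over all of them at every threshold
#' (micro-averaged TPR and FPR), and integrates the pooled ROC curve by
#' the trapezoidal rule. Tied scores contribute diagonal segments, i.e.
#' tied pairs count one half.
#'
#' @param scores `N x K` numeric matrix of per-sample class scores.
#' @param truth Integer vector of true class indices in `1..K`.
#' @return AUC in `[0, 1]`.
#' @export
auc_micro <- function(scores, truth) {
  v <- .check_scores(scores, truth)
  K <- ncol(v$scores)
  pooled_s <- as.vector(v$scores)
  pooled_y <- as.vector(vapply(seq_len(K), function(k) v$truth == k,
                               logical(nrow(v$scores))))
  if (!any(pooled_y) || all(pooled_y)) {
    stop("micro AUC undefined: pooled one-vs-rest labels are degenerate",
         call. = FALSE)
  }
  r <- .binary_roc(pooled_s, pooled_y)
  .trapz(r$fpr, r$tpr)
}

#' Macro-averaged one-vs-rest ROC-AUC
#'
#' Two constructions are provided. `"curve"` builds the per-class
#' one-vs-rest ROC curves and averages them pointwise across classes in
#' the false-positive-rate domain (vertical curve segments are handled by
#' their left/right limits), then integrates the averaged curve; by
#' linearity of integration its area equals the unweighted mean of the
#' per-class AUCs, which `"mean"` computes directly. The two variants
#' therefore agree to numerical precision and serve as mutual
#' cross-checks of the curve construction.
#'
#' @inheritParams auc_micro
#' @param variant `"curve"` (pointwise-averaged TPR/FPR curve, default) or
#'   `"mean"` (average of per-class AUCs).
#' @return AUC in `[0, 1]`.
#' @export
auc_macro <- function(scores, truth, variant = c("curve", "mean")) {
  variant <- match.arg(variant)
  v <- .check_scores(scores, truth)
  K <- ncol(v$scores)
  missing <- setdiff(seq_len(K), unique(v$truth))
  if (length(missing) > 0L) {
    stop("macro AUC undefined: class ", paste(missing, collapse = ", "),
         " absent from truth", call. = FALSE)
  }
  if (K < 2L) stop("macro AUC requires at least two classes", call. = FALSE)
  if (variant == "mean") {
    aucs <- vapply(seq_len(K), function(k) {
      r <- .binary_roc(v$scores[, k], v$truth == k)
      .trapz(r$fpr, r$tpr)
    }, numeric(1))
    return(mean(aucs))
  }
  paths <- lapply(seq_len(K), function(k)
    .binary_roc(v$scores[, k], v$truth == k))
  grid <- sort(unique(unlist(lapply(paths, `[[`, "fpr"))))
  # left/right TPR limits of each piecewise-linear ROC path at every grid x
  lims <- lapply(paths, function(p) .roc_limits(p$fpr, p$tpr, grid))
  yl <- rowMeans(vapply(lims, `[[`, numeric(length(grid)), "left"))
  yr <- rowMeans(vapply(lims, `[[`, numeric(length(grid)), "right"))
  n <- length(grid)
  sum(diff(grid) * (yr[-n] + yl[-1]) / 2)
}

# left/right limits of a monotone piecewise-linear ROC path (px, py) at
# the sorted grid values; vertical segments (repeated px) give distinct
# arrival/departure limits so averaging preserves each path's exact area
.roc_limits <- function(px, py, grid) {
  left <- right <- numeric(length(grid))
  for (i in seq_along(grid)) {
    g <- grid[i]
    at <- which(px == g)
    if (length(at) > 0L) {
      left[i] <- py[at[1L]]
      right[i] <- py[at[length(at)]]
    } else {
      iL <- max(which(px < g))
      left[i] <- right[i] <- py[iL] +
        (py[iL + 1L] - py[iL]) * (g - px[iL]) / (px[iL + 1L] - px[iL])
    }
  }
  list(left = left, right = right)
}

#' One-vs-rest confusion counts per class
#'
#' Counts TP/FP/FN/TN for every class treating that class as positive and
#' all others as negative; works for label vectors and for label planes
#' (matrices) such as segmentation masks.
#'
#' @param pred,truth Integer labels in `1..k` (vectors or equal-shaped
#'   matrices).
#' @param k Number of classes.
#' @return An object of class `"confusion_counts"`: a data frame with
#'   columns `class`, `tp`, `fp`, `fn`, `tn`; one row per class, with
#'   `tp + fp + fn + tn` equal to the number of scored units in every row.
#' @export
confusion_counts <- function(pred, truth, k) {
  if (!identical(dim(pred), dim(truth)) || length(pred) != length(truth)) {
    stop("pred and truth must have identical shape", call. = FALSE)
  }
  pred <- as.integer(pred)
  truth <- as.integer(truth)
  if (any(pred < 1L | pred > k) || any(truth < 1L | truth > k)) {
    stop("labels out of range 1..k", call. = FALSE)
  }
  n <- length(pred)
  rows <- lapply(seq_len(k), function(c) {
    tp <- sum(pred == c & truth == c)
    fp <- sum(pred == c & truth != c)
    fn <- sum(pred != c & truth == c)
    data.frame(class = c, tp = tp, fp = fp, fn = fn, tn = n - tp - fp - fn)
  })
  structure(do.call(rbind, rows), class = c("confusion_counts", "data.frame"))
}

#' Segmentation metric suite from confusion counts
#'
#' Per class: IOU (Jaccard) `TP/(TP+FP+FN)`, Dice/F1 `2TP/(2TP+FP+FN)`,
#' accuracy `(TP+TN)/total`, precision `TP/(TP+FP)`, sensitivity
#' `TP/(TP+FN)`, specificity `TN/(TN+FP)`; plus `miou`, the mean of the
#' per-class IOUs. A metric with a zero denominator is reported as `NA`
#' (undefined, distinct from 0), excluded from `miou`, and flagged with a
#' warning.
#'
#' @param cc A `"confusion_counts"` object.
#' @return List with `per_class` (data frame of the six metrics per class)
#'   and `miou` (scalar).
#' @export
segmentation_suite <- function(cc) {
  stopifnot(inherits(cc, "confusion_counts"))
  safe <- function(num, den, what, cls) {
    out <- ifelse(den == 0, NA_real_, num / den)
    if (anyNA(out)) {
      warning(what, " undefined (zero denominator) for class ",
              paste(cls[is.na(out)], collapse = ", "), call. = FALSE)
    }
    out
  }
  with(cc, {
    total <- tp + fp + fn + tn
    per_class <- data.frame(
      class = class,
      iou = safe(tp, tp + fp + fn, "IOU", class),
      f1 = safe(2 * tp, 2 * tp + fp + fn, "F1", class),
      acc = safe(tp + tn, total, "accuracy", class),
      precision = safe(tp, tp + fp, "precision", class),
      sensitivity = safe(tp, tp + fn, "sensitivity", class),
      specificity = safe(tn, tn + fp, "specificity", class)
    )
    list(per_class = per_class, miou = mean(per_class$iou, na.rm = TRUE))
  })
}

#' Cohen's kappa inter-rater agreement
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` between two rating
#' lists, with expected agreement from the product of marginal label
#' frequencies. Complete agreement on a single repeated label (where
#' `p_e = 1`) is defined as 1.
#'
#' @param ratings_a,ratings_b Equal-length label vectors.
#' @return Kappa in `[-1, 1]`.
#' @export
cohen_kappa <- function(ratings_a, ratings_b) {
  if (length(ratings_a) != length(ratings_b) || length(ratings_a) < 1L) {
    stop("rating lists must have equal positive length", call. = FALSE)
  }
  a <- as.character(ratings_a)
  b <- as.character(ratings_b)
  labs <- union(unique(a), unique(b))
  p_o <- mean(a == b)
  p_e <- sum(vapply(labs, function(l) mean(a == l) * mean(b == l), numeric(1)))
  if (abs(1 - p_e) < .Machine$double.eps * 8) {
    if (p_o >= 1 - .Machine$double.eps * 8) return(1)
    stop("kappa undefined: expected agreement is 1 without perfect agreement",
         call. = FALSE)
  }
  (p_o - p_e) / (1 - p_e)
}

#' Aggregate per-fold metrics into mean +/- sigma
#'
#' @param per_fold List of named numeric vectors, one per fold, sharing the
#'   same metric names.
#' @param sigma `"population"` (divide-by-n, default) or `"sample"`.
#' @return A `"metric_report"`: data frame with columns `metric`, `mean`,
#'   `sigma`; the raw per-fold values are retained in attribute
#'   `"per_fold"`.
#' @export
aggregate_folds <- function(per_fold, sigma = c("population", "sample")) {
  sigma <- match.arg(sigma)
  stopifnot(is.list(per_fold), length(per_fold) >= 1L)
  keys <- names(per_fold[[1]])
  if (is.null(keys) || any(vapply(per_fold, function(f)
        !identical(sort(names(f)), sort(keys)), logical(1)))) {
    stop("inconsistent metric names across folds", call. = FALSE)
  }
  m <- do.call(rbind, lapply(per_fold, function(f) f[keys]))
  sd_pop <- function(x) sqrt(mean((x - mean(x))^2))
  out <- data.frame(
    metric = keys,
    mean = colMeans(m),
    sigma = apply(m, 2, if (sigma == "population") sd_pop else stats::sd),
    row.names = NULL
  )
  if (length(per_fold) == 1L) out$sigma <- 0
  attr(out, "per_fold") <- m
  class(out) <- c("metric_report", "data.frame")
  out
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("metric report over %d fold(s):\n", nrow(attr(x, "per_fold"))))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-12s %.4f +/- %.4f\n", x$metric[i], x$mean[i], x$sigma[i]))
  }
  invisible(x)
}
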