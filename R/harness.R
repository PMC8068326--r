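#' Model contracts and desk-scale experiment drivers
#'
#' Deep backbones (Xception, ResNet, MobileNetv2, DeepLabv3+) are external
#' plugins behind a small model contract; the package ships deterministic
#' reference models — a subband-energy/quantile linear-softmax classifier
#' and a per-pixel segmenter — so every pipeline path (enhancement,
#' augmentation, cross-validation, metrics) is exercisable on one CPU.
#' The two-stage fine-tuning schedule and the DeepLabv3+ settings are
#' carried as configuration metadata for plugins, never executed here.
#'
#' @name harness
NULL

#' Two-stage fine-tuning schedule (plugin configuration)
#'
#' Stage 1 trains only the added classification head (learning rate 0.001);
#' stage 2 fine-tunes the backbone except the head (learning rate 0.0001);
#' both use learning-rate decay 1e-6. Serialized into plugin configs.
#'
#' @param stage1_lr,stage2_lr,lr_decay Positive learning rates,
#'   `stage2_lr < stage1_lr`.
#' @return A `"train_schedule"` list.
#' @export
train_schedule <- function(stage1_lr = 0.001, stage2_lr = 0.0001,
                           lr_decay = 1e-6) {
  stopifnot(stage1_lr > 0, stage2_lr > 0, lr_decay >= 0)
  if (stage2_lr >= stage1_lr) {
    stop("stage-2 learning rate must be smaller than stage 1", call. = FALSE)
  }
  structure(list(stage1_lr = stage1_lr, stage2_lr = stage2_lr,
                 lr_decay = lr_decay,
                 stage1_trainable = "added_head_only",
                 stage2_trainable = "backbone_except_head"),
            class = "train_schedule")
}

#' DeepLabv3+ segmentation settings (plugin configuration)
#'
#' @param atrous_rates Integer ASPP atrous rates (reference: 12, 24, 36).
#' @param output_stride Encoder output stride (reference: 8).
#' @param decoder_output_stride Decoder output stride (reference: 4).
#' @param backbone Free-text backbone descriptor.
#' @return A `"seg_config"` list.
#' @export
seg_config <- function(atrous_rates = c(12L, 24L, 36L), output_stride = 8L,
                       decoder_output_stride = 4L, backbone = "xception_65") {
  stopifnot(all(atrous_rates > 0), output_stride > 0, decoder_output_stride > 0)
  structure(list(atrous_rates = as.integer(atrous_rates),
                 output_stride = as.integer(output_stride),
                 decoder_output_stride = as.integer(decoder_output_stride),
                 backbone = backbone),
            class = "seg_config")
}

# ---- internal multinomial softmax fit (ridge-penalized, deterministic) ----

.softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# X: n x p (no intercept column), y: integer 1..K. Returns fit state.
.softmax_fit <- function(X, y, K, lambda = 1e-3, maxit = 300L) {
  n <- nrow(X)
  p <- ncol(X)
  Xi <- cbind(1, X)
  Y <- matrix(0, n, K)
  Y[cbind(seq_len(n), y)] <- 1
  obj <- function(w) {
    W <- matrix(w, p + 1L, K)
    P <- .softmax_rows(Xi %*% W)
    -sum(Y * log(pmax(P, 1e-12))) / n + lambda / 2 * sum(W[-1, ]^2)
  }
  grad <- function(w) {
    W <- matrix(w, p + 1L, K)
    P <- .softmax_rows(Xi %*% W)
    G <- crossprod(Xi, P - Y) / n
    G[-1, ] <- G[-1, ] + lambda * W[-1, ]
    as.vector(G)
  }
  fit <- stats::optim(rep(0, (p + 1L) * K), obj, grad, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-10))
  matrix(fit$par, p + 1L, K)
}

.softmax_scores <- function(W, X) .softmax_rows(cbind(1, X) %*% W)

# ---- reference classifier ----

# per-image features: luminance summary statistics, quantiles, and log
# subband energies of the level-1 haar decomposition
.classifier_features <- function(image) {
  lum <- 0.2126 * image[, , 1] + 0.7152 * image[, , 2] + 0.0722 * image[, , 3]
  b <- swt_decompose(image, "haar")
  loge <- function(x) log(sum(x^2) + 1e-12)
  c(mean(lum), stats::sd(lum),
    stats::quantile(lum, c(0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE),
    loge(b$lh), loge(b$hl), loge(b$hh),
    log(stats::var(as.vector(b$ll)) + 1e-12),
    mean(image[, , 1]), mean(image[, , 2]), mean(image[, , 3]))
}

.feature_matrix <- function(images) {
  t(vapply(images, .classifier_features, numeric(14L)))
}

.standardize_fit <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[!is.finite(sd) | sd < 1e-8] <- 1
  list(mu = mu, sd = sd)
}

.standardize_apply <- function(X, st) sweep(sweep(X, 2, st$mu), 2, st$sd, "/")

#' Deterministic reference classifier
#'
#' A desk-scale stand-in for the GPU backbones: each image is summarized
#' by luminance statistics, quantiles and log subband energies of its
#' level-1 haar decomposition, and a ridge-penalized linear softmax model
#' (fit by BFGS from a zero start, hence fully deterministic) maps the
#' standardized features to class probabilities. Trains in seconds on a
#' few hundred small images.
#'
#' @param lambda Ridge penalty on the non-intercept weights.
#' @return A `"model_contract"` list with `fit(train)`,
#'   `predict_scores(images, state)`, `deterministic = TRUE` and a
#'   `descriptor`.
#' @export
reference_classifier <- function(lambda = 1e-3) {
  structure(list(
    descriptor = "reference subband-energy/quantile softmax classifier",
    deterministic = TRUE,
    fit = function(train) {
      stopifnot(inherits(train, "labeled_dataset"))
      levels <- sort(unique(train$grades))
      if (length(levels) < 2L) {
        stop("cannot fit classifier on a single-class training set",
             call. = FALSE)
      }
      X <- .feature_matrix(train$images)
      st <- .standardize_fit(X)
      y <- match(train$grades, levels)
      W <- .softmax_fit(.standardize_apply(X, st), y, length(levels), lambda)
      list(W = W, st = st, levels = levels)
    },
    predict_scores = function(images, state) {
      X <- .standardize_apply(.feature_matrix(images), state$st)
      sc <- .softmax_scores(state$W, X)
      colnames(sc) <- state$levels
      sc
    }
  ), class = "model_contract")
}

# ---- reference segmenter ----

.box_filter <- function(m, half = 2L) {
  h <- rep(1, 2L * half + 1L) / (2L * half + 1L)
  # circular separable box mean, center-aligned
  out <- .circ_shift_cols(.circ_filter_cols(m, h), -half)
  t(.circ_shift_cols(.circ_filter_cols(t(out), h), -half))
}

# per-pixel feature planes: RGB, local luminance mean/sd, smoothed local
# detail magnitude from the haar decomposition
.pixel_features <- function(image) {
  lum <- 0.2126 * image[, , 1] + 0.7152 * image[, , 2] + 0.0722 * image[, , 3]
  b <- swt_decompose(image, "haar")
  od <- dim(lum)
  crop <- function(m) m[seq_len(od[1]), seq_len(od[2]), drop = FALSE]
  detail <- crop(abs(b$lh[, , 1]) + abs(b$hl[, , 1]) + abs(b$hh[, , 1]))
  lmean <- .box_filter(lum)
  lsq <- .box_filter(lum^2)
  lsd <- sqrt(pmax(lsq - lmean^2, 0))
  cbind(as.vector(image[, , 1]), as.vector(image[, , 2]),
        as.vector(image[, , 3]), as.vector(lmean), as.vector(lsd),
        as.vector(.box_filter(detail)))
}

#' Deterministic reference segmenter
#'
#' Per-pixel two-class classifier on local color, local mean/sd and
#' smoothed subband-detail magnitude, fit with the same internal softmax
#' as the reference classifier on a deterministic stride subsample of the
#' training pixels, followed by a 3x3 majority smoothing vote on the
#' predicted labels. Sufficient to exercise the preprocessing and metric
#' paths; not a DeepLabv3+ substitute.
#'
#' @param lambda Ridge penalty.
#' @param max_train_pixels Upper bound on pixels used for fitting (taken
#'   by a fixed stride over the pooled training pixels).
#' @return A `"model_contract"` with `fit(pairs)` and
#'   `predict_mask(image, state)`; masks use labels 1 = stroma,
#'   2 = epithelium.
#' @export
reference_segmenter <- function(lambda = 1e-3, max_train_pixels = 20000L) {
  structure(list(
    descriptor = "reference per-pixel softmax segmenter with majority vote",
    deterministic = TRUE,
    fit = function(pairs) {
      X <- do.call(rbind, lapply(pairs, function(p) .pixel_features(p$image)))
      y <- unlist(lapply(pairs, function(p) as.integer(p$mask)))
      stopifnot(length(y) == nrow(X), all(y %in% c(1L, 2L)))
      if (length(unique(y)) < 2L) {
        stop("cannot fit segmenter: training masks contain one class",
             call. = FALSE)
      }
      step <- max(1L, floor(length(y) / max_train_pixels))
      keep <- seq(1L, length(y), by = step)
      st <- .standardize_fit(X[keep, , drop = FALSE])
      W <- .softmax_fit(.standardize_apply(X[keep, , drop = FALSE], st),
                       y[keep], 2L, lambda)
      list(W = W, st = st)
    },
    predict_mask = function(image, state) {
      X <- .standardize_apply(.pixel_features(image), state$st)
      sc <- .softmax_scores(state$W, X)
      lab <- matrix(max.col(sc, ties.method = "first"), nrow = dim(image)[1])
      # 3x3 majority vote: smooth the epithelium indicator
      vote <- .box_filter(matrix(as.numeric(lab == 2L), nrow(lab)), half = 1L)
      matrix(ifelse(vote > 0.5, 2L, 1L), nrow(lab))
    }
  ), class = "model_contract")
}

# ---- cross-validated drivers ----

.is_identity_mapping <- function(params) {
  !is.null(params) && params$a == 0 && params$b == 0 &&
    params$c == 1 && params$d == 0
}

#' Cross-validated grading experiment
#'
#' Runs the full first-stage protocol: optional enhancement of every image
#' (identity mapping is a no-op and reproduces the unpreprocessed run
#' exactly), stratified k-fold splitting, seven-transform augmentation of
#' the training partition only, model fitting, and scoring of the
#' untouched test fold. A source-level leakage audit runs inside every
#' fold. Returns micro- and macro-AUC aggregated as mean +/- sigma.
#'
#' @param dataset A `"labeled_dataset"` of original samples.
#' @param model A classifier `"model_contract"`.
#' @param params Optional `"mapping_params"`; `NULL` disables enhancement.
#' @param k Number of folds.
#' @param seed Seed for the fold assignment.
#' @param folds Optional precomputed `"fold_assignment"` (overrides
#'   `k`/`seed` splitting).
#' @return A `"metric_report"` with metrics `auc_macro` and `auc_micro`.
#' @export
run_classification_cv <- function(dataset, model, params = NULL, k = 5L,
                                  seed = 1L, folds = NULL) {
  stopifnot(inherits(dataset, "labeled_dataset"),
            inherits(model, "model_contract"))
  if (is.null(folds)) folds <- stratified_kfold(dataset, k, seed)
  if (!is.null(params) && !.is_identity_mapping(params)) {
    dataset$images <- enhance_images(dataset$images, params)
  }
  per_fold <- lapply(seq_len(folds$k), function(f) {
    train <- build_training_set(dataset, folds, f)
    test <- build_test_set(dataset, folds, f)
    assert_no_leakage(train, test)
    state <- tryCatch(model$fit(train), error = function(e) {
      stop("model training failed in fold ", f, ": ", conditionMessage(e),
           call. = FALSE)
    })
    sc <- model$predict_scores(test$images, state)
    truth <- match(test$grades, colnames(sc))
    c(auc_macro = auc_macro(sc, truth), auc_micro = auc_micro(sc, truth))
  })
  aggregate_folds(per_fold)
}

.PREPROCESS_WAVELET <- c(ll_haar = "haar", ll_sym2 = "sym2",
                         ll_db2 = "db2", ll_bior13 = "bior1.3")

#' Cross-validated epithelium/stroma segmentation experiment
#'
#' Optional LL-subband preprocessing of every image, seeded k-fold split
#' of the image/mask pairs, segmenter fitting per fold, and pooled
#' confusion counts over the held-out pairs. Reports mIOU over both
#' tissue classes plus F1, accuracy, precision, sensitivity and
#' specificity for the epithelium class (label 2) as the positive class.
#'
#' @param pairs List of `list(image, mask)` with masks labelled 1 = stroma,
#'   2 = epithelium.
#' @param segmenter A segmenter `"model_contract"`.
#' @param preprocess One of `"none"`, `"ll_haar"`, `"ll_sym2"`, `"ll_db2"`,
#'   `"ll_bior13"`.
#' @param k Number of folds.
#' @param seed Seed for the fold split.
#' @return A `"metric_report"` with metrics `miou`, `f1`, `acc`,
#'   `precision`, `sensitivity`, `specificity`.
#' @export
run_segmentation_eval <- function(pairs, segmenter,
                                  preprocess = c("none", "ll_haar", "ll_sym2",
                                                 "ll_db2", "ll_bior13"),
                                  k = 5L, seed = 1L) {
  preprocess <- match.arg(preprocess)
  stopifnot(is.list(pairs), length(pairs) >= k,
            inherits(segmenter, "model_contract"))
  for (p in pairs) {
    stopifnot(identical(dim(p$image)[1:2], dim(p$mask)))
  }
  if (preprocess != "none") {
    wv <- .PREPROCESS_WAVELET[[preprocess]]
    pairs <- lapply(pairs, function(p) {
      p$image <- extract_ll(p$image, wv)
      p
    })
  }
  rng <- .seeded_rng(seed)
  fold <- ((rng$permutation(length(pairs)) - 1L) %% k) + 1L
  per_fold <- lapply(seq_len(k), function(f) {
    state <- segmenter$fit(pairs[fold != f])
    test <- pairs[fold == f]
    pred <- lapply(test, function(p) segmenter$predict_mask(p$image, state))
    cc <- confusion_counts(unlist(pred), unlist(lapply(test, function(p)
      as.integer(p$mask))), k = 2L)
    s <- segmentation_suite(cc)
    epi <- s$per_class[s$per_class$class == 2L, ]
    c(miou = s$miou, f1 = epi$f1, acc = epi$acc, precision = epi$precision,
      sensitivity = epi$sensitivity, specificity = epi$specificity)
  })
  aggregate_folds(per_fold)
}
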