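## Openness prediction harness: balanced training/validation sampling,
## random-forest classification of labelled vs highly accessible regions,
## stratified k-fold cross-validation, ROC/AUC from pooled held-out scores,
## the systematic TF-subset sweep (2^n - 1 models), Gini feature importance
## and support-vector regression of the quantitative ATAC signal.
##
## Features and the regression target are log2(RPKM + 1): coverage is
## heavy-tailed and the log stabilises both the forest splits and the SVR
## kernel. Regions where a TF has no peak contribute feature 0, not NA.

#' Build labelled examples from a classification and occupancy matrix
#'
#' One example per TF-bound universe region: per-TF `log2(RPKM + 1)`
#' features, a binary label (`labelled` = not open, `HighAcc` = open) and
#' the quantitative openness value (`log2(ATAC RPKM + 1)`) for regression.
#'
#' @param assignment a [classify_regions()] result.
#' @param occ occupancy matrix with one column per TF (rows align with the
#'   universe or with its TF-bound subset).
#' @param atac_rpkm ATAC RPKM vector aligned the same way.
#' @param log_transform apply `log2(x + 1)` (default TRUE).
#' @return data.frame with `region_id`, one feature column per TF, `label`
#'   (factor labelled/HighAcc) and `openness`.
#' @export
build_examples <- function(assignment, occ, atac_rpkm,
                           log_transform = TRUE) {
  n_all <- length(assignment$universe)
  if (nrow(occ) == n_all) {
    occ <- occ[assignment$is_unified, , drop = FALSE]
    atac_rpkm <- atac_rpkm[assignment$is_unified]
  } else if (nrow(occ) != sum(assignment$is_unified)) {
    stop("occupancy rows do not align with the region universe")
  }
  stopifnot(all(assignment$tf_names %in% colnames(occ)))
  feats <- occ[, assignment$tf_names, drop = FALSE]
  if (log_transform) {
    feats <- log2(feats + 1)
    atac_rpkm <- log2(atac_rpkm + 1)
  }
  open <- assignment$open[assignment$is_unified]
  ids <- region_ids(assignment$universe[assignment$is_unified])
  out <- data.frame(region_id = ids, feats,
                    label = factor(ifelse(open, "HighAcc", "labelled"),
                                   levels = c("labelled", "HighAcc")),
                    openness = atac_rpkm,
                    stringsAsFactors = FALSE, check.names = FALSE)
  rownames(out) <- NULL
  out
}

#' Balanced, disjoint training and validation sets
#'
#' Draws `n_per_class` examples per class for training and another
#' `n_per_class` per class for validation, uniformly without replacement;
#' the two sets are disjoint and exactly class-balanced.
#'
#' @param examples a [build_examples()] data.frame.
#' @param n_per_class examples per class per set (default 1000).
#' @param seed RNG seed.
#' @return list with `train` and `valid` data.frames.
#' @export
sample_training_validation <- function(examples, n_per_class = 1000L,
                                       seed = 1L) {
  avail <- table(examples$label)
  short <- avail < 2L * n_per_class
  if (any(short))
    stop("insufficient regions for balanced sampling: need ",
         2L * n_per_class, " per class, have ",
         paste(names(avail), "=", as.integer(avail), collapse = ", "))
  set.seed(seed)
  idx <- lapply(levels(examples$label), function(lv) {
    pool <- which(examples$label == lv)
    sample(pool, 2L * n_per_class)
  })
  train <- sort(unlist(lapply(idx, function(i) i[seq_len(n_per_class)])))
  valid <- sort(unlist(lapply(idx, function(i)
    i[n_per_class + seq_len(n_per_class)])))
  list(train = examples[train, , drop = FALSE],
       valid = examples[valid, , drop = FALSE])
}

#' Model specification for the openness models
#'
#' @param tf_subset non-empty character vector of feature (TF) names.
#' @param task `"classification"` or `"regression"`.
#' @param cv_folds folds for cross-validation (default 10).
#' @param seed RNG seed.
#' @param ntree random-forest size (default 500).
#' @param mtry per-split feature draw; default `floor(sqrt(p))`, min 1.
#' @param svr_kernel kernel for the support-vector regressor.
#' @return list of class `model_spec`.
#' @export
model_spec <- function(tf_subset, task = c("classification", "regression"),
                       cv_folds = 10L, seed = 1L, ntree = 500L,
                       mtry = NULL, svr_kernel = "radial") {
  task <- match.arg(task)
  if (length(tf_subset) < 1L) stop("tf_subset must be non-empty")
  if (cv_folds < 2L) stop("cv_folds must be >= 2")
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(length(tf_subset))))
  structure(list(tf_subset = tf_subset, task = task, cv_folds = cv_folds,
                 seed = seed, ntree = ntree, mtry = mtry,
                 svr_kernel = svr_kernel),
            class = "model_spec")
}

example_features <- function(examples, tf_subset) {
  missing <- setdiff(tf_subset, colnames(examples))
  if (length(missing))
    stop("feature column(s) absent: ", paste(missing, collapse = ", "))
  as.matrix(examples[, tf_subset, drop = FALSE])
}

#' Fit a random-forest openness classifier
#'
#' Bootstrapped decision-tree ensemble with random feature sub-sampling;
#' deterministic given `spec$seed` and exposing class-probability scores
#' for ROC analysis.  A constant feature column triggers a warning, not an
#' error.
#'
#' @param train training examples ([build_examples()] layout).
#' @param spec a [model_spec()] with `task = "classification"`.
#' @return a `randomForest` fit.
#' @export
fit_openness_classifier <- function(train, spec) {
  stopifnot(spec$task == "classification")
  x <- example_features(train, spec$tf_subset)
  if (any(apply(x, 2L, function(col) length(unique(col))) == 1L))
    warning("constant feature column(s) in training set")
  set.seed(spec$seed)
  randomForest::randomForest(
    x = x, y = train$label, ntree = spec$ntree,
    mtry = min(spec$mtry, ncol(x)), importance = TRUE)
}

#' Classification metrics from a confusion count
#'
#' @param tp,fn,tn,fp non-negative integer counts (positive class =
#'   `HighAcc`/open).
#' @return list with `accuracy`, `sensitivity`, `specificity`.
#' @export
binary_metrics <- function(tp, fn, tn, fp) {
  counts <- c(tp, fn, tn, fp)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (sum(counts) == 0) stop("at least one count must be positive")
  list(accuracy = (tp + tn) / sum(counts),
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else 0,
       specificity = if (tn + fp > 0) tn / (tn + fp) else 0)
}

#' ROC points from scores
#'
#' Thresholds descend over the unique score values; ties are grouped, so
#' the trapezoidal area equals the mid-rank Mann-Whitney statistic.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels logical or factor; `TRUE`/second level = positive.
#' @return data.frame with `fpr`, `tpr`, both non-decreasing from (0,0) to
#'   (1,1).
#' @export
roc_points <- function(scores, labels) {
  pos <- as.logical(labels == if (is.factor(labels)) levels(labels)[2L]
                    else TRUE)
  ord <- order(scores, decreasing = TRUE)
  pos <- pos[ord]
  s <- scores[ord]
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L)
    stop("both classes required for a ROC curve")
  last <- !duplicated(s, fromLast = TRUE)   # last index of each tie group
  tp <- cumsum(pos)[last]
  fp <- cumsum(!pos)[last]
  data.frame(fpr = c(0, fp / n_neg), tpr = c(0, tp / n_pos))
}

#' Area under a ROC curve by trapezoidal integration
#'
#' @param roc a [roc_points()] data.frame.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(roc) {
  sum(diff(roc$fpr) * (head(roc$tpr, -1) + roc$tpr[-1]) / 2)
}

confusion_metrics <- function(pred_pos, truth_pos) {
  binary_metrics(tp = sum(pred_pos & truth_pos),
                 fn = sum(!pred_pos & truth_pos),
                 tn = sum(!pred_pos & !truth_pos),
                 fp = sum(pred_pos & !truth_pos))
}

stratified_folds <- function(labels, k) {
  folds <- integer(length(labels))
  for (lv in levels(labels)) {
    idx <- which(labels == lv)
    if (length(idx) < k)
      stop("class '", lv, "' smaller than the number of folds (", k, ")")
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  folds
}

#' Stratified k-fold cross-validation of the openness classifier
#'
#' Class-balanced folds; held-out predictions are pooled across folds and
#' metrics plus the ROC/AUC are computed on the pooled scores (probability
#' of the `HighAcc` class).
#'
#' @param train training examples.
#' @param spec a [model_spec()].
#' @return list of class `model_evaluation`: `accuracy`, `sensitivity`,
#'   `specificity`, `auc`, `roc` (data.frame), `scores`, `labels`,
#'   `importances`.
#' @export
cross_validate <- function(train, spec) {
  set.seed(spec$seed)
  folds <- stratified_folds(train$label, spec$cv_folds)
  scores <- numeric(nrow(train))
  for (f in seq_len(spec$cv_folds)) {
    hold <- folds == f
    fit <- suppressWarnings(
      fit_openness_classifier(train[!hold, , drop = FALSE], spec))
    scores[hold] <- predict(fit, example_features(train[hold, , drop = FALSE],
                                                  spec$tf_subset),
                            type = "prob")[, "HighAcc"]
  }
  truth_pos <- train$label == "HighAcc"
  metrics <- confusion_metrics(scores > 0.5, truth_pos)
  roc <- roc_points(scores, train$label)
  structure(c(metrics,
              list(auc = roc_auc(roc), roc = roc, scores = scores,
                   labels = train$label)),
            class = "model_evaluation")
}

#' Evaluate a fitted classifier on an independent validation set
#'
#' @param fit a [fit_openness_classifier()] model.
#' @param valid validation examples.
#' @param spec the [model_spec()] used for the fit.
#' @return `model_evaluation` list (metrics, ROC, AUC on the validation
#'   scores).
#' @export
evaluate_on_validation <- function(fit, valid, spec) {
  scores <- predict(fit, example_features(valid, spec$tf_subset),
                    type = "prob")[, "HighAcc"]
  truth_pos <- valid$label == "HighAcc"
  metrics <- confusion_metrics(scores > 0.5, truth_pos)
  roc <- roc_points(scores, valid$label)
  structure(c(metrics, list(auc = roc_auc(roc), roc = roc, scores = scores,
                            labels = valid$label)),
            class = "model_evaluation")
}

#' Mean-decrease-in-Gini feature importance
#'
#' @param fit a fitted `randomForest` classifier.
#' @return named numeric vector (one non-negative value per feature),
#'   decreasing.
#' @export
feature_importance <- function(fit) {
  imp <- randomForest::importance(fit, type = 2L)[, "MeanDecreaseGini"]
  sort(imp, decreasing = TRUE)
}

#' Systematic TF-subset model sweep
#'
#' Fits one random-forest classifier per non-empty TF subset (2^n - 1
#' models; 31 for five TFs), reporting both stratified-CV metrics on the
#' training set and metrics on the independent validation set, plus Gini
#' importances.  Per-subset seeds fan out deterministically from
#' `base_spec$seed` (seed + subset index) so the sweep is reproducible.
#'
#' @param train,valid balanced example sets
#'   ([sample_training_validation()]).
#' @param tf_names all TF names (n <= 12).
#' @param base_spec template [model_spec()] (its `tf_subset` is ignored).
#' @return list of class `sweep_result`: `table` (data.frame: subset,
#'   size, cv/val accuracy, sensitivity, specificity, auc),
#'   `importances` (named list), `evaluations` (named list).
#' @export
sweep_combinations <- function(train, valid, tf_names, base_spec) {
  n <- length(tf_names)
  if (n > 12L) stop("sweep is tractable only up to 12 TFs")
  subsets <- unlist(lapply(seq_len(n), function(k)
    combn(tf_names, k, simplify = FALSE)), recursive = FALSE)
  rows <- vector("list", length(subsets))
  importances <- evaluations <- setNames(vector("list", length(subsets)),
    vapply(subsets, paste, character(1), collapse = "+"))
  for (i in seq_along(subsets)) {
    spec <- model_spec(subsets[[i]], task = "classification",
                       cv_folds = base_spec$cv_folds,
                       seed = base_spec$seed + i,
                       ntree = base_spec$ntree)
    cv <- cross_validate(train, spec)
    fit <- suppressWarnings(fit_openness_classifier(train, spec))
    val <- evaluate_on_validation(fit, valid, spec)
    importances[[i]] <- feature_importance(fit)
    evaluations[[i]] <- val
    rows[[i]] <- data.frame(
      subset = names(evaluations)[i], size = length(subsets[[i]]),
      cv_accuracy = cv$accuracy, cv_sensitivity = cv$sensitivity,
      cv_specificity = cv$specificity, cv_auc = cv$auc,
      val_accuracy = val$accuracy, val_sensitivity = val$sensitivity,
      val_specificity = val$specificity, val_auc = val$auc,
      stringsAsFactors = FALSE)
  }
  structure(list(table = do.call(rbind, rows), importances = importances,
                 evaluations = evaluations, tf_names = tf_names),
            class = "sweep_result")
}

#' Per-subset-size summary of a sweep (box-plot substrate)
#'
#' @param sweep a [sweep_combinations()] result.
#' @param metric column of the sweep table to summarise (default
#'   `"val_accuracy"`).
#' @return data.frame with `size`, `n_models`, `min`, `median`, `max`.
#' @export
sweep_size_summary <- function(sweep, metric = "val_accuracy") {
  tab <- sweep$table
  out <- do.call(rbind, lapply(split(tab[[metric]], tab$size), function(v)
    data.frame(n_models = length(v), min = min(v), median = median(v),
               max = max(v))))
  out$size <- as.integer(rownames(out))
  rownames(out) <- NULL
  out[, c("size", "n_models", "min", "median", "max")]
}

#' Support-vector regression of quantitative openness
#'
#' Radial-kernel epsilon-SVR predicting the (log-transformed) ATAC signal
#' from TF occupancy features; reports the Pearson correlation between
#' predicted and measured openness on the independent validation set.
#'
#' @param train,valid example sets with an `openness` column.
#' @param spec a [model_spec()] with `task = "regression"`.
#' @return list with `fit`, `pearson_r`, `predicted`, `measured`.
#' @export
fit_openness_regressor <- function(train, valid, spec) {
  stopifnot(spec$task == "regression")
  if (sd(train$openness) == 0)
    stop("regression target has zero variance")
  x <- example_features(train, spec$tf_subset)
  set.seed(spec$seed)
  fit <- e1071::svm(x = x, y = train$openness, type = "eps-regression",
                    kernel = spec$svr_kernel)
  pred <- predict(fit, example_features(valid, spec$tf_subset))
  list(fit = fit, pearson_r = cor(pred, valid$openness),
       predicted = as.numeric(pred), measured = valid$openness)
}
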