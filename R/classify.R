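#' Configuration for the bagged-forest evaluation
#'
#' @param n_trees trees per forest (default 500).
#' @param k_folds cross-validation folds (default 10); must not exceed the
#'   minority class size of the dataset it is applied to.
#' @param oversample balance training folds by resampling the minority
#'   class (default `TRUE`).
#' @param importance_method `"impurity"` (mean decrease in node impurity,
#'   default) or `"permutation"` (mean decrease in accuracy, clamped at 0).
#' @param bootstrap_reps bootstrap resamples for the AUC confidence
#'   interval (default 2000).
#' @param seed integer seed for fold assignment, oversampling and forests.
#' @return an object of class `model_config`.
#' @export
model_config <- function(n_trees = 500, k_folds = 10, oversample = TRUE,
                         importance_method = c("impurity", "permutation"),
                         bootstrap_reps = 2000, seed = 1L) {
  importance_method <- match.arg(importance_method)
  if (n_trees < 1) stop_bad("n_trees must be >= 1")
  if (k_folds < 2) stop_bad("k_folds must be >= 2")
  structure(list(n_trees = as.integer(n_trees),
                 k_folds = as.integer(k_folds),
                 oversample = isTRUE(oversample),
                 importance_method = importance_method,
                 bootstrap_reps = as.integer(bootstrap_reps),
                 seed = as.integer(seed)),
            class = "model_config")
}

#' Oversample the minority class to balance a training set
#'
#' Minority-class rows are resampled with replacement and appended until
#' both classes have equal counts; every duplicate is a copy of an original
#' minority row. Applied to training folds only — held-out folds are never
#' touched.
#'
#' @param x feature matrix / data.frame.
#' @param y two-level factor of class labels.
#' @return list with balanced `x` and `y`.
#' @export
oversample_minority <- function(x, y) {
  y <- droplevels(as.factor(y))
  if (nlevels(y) != 2L) stop_bad("need exactly two classes to balance")
  tab <- table(y)
  if (tab[1] == tab[2]) return(list(x = x, y = y))
  minority <- names(tab)[which.min(tab)]
  idx <- which(y == minority)
  extra <- sample(idx, max(tab) - min(tab), replace = TRUE)
  list(x = rbind(x, x[extra, , drop = FALSE]),
       y = factor(c(as.character(y), as.character(y[extra])),
                  levels = levels(y)))
}

#' Rank-based (Mann–Whitney) AUC
#'
#' The fraction of (high, low) pairs in which the high-class score exceeds
#' the low-class score, ties counted one half — the probability that a
#' random positive outranks a random negative.
#'
#' @param scores numeric predicted scores (higher = more "high").
#' @param labels two-level factor/logical; the positive class is `"high"`
#'   if present, otherwise the second factor level (or `TRUE`).
#' @return AUC in `[0, 1]`.
#' @export
compute_auc <- function(scores, labels) {
  pos <- positive_mask(labels)
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop_bad("both classes must be present")
  r <- rank(scores)            # midranks handle ties as 1/2
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

positive_mask <- function(labels) {
  if (is.logical(labels)) return(labels)
  f <- droplevels(as.factor(labels))
  if (nlevels(f) != 2L) stop_bad("labels must have exactly two classes")
  positive <- if ("high" %in% levels(f)) "high" else levels(f)[2]
  f == positive
}

#' Bootstrap confidence interval for the AUC
#'
#' 95% percentile interval over stratified bootstrap resamples of the
#' scored images (classes resampled separately, preserving their sizes).
#'
#' @param scores,labels as in [compute_auc()].
#' @param reps bootstrap resamples (>= 100).
#' @param level confidence level, default 0.95.
#' @return numeric `(lo, hi)`.
#' @export
auc_ci <- function(scores, labels, reps = 2000, level = 0.95) {
  if (reps < 100) stop_bad("reps must be >= 100")
  pos <- positive_mask(labels)
  s1 <- scores[pos]; s0 <- scores[!pos]
  stat <- vapply(seq_len(reps), function(...) {
    b1 <- sample(s1, replace = TRUE)
    b0 <- sample(s0, replace = TRUE)
    compute_auc(c(b1, b0), c(rep(TRUE, length(b1)), rep(FALSE, length(b0))))
  }, numeric(1))
  a <- (1 - level) / 2
  unname(quantile(stat, c(a, 1 - a), type = 7))
}

stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in levels(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Cross-validated bagged-forest evaluation of one category dataset
#'
#' Stratified k-fold cross-validation of a bagged ensemble of decision
#' trees (`randomForest` with its bagging defaults beyond `ntree`). Within
#' each fold the training portion is rebalanced by minority oversampling
#' (never the held-out fold), a forest of `n_trees` is fit, and the
#' held-out images are scored with the out-of-fold probability of the
#' `high` class. Pooled out-of-fold scores give the AUC and its stratified
#' bootstrap CI; per-feature importances are averaged across folds.
#'
#' @param dataset data.frame from [build_category_datasets()] (columns
#'   `image_id`, `category`, `label`, then features), or any data.frame
#'   with a two-level `label` column and numeric feature columns.
#' @param config a [model_config()].
#' @param category name recorded in the report.
#' @return an object of class `model_report`: list with `category`,
#'   `out_of_fold_scores` (named by image), `labels`, `auc`, `auc_ci`,
#'   `per_fold_auc`, `importance` (named, non-negative, one per feature),
#'   `config`.
#' @export
cross_validate <- function(dataset, config = model_config(),
                           category = "All") {
  stopifnot(inherits(config, "model_config"))
  y <- droplevels(factor(dataset$label, levels = c("low", "high")))
  if (nlevels(y) != 2L) stop_bad("dataset must contain both classes")
  feat_cols <- setdiff(names(dataset), c("image_id", "category", "label"))
  x <- as.matrix(dataset[, feat_cols, drop = FALSE])
  colnames(x) <- feat_cols
  ids <- dataset$image_id %||% as.character(seq_len(nrow(dataset)))
  if (min(table(y)) < config$k_folds) {
    stop_bad("dataset too small: minority class has ", min(table(y)),
             " samples but k_folds = ", config$k_folds)
  }

  set.seed(config$seed)
  fold <- stratified_folds(y, config$k_folds)
  scores <- numeric(length(y))
  per_fold_auc <- numeric(config$k_folds)
  imp <- matrix(0, nrow = length(feat_cols), ncol = config$k_folds,
                dimnames = list(feat_cols, NULL))
  perm <- config$importance_method == "permutation"
  for (f in seq_len(config$k_folds)) {
    tr <- fold != f
    xtr <- x[tr, , drop = FALSE]; ytr <- y[tr]
    if (config$oversample) {
      bal <- oversample_minority(xtr, ytr)
      xtr <- bal$x; ytr <- bal$y
    }
    rf <- randomForest::randomForest(x = xtr, y = ytr,
                                     ntree = config$n_trees,
                                     importance = perm)
    scores[!tr] <- predict(rf, x[!tr, , drop = FALSE],
                           type = "prob")[, "high"]
    per_fold_auc[f] <- compute_auc(scores[!tr], y[!tr])
    imp[, f] <- if (perm) {
      pmax(randomForest::importance(rf, type = 1, scale = FALSE)[, 1], 0)
    } else {
      randomForest::importance(rf, type = 2)[, 1]
    }
  }
  names(scores) <- ids
  ci <- auc_ci(scores, y, reps = config$bootstrap_reps)
  structure(
    list(category = category,
         out_of_fold_scores = scores,
         labels = y,
         auc = compute_auc(scores, y),
         auc_ci = ci,
         per_fold_auc = per_fold_auc,
         importance = rowMeans(imp),
         config = config),
    class = "model_report"
  )
}

#' @export
print.model_report <- function(x, ...) {
  cat(sprintf("<model_report> %s: AUC %.3f (95%% CI %.3f-%.3f), %d folds\n",
              x$category, x$auc, x$auc_ci[1], x$auc_ci[2],
              length(x$per_fold_auc)))
  invisible(x)
}
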