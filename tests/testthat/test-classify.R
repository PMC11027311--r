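test_that("minority oversampling balances the published cancer-type imbalance", {
  set.seed(2)
  x <- matrix(rnorm(616 * 3), 616, 3)
  y <- factor(rep(c("high", "low"), c(545, 71)), levels = c("low", "high"))
  bal <- oversample_minority(x, y)
  expect_equal(as.vector(table(bal$y)), c(545L, 545L))
  # duplicates are copies of original minority rows
  extra <- bal$x[617:nrow(bal$x), , drop = FALSE]
  orig <- x[y == "low", , drop = FALSE]
  expect_true(all(apply(extra, 1, function(r)
    any(colSums(abs(t(orig) - r)) == 0))))

  even <- oversample_minority(x[1:100, ],
                              factor(rep(c("high", "low"), 50)))
  expect_equal(nrow(even$x), 100)
})

test_that("AUC is the pairwise rank statistic", {
  expect_equal(compute_auc(c(0.9, 0.8, 0.1, 0.2),
                           c(TRUE, TRUE, FALSE, FALSE)), 1.0)
  expect_equal(compute_auc(rep(0.5, 10), rep(c(TRUE, FALSE), 5)), 0.5)
  expect_equal(compute_auc(c(0.7, 0.4, 0.6, 0.3),
                           c(TRUE, TRUE, FALSE, FALSE)), 0.75)
  expect_error(compute_auc(1:3, c(TRUE, TRUE, TRUE)), "both classes")
})

test_that("AUC matches the brute-force pairwise oracle (with ties)", {
  set.seed(4)
  for (i in 1:100) {
    n <- sample(6:40, 1)
    scores <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # forces ties
    pos <- runif(n) < 0.5
    if (!any(pos) || all(pos)) next
    expect_equal(compute_auc(scores, pos), oracle_auc(scores, pos),
                 tolerance = 1e-12)
  }
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(11)
  scores <- rnorm(60)
  pos <- runif(60) < 0.4
  expect_equal(compute_auc(scores, pos),
               as.numeric(pROC::auc(pROC::roc(pos, scores, quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-12)
})

test_that("bootstrap CI behaves at the extremes and contains the point AUC", {
  sep_scores <- c(rep(0.9, 20), rep(0.1, 20))
  sep_pos <- rep(c(TRUE, FALSE), each = 20)
  set.seed(6)
  ci <- auc_ci(sep_scores, sep_pos, reps = 200)
  expect_equal(ci, c(1, 1))

  set.seed(7)
  scores <- rnorm(200)
  pos <- rep(c(TRUE, FALSE), 100)
  ci0 <- auc_ci(scores, pos, reps = 1000)
  a <- compute_auc(scores, pos)
  expect_lte(ci0[1], a)
  expect_gte(ci0[2], a)
  expect_lt(ci0[1], 0.5)
  expect_gt(ci0[2], 0.5)
  expect_error(auc_ci(scores, pos, reps = 50), ">= 100")
})

make_toy_dataset <- function(n, separable = TRUE, seed = 1) {
  set.seed(seed)
  y <- factor(rep(c("low", "high"), each = n / 2), levels = c("low", "high"))
  x1 <- rnorm(n) + if (separable) ifelse(y == "high", 6, 0) else 0
  data.frame(image_id = sprintf("s%03d", seq_len(n)),
             category = "All", label = y,
             f1 = x1, f2 = rnorm(n), f3 = rnorm(n),
             stringsAsFactors = FALSE)
}

test_that("cross-validation recovers a perfectly separable signal", {
  d <- make_toy_dataset(200, separable = TRUE)
  cfg <- model_config(n_trees = 100, bootstrap_reps = 200, seed = 5)
  rep1 <- cross_validate(d, cfg)
  expect_equal(rep1$auc, 1.0)
  expect_length(rep1$out_of_fold_scores, 200)
  expect_length(rep1$importance, 3)
  expect_true(all(rep1$importance >= 0))
  expect_gt(rep1$importance[["f1"]], rep1$importance[["f2"]])

  # determinism under a fixed seed
  rep2 <- cross_validate(d, cfg)
  expect_identical(rep1$out_of_fold_scores, rep2$out_of_fold_scores)
  expect_identical(rep1$importance, rep2$importance)
  expect_identical(rep1$auc_ci, rep2$auc_ci)
})

test_that("every image is scored exactly once, out of fold", {
  d <- make_toy_dataset(120, separable = FALSE, seed = 3)
  cfg <- model_config(n_trees = 50, bootstrap_reps = 200, seed = 9)
  r <- cross_validate(d, cfg)
  expect_identical(sort(names(r$out_of_fold_scores)), sort(d$image_id))
  expect_length(r$per_fold_auc, 10)
})

test_that("fold sizing guards fire for degenerate datasets", {
  d <- make_toy_dataset(200, seed = 2)
  d$label[d$label == "low"] <- "high"
  expect_error(cross_validate(d, model_config()), "both classes")
  d2 <- make_toy_dataset(200, seed = 2)[c(1:5, 101:200), ]
  expect_error(cross_validate(d2, model_config(k_folds = 10)),
               "too small")
})

test_that("permutation importance is available and non-negative", {
  d <- make_toy_dataset(100, separable = TRUE, seed = 8)
  cfg <- model_config(n_trees = 50, k_folds = 5,
                      importance_method = "permutation",
                      bootstrap_reps = 200, seed = 4)
  r <- cross_validate(d, cfg)
  expect_true(all(r$importance >= 0))
  expect_gt(r$importance[["f1"]], r$importance[["f2"]])
})
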