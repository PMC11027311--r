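#' Average an observer panel
#'
#' The gist score of an image is the arithmetic mean of its observer
#' scores; averaging suppresses the per-observer noise of the gist signal.
#'
#' @param panel a `gist_panel` (or bare numeric vector of scores).
#' @return the mean score.
#' @export
average_panel <- function(panel) {
  scores <- if (inherits(panel, "gist_panel")) panel$scores else panel
  if (length(scores) == 0L) stop_bad("panel has no observer scores")
  mean(scores)
}

#' Quartile labeling of averaged gist scores
#'
#' Rank-based extreme-group design over the full image pool: the
#' `ceiling(n / 4)` highest-scoring images are labeled `high`, the
#' `ceiling(n / 4)` lowest `low`, and the middle half `excluded` (kept,
#' never silently dropped). Ties at either cut are broken by ascending
#' `image_id`, making the split deterministic. On a pool of 4191 distinct
#' scores this yields 1048 high- and 1048 low-gist images.
#'
#' @param mean_scores numeric vector of per-image averaged scores.
#' @param image_id image identifiers, same length (default generated).
#' @return data.frame: `image_id`, `mean_score`, `label` (factor with
#'   levels low / excluded / high), in the input order.
#' @export
quartile_split <- function(mean_scores, image_id = NULL) {
  n <- length(mean_scores)
  if (n < 4L) stop_bad("need at least 4 images to form quartiles")
  if (is.null(image_id)) image_id <- sprintf("img-%05d", seq_len(n))
  stopifnot(length(image_id) == n, !anyNA(mean_scores))
  k <- ceiling(n / 4)
  ord <- order(-mean_scores, image_id)   # descending score, id tie-break
  label <- rep("excluded", n)
  label[ord[seq_len(k)]] <- "high"
  label[ord[seq.int(n - k + 1L, n)]] <- "low"
  data.frame(image_id = image_id, mean_score = mean_scores,
             label = factor(label, levels = c("low", "excluded", "high")),
             stringsAsFactors = FALSE)
}

#' Materialize the eight per-category classification datasets
#'
#' Joins quartile labels with the feature table and builds one dataset per
#' model: `All` holds every non-excluded image (including any Prior-3
#' members, which are too rare for their own model); `Prior-1` holds the
#' union of `Missed`, `Prior-Visible` and `Prior-Invisible`; the remaining
#' six filter by their own category. Excluded (middle-half) images appear
#' in no dataset.
#'
#' @param labels data.frame from [quartile_split()] plus a `category`
#'   column (or pass `categories` separately).
#' @param feature_table data.frame from [extract_feature_table()].
#' @param categories optional per-image category vector aligned with
#'   `labels` (used if `labels` has no `category` column).
#' @return named list over the eight model categories; each element is a
#'   data.frame of feature columns plus `image_id`, `category`, `label`
#'   (factor low/high). Attribute `"class_counts"` summarizes per-dataset
#'   high/low counts.
#' @export
build_category_datasets <- function(labels, feature_table,
                                    categories = NULL) {
  if (!"category" %in% names(labels)) {
    stopifnot(!is.null(categories), length(categories) == nrow(labels))
    labels$category <- categories
  }
  kept <- labels[labels$label != "excluded", , drop = FALSE]
  missing <- setdiff(kept$image_id, feature_table$image_id)
  if (length(missing)) {
    stop_bad("no feature row for image(s): ",
             paste(head(missing, 10), collapse = ", "))
  }
  feats <- feature_table[match(kept$image_id, feature_table$image_id), ,
                         drop = FALSE]
  feats$category <- NULL
  base <- cbind(kept[, c("image_id", "category")],
                label = droplevels(factor(kept$label,
                                          levels = c("low", "high"))),
                feats[, setdiff(names(feats), "image_id"), drop = FALSE])
  pick <- function(cat) {
    sel <- switch(cat,
                  "All" = rep(TRUE, nrow(base)),
                  "Prior-1" = base$category %in% PRIOR1_MEMBERS,
                  base$category == cat)
    base[sel, , drop = FALSE]
  }
  out <- lapply(MODEL_CATEGORIES, pick)
  names(out) <- MODEL_CATEGORIES
  counts <- t(vapply(out, function(d) c(high = sum(d$label == "high"),
                                        low = sum(d$label == "low")),
                     numeric(2)))
  attr(out, "class_counts") <- counts
  out
}
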