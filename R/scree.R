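#' Scree-test selection of important features
#'
#' Elbow rule on the importance profile: sort the scores descending (ties
#' broken by the canonical feature order), take the 129 consecutive
#' differences, and cut at the first occurrence of the largest gap — the
#' "steep slope" of a scree plot. Features above the cut are selected. If
#' all scores are equal there is no gap and all features are selected.
#' The rule is parameter-free and invariant to shifting or positively
#' rescaling the scores.
#'
#' @param importance named numeric vector of finite, non-negative
#'   importance scores, one per feature.
#' @param n_features expected length (default 130); set `NULL` to skip the
#'   length check.
#' @return an object of class `scree_selection`: list with
#'   `ordered_features`, `sorted_scores`, `gaps`, `cut_index`, `selected`
#'   (feature names above the cut) and `families`
#'   (see [group_families()]).
#' @export
scree_select <- function(importance, n_features = 130) {
  if (is.null(names(importance)) || anyNA(names(importance))) {
    stop_bad("importance scores must be named by feature")
  }
  if (!is.null(n_features) && length(importance) != n_features) {
    stop_bad("expected ", n_features, " importance scores, got ",
             length(importance))
  }
  if (any(!is.finite(importance)) || any(importance < 0)) {
    stop_bad("importance scores must be finite and non-negative")
  }
  ord <- order(-importance, seq_along(importance))
  s <- unname(importance[ord])
  nm <- names(importance)[ord]
  gaps <- s[-length(s)] - s[-1]
  cut <- if (all(gaps == 0)) length(s) else which.max(gaps)
  sel <- nm[seq_len(cut)]
  fams <- if (all(sel %in% grf_feature_names())) group_families(sel)
  structure(list(ordered_features = nm, sorted_scores = s, gaps = gaps,
                 cut_index = cut, selected = sel,
                 families = fams),
            class = "scree_selection")
}

#' Group feature names into families
#'
#' Strips the pixel-distance suffix from GLCM feature names
#' (`Cluster_shade_9` to `Cluster_shade`), merges the three range
#' statistics (`Range_all`, `Range5`, `Range2`) into `Range`, and maps the
#' remaining first-order names to themselves; returns the distinct set.
#'
#' @param feature_names character vector following the 130-feature naming
#'   scheme.
#' @return character vector of distinct family names, in first-appearance
#'   order.
#' @export
group_families <- function(feature_names) {
  unique(feature_family(feature_names))
}

#' Per-feature family mapping
#'
#' Vectorized companion of [group_families()]: returns the family of each
#' feature name, without deduplication — convenient for aggregating
#' importance scores at the family level.
#'
#' @param feature_names character vector following the 130-feature naming
#'   scheme.
#' @return character vector of family names, one per input.
#' @export
feature_family <- function(feature_names) {
  all_names <- grf_feature_names()
  bad <- setdiff(feature_names, all_names)
  if (length(bad)) {
    stop_bad("unknown feature name(s): ", paste(head(bad, 5), collapse = ", "))
  }
  fam <- sub(paste0("_(", paste(GLCM_DISTANCES, collapse = "|"), ")$"), "",
             feature_names)
  fam[fam %in% c("Range_all", "Range5", "Range2")] <- "Range"
  fam
}

#' Family frequency across several scree selections
#'
#' For each feature family, the number of models whose scree selection
#' contains it; useful for spotting features that drive the gist signal in
#' most image categories.
#'
#' @param selections named list of [scree_select()] results (typically one
#'   per model category).
#' @return data.frame `family`, `n_models`, sorted by descending count
#'   (ties alphabetical).
#' @export
cross_model_summary <- function(selections) {
  fams <- unlist(lapply(selections, function(s) unique(s$families)))
  tab <- table(fams)
  out <- data.frame(family = names(tab), n_models = as.integer(tab),
                    stringsAsFactors = FALSE)
  out[order(-out$n_models, out$family), , drop = FALSE]
}

#' Published per-model feature-importance scores
#'
#' The 130-feature importance table reported for the eight gist
#' classifiers of the motivating mammography study (models `All`, `Normal`,
#' `Cancer`, `Missed`, `Prior-Visible`, `Prior-Invisible`, `Prior-1`,
#' `Prior-2`), with a `flagged` column marking the features the study
#' highlighted as important. Ships with the package as a plain CSV; used to
#' validate the scree rule against the published selection counts.
#'
#' @return data.frame: `feature`, one numeric column per model, `flagged`.
#' @export
reference_importances <- function() {
  path <- system.file("extdata", "reference_importances.csv",
                      package = "mammogist", mustWork = TRUE)
  read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}
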