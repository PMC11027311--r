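GLCM_STAT_NAMES <- c(
  "Autocorrelation", "Contrast", "Correlation_m", "Correlation_p",
  "Cluster_prominence", "Cluster_shade", "Dissimilarity", "Energy",
  "Entropy", "Homogeneity_m", "Homogeneity", "Maximum_probability",
  "Sum_of_squares_variance", "Sum_average", "Sum_variance", "Sum_entropy",
  "Difference_variance", "Difference_entropy",
  "Information_measure_of_correlation1",
  "Information_measure_of_correlation2",
  "Inverse_difference_normalized", "Inverse_difference_moment_normalized")

FOS_NAMES <- c(
  "Mean", "Standard_deviation", "Skewness", "Kurtosis", "Minimum",
  "5th_percentile", "10th_percentile", "15th_percentile", "20th_percentile",
  "25th_percentile", "Median", "75th_percentile", "80th_percentile",
  "85th_percentile", "90th_percentile", "95th_percentile", "Maximum",
  "Range_all", "Range5", "Range2")

GLCM_DISTANCES <- c(1L, 3L, 5L, 9L, 11L)

#' Names of the 130 global radiomic features
#'
#' 110 GLCM names — each of the 22 co-occurrence statistics suffixed with
#' the pixel distance, distances 1, 3, 5, 9, 11 nested within statistic —
#' followed by the 20 first-order names, in canonical table order.
#'
#' @param distances pixel distances for the GLCM block.
#' @return character vector of length 130.
#' @export
grf_feature_names <- function(distances = GLCM_DISTANCES) {
  glcm <- as.vector(t(outer(GLCM_STAT_NAMES, distances, paste, sep = "_")))
  c(glcm, FOS_NAMES)
}

#' Extract the 130 global radiomic features of one image
#'
#' Quantizes the ROI intensities to `n_levels` gray levels, computes one
#' angle-accumulated GLCM per pixel distance and its 22 statistics (110
#' features), then the 20 first-order statistics of the raw ROI
#' intensities.
#'
#' @param pixels gray-level matrix (typically preprocessed and cropped).
#' @param roi logical ROI matrix or `roi_mask`.
#' @param n_levels GLCM gray levels, default 8.
#' @param distances pixel distances, default `c(1, 3, 5, 9, 11)`.
#' @param symmetric symmetric pair counting, default `TRUE`.
#' @param log_base base for entropy-type statistics, default natural.
#' @param image_id identifier used in error messages.
#' @return named numeric vector of length 130 (all finite).
#' @export
extract_features <- function(pixels, roi, n_levels = 8,
                             distances = GLCM_DISTANCES, symmetric = TRUE,
                             log_base = exp(1), image_id = "") {
  m <- if (inherits(roi, "roi_mask")) roi$mask else roi
  q <- quantize_roi(pixels, m, n_levels)
  glcm_part <- unlist(lapply(distances, function(d) {
    g <- tryCatch(compute_glcm(q, d, symmetric = symmetric),
                  error = function(e) {
                    stop_bad(conditionMessage(e),
                             if (nzchar(image_id))
                               paste0(" (image ", image_id, ")") else "")
                  })
    s <- glcm_statistics(g, log_base)
    names(s) <- paste(names(s), d, sep = "_")
    s
  }))
  out <- c(glcm_part, fos_statistics(pixels[m]))
  out <- out[grf_feature_names(distances)]
  stopifnot(!anyNA(out), all(is.finite(out)))
  out
}

#' Feature table for a whole cohort
#'
#' Runs preprocessing (laterality flip, threshold mask, crop), ROI erosion
#' (radius scaled to image rows, see [scale_erosion_radius()]) and
#' [extract_features()] for every image, returning one row per image.
#'
#' @param images list of `cohort_image` objects.
#' @param threshold segmentation gray level, default 100.
#' @param base_radius,base_rows erosion radius policy, see
#'   [scale_erosion_radius()].
#' @param ... passed on to [extract_features()].
#' @return data.frame: `image_id`, `category`, then the 130 feature columns.
#' @export
extract_feature_table <- function(images, threshold = 100,
                                  base_radius = 100, base_rows = 2800, ...) {
  rows <- lapply(images, function(img) {
    pre <- preprocess_image(img, threshold)
    r <- scale_erosion_radius(nrow(pre$pixels), base_radius, base_rows)
    roi <- erode_mask(pre$mask, r, parent_id = img$image_id)
    extract_features(pre$pixels, roi, image_id = img$image_id, ...)
  })
  feat <- do.call(rbind, rows)
  out <- data.frame(
    image_id = vapply(images, function(i) i$image_id, character(1)),
    category = vapply(images, function(i) i$category, character(1)),
    stringsAsFactors = FALSE, check.names = FALSE
  )
  cbind(out, as.data.frame(feat, check.names = FALSE))
}
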