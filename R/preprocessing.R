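#' Breast mask by gray-level thresholding
#'
#' A pixel belongs to the breast iff its gray level is at least `threshold`
#' (default 100, the conventional cut separating the vendor-rendered dark
#' background from breast tissue on 8-bit mammograms). For 16-bit inputs the
#' threshold applies on the native scale and should be set accordingly.
#'
#' @param pixels numeric matrix of gray levels.
#' @param threshold gray level; pixels `>= threshold` are foreground.
#' @param image_id identifier used in error messages.
#' @return an object of class `breast_mask`: list with `mask` (logical
#'   matrix congruent with `pixels`), `threshold_used`, `source_image_id`.
#' @export
threshold_mask <- function(pixels, threshold = 100, image_id = "") {
  if (!is.matrix(pixels) || length(pixels) == 0L) {
    stop_bad("pixels must be a non-empty matrix")
  }
  mask <- pixels >= threshold
  if (!any(mask)) {
    stop_bad("no breast region: no pixel >= ", threshold,
             if (nzchar(image_id)) paste0(" in image ", image_id) else "")
  }
  structure(list(mask = mask, threshold_used = threshold,
                 source_image_id = image_id),
            class = "breast_mask")
}

#' Standardize image laterality
#'
#' Right-breast images are mirrored about the vertical axis and relabeled
#' `"L"`, so the chest wall sits on the left edge of every image; left
#' images pass through unchanged.
#'
#' @param image a `cohort_image`.
#' @return the image, with `laterality == "L"`.
#' @export
standardize_laterality <- function(image) {
  if (!image$laterality %in% c("L", "R")) {
    stop_bad("unknown laterality '", image$laterality, "'")
  }
  if (image$laterality == "R") {
    image$pixels <- image$pixels[, rev(seq_len(ncol(image$pixels))),
                                 drop = FALSE]
    image$laterality <- "L"
  }
  image
}

#' Crop image and mask to the breast bounding box
#'
#' Cuts both to the tight bounding box of true mask pixels; the relative
#' geometry of image and mask is preserved.
#'
#' @param pixels gray-level matrix.
#' @param mask a `breast_mask` (or bare logical matrix of the same shape).
#' @return list with cropped `pixels` and logical `mask`.
#' @export
crop_to_breast <- function(pixels, mask) {
  m <- if (inherits(mask, "breast_mask")) mask$mask else mask
  stopifnot(identical(dim(m), dim(pixels)))
  if (!any(m)) stop_bad("no breast region: empty mask")
  rows <- range(which(rowSums(m) > 0))
  cols <- range(which(colSums(m) > 0))
  list(pixels = pixels[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE],
       mask = m[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE])
}

#' Preprocess one image: flip, mask, crop
#'
#' Convenience wrapper chaining [standardize_laterality()],
#' [threshold_mask()] and [crop_to_breast()].
#'
#' @param image a `cohort_image`.
#' @param threshold segmentation gray level, default 100.
#' @return list with `pixels`, `mask` (both cropped) and `image_id`.
#' @export
preprocess_image <- function(image, threshold = 100) {
  image <- standardize_laterality(image)
  bm <- threshold_mask(image$pixels, threshold, image$image_id)
  out <- crop_to_breast(image$pixels, bm)
  out$image_id <- image$image_id
  out
}
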