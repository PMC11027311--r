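#' Euclidean disk structuring element
#'
#' The element contains offset `(dx, dy)` iff `dx^2 + dy^2 <= radius^2`,
#' with the origin at the center — the exact Euclidean disk, not a
#' decomposed approximation.
#'
#' @param radius non-negative integer, in pixels (distance from the origin
#'   to the edge of the disk).
#' @return logical matrix of size `(2 * radius + 1)^2`.
#' @export
disk_element <- function(radius) {
  if (length(radius) != 1L || !is.finite(radius) || radius < 0 ||
      radius != round(radius)) {
    stop_bad("radius must be a single non-negative integer")
  }
  d <- -radius:radius
  outer(d^2, d^2, `+`) <= radius^2
}

#' Binary erosion with a disk structuring element
#'
#' An output pixel is true iff every disk offset from it lands on a true
#' mask pixel; positions outside the image count as background, so erosion
#' also shrinks the mask away from the image borders. This removes the
#' vendor-enhanced skin–air margin of the breast, leaving the interior
#' tissue region over which features are computed.
#'
#' Implemented through an exact Euclidean distance transform: a pixel
#' survives iff its squared distance to the nearest background pixel
#' (including the virtual border) exceeds `radius^2`. Squared Euclidean
#' distances between pixel centers are integers, so the comparison is exact.
#'
#' @param mask a `breast_mask` or logical matrix.
#' @param radius disk radius in pixels. The conventional value for
#'   full-resolution mammograms (about 2800 rows) is 100; see
#'   [scale_erosion_radius()] for smaller images.
#' @param parent_id identifier of the parent mask, for error messages.
#' @return an object of class `roi_mask`: list with `mask` (logical),
#'   `erosion_radius`, `parent_mask_id`.
#' @export
erode_mask <- function(mask, radius, parent_id = "") {
  m <- if (inherits(mask, "breast_mask")) mask$mask else mask
  if (inherits(mask, "breast_mask") && !nzchar(parent_id)) {
    parent_id <- mask$source_image_id
  }
  if (!any(m)) stop_bad("cannot erode an empty mask")
  if (length(radius) != 1L || radius < 0 || radius != round(radius)) {
    stop_bad("radius must be a single non-negative integer")
  }
  nr <- nrow(m); nc <- ncol(m)
  padded <- matrix(0L, nr + 2L, nc + 2L)
  padded[2:(nr + 1), 2:(nc + 1)] <- m
  d <- EBImage::distmap(padded, metric = "euclidean")
  d2 <- round(d[2:(nr + 1), 2:(nc + 1)]^2)
  out <- m & (d2 > radius^2)
  if (!any(out)) {
    stop_bad("ROI empty at radius ", radius,
             if (nzchar(parent_id)) paste0(" (mask ", parent_id, ")") else "",
             "; use a smaller radius")
  }
  structure(list(mask = out, erosion_radius = radius,
                 parent_mask_id = parent_id),
            class = "roi_mask")
}

#' Scale the erosion radius to image size
#'
#' The 100-pixel disk is tied to clinical resolution (roughly 2800 image
#' rows); smaller images keep a proportional skin–air margin via
#' `round(base_radius * rows / base_rows)`.
#'
#' @param rows number of image rows.
#' @param base_radius radius at reference resolution (default 100).
#' @param base_rows reference number of rows (default 2800).
#' @return non-negative integer radius.
#' @export
scale_erosion_radius <- function(rows, base_radius = 100, base_rows = 2800) {
  max(0L, as.integer(round(base_radius * rows / base_rows)))
}
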