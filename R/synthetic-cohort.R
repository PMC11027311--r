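#' Parameters for a synthetic gist-study cohort
#'
#' Bundles the design constants of the emulated observer study — 13 readers
#' scoring each image on a 0–100 abnormality scale, eight image categories —
#' with the knobs of the texture generator. The planted `texture_effect`
#' components shift, for images with a high latent gist, the co-occurrence
#' asymmetry (cluster shade), the first-order intensity spread, and the
#' intensity skewness of the breast interior, so that downstream features
#' carry a recoverable association with the gist labels.
#'
#' @param n_images number of images in the cohort.
#' @param category_mix named proportions over the seven disjoint generative
#'   categories (`Normal`, `Cancer`, `Missed`, `Prior-Visible`,
#'   `Prior-Invisible`, `Prior-2`, `Prior-3`; the middle three together form
#'   `Prior-1`). Must sum to 1. Defaults follow the per-category image counts
#'   of the motivating screening cohort (4191 images).
#' @param texture_effect named numeric with components `cluster_shade`,
#'   `spread` and `skew`. `spread` is in gray levels (added to the interior
#'   standard deviation at latent gist 100); `cluster_shade` and `skew` are
#'   dimensionless coefficients of an asymmetric intensity warp. Each effect
#'   enters scaled by `latent_gist / 100`.
#' @param observer_count number of observers in the panel (default 13).
#' @param observer_noise_sd standard deviation, in score units on the 0–100
#'   scale, of the Gaussian observer noise around the latent gist.
#' @param image_shape integer `(rows, cols)`; at least 64 x 64.
#' @param background_level background gray level, strictly below the breast
#'   segmentation threshold of 100.
#' @param high_gist_weight named per-category probability that an image's
#'   latent gist is drawn from the high mixture component (see
#'   [generate_cohort()]).
#' @param seed integer seed controlling all cohort randomness.
#'
#' @return an object of class `synthetic_params`.
#' @seealso [generate_cohort()], [generate_image()], [generate_panel()]
#' @export
synthetic_params <- function(n_images = 400,
                             category_mix = NULL,
                             texture_effect = c(cluster_shade = 0.5,
                                                spread = 30,
                                                skew = 0),
                             observer_count = 13,
                             observer_noise_sd = 10,
                             image_shape = c(128L, 96L),
                             background_level = 40,
                             high_gist_weight = NULL,
                             seed = 1L) {
  if (is.null(category_mix)) {
    # per-category counts of the motivating 4191-image screening cohort
    counts <- c("Normal" = 1409, "Cancer" = 923, "Missed" = 375,
                "Prior-Visible" = 308, "Prior-Invisible" = 755,
                "Prior-2" = 419, "Prior-3" = 2)
    category_mix <- counts / sum(counts)
  }
  if (is.null(high_gist_weight)) {
    # emulates the observed asymmetry of extreme-quartile membership across
    # categories (e.g. cancer-containing images mostly score high)
    high_gist_weight <- c("Normal" = 0.25, "Cancer" = 0.88, "Missed" = 0.59,
                          "Prior-Visible" = 0.46, "Prior-Invisible" = 0.29,
                          "Prior-2" = 0.40, "Prior-3" = 0.50)
  }
  if (!setequal(names(category_mix), BASE_CATEGORIES)) {
    stop_bad("category_mix must be named over the seven base categories: ",
             paste(BASE_CATEGORIES, collapse = ", "))
  }
  category_mix <- category_mix[BASE_CATEGORIES]
  if (any(category_mix < 0) || abs(sum(category_mix) - 1) > 1e-9) {
    stop_bad("category_mix must be non-negative and sum to 1")
  }
  if (!setequal(names(high_gist_weight), BASE_CATEGORIES)) {
    stop_bad("high_gist_weight must be named over the seven base categories")
  }
  high_gist_weight <- high_gist_weight[BASE_CATEGORIES]
  needed <- c("cluster_shade", "spread", "skew")
  if (!all(needed %in% names(texture_effect))) {
    stop_bad("texture_effect needs components: ",
             paste(needed, collapse = ", "))
  }
  assert_scalar_number(observer_count, "observer_count", min = 1)
  assert_scalar_number(observer_noise_sd, "observer_noise_sd", min = 0)
  assert_scalar_number(background_level, "background_level", min = 0)
  if (background_level >= 100) {
    stop_bad("background_level must be < 100 so that thresholding at 100 ",
             "recovers the breast foreground")
  }
  image_shape <- as.integer(image_shape)
  if (length(image_shape) != 2L || any(image_shape < 64L)) {
    stop_bad("image_shape must be (rows, cols) with both >= 64")
  }
  structure(
    list(n_images = as.integer(n_images),
         category_mix = category_mix,
         texture_effect = texture_effect[needed],
         observer_count = as.integer(observer_count),
         observer_noise_sd = observer_noise_sd,
         image_shape = image_shape,
         background_level = background_level,
         high_gist_weight = high_gist_weight,
         seed = as.integer(seed)),
    class = "synthetic_params"
  )
}

# separable box-kernel smoothing of a white-noise field; gives spatially
# correlated texture so that co-occurrence statistics are non-trivial
smooth_field <- function(z, width = 5L) {
  k <- rep(1 / width, width)
  z <- apply(z, 2, function(col) stats::filter(col, k, circular = TRUE))
  t(apply(z, 1, function(row) stats::filter(row, k, circular = TRUE)))
}

breast_outline <- function(shape, laterality) {
  nr <- shape[1]; nc <- shape[2]
  r0 <- (nr + 1) / 2
  a <- 0.45 * nr          # vertical semi-axis
  b <- 0.72 * nc          # horizontal semi-axis, anchored at the chest wall
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  x <- if (laterality == "L") cc - 1 else nc - cc
  ((rr - r0) / a)^2 + (x / b)^2 <= 1
}

#' Generate one synthetic breast image
#'
#' Draws a half-elliptical breast foreground anchored at the chest-wall edge
#' (left edge for laterality `"L"`, right for `"R"`) over a dark background.
#' The interior is spatially correlated Gaussian texture passed through an
#' asymmetric quadratic warp; the `texture_effect` components of `params`,
#' each scaled by `latent_gist / 100`, widen the intensity spread and skew
#' the intensity distribution of high-latent-gist images. Foreground pixels
#' are clamped to `[100, 255]`, background pixels stay strictly below 100,
#' so segmentation by thresholding at 100 is exact.
#'
#' Consumes the ambient RNG stream; seed it (or use [generate_cohort()],
#' which does) for reproducibility.
#'
#' @param params a [synthetic_params()] object.
#' @param category one of the seven base category names.
#' @param latent_gist latent gist score in `[0, 100]` (ground truth, hidden
#'   from the analysis pipeline).
#' @param laterality `"L"` or `"R"`.
#' @param image_id identifier string.
#' @return an object of class `cohort_image`: list with `image_id`, `pixels`
#'   (integer matrix, 8-bit range), `laterality`, `category`, `latent_gist`.
#' @export
generate_image <- function(params, category, latent_gist,
                           laterality = "L", image_id = "img-1") {
  if (!category %in% BASE_CATEGORIES) {
    stop_bad("unknown category '", category, "'")
  }
  if (!laterality %in% c("L", "R")) stop_bad("laterality must be 'L' or 'R'")
  if (latent_gist < 0 || latent_gist > 100) {
    stop_bad("latent_gist must lie in [0, 100]")
  }
  shape <- params$image_shape
  fg <- breast_outline(shape, laterality)

  f <- latent_gist / 100
  eff <- params$texture_effect
  # per-image nuisance variation: overall brightness and base texture scale
  # differ across breasts independently of gist, so only the planted effect
  # families carry the gist signal
  mu_fg <- rnorm(1, 177, 8)
  sd_base <- max(6, rnorm(1, 12, 1.5))
  z <- smooth_field(matrix(rnorm(prod(shape)), shape[1], shape[2]))
  z <- (z - mean(z)) / sd(as.vector(z))
  # asymmetric warp: zero-mean quadratic term plants positive skewness in
  # the marginal histogram, which the co-occurrence cluster shade picks up
  cwarp <- (eff[["cluster_shade"]] + eff[["skew"]]) * f + rnorm(1, 0, 0.05)
  w <- z + cwarp * (z^2 - 1) / 2
  w <- (w - mean(w)) / sd(as.vector(w))
  # smooth monotone squash bounds the field before the spread is applied,
  # so intensities stay inside [100, 255] by construction: the spread then
  # scales the histogram linearly and min-max quantization cancels it for
  # the co-occurrence features, keeping the planted knobs decoupled
  w <- 1.6 * tanh(w / 1.6)

  sd_fg <- sd_base + eff[["spread"]] * f
  vals <- round(mu_fg + sd_fg * w)
  vals <- pmin(pmax(vals, 100), 255)

  bg <- round(params$background_level + rnorm(prod(shape), sd = 4))
  bg <- pmin(pmax(bg, 0), 99)

  pixels <- matrix(as.integer(ifelse(fg, vals, bg)), shape[1], shape[2])
  structure(
    list(image_id = image_id, pixels = pixels, laterality = laterality,
         category = category, latent_gist = latent_gist),
    class = "cohort_image"
  )
}

#' Generate a synthetic observer panel for one image
#'
#' Each of the `observer_count` observers reports
#' `clip(latent_gist + N(0, observer_noise_sd), 0, 100)`; the panel mean is
#' recomputed from the realized scores. Uses the ambient RNG stream.
#'
#' @param image a `cohort_image`.
#' @param params a [synthetic_params()] object.
#' @return an object of class `gist_panel`: list with `image_id`, `scores`
#'   (length `observer_count`, each in `[0, 100]`) and `mean_score`.
#' @export
generate_panel <- function(image, params) {
  g <- image$latent_gist
  scores <- g + rnorm(params$observer_count, sd = params$observer_noise_sd)
  scores <- pmin(pmax(scores, 0), 100)
  structure(
    list(image_id = image$image_id, scores = scores,
         mean_score = mean(scores)),
    class = "gist_panel"
  )
}

# latent gist: truncated-Gaussian mixture, components N(25, 10) and
# N(75, 10) truncated to [0, 100], mixed with a category-specific weight on
# the high component (inverse-CDF sampling, fully deterministic given RNG)
rtruncnorm01 <- function(n, mean, sd, lo = 0, hi = 100) {
  plo <- pnorm(lo, mean, sd)
  phi <- pnorm(hi, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

#' Generate a full synthetic cohort
#'
#' Draws categories from `params$category_mix`, lateralities uniformly,
#' latent gist scores from a two-component truncated-Gaussian mixture
#' (means 25 and 75, sd 10, truncated to `[0, 100]`) whose weight on the
#' high component is category-specific (`params$high_gist_weight`), then
#' generates images and observer panels. All randomness derives from
#' `params$seed`; identical parameters reproduce the cohort bit for bit.
#'
#' @param params a [synthetic_params()] object with `n_images >= 8`.
#' @param images if `FALSE`, skip pixel generation and return only the
#'   manifest and panels (useful for design-level checks on large n).
#' @return list with `images` (list of `cohort_image`, or `NULL`), `panels`
#'   (list of `gist_panel`), and `manifest` (data.frame: `image_id`,
#'   `laterality`, `category`, `latent_gist`, `mean_score`) carrying the
#'   generating parameters as attribute `"params"`.
#' @export
generate_cohort <- function(params, images = TRUE) {
  stopifnot(inherits(params, "synthetic_params"))
  if (params$n_images < 8L) stop_bad("n_images must be >= 8")
  if (any(params$category_mix == 1)) {
    message("degenerate category_mix: all mass on one category")
  }
  n <- params$n_images
  set.seed(params$seed)

  ids <- sprintf("img-%05d", seq_len(n))
  category <- sample(BASE_CATEGORIES, n, replace = TRUE,
                     prob = params$category_mix)
  laterality <- sample(c("L", "R"), n, replace = TRUE)
  whigh <- params$high_gist_weight[category]
  comp_high <- runif(n) < whigh
  latent <- ifelse(comp_high,
                   rtruncnorm01(n, 75, 10),
                   rtruncnorm01(n, 25, 10))

  imgs <- vector("list", n)
  panels <- vector("list", n)
  for (i in seq_len(n)) {
    img <- if (images) {
      generate_image(params, category[i], latent[i], laterality[i], ids[i])
    } else {
      structure(list(image_id = ids[i], pixels = NULL,
                     laterality = laterality[i], category = category[i],
                     latent_gist = latent[i]),
                class = "cohort_image")
    }
    imgs[[i]] <- img
    panels[[i]] <- generate_panel(img, params)
  }
  manifest <- data.frame(
    image_id = ids,
    laterality = laterality,
    category = category,
    latent_gist = latent,
    mean_score = vapply(panels, function(p) p$mean_score, numeric(1)),
    stringsAsFactors = FALSE
  )
  attr(manifest, "params") <- params
  list(images = if (images) imgs else NULL,
       panels = panels,
       manifest = manifest)
}

#' Write a cohort to disk
#'
#' Images go out as 8-bit grayscale TIFF (one file per image), the manifest
#' and the observer panels as CSV (`observer_1 ... observer_k`, then
#' `mean_score`).
#'
#' @param cohort result of [generate_cohort()] (with pixel data).
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(cohort$images)) {
    img_dir <- file.path(dir, "images")
    dir.create(img_dir, showWarnings = FALSE)
    for (img in cohort$images) {
      tiff::writeTIFF(img$pixels / 255,
                      file.path(img_dir, paste0(img$image_id, ".tif")),
                      bits.per.sample = 8L)
    }
  }
  man <- cohort$manifest
  write.csv(man[, c("image_id", "laterality", "category", "latent_gist")],
            file.path(dir, "manifest.csv"), row.names = FALSE)
  write.csv(panels_to_df(cohort$panels), file.path(dir, "panels.csv"),
            row.names = FALSE)
  invisible(dir)
}

panels_to_df <- function(panels) {
  k <- length(panels[[1]]$scores)
  scores <- t(vapply(panels, function(p) p$scores, numeric(k)))
  colnames(scores) <- paste0("observer_", seq_len(k))
  data.frame(image_id = vapply(panels, function(p) p$image_id, character(1)),
             scores,
             mean_score = vapply(panels, function(p) p$mean_score,
                                 numeric(1)),
             stringsAsFactors = FALSE, check.names = FALSE)
}
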