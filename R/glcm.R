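#' Quantize ROI intensities to discrete gray levels
#'
#' Linear binning of the ROI intensity range `[min, max]` into `n_levels`
#' equal-width bins, 1-based; the maximum maps to bin `n_levels`. A constant
#' ROI maps everything to level 1. Pixels outside the ROI are `NA`.
#'
#' @param pixels gray-level matrix.
#' @param mask logical ROI matrix (or `roi_mask`), same shape as `pixels`.
#' @param n_levels number of gray levels `N_g` (>= 2), default 8.
#' @return an object of class `quantized_roi`: list with `levels` (integer
#'   matrix, `NA` off-ROI), `n_levels`, `range` (source lo, hi).
#' @export
quantize_roi <- function(pixels, mask, n_levels = 8) {
  m <- if (inherits(mask, "roi_mask")) mask$mask else mask
  stopifnot(identical(dim(m), dim(pixels)))
  if (!any(m)) stop_bad("ROI is empty")
  if (n_levels < 2) stop_bad("n_levels must be >= 2")
  v <- pixels[m]
  lo <- min(v); hi <- max(v)
  lev <- matrix(NA_integer_, nrow(pixels), ncol(pixels))
  if (lo == hi) {
    lev[m] <- 1L
  } else {
    lev[m] <- pmin(as.integer(floor((v - lo) / (hi - lo) * n_levels)) + 1L,
                   as.integer(n_levels))
  }
  structure(list(levels = lev, n_levels = as.integer(n_levels),
                 range = c(lo, hi)),
            class = "quantized_roi")
}

# (drow, dcol) offsets of the four standard co-occurrence angles at
# distance d: 0, 45, 90, 135 degrees
angle_offsets <- function(d, angles) {
  all <- list(`0` = c(0L, d), `45` = c(-d, d),
              `90` = c(-d, 0L), `135` = c(-d, -d))
  bad <- setdiff(as.character(angles), names(all))
  if (length(bad)) stop_bad("unknown angle(s): ", paste(bad, collapse = ", "))
  all[as.character(angles)]
}

#' Gray-level co-occurrence matrix over an ROI
#'
#' Counts ordered pairs of gray levels at the given pixel distance along
#' the requested angles (default all four: 0, 45, 90, 135 degrees),
#' accumulated into a single matrix per distance. A pair is counted only if
#' both pixels lie inside the ROI. With `symmetric = TRUE` (the usual
#' Haralick convention) every pair is also counted in reverse, making the
#' matrix exactly symmetric. Counts are normalized to probabilities.
#'
#' @param q a [quantize_roi()] result.
#' @param distance pixel distance `d >= 1` between a pixel and its
#'   neighbour.
#' @param angles subset of `c(0, 45, 90, 135)`.
#' @param symmetric count each pair in both directions (default `TRUE`).
#' @return an object of class `glcm`: list with `p` (`N_g x N_g` matrix of
#'   pair probabilities summing to 1), `distance`, `angles`, `symmetric`,
#'   `pair_count`.
#' @export
compute_glcm <- function(q, distance, angles = c(0, 45, 90, 135),
                         symmetric = TRUE) {
  stopifnot(inherits(q, "quantized_roi"))
  d <- as.integer(distance)
  if (d < 1L) stop_bad("distance must be >= 1")
  ng <- q$n_levels
  lev <- q$levels
  nr <- nrow(lev); nc <- ncol(lev)
  counts <- matrix(0, ng, ng)
  total <- 0L
  for (off in angle_offsets(d, angles)) {
    dr <- off[1]; dc <- off[2]
    rlo <- max(1L, 1L - dr); rhi <- min(nr, nr - dr)
    clo <- max(1L, 1L - dc); chi <- min(nc, nc - dc)
    if (rlo > rhi || clo > chi) next
    r1 <- rlo:rhi
    c1 <- clo:chi
    a <- lev[r1, c1, drop = FALSE]
    b <- lev[r1 + dr, c1 + dc, drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) next
    idx <- a[ok] + (b[ok] - 1L) * ng
    tab <- tabulate(idx, nbins = ng * ng)
    counts <- counts + matrix(tab, ng, ng)
    total <- total + sum(tab)
  }
  if (total == 0L) {
    stop_bad("empty GLCM: no valid pixel pairs at distance ", d)
  }
  if (symmetric) {
    counts <- counts + t(counts)
    total <- 2L * total
  }
  structure(list(p = counts / total, distance = d, angles = angles,
                 symmetric = symmetric, pair_count = total),
            class = "glcm")
}

#' The 22 co-occurrence texture statistics
#'
#' Computes, from a normalized GLCM, the 22-statistic Haralick-style
#' formulary: autocorrelation, contrast, two correlation variants, cluster
#' prominence, cluster shade, dissimilarity, energy, entropy, two
#' homogeneity variants, maximum probability, sum-of-squares variance, sum
#' average/variance/entropy, difference variance/entropy, the two
#' information measures of correlation, and the two normalized inverse
#' difference statistics. Entropies use `0 log 0 = 0` and the natural
#' logarithm by default.
#'
#' Degenerate cases are kept finite for classifier input: when the marginal
#' standard deviations vanish both correlations are 0, and the information
#' measures fall back to 0 when their guards (zero marginal entropy,
#' negative radicand) trigger.
#'
#' @param g a [compute_glcm()] result (or a bare normalized matrix).
#' @param log_base base of the logarithm for entropy-type statistics
#'   (default `exp(1)`; use 2 for bits).
#' @return named numeric vector of length 22, in canonical feature order.
#' @export
glcm_statistics <- function(g, log_base = exp(1)) {
  p <- if (inherits(g, "glcm")) g$p else g
  ng <- nrow(p)
  stopifnot(ncol(p) == ng, abs(sum(p) - 1) < 1e-6)
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  lv <- seq_len(ng)

  px <- rowSums(p); py <- colSums(p)
  mux <- sum(lv * px); muy <- sum(lv * py)
  sigx <- sqrt(sum((lv - mux)^2 * px))
  sigy <- sqrt(sum((lv - muy)^2 * py))

  # diagonal-band marginals p_{x+y}, p_{x-y}
  ks <- 2:(2 * ng)
  psum <- vapply(ks, function(k) sum(p[i + j == k]), numeric(1))
  kd <- 0:(ng - 1)
  pdiff <- vapply(kd, function(k) sum(p[abs(i - j) == k]), numeric(1))

  acor <- sum(i * j * p)
  corr <- if (sigx * sigy == 0) c(0, 0) else c(
    (acor - mux * muy) / (sigx * sigy),
    sum((i - mux) * (j - muy) * p) / (sigx * sigy)
  )

  hx <- -sum(xlogx(px, log_base))
  hy <- -sum(xlogx(py, log_base))
  hxy <- -sum(xlogx(p, log_base))
  pxy <- outer(px, py)
  lpxy <- matrix(0, ng, ng)
  pos <- pxy > 0
  lpxy[pos] <- log(pxy[pos], base = log_base)
  hxy1 <- -sum(p * lpxy)
  hxy2 <- -sum(xlogx(pxy, log_base))
  imc1 <- if (max(hx, hy) == 0) 0 else (hxy - hxy1) / max(hx, hy)
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy))))

  sa <- sum(ks * psum)
  mud <- sum(kd * pdiff)

  c(Autocorrelation = acor,
    Contrast = sum((i - j)^2 * p),
    Correlation_m = corr[1],
    Correlation_p = corr[2],
    Cluster_prominence = sum((i + j - mux - muy)^4 * p),
    Cluster_shade = sum((i + j - mux - muy)^3 * p),
    Dissimilarity = sum(abs(i - j) * p),
    Energy = sum(p^2),
    Entropy = hxy,
    Homogeneity_m = sum(p / (1 + abs(i - j))),
    Homogeneity = sum(p / (1 + (i - j)^2)),
    Maximum_probability = max(p),
    Sum_of_squares_variance = sum((i - mux)^2 * p),
    Sum_average = sa,
    Sum_variance = sum((ks - sa)^2 * psum),
    Sum_entropy = -sum(xlogx(psum, log_base)),
    Difference_variance = sum((kd - mud)^2 * pdiff),
    Difference_entropy = -sum(xlogx(pdiff, log_base)),
    Information_measure_of_correlation1 = imc1,
    Information_measure_of_correlation2 = imc2,
    Inverse_difference_normalized = sum(p / (1 + abs(i - j) / ng)),
    Inverse_difference_moment_normalized = sum(p / (1 + ((i - j) / ng)^2)))
}
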