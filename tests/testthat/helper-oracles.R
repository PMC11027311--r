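# Independent brute-force reference implementations, written as plain
# double loops so they share no code path with the package.

oracle_erode <- function(mask, r) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ok <- TRUE
    for (dx in -r:r) {
      for (dy in -r:r) {
        if (dx * dx + dy * dy > r * r) next
        ii <- i + dx; jj <- j + dy
        if (ii < 1 || ii > nr || jj < 1 || jj > nc || !mask[ii, jj]) {
          ok <- FALSE
          break
        }
      }
      if (!ok) break
    }
    out[i, j] <- ok
  }
  out
}

# pair counting by explicit enumeration; levels has NA outside the ROI
oracle_glcm <- function(levels, ng, d, angles = c(0, 45, 90, 135),
                        symmetric = TRUE) {
  offs <- list(`0` = c(0, d), `45` = c(-d, d), `90` = c(-d, 0),
               `135` = c(-d, -d))[as.character(angles)]
  counts <- matrix(0, ng, ng)
  nr <- nrow(levels); nc <- ncol(levels)
  for (off in offs) {
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      ii <- i + off[1]; jj <- j + off[2]
      if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
      a <- levels[i, j]; b <- levels[ii, jj]
      if (is.na(a) || is.na(b)) next
      counts[a, b] <- counts[a, b] + 1
    }
  }
  if (symmetric) counts <- counts + t(counts)
  counts / sum(counts)
}

oracle_glcm_stats <- function(p, base = exp(1)) {
  ng <- nrow(p)
  lg <- function(x) if (x > 0) log(x, base = base) else 0
  px <- rowSums(p); py <- colSums(p)
  mux <- 0; muy <- 0
  for (i in 1:ng) { mux <- mux + i * px[i]; muy <- muy + i * py[i] }
  sigx <- sqrt(sum(((1:ng) - mux)^2 * px))
  sigy <- sqrt(sum(((1:ng) - muy)^2 * py))
  acor <- 0; contrast <- 0; cp <- 0; cs <- 0; dis <- 0; energy <- 0
  ent <- 0; hom_m <- 0; hom <- 0; ssv <- 0; idn <- 0; idmn <- 0
  corr_p <- 0
  for (i in 1:ng) for (j in 1:ng) {
    v <- p[i, j]
    acor <- acor + i * j * v
    contrast <- contrast + (i - j)^2 * v
    cp <- cp + (i + j - mux - muy)^4 * v
    cs <- cs + (i + j - mux - muy)^3 * v
    dis <- dis + abs(i - j) * v
    energy <- energy + v^2
    ent <- ent - v * lg(v)
    hom_m <- hom_m + v / (1 + abs(i - j))
    hom <- hom + v / (1 + (i - j)^2)
    ssv <- ssv + (i - mux)^2 * v
    idn <- idn + v / (1 + abs(i - j) / ng)
    idmn <- idmn + v / (1 + ((i - j) / ng)^2)
    corr_p <- corr_p + (i - mux) * (j - muy) * v
  }
  psum <- numeric(2 * ng - 1)  # index k - 1 for k in 2..2ng
  pdiff <- numeric(ng)         # index k + 1 for k in 0..ng-1
  for (i in 1:ng) for (j in 1:ng) {
    psum[i + j - 1] <- psum[i + j - 1] + p[i, j]
    pdiff[abs(i - j) + 1] <- pdiff[abs(i - j) + 1] + p[i, j]
  }
  sa <- 0; for (k in 2:(2 * ng)) sa <- sa + k * psum[k - 1]
  sv <- 0; se <- 0
  for (k in 2:(2 * ng)) {
    sv <- sv + (k - sa)^2 * psum[k - 1]
    se <- se - psum[k - 1] * lg(psum[k - 1])
  }
  mud <- 0; for (k in 0:(ng - 1)) mud <- mud + k * pdiff[k + 1]
  dv <- 0; de <- 0
  for (k in 0:(ng - 1)) {
    dv <- dv + (k - mud)^2 * pdiff[k + 1]
    de <- de - pdiff[k + 1] * lg(pdiff[k + 1])
  }
  hx <- 0; hy <- 0
  for (i in 1:ng) { hx <- hx - px[i] * lg(px[i]); hy <- hy - py[i] * lg(py[i]) }
  hxy1 <- 0; hxy2 <- 0
  for (i in 1:ng) for (j in 1:ng) {
    hxy1 <- hxy1 - if (p[i, j] > 0) p[i, j] * lg(px[i] * py[j]) else 0
    hxy2 <- hxy2 - px[i] * py[j] * lg(px[i] * py[j])
  }
  imc1 <- if (max(hx, hy) == 0) 0 else (ent - hxy1) / max(hx, hy)
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - ent))))
  corr <- if (sigx * sigy == 0) c(0, 0) else
    c((acor - mux * muy) / (sigx * sigy), corr_p / (sigx * sigy))
  c(Autocorrelation = acor, Contrast = contrast, Correlation_m = corr[1],
    Correlation_p = corr[2], Cluster_prominence = cp, Cluster_shade = cs,
    Dissimilarity = dis, Energy = energy, Entropy = ent,
    Homogeneity_m = hom_m, Homogeneity = hom, Maximum_probability = max(p),
    Sum_of_squares_variance = ssv, Sum_average = sa, Sum_variance = sv,
    Sum_entropy = se, Difference_variance = dv, Difference_entropy = de,
    Information_measure_of_correlation1 = imc1,
    Information_measure_of_correlation2 = imc2,
    Inverse_difference_normalized = idn,
    Inverse_difference_moment_normalized = idmn)
}

# type-7 quantile by hand: h = (n - 1) p + 1, linear interpolation
oracle_quantile7 <- function(v, p) {
  x <- sort(v)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- min(lo + 1, n)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

oracle_fos <- function(v) {
  n <- length(v)
  mu <- sum(v) / n
  m2 <- sum((v - mu)^2) / n
  m3 <- sum((v - mu)^3) / n
  m4 <- sum((v - mu)^4) / n
  q <- vapply(c(0.01, 0.05, 0.10, 0.15, 0.20, 0.25, 0.50, 0.75, 0.80,
                0.85, 0.90, 0.95, 0.99),
              function(p) oracle_quantile7(v, p), numeric(1))
  c(Mean = mu,
    Standard_deviation = if (m2 == 0) 0 else sqrt(sum((v - mu)^2) / (n - 1)),
    Skewness = if (m2 == 0) 0 else m3 / m2^1.5,
    Kurtosis = if (m2 == 0) 0 else m4 / m2^2,
    Minimum = min(v),
    `5th_percentile` = q[2], `10th_percentile` = q[3],
    `15th_percentile` = q[4], `20th_percentile` = q[5],
    `25th_percentile` = q[6], Median = q[7], `75th_percentile` = q[8],
    `80th_percentile` = q[9], `85th_percentile` = q[10],
    `90th_percentile` = q[11], `95th_percentile` = q[12],
    Maximum = max(v), Range_all = max(v) - min(v),
    Range5 = q[12] - q[2], Range2 = q[13] - q[1])
}

oracle_auc <- function(scores, positive) {
  s1 <- scores[positive]; s0 <- scores[!positive]
  tot <- 0
  for (a in s1) for (b in s0) {
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(s1) * length(s0))
}

# random normalized GLCM-like matrix with some structural zeros
random_glcm_matrix <- function(ng = 8, sparsity = 0.3) {
  m <- matrix(runif(ng * ng), ng, ng)
  m[runif(ng * ng) < sparsity] <- 0
  if (sum(m) == 0) m[1, 1] <- 1
  m / sum(m)
}

small_test_image <- function(seed = 1, shape = c(96, 72), latent = 50,
                             category = "Normal", laterality = "L",
                             params = NULL) {
  if (is.null(params)) {
    params <- synthetic_params(n_images = 8, image_shape = shape)
  }
  set.seed(seed)
  generate_image(params, category, latent, laterality,
                 sprintf("t-%03d", seed))
}
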