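#' The 20 first-order statistics
#'
#' Histogram descriptors of the raw (unquantized) ROI intensities: mean,
#' standard deviation (n - 1 denominator), skewness and kurtosis
#' (moment-based; kurtosis is non-excess, so a normal sample is near 3),
#' minimum, percentiles 5/10/15/20/25, median, percentiles 75/80/85/90/95,
#' maximum, and three ranges: `Range_all = max - min`,
#' `Range5 = P95 - P5`, `Range2 = P99 - P1`. Percentiles use linear
#' interpolation between order statistics (`quantile` type 7). For a
#' constant sample, standard deviation, skewness and kurtosis are all
#' defined as 0.
#'
#' @param values numeric vector of ROI intensities (non-empty).
#' @param excess_kurtosis subtract 3 from kurtosis (default `FALSE`).
#' @return named numeric vector of length 20.
#' @export
fos_statistics <- function(values, excess_kurtosis = FALSE) {
  v <- as.numeric(values)
  if (length(v) == 0L || anyNA(v)) stop_bad("values must be non-empty, no NA")
  n <- length(v)
  mu <- mean(v)
  m2 <- mean((v - mu)^2)
  if (m2 == 0) {
    sdev <- 0; skew <- 0; kurt <- 0
  } else {
    sdev <- sqrt(m2 * n / max(1, n - 1))
    skew <- mean((v - mu)^3) / m2^1.5
    kurt <- mean((v - mu)^4) / m2^2
    if (excess_kurtosis) kurt <- kurt - 3
  }
  q <- quantile(v, c(0.01, 0.05, 0.10, 0.15, 0.20, 0.25, 0.50,
                     0.75, 0.80, 0.85, 0.90, 0.95, 0.99),
                names = FALSE, type = 7)
  c(Mean = mu,
    Standard_deviation = sdev,
    Skewness = skew,
    Kurtosis = kurt,
    Minimum = min(v),
    `5th_percentile` = q[2],
    `10th_percentile` = q[3],
    `15th_percentile` = q[4],
    `20th_percentile` = q[5],
    `25th_percentile` = q[6],
    Median = q[7],
    `75th_percentile` = q[8],
    `80th_percentile` = q[9],
    `85th_percentile` = q[10],
    `90th_percentile` = q[11],
    `95th_percentile` = q[12],
    Maximum = max(v),
    Range_all = max(v) - min(v),
    Range5 = q[12] - q[2],
    Range2 = q[13] - q[1])
}
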