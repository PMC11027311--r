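test_that("quantization bins the ROI range linearly", {
  full <- matrix(0:255, 16, 16)
  q <- quantize_roi(full, matrix(TRUE, 16, 16), n_levels = 8)
  expect_equal(q$levels[full == 0], 1)
  expect_equal(q$levels[full == 255], 8)
  expect_true(all(q$levels >= 1 & q$levels <= 8))

  const <- quantize_roi(matrix(42, 4, 4), matrix(TRUE, 4, 4), 8)
  expect_true(all(const$levels == 1))

  v <- matrix(c(10, 20, 30, 40), 2, 2)
  q2 <- quantize_roi(v, matrix(TRUE, 2, 2), 2)
  expect_identical(as.vector(q2$levels)[order(as.vector(v))],
                   c(1L, 1L, 2L, 2L))
  expect_error(quantize_roi(v, matrix(TRUE, 2, 2), 1), "n_levels")
})

test_that("GLCM matches brute-force pair enumeration", {
  # hand-checkable toy grid, single angle, asymmetric
  g4 <- matrix(c(0, 0, 1, 1,
                 0, 0, 1, 1,
                 0, 2, 2, 2,
                 2, 2, 3, 3), 4, 4, byrow = TRUE) + 1L
  q <- structure(list(levels = g4, n_levels = 4L, range = c(1, 4)),
                 class = "quantized_roi")
  got <- compute_glcm(q, 1, angles = 0, symmetric = FALSE)
  ref <- oracle_glcm(g4, 4, 1, angles = 0, symmetric = FALSE)
  expect_equal(got$p, ref, tolerance = 1e-12)

  # random masked ROIs, all angles, both symmetry modes
  set.seed(8)
  for (i in 1:40) {
    px <- matrix(sample(0:255, 256, replace = TRUE), 16, 16)
    m <- matrix(runif(256) > 0.25, 16, 16)
    if (sum(m) < 8) next
    ng <- sample(c(4, 8), 1)
    d <- sample(c(1, 2, 3), 1)
    sym <- sample(c(TRUE, FALSE), 1)
    q <- quantize_roi(px, m, ng)
    got <- compute_glcm(q, d, symmetric = sym)
    ref <- oracle_glcm(q$levels, ng, d, symmetric = sym)
    expect_equal(got$p, ref, tolerance = 1e-12)
    expect_equal(sum(got$p), 1, tolerance = 1e-9)
    if (sym) expect_identical(got$p, t(got$p))
  }
})

test_that("degenerate and hand-computed GLCMs give the expected statistics", {
  const <- matrix(110, 5, 5)
  q <- quantize_roi(const, matrix(TRUE, 5, 5), 8)
  g <- compute_glcm(q, 1)
  expect_equal(g$p[1, 1], 1)
  s <- glcm_statistics(g)
  expect_equal(unname(s["Contrast"]), 0)
  expect_equal(unname(s["Dissimilarity"]), 0)
  expect_equal(unname(s["Energy"]), 1)
  expect_equal(unname(s["Entropy"]), 0)
  expect_equal(unname(s["Maximum_probability"]), 1)
  expect_equal(unname(s["Cluster_shade"]), 0)

  p2 <- matrix(c(0.5, 0, 0, 0.5), 2, 2)
  s2 <- glcm_statistics(p2)
  expect_equal(unname(s2["Contrast"]), 0)
  expect_equal(unname(s2["Energy"]), 0.5)
  expect_equal(unname(s2["Entropy"]), log(2))

  expect_error(compute_glcm(quantize_roi(matrix(1:4, 2, 2),
                                         matrix(TRUE, 2, 2), 2), 5),
               "empty GLCM")
})

test_that("all 22 GLCM statistics match the direct-summation oracle", {
  set.seed(101)
  for (i in 1:100) {
    p <- random_glcm_matrix(ng = sample(c(4, 8), 1))
    got <- glcm_statistics(p)
    ref <- oracle_glcm_stats(p)
    expect_equal(got, ref, tolerance = 1e-10)
  }
  # log base 2 variant stays consistent with the oracle too
  p <- random_glcm_matrix(8)
  expect_equal(glcm_statistics(p, log_base = 2),
               oracle_glcm_stats(p, base = 2), tolerance = 1e-10)
})

test_that("GLCM features are invariant to a constant intensity shift", {
  set.seed(17)
  px <- matrix(sample(40:200, 400, replace = TRUE), 20, 20)
  m <- matrix(TRUE, 20, 20)
  f1 <- glcm_statistics(compute_glcm(quantize_roi(px, m, 8), 1))
  f2 <- glcm_statistics(compute_glcm(quantize_roi(px + 37, m, 8), 1))
  expect_equal(f1, f2, tolerance = 1e-12)
})
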