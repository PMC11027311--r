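test_that("image generation is deterministic and respects the gray-level contract", {
  p <- synthetic_params(n_images = 8, image_shape = c(96, 72),
                        texture_effect = c(cluster_shade = 0, spread = 0,
                                           skew = 0))
  set.seed(42)
  a <- generate_image(p, "Normal", 50, "L", "a")
  set.seed(42)
  b <- generate_image(p, "Normal", 50, "L", "a")
  expect_identical(a$pixels, b$pixels)

  for (lat in c("L", "R")) {
    img <- generate_image(p, "Cancer", 90, lat, "x")
    fg <- img$pixels >= 100
    expect_true(any(fg))
    expect_lt(max(img$pixels[!fg]), 100)
    expect_gte(min(img$pixels[fg]), 100)
    expect_lte(max(img$pixels), 255)
    # breast anchored at the chest-wall edge
    edge_col <- if (lat == "L") 1 else ncol(img$pixels)
    expect_true(any(fg[, edge_col]))
  }

  expect_error(generate_image(p, "NotACategory", 50), "category")
  expect_error(synthetic_params(image_shape = c(32, 32)), "64")
  expect_error(synthetic_params(background_level = 120), "< 100")
})

test_that("planted spread shift raises foreground standard deviation (high vs low latent)", {
  p <- synthetic_params(n_images = 8, image_shape = c(64, 64),
                        texture_effect = c(cluster_shade = 0, spread = 30,
                                           skew = 0))
  set.seed(99)
  sd_of <- function(latent) {
    vapply(seq_len(200), function(i) {
      img <- generate_image(p, "Normal", latent, "L", "s")
      sd(img$pixels[img$pixels >= 100])
    }, numeric(1))
  }
  hi <- sd_of(100)
  lo <- sd_of(0)
  expect_gt(mean(hi), mean(lo))
  # the shift is large, not a borderline fluctuation
  expect_gt(mean(hi) - mean(lo), 5)
})

test_that("observer panels follow the clipped-Gaussian score model", {
  p0 <- synthetic_params(n_images = 8, observer_noise_sd = 0)
  img <- list(image_id = "z", latent_gist = 73)
  panel <- generate_panel(img, p0)
  expect_length(panel$scores, 13)
  expect_true(all(panel$scores == 73))
  expect_equal(panel$mean_score, 73)

  p <- synthetic_params(n_images = 8, observer_noise_sd = 25)
  set.seed(5)
  low <- generate_panel(list(image_id = "z", latent_gist = 0), p)
  expect_true(all(low$scores >= 0))
  expect_true(all(low$scores <= 100))
  expect_equal(low$mean_score, mean(low$scores))
})

test_that("panel means concentrate on the latent gist (law of large numbers)", {
  p <- synthetic_params(n_images = 8, observer_noise_sd = 10)
  set.seed(31)
  means <- vapply(seq_len(1000), function(i) {
    generate_panel(list(image_id = "z", latent_gist = 50), p)$mean_score
  }, numeric(1))
  expect_lt(abs(mean(means) - 50), 1)
})

test_that("cohort generation conserves counts and is reproducible", {
  p <- synthetic_params(n_images = 50, image_shape = c(64, 64), seed = 12)
  co <- generate_cohort(p, images = FALSE)
  expect_equal(nrow(co$manifest), 50)
  expect_length(co$panels, 50)
  expect_true(all(co$manifest$category %in%
                    c("Normal", "Cancer", "Missed", "Prior-Visible",
                      "Prior-Invisible", "Prior-2", "Prior-3")))
  expect_true(all(co$manifest$latent_gist >= 0 &
                    co$manifest$latent_gist <= 100))
  co2 <- generate_cohort(p, images = FALSE)
  expect_identical(co$manifest, co2$manifest)

  small <- synthetic_params(n_images = 12, image_shape = c(64, 64), seed = 4)
  full <- generate_cohort(small)
  expect_length(full$images, 12)
  expect_identical(full$images[[3]]$pixels,
                   generate_cohort(small)$images[[3]]$pixels)
  expect_error(generate_cohort(synthetic_params(n_images = 4)), ">= 8")
})

test_that("category draws follow the mix within binomial bounds", {
  mix <- setNames(rep(1 / 7, 7),
                  c("Normal", "Cancer", "Missed", "Prior-Visible",
                    "Prior-Invisible", "Prior-2", "Prior-3"))
  p <- synthetic_params(n_images = 7000, category_mix = mix, seed = 8)
  co <- generate_cohort(p, images = FALSE)
  counts <- table(co$manifest$category)
  expected <- 1000
  band <- 4 * sqrt(7000 * (1 / 7) * (6 / 7))
  expect_true(all(abs(counts - expected) <= band))
})
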