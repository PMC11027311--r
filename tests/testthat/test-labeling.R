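test_that("panel averaging is the arithmetic mean", {
  expect_equal(average_panel(rep(50, 13)), 50)
  expect_equal(average_panel(c(0, 100)), 50)
  expect_equal(average_panel(c(rep(10, 12), 100)), 220 / 13)
  expect_error(average_panel(numeric(0)), "no observer scores")
})

test_that("quartile split takes the top and bottom ceiling(n/4)", {
  set.seed(1)
  scores <- sample(seq_len(4191))  # distinct
  lab <- quartile_split(scores)
  expect_equal(sum(lab$label == "high"), 1048)
  expect_equal(sum(lab$label == "low"), 1048)
  expect_equal(sum(lab$label == "excluded"), 4191 - 2 * 1048)

  lab8 <- quartile_split(c(5, 1, 9, 3, 7, 2, 8, 4))
  expect_equal(sum(lab8$label == "high"), 2)
  expect_equal(sum(lab8$label == "low"), 2)
  expect_equal(sum(lab8$label == "excluded"), 4)
  expect_setequal(lab8$mean_score[lab8$label == "high"], c(9, 8))
  expect_setequal(lab8$mean_score[lab8$label == "low"], c(1, 2))

  expect_error(quartile_split(c(1, 2, 3)), "at least 4")
})

test_that("label monotonicity: high >= excluded >= low", {
  set.seed(20)
  for (i in 1:10) {
    scores <- round(runif(sample(10:200, 1), 0, 100), 1)  # plenty of ties
    lab <- quartile_split(scores)
    hi <- lab$mean_score[lab$label == "high"]
    mid <- lab$mean_score[lab$label == "excluded"]
    lo <- lab$mean_score[lab$label == "low"]
    if (length(mid)) {
      expect_gte(min(hi), max(mid))
      expect_gte(min(mid), max(lo))
    } else {
      expect_gte(min(hi), max(lo))
    }
  }
})

test_that("fully tied scores split deterministically by image id", {
  lab <- quartile_split(rep(50, 8), sprintf("i%02d", 1:8))
  expect_equal(sum(lab$label == "high"), 2)
  expect_equal(sum(lab$label == "low"), 2)
  expect_identical(lab$image_id[lab$label == "high"], c("i01", "i02"))
  expect_identical(lab$image_id[lab$label == "low"], c("i07", "i08"))
  expect_identical(quartile_split(rep(50, 8), sprintf("i%02d", 1:8)), lab)
})

test_that("category datasets partition the labeled pool as published", {
  set.seed(33)
  n <- 300
  cats <- sample(c("Normal", "Cancer", "Missed", "Prior-Visible",
                   "Prior-Invisible", "Prior-2", "Prior-3"), n,
                 replace = TRUE)
  scores <- runif(n, 0, 100)
  ids <- sprintf("img-%04d", seq_len(n))
  feats <- data.frame(image_id = ids, category = cats,
                      f1 = rnorm(n), f2 = rnorm(n),
                      stringsAsFactors = FALSE)
  lab <- quartile_split(scores, ids)
  lab$category <- cats
  ds <- build_category_datasets(lab, feats)

  expect_named(ds, c("All", "Normal", "Cancer", "Prior-1", "Prior-2",
                     "Missed", "Prior-Visible", "Prior-Invisible"))
  kept <- lab[lab$label != "excluded", ]
  # group-by oracle for the per-category sizes
  expect_equal(nrow(ds$All), nrow(kept))
  for (cat in c("Normal", "Cancer", "Prior-2", "Missed", "Prior-Visible",
                "Prior-Invisible")) {
    expect_equal(nrow(ds[[cat]]), sum(kept$category == cat))
  }
  expect_equal(nrow(ds[["Prior-1"]]),
               sum(kept$category %in% c("Missed", "Prior-Visible",
                                        "Prior-Invisible")))
  # disjoint base categories plus Prior-3 reassemble the All set
  expect_equal(nrow(ds$Normal) + nrow(ds$Cancer) + nrow(ds[["Prior-1"]]) +
                 nrow(ds[["Prior-2"]]) + sum(kept$category == "Prior-3"),
               nrow(ds$All))
  # excluded images appear nowhere
  excl <- lab$image_id[lab$label == "excluded"]
  for (d in ds) expect_length(intersect(d$image_id, excl), 0)

  drop_id <- kept$image_id[1]
  expect_error(build_category_datasets(lab,
                                       feats[feats$image_id != drop_id, ]),
               "no feature row")
})
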