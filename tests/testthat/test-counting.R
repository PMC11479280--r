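test_that("probability filtering is inclusive at the threshold", {
  preds <- data.frame(x0 = 0, y0 = 0, x1 = 1, y1 = 1,
                      probability = c(0.90, 0.899, 0.95, 0.2))
  kept <- filter_by_probability(preds)
  expect_equal(kept$probability, c(0.90, 0.95))
  expect_equal(nrow(filter_by_probability(preds[0, ])), 0)
})

test_that("iou matches analytic values and basic properties", {
  a <- cs_rect(0, 0, 0.2, 0.25)
  expect_equal(iou(a, a), 1)
  expect_equal(iou(a, cs_rect(1, 1, 1.2, 1.25)), 0)
  ## two 0.2 x 0.25 rects offset 0.1 in x: inter 0.025, union 0.075
  b <- cs_rect(0.1, 0, 0.3, 0.25)
  expect_equal(iou(a, b), 1 / 3)
  expect_equal(iou(b, a), iou(a, b))
  expect_error(iou(list(x0 = 0, y0 = 0, x1 = 0, y1 = 1), a), "zero-area")
})

test_that("iou is symmetric, bounded, and 1 only for identical rects", {
  set.seed(12)
  for (i in 1:50) {
    p <- random_preds(2)
    v <- iou(p[1, ], p[2, ])
    expect_gte(v, 0); expect_lte(v, 1)
    expect_equal(v, iou(p[2, ], p[1, ]))
    if (v == 1) expect_equal(unlist(p[1, 1:4]), unlist(p[2, 1:4]))
  }
})

test_that("dedup keeps the most confident of overlapping predictions", {
  two <- data.frame(x0 = c(0, 0), y0 = c(0, 0), x1 = c(0.2, 0.2),
                    y1 = c(0.25, 0.25), probability = c(0.95, 0.92))
  kept <- dedup_predictions(two)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$probability, 0.95)
  ## rects at least one block apart survive untouched
  far <- data.frame(x0 = c(0, 0.6), y0 = c(0, 0), x1 = c(0.2, 0.8),
                    y1 = c(0.25, 0.25), probability = c(0.5, 0.9))
  expect_equal(nrow(dedup_predictions(far)), 2)
  ## with no expansion, non-overlapping tiles are a no-op
  adj <- data.frame(x0 = c(0, 0.2), y0 = 0, x1 = c(0.2, 0.4), y1 = 0.25,
                    probability = c(0.9, 0.8))
  expect_equal(nrow(dedup_predictions(adj, expand_frac = 0)), 2)
  expect_equal(nrow(dedup_predictions(adj, expand_frac = 0.25)), 1)
})

test_that("dedup agrees with the exhaustive greedy oracle", {
  set.seed(77)
  for (trial in 1:200) {
    n <- sample(1:10, 1)
    preds <- random_preds(n, grid = trial %% 2 == 0)
    kept <- dedup_predictions(preds)
    want <- oracle_nms(preds)
    expect_identical(as.integer(rownames(kept)), want)
    ## subset property and pairwise-compatibility of the kept set
    ex <- preds[want, ]
    w <- (ex$x1 - ex$x0) * 0.125; h <- (ex$y1 - ex$y0) * 0.125
    ex2 <- data.frame(x0 = ex$x0 - w, y0 = ex$y0 - h,
                      x1 = ex$x1 + w, y1 = ex$y1 + h)
    if (nrow(ex2) > 1) {
      for (i in 1:(nrow(ex2) - 1)) for (j in (i + 1):nrow(ex2))
        expect_lte(iou(ex2[i, ], ex2[j, ]), 0.1 + 1e-12)
    }
  }
})

test_that("region counts use rect centres with half-open edges", {
  preds <- data.frame(x0 = c(0, 0.4, 0.9), y0 = 0,
                      x1 = c(0.2, 0.6, 1.1), y1 = 0.25,
                      probability = 1)
  region <- cs_rect(0, 0, 1, 1)
  expect_equal(count_region(preds, region), 2)  # centre 1.0 is on the high edge
  expect_equal(count_region(preds[0, ], region), 0L)
})

test_that("confusion counts enumerate the four cells", {
  truth <- c(rep("corn", 6), rep("non_corn", 4))
  pred <- c(rep("corn", 5), "non_corn", "corn", rep("non_corn", 3))
  cc <- confusion_counts(pred, truth)
  expect_equal(cc, c(tp = 5, fp = 1, fn = 1, tn = 3))
  perfect <- confusion_counts(truth, truth)
  expect_equal(perfect[["fp"]] + perfect[["fn"]], 0)
  inverted <- confusion_counts(ifelse(truth == "corn", "non_corn", "corn"), truth)
  expect_equal(inverted[["tp"]] + inverted[["tn"]], 0)
  expect_equal(sum(cc), length(truth))
  expect_error(confusion_counts(pred[1:3], truth), "length")
})

test_that("precision/recall/F1 follow their formulas with safe degenerates", {
  prf <- precision_recall_f1(c(tp = 9, fp = 1, fn = 1))
  expect_equal(unname(prf), c(0.9, 0.9, 0.9))
  ## precision and F1 both warn on their zero denominators
  expect_warning(expect_warning(
    z <- precision_recall_f1(c(tp = 0, fp = 0, fn = 5))))
  expect_equal(unname(z), c(0, 0, 0))
  pr <- precision_recall_f1(c(tp = 2, fp = 0, fn = 2))  # P = 1, R = 0.5
  expect_equal(pr[["f1"]], 2 / 3)
  ## harmonic mean lies between P and R
  set.seed(9)
  for (i in 1:25) {
    cc <- c(tp = sample(1:50, 1), fp = sample(0:50, 1), fn = sample(0:50, 1))
    v <- precision_recall_f1(cc)
    expect_gte(v[["f1"]], min(v[["precision"]], v[["recall"]]) - 1e-12)
    expect_lte(v[["f1"]], max(v[["precision"]], v[["recall"]]) + 1e-12)
  }
})

test_that("rmse and r_squared match hand calculations and edge cases", {
  x <- c(229, 274, 184, 116, 140)
  expect_equal(rmse(x, x), 0)
  expect_equal(rmse(c(0), c(3)), 3)
  p5 <- c(210, 266, 178, 111, 137)
  expect_equal(round(rmse(x, p5), 2), 9.95)
  expect_equal(r_squared(x, x), 1)
  expect_equal(r_squared(x, rep(mean(x), 5)), 0)
  ## independent arithmetic for a published-version row
  p2 <- c(211, 263, 177, 111, 137)
  expect_equal(r_squared(x, p2), 1 - sum((x - p2)^2) / sum((x - mean(x))^2))
  expect_error(rmse(x, p5[1:3]), "equal-length")
  expect_error(r_squared(c(5, 5, 5), c(1, 2, 3)), "constant")
  ## rmse is zero iff the vectors agree
  expect_gt(rmse(x, x + c(0, 0, 1, 0, 0)), 0)
})

test_that("the comparison table averages per model and is order-invariant", {
  tab <- stand_count_table()
  mc <- model_comparison_table(tab)
  expect_equal(nrow(mc$versions), 20)
  vgg16 <- mc$models[mc$models$model == "vgg16", ]
  expect_equal(round(vgg16$mean_rmse, 2), 10.86)
  ## identical-to-truth single version
  toy <- data.frame(model = c("ground_truth", "m"), version = c(NA, 1),
                    TR1 = c(10, 10), TR2 = c(20, 20), TR3 = c(30, 30))
  mt <- model_comparison_table(toy)
  expect_equal(mt$models$mean_rmse, 0)
  expect_equal(mt$models$mean_r2, 1)
  ## permuting version order leaves the means unchanged
  perm <- tab[c(1, sample(2:nrow(tab))), ]
  mc2 <- model_comparison_table(perm)
  m1 <- mc$models[order(mc$models$model), c("mean_r2", "mean_rmse")]
  m2 <- mc2$models[order(mc2$models$model), c("mean_r2", "mean_rmse")]
  expect_equal(m1, m2, ignore_attr = TRUE)
})
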