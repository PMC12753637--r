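test_that("pixel metrics reproduce a hand-built confusion matrix", {
  gt <- matrix(c(1L, 2L, 0L, 0L), 2L, 2L)      # [[1,0],[2,0]]
  pred <- matrix(c(1L, 0L, 0L, 0L), 2L, 2L)    # [[1,0],[0,0]]
  pm <- pixel_metrics(gt, pred)
  expect_equal(pm$accuracy, 0.75)
  expect_equal(unname(pm$sensitivity["positive"]), 1.0)
  expect_equal(unname(pm$sensitivity["negative"]), 0.0)
  expect_equal(unname(pm$specificity["positive"]), 1.0)
  expect_equal(pm$macro_sensitivity, 0.5)
})

test_that("identical masks score perfectly; absent classes are undefined", {
  set.seed(3)
  m <- random_mask()
  pm <- pixel_metrics(m, m)
  expect_equal(pm$accuracy, 1.0)
  expect_true(all(pm$sensitivity[!is.na(pm$sensitivity)] == 1))

  z <- matrix(0L, 8L, 8L)
  pm0 <- pixel_metrics(z, z)
  expect_equal(pm0$accuracy, 1.0)
  expect_true(is.na(pm0$sensitivity["positive"]))
  expect_true(is.na(pm0$sensitivity["negative"]))
  expect_true(is.na(pm0$macro_sensitivity))

  expect_error(pixel_metrics(matrix(0L, 2L, 2L), matrix(0L, 3L, 3L)),
               "identical shape")
})

test_that("pixel metrics agree with a naive per-pixel tally", {
  set.seed(9)
  for (i in 1:10) {
    gt <- random_mask(32L, 32L, 20L, 2L)
    pred <- random_mask(32L, 32L, 20L, 2L)
    pm <- pixel_metrics(gt, pred)
    cm <- oracle_confusion(as.vector(gt), as.vector(pred))
    expect_equal(unname(pm$confusion), cm, tolerance = 1e-12)
    expect_equal(pm$accuracy, sum(diag(cm)) / sum(cm), tolerance = 1e-12)
    for (k in 1:3) {
      if (sum(cm[k, ]) > 0) {
        expect_equal(unname(pm$sensitivity[k]), cm[k, k] / sum(cm[k, ]),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("object metrics are perfect when prediction equals truth", {
  set.seed(4)
  m <- random_mask()
  if (length(label_cells(m, 1L)) > 0) {
    om <- object_metrics(m, m, 1L)
    expect_equal(om$precision, 1.0)
    expect_equal(om$recall, 1.0)
    expect_identical(om$n_matched, om$n_gt_objects)
  }
})

test_that("missed objects lower recall but not precision", {
  gt <- matrix(0L, 64L, 64L)
  gt[5:9, 5:9] <- 1L
  gt[40:44, 40:44] <- 1L
  pred <- matrix(0L, 64L, 64L)
  pred[5:9, 5:9] <- 1L            # reproduces one object, adds none
  om <- object_metrics(gt, pred, 1L)
  expect_equal(om$precision, 1.0)
  expect_equal(om$recall, 0.5)
  expect_identical(om$n_matched, 1L)
})

test_that("degenerate object sets follow the stated conventions", {
  gt <- matrix(0L, 32L, 32L)
  gt[2:5, 2:5] <- 1L; gt[2:5, 20:23] <- 1L; gt[20:23, 2:5] <- 1L
  empty <- matrix(0L, 32L, 32L)
  om <- object_metrics(gt, empty, 1L)
  expect_equal(om$precision, 0)
  expect_equal(om$recall, 0)
  expect_true(om$degenerate)
  both <- object_metrics(empty, empty, 1L)
  expect_equal(both$precision, 1)
  expect_equal(both$recall, 1)
  expect_false(both$degenerate)
})

test_that("greedy matching is one-to-one by descending overlap", {
  gt <- matrix(0L, 32L, 32L)
  gt[5:14, 5:14] <- 1L                       # one large object
  pred <- matrix(0L, 32L, 32L)
  pred[5:14, 5:10] <- 1L                     # large overlap
  pred[5:14, 25:28] <- 1L                    # no overlap
  om <- object_metrics(gt, pred, 1L)
  expect_identical(om$n_matched, 1L)
  expect_equal(om$precision, 0.5)
  expect_equal(om$recall, 1.0)
})

test_that("patient metrics recover exact and inverse agreement", {
  pm <- patient_metrics(c(0, 10, 60), c(0, 10, 60))
  expect_equal(pm$pearson_r, 1.0)
  expect_equal(pm$interval_concordance, 1.0)
  pm2 <- patient_metrics(c(0, 50), c(50, 0))
  expect_equal(pm2$pearson_r, -1.0)
})

test_that("clinical interval concordance ignores raw-score differences", {
  pm <- patient_metrics(c(0.5, 30, 70), c(0.8, 45, 55))
  expect_equal(pm$interval_concordance, 1.0)
  # under the routing bands, 45 vs 30 and 55 vs 70 land differently
  pm_band <- patient_metrics(c(0.5, 30, 70), c(0.8, 45, 55),
                             scheme = default_scheme())
  expect_equal(pm_band$interval_concordance, 1 / 3)
})

test_that("patient metrics are permutation-invariant and guard inputs", {
  gt <- c(2, 15, 48, 62, 90); pred <- c(1, 18, 44, 70, 85)
  a <- patient_metrics(gt, pred)
  o <- sample(5)
  b <- patient_metrics(gt[o], pred[o])
  expect_equal(a$pearson_r, b$pearson_r)
  expect_equal(a$interval_concordance, b$interval_concordance)
  expect_error(patient_metrics(1, c(1, 2)), "equal length")
  expect_error(patient_metrics(5, 5), "two cases")
  expect_warning(pm <- patient_metrics(c(5, 5), c(0.5, 9)), "constant")
  expect_true(is.na(pm$pearson_r))
  expect_equal(pm$interval_concordance, 0.5)
})
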