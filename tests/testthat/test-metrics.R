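test_that("confusion counts match the per-pixel counting oracle", {
  truth <- matrix(c(0, 1, 1, 0, 1, 0, 1, 1, 0), 3)
  expect_equal(unclass(confusion(truth, truth, 1))[c("fp", "fn")],
               list(fp = 0L, fn = 0L), ignore_attr = TRUE)
  flip <- 1 - truth
  cm <- confusion(flip, truth, 1)
  expect_equal(cm$tp + cm$tn, 0)
  set.seed(0)
  for (i in 1:5) {
    p <- matrix(rbinom(100, 1, 0.5), 10)
    t <- matrix(rbinom(100, 1, 0.5), 10)
    or <- confusion_oracle(p, t, 1)
    cm <- confusion(p, t, 1)
    expect_equal(list(tp = cm$tp, fp = cm$fp, tn = cm$tn, fn = cm$fn), or)
    expect_equal(cm$tp + cm$fp + cm$tn + cm$fn, 100)
  }
  expect_error(confusion(matrix(0, 2, 2), matrix(0, 3, 3)), "identical shapes")
})

test_that("classification metrics reproduce the worked fraction arithmetic", {
  cm <- structure(list(tp = 9, fp = 1, tn = 8, fn = 2, total = 20),
                  class = "confusion_counts")
  m <- classification_metrics(cm)
  expect_equal(m$accuracy, 0.85)
  expect_equal(m$precision, 0.9)
  expect_equal(m$recall, 9 / 11)
  expect_equal(m$sensitivity, 9 / 11)
  expect_equal(m$specificity, 8 / 9)
  # perfect classifier
  cm2 <- structure(list(tp = 5, fp = 0, tn = 7, fn = 0, total = 12),
                   class = "confusion_counts")
  m2 <- classification_metrics(cm2)
  expect_true(all(unlist(m2) == 1))
  # empty positive-prediction set -> undefined marker, never 0
  cm3 <- structure(list(tp = 0, fp = 0, tn = 9, fn = 1, total = 10),
                   class = "confusion_counts")
  expect_true(is.na(classification_metrics(cm3)$precision))
})

test_that("rate identities hold in exact rational arithmetic on random tables", {
  set.seed(1)
  for (i in 1:200) {
    v <- sample(0:50, 4, replace = TRUE)
    if (sum(v) == 0) v[1] <- 1
    cm <- structure(list(tp = v[1], fp = v[2], tn = v[3], fn = v[4],
                         total = sum(v)), class = "confusion_counts")
    m <- classification_metrics(cm)
    # the stored rate is exactly the rational quotient of the counts
    expect_identical(m$accuracy, (v[1] + v[3]) / cm$total)
    if (!is.na(m$precision)) expect_identical(m$precision, v[1] / (v[1] + v[2]))
    if (!is.na(m$specificity)) expect_identical(m$specificity, v[3] / (v[3] + v[2]))
  }
})

test_that("the paper-exact switch changes only sensitivity and specificity", {
  cm <- structure(list(tp = 9, fp = 1, tn = 8, fn = 2, total = 20),
                  class = "confusion_counts")
  m <- classification_metrics(cm, paper_exact = TRUE)
  expect_equal(m$sensitivity, 9 / 10)   # TP/(TP+FP) as printed
  expect_equal(m$specificity, 8 / 10)   # TN/(TP+FP) as printed
  expect_equal(m$accuracy, 0.85)
  expect_equal(m$precision, 0.9)
})

test_that("mse and psnr follow their closed forms", {
  x <- matrix(rnorm(16), 4)
  expect_equal(mse(x, x), 0)
  expect_equal(mse(x + 1, x), 1)
  expect_equal(mse(matrix(c(1, -1, 2, 0) + 5, 2), matrix(5, 2, 2)), 1.5)
  expect_identical(psnr(x, x), Inf)
  y <- x; y[1] <- x[1] + 4                # mse = 16/16 = 1 = peak^2 at peak 1
  expect_equal(psnr(y, x, peak = 1), 0)
  z <- x + 0.1                            # mse 0.01, peak 1 -> 20 dB
  expect_equal(psnr(z, x, peak = 1), 20)
  expect_error(psnr(x, x, peak = 0), "positive")
  expect_error(mse(x, matrix(0, 2, 2)), "identical shapes")
})

test_that("psnr strictly decreases with added noise variance", {
  set.seed(123)
  ref <- matrix(runif(64 * 64), 64)
  vals <- sapply(c(0.01, 0.02, 0.05, 0.1, 0.2), function(s) {
    psnr(ref + matrix(rnorm(64 * 64, 0, s), 64), ref, peak = 1)
  })
  expect_true(all(diff(vals) < 0))
})

test_that("segmentation_report aggregates per-class dice and rates", {
  truth <- matrix(0L, 8, 8); truth[3:6, 3:6] <- 1L; truth[4:5, 4:5] <- 2L
  rep_perfect <- segmentation_report(truth, truth)
  expect_equal(rep_perfect$dice, c(1, 1))
  expect_equal(rep_perfect$class, c(1, 2))
  pred <- truth; pred[3, 3] <- 0L
  rep2 <- segmentation_report(pred, truth, image_pred = truth + 0.1,
                              image_ref = truth + 0, peak = 2)
  expect_lt(rep2$dice[1], 1)
  expect_equal(rep2$mse[1], 0.01)
  expect_true(all(c("accuracy", "precision", "recall", "specificity") %in%
                    names(rep2)))
})

test_that("metric reports round-trip to JSON and TSV", {
  df <- segmentation_report(matrix(c(0, 1, 1, 0), 2), matrix(c(0, 1, 0, 1), 2))
  tmp <- tempfile(fileext = ".tsv")
  write_metrics_tsv(df, tmp)
  back <- read.delim(tmp)
  expect_equal(back$dice, df$dice)
  tmp2 <- tempfile(fileext = ".json")
  write_metrics_json(df, tmp2)
  expect_true(jsonlite::validate(paste(readLines(tmp2), collapse = "")))
})
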