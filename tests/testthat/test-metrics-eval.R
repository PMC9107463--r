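test_that("confusion counts are exact", {
  expect_equal(confusion(c(1, 1, 0, 0), c(1, 1, 0, 0)),
               c(TP = 2L, FP = 0L, FN = 0L, TN = 2L))
  expect_equal(confusion(c(1, 1, 0, 0), c(0, 0, 1, 1)),
               c(TP = 0L, FP = 2L, FN = 2L, TN = 0L))
  expect_equal(confusion(c(1, 0, 1, 0, 0), c(1, 1, 0, 0, 0)),
               c(TP = 1L, FP = 1L, FN = 1L, TN = 2L))
  expect_error(confusion(c(1, 0), c(1, 0, 0)), "equal length")
  expect_error(confusion(c(1, 2), c(1, 0)), "binary")
})

test_that("threshold metrics use standard definitions with NA for 0/0", {
  perfect <- threshold_metrics(c(TP = 2L, FP = 0L, FN = 0L, TN = 2L))
  expect_true(all(perfect == 1))

  none_pos <- threshold_metrics(c(TP = 0L, FP = 0L, FN = 2L, TN = 3L))
  expect_true(is.na(none_pos[["precision"]]))
  expect_equal(none_pos[["npv"]], 3 / 5)

  m <- threshold_metrics(c(TP = 1L, FP = 1L, FN = 1L, TN = 2L))
  expect_equal(m[["precision"]], 0.5)
  expect_equal(m[["sensitivity"]], 0.5)
  expect_equal(m[["specificity"]], 2 / 3)
  expect_equal(m[["accuracy"]], 0.6)
  expect_equal(m[["f1"]], 0.5)
  expect_equal(m[["npv"]], 2 / 3)
})

test_that("AUROC equals exhaustive pair counting, with tie and sign laws", {
  expect_equal(auroc(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1.0)
  expect_equal(auroc(c(1, 0, 1, 0), rep(0.5, 4)), 0.5)
  expect_equal(auroc(c(1, 0, 1, 0), c(0.9, 0.8, 0.7, 0.1)), 0.75)
  expect_true(is.na(auroc(c(1, 1), c(0.2, 0.3))))

  for (case in 1:50) {
    dat <- withr::with_seed(case, {
      n <- sample(4:50, 1)
      y <- stats::rbinom(n, 1, 0.5)
      if (length(unique(y)) < 2) y[1:2] <- 0:1
      s <- round(stats::runif(n), 2)  # rounding forces ties
      list(y = y, s = s)
    })
    expect_identical(auroc(dat$y, dat$s), auroc_bruteforce(dat$y, dat$s))
    if (!anyDuplicated(dat$s)) {
      expect_equal(auroc(dat$y, dat$s) + auroc(dat$y, -dat$s), 1)
    }
  }
})

test_that("AUROC agrees with an established implementation", {
  for (seed in 1:5) {
    dat <- withr::with_seed(seed, {
      y <- rep(0:1, each = 20)
      list(y = y, s = stats::rnorm(40, mean = y))
    })
    ref <- as.numeric(pROC::auc(pROC::roc(dat$y, dat$s, quiet = TRUE,
                                          direction = "<")))
    expect_equal(auroc(dat$y, dat$s), ref, tolerance = 1e-12)
  }
})

test_that("PR curve step integration matches a direct enumeration", {
  y <- c(1, 0, 1, 0)
  s <- c(0.9, 0.8, 0.7, 0.1)
  # direct: walk thresholds in descending score order
  expect_equal(auprc(y, s), 0.5 * 1 + 0.5 * (2 / 3), tolerance = 1e-12)
  pr <- pr_points(y, s)
  expect_equal(pr$recall, c(0.5, 0.5, 1, 1))
  expect_equal(pr$precision, c(1, 1 / 2, 2 / 3, 1 / 2))
  expect_true(is.na(auprc(c(1, 1), c(0.1, 0.2))))
})

test_that("ROC points trace the empirical operating curve", {
  y <- c(1, 0, 1, 0)
  s <- c(0.9, 0.8, 0.7, 0.1)
  roc <- roc_points(y, s)
  expect_equal(roc$fpr, c(0, 0, 0.5, 0.5, 1))
  expect_equal(roc$tpr, c(0, 0.5, 0.5, 1, 1))
})

test_that("bootstrap reports are deterministic with ordered percentiles", {
  dat <- withr::with_seed(21, {
    y <- rep(0:1, each = 25)
    list(y = y, s = stats::rnorm(50, mean = 1.2 * y))
  })
  r1 <- bootstrap_ci(dat$y, dat$s, n_boot = 100, seed = 3)
  r2 <- bootstrap_ci(dat$y, dat$s, n_boot = 100, seed = 3)
  expect_identical(r1$metrics, r2$metrics)
  expect_s3_class(r1, "metric_report")
  expect_equal(r1$metrics$metric,
               c("auroc", "accuracy", "f1", "precision", "sensitivity",
                 "specificity", "npv"))
  ok <- stats::complete.cases(r1$metrics[c("lower", "median", "upper")])
  expect_true(all(r1$metrics$lower[ok] <= r1$metrics$median[ok]))
  expect_true(all(r1$metrics$median[ok] <= r1$metrics$upper[ok]))
  expect_equal(sum(r1$confusion), 50)
  expect_error(bootstrap_ci(dat$y, dat$s, n_boot = 1), "n_boot")
  expect_error(bootstrap_ci(rep(1, 10), stats::runif(10)), "both classes")
})

test_that("bootstrap percentiles bracket the point estimate", {
  hits <- 0
  n_cases <- 20
  for (case in seq_len(n_cases)) {
    dat <- withr::with_seed(100 + case, {
      y <- rep(0:1, each = 15)
      list(y = y, s = stats::rnorm(30, mean = 0.8 * y))
    })
    r <- bootstrap_ci(dat$y, dat$s, n_boot = 1000, seed = case)
    au <- r$metrics[r$metrics$metric == "auroc", ]
    if (au$lower <= au$point && au$point <= au$upper) hits <- hits + 1
  }
  expect_gte(hits / n_cases, 0.9)
})

test_that("unstratified resampling skips single-class resamples", {
  y <- c(rep(0, 18), 1, 1)
  s <- withr::with_seed(31, stats::runif(20) + y)
  r <- bootstrap_ci(y, s, n_boot = 200, seed = 4, stratified = FALSE)
  expect_lt(r$n_boot_effective, 200)
  expect_gt(r$n_boot_effective, 50)
  ok <- stats::complete.cases(r$metrics[c("lower", "upper")])
  expect_true(all(r$metrics$lower[ok] <= r$metrics$upper[ok]))
})

test_that("metric reports serialise to JSON", {
  dat <- withr::with_seed(41, {
    y <- rep(0:1, each = 10)
    list(y = y, s = stats::runif(20) + y)
  })
  r <- bootstrap_ci(dat$y, dat$s, n_boot = 50, seed = 1)
  path <- withr::local_tempfile(fileext = ".json")
  write_metric_report(r, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$metrics$point, r$metrics$point, tolerance = 1e-12)
  expect_equal(back$n_boot, 50)
})
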