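test_that("fisher discriminant on two 1-D point classes puts the boundary at
           the midpoint with LEGH on the positive side", {
  # two coincident points per class have zero scatter, so the fit falls back
  # to the ridge solve; the boundary is still the midpoint
  expect_warning(
    m <- fit_fisher(matrix(c(0, 0), ncol = 1), matrix(c(2, 2), ncol = 1),
                    feature_names = "x"),
    "ridge")
  # boundary at x = 1: D(1) = 0, and ties go to the positive label
  expect_equal(predict(m, matrix(1), type = "score"), 0)
  expect_equal(classify(m, matrix(1)), "LEGH")
  expect_equal(classify(m, matrix(c(0.5, 1.5), ncol = 1)), c("EC", "LEGH"))
})

test_that("swapping the class inputs negates the decision function", {
  set.seed(17)
  xe <- matrix(rnorm(40, 0), 20, 2)
  xl <- matrix(rnorm(40, 3), 20, 2)
  m1 <- fit_fisher(xe, xl)
  m2 <- fit_fisher(xl, xe)
  x <- matrix(rnorm(20), 10, 2)
  expect_equal(predict(m1, x, type = "score"),
               -predict(m2, x, type = "score"), tolerance = 1e-10)
})

test_that("fisher fit is invariant to a common affine shift of all samples", {
  set.seed(18)
  xe <- matrix(rnorm(60, 0), 30, 2)
  xl <- matrix(rnorm(60, 4), 30, 2)
  shift <- c(5, -3)
  m0 <- fit_fisher(xe, xl)
  m1 <- fit_fisher(sweep(xe, 2, shift, "+"), sweep(xl, 2, shift, "+"))
  expect_equal(m0$weights, m1$weights, tolerance = 1e-10)
  x <- matrix(rnorm(20, 2), 10, 2)
  expect_equal(classify(m0, x), classify(m1, sweep(x, 2, shift, "+")))
})

test_that("well-separated gaussian clouds are almost perfectly separated and
           agree with an independent LDA implementation", {
  skip_if_not_installed("MASS")
  set.seed(123)
  n <- 200
  xe <- matrix(rnorm(2 * n, mean = 0, sd = 1), n, 2)
  xl <- matrix(rnorm(2 * n, mean = 5, sd = 1), n, 2)  # 5-sigma separation
  m <- fit_fisher(xe, xl)
  pred <- classify(m, rbind(xe, xl))
  truth <- rep(c("EC", "LEGH"), each = n)
  expect_gte(mean(pred == truth), 0.99)

  fit <- MASS::lda(x = rbind(xe, xl), grouping = factor(truth))
  ref <- as.character(stats::predict(fit, rbind(xe, xl))$class)
  expect_gte(mean(pred == ref), 0.99)
})

test_that("singular scatter falls back to a ridge solve with a warning", {
  xe <- cbind(c(1, 1, 1), c(0, 1, 2))   # first feature constant
  xl <- cbind(c(1, 1, 1), c(10, 11, 12))
  expect_warning(m <- fit_fisher(xe, xl), "ridge")
  expect_equal(classify(m, rbind(c(1, 0), c(1, 12))), c("EC", "LEGH"))
  expect_error(fit_fisher(matrix(1, 1, 2), xl), "at least 2")
})

test_that("bundled discriminants carry the printed coefficients and both
           orientation readings behave as documented", {
  pm <- preset_discriminants()
  expect_named(pm, c("2D", "3D", "sRGB"))
  expect_equal(pm[["2D"]]$weights, c(15.01, -43.55))
  expect_equal(pm[["2D"]]$bias, 1.454)
  expect_equal(pm[["3D"]]$weights, c(41.52, -55.34, -46.79))
  expect_equal(pm[["3D"]]$bias, 3.263)
  expect_equal(pm[["sRGB"]]$weights, c(83.41, -368.9, 365.8))
  expect_equal(pm[["sRGB"]]$bias, -74.22)
  expect_identical(pm[["2D"]]$feature_names, c("EY", "OG"))
  expect_identical(pm[["3D"]]$feature_names, c("EY", "LG", "OG"))
  expect_identical(pm[["sRGB"]]$feature_names, c("R", "G", "B"))

  # default orientation matches the published tables: an OG-free, EY-rich
  # sample is EC; an OG-rich sample is LEGH
  expect_equal(classify(pm[["2D"]], c(EY = 0.5, OG = 0)), "EC")
  expect_equal(classify(pm[["2D"]], c(EY = 0.1, OG = 0.4)), "LEGH")
  # literal printed rule: D >= 0 labeled LEGH, so the origin is LEGH
  pl <- preset_discriminants(positive_label = "LEGH")
  expect_equal(classify(pl[["2D"]], c(EY = 0, OG = 0)), "LEGH")
  expect_equal(classify(pl[["3D"]], c(EY = 0, LG = 0, OG = 0)), "LEGH")
  # D(1, 1) = 15.01 - 43.55 + 1.454 < 0 -> the non-positive label
  expect_equal(classify(pl[["2D"]], c(EY = 1, OG = 1)), "EC")
  # decision values themselves are orientation-independent
  expect_equal(predict(pm[["2D"]], c(EY = 0, OG = 0), type = "score"), 1.454)
  expect_equal(predict(pm[["3D"]], c(EY = 0, LG = 0, OG = 0), type = "score"),
               3.263)
})

test_that("classification agrees with direct evaluation of w.x + b", {
  set.seed(31)
  m <- discriminant_model(c("a", "b", "c"), c(1.5, -2, 0.3), -0.1)
  x <- matrix(rnorm(60), 20, 3)
  d <- drop(x %*% c(1.5, -2, 0.3)) - 0.1
  expect_equal(classify(m, x), ifelse(d >= 0, "LEGH", "EC"))
  expect_error(classify(m, matrix(1, 2, 2)), "2 columns")
})

test_that("evaluation metrics match hand-enumerated oracles on random
           confusion matrices", {
  set.seed(41)
  for (i in 1:25) {
    cm <- matrix(sample(0:40, 4, replace = TRUE), 2, 2)
    if (sum(cm) == 0) next
    rep <- eval_report_from_confusion(cm, "LEGH")
    tp <- cm[2, 2]; fp <- cm[1, 2]; fn <- cm[2, 1]; tn <- cm[1, 1]
    expect_equal(rep$accuracy, (tp + tn) / sum(cm))
    p <- if (tp + fp == 0) 0 else tp / (tp + fp)
    r <- if (tp + fn == 0) 0 else tp / (tp + fn)
    expect_equal(rep$precision, p)
    expect_equal(rep$recall, r)
    expect_equal(rep$f_value, if (p + r == 0) 0 else 2 * p * r / (p + r))
  }
})

test_that("evaluation from label vectors builds the right confusion matrix", {
  truth <- c("EC", "EC", "EC", "LEGH", "LEGH")
  pred  <- c("EC", "LEGH", "EC", "LEGH", "EC")
  rep <- evaluate_classification(truth, pred, positive_class = "LEGH")
  expect_equal(unclass(rep$confusion),
               matrix(c(2L, 1L, 1L, 1L), 2, 2,
                      dimnames = list(true = c("EC", "LEGH"),
                                      predicted = c("EC", "LEGH"))))
  perfect <- evaluate_classification(truth, truth, "LEGH")
  expect_equal(c(perfect$accuracy, perfect$precision, perfect$recall,
                 perfect$f_value), rep(1, 4))
  expect_error(evaluate_classification(c("EC", "XX"), c("EC", "EC"), "LEGH"),
               "unknown label")
  expect_error(evaluate_classification(truth, pred, "mucin"), "positive_class")
})
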