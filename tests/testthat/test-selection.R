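test_that("quantile threshold uses linear interpolation in both directions", {
  expect_equal(quantile_threshold(1:10, 0.8)$value, 8.2)
  expect_equal(quantile_threshold(1:10, 0.8, "bottom")$value, 2.8)
  expect_equal(quantile_threshold(1:11, 0.5)$value, 6)  # median
  expect_error(quantile_threshold(1:10, 1.2), "tau")
  expect_error(quantile_threshold(1:3, 0.8), "at least 5")
})

test_that("observed labels use strict inequalities with ties labeled 0", {
  top <- quantile_threshold(1:10, 0.8)                 # Y_tau = 8.2
  expect_equal(observed_labels(c(7, 9), top), c(0L, 1L))
  expect_equal(sum(observed_labels(1:10, top)), 2L)
  tie <- top; tie$value <- 8
  expect_equal(observed_labels(c(8, 8.0001), tie), c(0L, 1L))

  bot <- quantile_threshold(1:10, 0.8, "bottom")       # threshold 2.8
  expect_equal(observed_labels(c(1, 3), bot), c(1L, 0L))
})

test_that("R classification thresholds predictions and shows shrinkage bias", {
  rule <- quantile_threshold(1:10, 0.8)
  rule$value <- 8
  expect_equal(classify_r(c(8.5, 7.9), rule), c(1L, 0L))
  expect_equal(classify_r(c(8, 8), rule), c(0L, 0L))    # strict rule

  # shrunken predictions against a trait-scale threshold under-select:
  # this is the structural bias of the R method
  y <- 1:10
  rule2 <- quantile_threshold(y, 0.8)
  pred <- 0.5 * y
  expect_lt(sum(classify_r(pred, rule2)), sum(observed_labels(y, rule2)))
  expect_equal(sum(classify_r(pred, rule2)), 0L)
})

test_that("RC count-matching reproduces the worked confusion matrix", {
  rule <- quantile_threshold(1:10, 0.8); rule$value <- 8
  y_obs <- c(10, 9, 5, 4, 3)
  y_pred <- c(9.5, 4.8, 8.7, 3.9, 2.0)
  rc <- classify_rc(y_obs, y_pred, rule,
                    line_ids = paste0("line", 1:5))
  expect_equal(rc$k, 2L)
  expect_equal(rc$predicted, c(1L, 0L, 1L, 0L, 0L))  # lines 1 and 3
  cm <- confusion(rc$observed, rc$predicted)
  expect_equal(unlist(cm[c("TP", "FP", "FN", "TN")]),
               c(TP = 1, FP = 1, FN = 1, TN = 2))

  # perfectly ranked predictions: TP = k, no mistakes
  rc2 <- classify_rc(y_obs, y_obs + 0.1, rule)
  expect_equal(sum(rc2$predicted & rc2$observed), rc2$k)

  # k = 0: nothing selected
  rc0 <- classify_rc(c(1, 2, 3), c(5, 9, 1), rule)
  expect_equal(rc0$predicted, c(0L, 0L, 0L))
})

test_that("RC equal-count invariant forces FP = FN and Sens = Precision", {
  set.seed(5)
  for (rep in 1:20) {
    y_obs <- rnorm(40)
    y_pred <- 0.6 * y_obs + rnorm(40, sd = 0.8)
    rule <- quantile_threshold(rnorm(50), 0.8)
    rc <- classify_rc(y_obs, y_pred, rule)
    expect_equal(sum(rc$predicted), sum(rc$observed))
    cm <- confusion(rc$observed, rc$predicted)
    expect_equal(cm$FP, cm$FN)
    ms <- metric_set(cm)
    expect_equal(ms$sensitivity, ms$precision)
  }
})

test_that("trait-scale threshold tuning balances sensitivity and specificity", {
  base <- quantile_threshold(1:10, 0.8)
  # one fold, perfect separation: objective 0 only in (3, 4) -> midpoint
  inner <- list(list(scores = 1:5, labels = c(0L, 0L, 0L, 1L, 1L)))
  rule <- optimize_regression_threshold(inner, base)
  expect_equal(rule$value, 3.5)
  expect_equal(rule$provenance, "optimized")
  expect_equal(rule$per_fold, 3.5)

  # two folds: final threshold is the mean of per-fold optima
  inner2 <- list(list(scores = 1:5, labels = c(0L, 0L, 0L, 1L, 1L)),
                 list(scores = 2:6, labels = c(0L, 0L, 0L, 1L, 1L)))
  expect_equal(optimize_regression_threshold(inner2, base)$value, 4.0)
  expect_equal(mean(optimize_regression_threshold(inner2, base)$per_fold),
               optimize_regression_threshold(inner2, base)$value)

  # degenerate fold skipped with a message; all-degenerate falls back
  inner3 <- c(inner, list(list(scores = 1:4, labels = rep(1L, 4))))
  expect_message(r3 <- optimize_regression_threshold(inner3, base),
                 "degenerate")
  expect_equal(r3$value, 3.5)
  expect_warning(
    rfb <- optimize_regression_threshold(
      list(list(scores = 1:4, labels = rep(0L, 4))), base),
    "falling back")
  expect_equal(rfb$value, base$value)
  expect_equal(rfb$provenance, "fixed_fallback")
})

test_that("probability threshold tuning prefers 0.5 among ties and tracks imbalance", {
  inner <- list(list(scores = c(0.1, 0.2, 0.8, 0.9),
                     labels = c(0L, 0L, 1L, 1L)))
  rule <- optimize_probability_threshold(inner)
  expect_equal(rule$value, 0.5)
  expect_equal(rule$scale, "probability")

  # positives clustered below 0.5 (the shrinkage regime that defeats the
  # fixed 0.5 rule): tuned threshold drops below 0.5
  set.seed(6)
  inner2 <- lapply(1:5, function(f) {
    pos <- runif(4, 0.30, 0.40)
    neg <- runif(16, 0.05, 0.20)
    list(scores = c(pos, neg), labels = c(rep(1L, 4), rep(0L, 16)))
  })
  rule2 <- optimize_probability_threshold(inner2)
  expect_lt(rule2$value, 0.5)
  expect_gt(rule2$value, 0)
})

test_that("tuned thresholds never do worse than the base rule on the tuning folds", {
  set.seed(7)
  gap2 <- function(scores, labels, t) {
    pred <- as.integer(scores > t)
    cm <- confusion(labels, pred)
    ms <- metric_set(cm)
    (ms$sensitivity - ms$specificity)^2
  }
  for (rep in 1:10) {
    y <- rnorm(60, 10, 2)
    base <- quantile_threshold(y, 0.8)
    folds <- split(seq_len(60), rep(1:5, each = 12))
    inner <- lapply(folds, function(idx) {
      sc <- 10 + 0.5 * (y[idx] - 10) + rnorm(12, sd = 0.5)
      list(scores = sc, labels = observed_labels(y[idx], base))
    })
    keep <- vapply(inner, function(f) length(unique(f$labels)) == 2,
                   logical(1))
    inner <- inner[keep]
    if (!length(inner)) next
    tuned <- suppressMessages(optimize_regression_threshold(inner, base))
    obj_tuned <- mean(mapply(function(f, t) gap2(f$scores, f$labels, t),
                             inner, tuned$per_fold))
    obj_base <- mean(vapply(inner, function(f)
      gap2(f$scores, f$labels, base$value), numeric(1)))
    expect_lte(obj_tuned, obj_base + 1e-12)
  }
})

test_that("adjusted predictions reproduce the tuned classification", {
  base <- quantile_threshold(1:10, 0.8); base$value <- 4
  opt <- base; opt$value <- 2; opt$provenance <- "optimized"
  y_pred <- c(2, 4)
  adj <- adjusted_predictions(y_pred, base, opt)
  expect_equal(adj, c(4, 8))
  expect_equal(classify_r(adj, base), classify_r(y_pred, opt))

  expect_equal(adjusted_predictions(y_pred, base, base), y_pred)

  neg <- opt; neg$value <- -2
  expect_warning(adjusted_predictions(y_pred, base, neg), "sign")
  zero <- opt; zero$value <- 0
  expect_error(adjusted_predictions(y_pred, base, zero), "zero")
})

test_that("fixed probability rules classify strictly", {
  expect_equal(classify_b(c(0.49, 0.51)), c(0L, 1L))
  expect_equal(classify_b(c(0.5, 0.5)), c(0L, 0L))
  expect_equal(sum(classify_b(runif(100, 0.01, 0.49))), 0L)
  rule <- optimize_probability_threshold(
    list(list(scores = c(0.1, 0.2, 0.8, 0.9), labels = c(0L, 0L, 1L, 1L))))
  expect_equal(classify_prob(c(0.4, 0.6), rule), c(0L, 1L))
})

test_that("simple tuning folds partition the fit's in-sample scores", {
  d <- make_sim_data(n = 100, p = 150, seed = 51)
  fit <- fit_gblup(d$y, d$G, test = names(d$y)[1:20],
                   settings = tiny_mcmc(15))
  base <- quantile_threshold(d$y[fit$train_ids], 0.8)
  labels <- observed_labels(d$y[fit$train_ids], base)
  folds <- simple_tuning_scores(fit, labels, k_folds = 10, seed = 77)
  expect_length(folds, 10)
  expect_equal(sum(lengths(lapply(folds, `[[`, "scores"))), 80)
  expect_equal(sort(unlist(lapply(folds, `[[`, "scores"))),
               sort(unname(fitted_values(fit))))
  # deterministic partition under the seed
  folds2 <- simple_tuning_scores(fit, labels, k_folds = 10, seed = 77)
  expect_identical(folds, folds2)
  expect_error(simple_tuning_scores(fit, labels, k_folds = 50, seed = 1),
               "fewer than 2")
})

test_that("threshold rules serialize to JSON with provenance", {
  rule <- optimize_regression_threshold(
    list(list(scores = 1:5, labels = c(0L, 0L, 0L, 1L, 1L)),
         list(scores = 2:6, labels = c(0L, 0L, 0L, 1L, 1L))),
    quantile_threshold(1:10, 0.8))
  js <- jsonlite::fromJSON(threshold_rule_json(rule))
  expect_equal(js$value, 4.0)
  expect_equal(js$provenance, "optimized")
  expect_equal(js$per_fold, c(3.5, 4.5))
})
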