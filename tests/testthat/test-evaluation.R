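test_that("confusion matrix counts the four cells", {
  cm <- confusion(c(1, 1, 0, 0), c(1, 0, 1, 0))
  expect_equal(unlist(cm[c("TP", "FN", "FP", "TN")]),
               c(TP = 1, FN = 1, FP = 1, TN = 1))
  expect_equal(cm$N, 4)
  same <- confusion(c(1, 0, 1), c(1, 0, 1))
  expect_equal(same$FP + same$FN, 0)
  set.seed(3)
  o <- rbinom(10, 1, 0.5); p <- rbinom(10, 1, 0.5)
  cm10 <- confusion(o, p)
  expect_equal(cm10$TP + cm10$TN + cm10$FP + cm10$FN, 10)
  expect_error(confusion(c(1, 2), c(0, 1)), "0/1")
})

test_that("metric set reproduces the hand-worked kappa example", {
  cm <- structure(list(TP = 2, TN = 6, FP = 1, FN = 1, N = 10),
                  class = "confusion_matrix")
  ms <- metric_set(cm)
  expect_equal(ms$sensitivity, 2 / 3)
  expect_equal(ms$specificity, 6 / 7)
  expect_equal(ms$precision, 2 / 3)
  expect_equal(ms$f1, 2 / 3)
  expect_equal(ms$kappa, (0.8 - 0.58) / (1 - 0.58))  # 0.5238...

  perfect <- metric_set(confusion(c(1, 1, 0), c(1, 1, 0)))
  expect_equal(unlist(perfect), c(sensitivity = 1, specificity = 1,
                                  precision = 1, f1 = 1, kappa = 1))

  degenerate <- metric_set(confusion(c(0, 0, 0), c(0, 0, 0)))
  expect_true(is.na(degenerate$kappa))     # Pe = 1
  expect_true(is.na(degenerate$sensitivity))
})

test_that("kappa and F1 satisfy their structural bounds", {
  set.seed(9)
  for (i in 1:200) {
    cells <- rmultinom(1, sample(4:60, 1), runif(4, 0.05, 1))
    cm <- structure(list(TP = cells[1], TN = cells[2], FP = cells[3],
                         FN = cells[4], N = sum(cells)),
                    class = "confusion_matrix")
    ms <- metric_set(cm)
    if (!is.na(ms$kappa)) {
      expect_lte(ms$kappa, 1)
      expect_gte(ms$kappa, -1)
      if (ms$kappa == 1) expect_true(cm$FP == 0 && cm$FN == 0)
    }
    if (cm$FP == 0 && cm$FN == 0 && cm$TP > 0 && cm$TN > 0)
      expect_equal(ms$kappa, 1)
    if (!is.na(ms$f1)) {
      expect_gte(ms$f1, min(ms$precision, ms$sensitivity) - 1e-12)
      expect_lte(ms$f1, max(ms$precision, ms$sensitivity) + 1e-12)
    }
  }
})

test_that("nested CV emits five metrics per fold and is seed-deterministic", {
  d <- make_sim_data(n = 80, p = 150, seed = 61)
  st <- tiny_mcmc(21)
  rows <- run_nested_cv(d$y, d$G, models = c("RC", "R"), method = "O",
                        settings = st, seed = 31)
  expect_equal(nrow(rows), 2 * 5 * 5)   # 2 models x 5 folds x 5 metrics
  expect_setequal(unique(rows$metric),
                  c("sensitivity", "specificity", "precision", "f1", "kappa"))
  # RC equal-count invariant per fold: sensitivity == precision
  rc <- rows[rows$model == "RC", ]
  sens <- rc$value[rc$metric == "sensitivity"]
  prec <- rc$value[rc$metric == "precision"]
  expect_equal(sens, prec)

  rows2 <- run_nested_cv(d$y, d$G, models = c("RC", "R"), method = "O",
                         settings = st, seed = 31)
  expect_identical(rows, rows2)
})

test_that("O and S runs record the matching threshold provenance", {
  d <- make_sim_data(n = 80, p = 150, seed = 62)
  st <- tiny_mcmc(22)
  plan <- cv_plan(names(d$y), seed = 33)
  ro_s <- run_nested_cv(d$y, d$G, models = "RO", method = "S", plan = plan,
                        settings = st, return_details = TRUE)
  prov_s <- unique(vapply(attr(ro_s, "thresholds"),
                          function(x) x$rule$provenance, character(1)))
  expect_equal(prov_s, "optimized_simple")
  bo_s <- run_nested_cv(d$y, d$G, models = "BO", method = "S", plan = plan,
                        settings = st, return_details = TRUE)
  expect_true(all(vapply(attr(bo_s, "thresholds"), function(x)
    x$rule$scale == "probability" && x$rule$value > 0 && x$rule$value < 1,
    logical(1))))
})

test_that("thresholds are built from training data only (leakage audit)", {
  d <- make_sim_data(n = 120, p = 200, seed = 63)
  st <- tiny_mcmc(23)
  test_ids <- names(d$y)[1:30]
  get_rules <- function(y) {
    res <- suppressMessages(
      holdout_selection(y, d$G, test_ids,
                        models = c("RC", "R", "RO", "B", "BO"),
                        method = "S", settings = st, inner_seed = 5))
    lapply(res, function(m) m$rule[c("value", "per_fold")])
  }
  clean <- get_rules(d$y)
  corrupted <- d$y
  corrupted[test_ids] <- rev(corrupted[test_ids]) * -3 + 100
  expect_identical(get_rules(corrupted), clean)
})

test_that("aggregation follows the fold -> trait/env -> dataset -> across chain", {
  base <- expand.grid(environment = c("e1", "e2"), trait = "t",
                      model = "RO", method = "O", fold = 1:2,
                      metric = "f1", stringsAsFactors = FALSE)
  rows <- rbind(
    cbind(dataset = "d1", base,
          value = c(0.4, 0.5, 0.6, 0.5)),   # e1 folds: .4/.6, e2: .5/.5
    cbind(dataset = "d2", base, value = c(0.5, 0.55, 0.58, 0.53)))
  te <- aggregate_metrics(rows, "trait_env")
  expect_equal(te$value[te$dataset == "d1" & te$environment == "e1"], 0.5)
  ds <- aggregate_metrics(rows, "dataset")
  expect_equal(ds$value[ds$dataset == "d1"], 0.5)
  combo_means_d2 <- c(mean(c(0.5, 0.58)), mean(c(0.55, 0.53)))
  expect_equal(ds$value[ds$dataset == "d2"], mean(combo_means_d2))
  expect_equal(ds$se[ds$dataset == "d2"],
               sd(combo_means_d2) / sqrt(2))
  across <- aggregate_metrics(rows, "across")
  expect_equal(across$value, mean(ds$value))
  expect_equal(unique(across$dataset), "Across_Data")

  # undefined metrics excluded with a count, not coerced to zero
  rows$value[1] <- NA
  te2 <- aggregate_metrics(rows, "trait_env")
  hit <- te2$dataset == "d1" & te2$environment == "e1"
  expect_equal(te2$value[hit], 0.6)
  expect_equal(te2$n_excluded[hit], 1)
})

test_that("relative efficiency handles improvement and decrease forms", {
  re <- relative_efficiency(0.5276, 0.4813)
  expect_equal(re$percent, 9.62)
  expect_equal(relative_efficiency(0.4, 0.4)$percent, 0)
  dec <- relative_efficiency(0.2895, 0.5126, form = "decrease")
  expect_equal(dec$percent, 43.52)
  expect_error(relative_efficiency(0.5, 0), "positive")
  expect_error(relative_efficiency(-1, 0.5), "positive")
})
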