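#' Confusion matrix from 0/1 label vectors
#'
#' @param observed,predicted Integer 0/1 vectors of equal length >= 1.
#' @return List of class `confusion_matrix` with counts `TP`, `TN`, `FP`,
#'   `FN` and total `N`.
#' @export
confusion <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 1)
  if (!all(observed %in% c(0, 1)) || !all(predicted %in% c(0, 1)))
    stop("labels must be 0/1")
  tp <- sum(observed == 1 & predicted == 1)
  tn <- sum(observed == 0 & predicted == 0)
  fp <- sum(observed == 0 & predicted == 1)
  fn <- sum(observed == 1 & predicted == 0)
  structure(list(TP = tp, TN = tn, FP = fp, FN = fn,
                 N = tp + tn + fp + fn),
            class = "confusion_matrix")
}

#' Classification metrics from a confusion matrix
#'
#' Sensitivity = TP/(TP+FN); Specificity = TN/(TN+FP);
#' Precision = TP/(TP+FP); F1 = harmonic mean of precision and
#' sensitivity; Cohen's kappa = (P0 - Pe)/(1 - Pe) with
#' P0 = (TP+TN)/N and
#' Pe = (TP+FN)/N x (TP+FP)/N + (FP+TN)/N x (FN+TN)/N.
#'
#' Degenerate cells (0/0 divisions, or Pe = 1 for kappa) are returned as
#' `NA` rather than coerced to 0: downstream aggregation excludes them
#' and reports the exclusion count, so dataset means are not biased.
#'
#' @param cm A `confusion_matrix`.
#' @return Named list with `sensitivity`, `specificity`, `precision`,
#'   `f1`, `kappa` (each possibly `NA`).
#' @export
metric_set <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"), cm$N >= 1)
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- safe_div(cm$TP, cm$TP + cm$FN)
  spec <- safe_div(cm$TN, cm$TN + cm$FP)
  prec <- safe_div(cm$TP, cm$TP + cm$FP)
  f1 <- if (is.na(prec) || is.na(sens) || (prec + sens) == 0) NA_real_
        else 2 * prec * sens / (prec + sens)
  p0 <- (cm$TP + cm$TN) / cm$N
  pe <- (cm$TP + cm$FN) / cm$N * (cm$TP + cm$FP) / cm$N +
        (cm$FP + cm$TN) / cm$N * (cm$FN + cm$TN) / cm$N
  kappa <- if (abs(1 - pe) < 1e-15) NA_real_ else (p0 - pe) / (1 - pe)
  list(sensitivity = sens, specificity = spec, precision = prec,
       f1 = f1, kappa = kappa)
}

#' Nested cross-validation plan
#'
#' Seeded partition of the lines into `outer_k` outer folds; each outer
#' training set is further partitioned into `inner_k` inner folds for
#' threshold tuning.  Inner partitions use seeds derived from the plan
#' seed and the outer fold index, independent of the outer randomization.
#'
#' @param line_ids Character vector of line ids.
#' @param outer_k Number of outer folds (default 5).
#' @param inner_k Number of inner folds (default 10).
#' @param seed Integer seed (required).
#' @return A list of class `cv_plan` with `outer` (list of id vectors),
#'   `inner_seed` per outer fold, and the settings.
#' @export
cv_plan <- function(line_ids, outer_k = 5, inner_k = 10, seed) {
  if (missing(seed)) stop("an explicit seed is required for the CV plan")
  stopifnot(!anyDuplicated(line_ids), outer_k >= 2, inner_k >= 2)
  n <- length(line_ids)
  if (n < outer_k) stop("fewer lines than outer folds")
  assign <- fold_partition(n, outer_k, seed)
  structure(list(
    outer = lapply(seq_len(outer_k), function(f) line_ids[assign == f]),
    inner_seeds = seed + 1000L * seq_len(outer_k),
    outer_k = as.integer(outer_k), inner_k = as.integer(inner_k),
    seed = as.integer(seed), line_ids = line_ids),
    class = "cv_plan")
}

#' Selection methods evaluated on one training/test split
#'
#' The per-fold engine behind [run_nested_cv()], exported so a single
#' split can be audited directly (e.g. the label-leakage test corrupts
#' the test responses and asserts that no threshold moves).  Fits the
#' linear model once for RC/R/RO and the probit model once for B/BO,
#' runs the inner tuning loop where required, classifies the test lines,
#' and returns labels, thresholds and metrics per model.
#'
#' All thresholds are built exclusively from training-side structures:
#' the base quantile from the training responses, tuned thresholds from
#' inner-validation splits of the training set.  Test responses are read
#' only after every threshold is fixed (the RC rule reads the test
#' labels' count k, which is part of its classification rule, not of any
#' threshold).
#'
#' @param y Response vector over all lines (named by line id or aligned
#'   with `rownames(G)`).
#' @param G Relationship matrix over all lines.
#' @param test_ids Character ids of the held-out test lines.
#' @param models Subset of `c("RC", "R", "RO", "B", "BO")`.
#' @param method `"O"` (per-fold refits in the inner loop) or `"S"`
#'   (Simple: one fit, tune on its in-sample scores).
#' @param tau Base quantile level (default 0.8).
#' @param direction `"top"` or `"bottom"`.
#' @param settings [mcmc_settings()] for the model fits.
#' @param inner_k Inner folds for threshold tuning (default 10).
#' @param inner_seed Seed for inner partitions.
#' @return List with per-model elements: `observed`, `predicted`,
#'   `metrics` (from [metric_set()]), and `rule` (the classification
#'   threshold used).
#' @export
holdout_selection <- function(y, G, test_ids, models, method = c("O", "S"),
                              tau = 0.8, direction = "top", settings,
                              inner_k = 10, inner_seed) {
  method <- match.arg(method)
  stopifnot(all(models %in% c("RC", "R", "RO", "B", "BO")),
            length(models) >= 1)
  if (missing(inner_seed)) inner_seed <- settings$seed + 7L
  ids <- rownames(G)
  stopifnot(!is.null(ids), all(test_ids %in% ids))
  is_test <- ids %in% test_ids
  tr_ids <- ids[!is_test]
  y <- if (!is.null(names(y))) y[ids] else stats::setNames(y, ids)
  y_tr <- y[tr_ids]
  rule_base <- quantile_threshold(y_tr, tau, direction)
  labels_tr <- observed_labels(y_tr, rule_base)

  need_lin <- any(c("RC", "R", "RO") %in% models)
  need_bin <- any(c("B", "BO") %in% models)
  out <- list()

  inner_assign <- NULL
  get_inner_folds <- function() {
    if (is.null(inner_assign))
      inner_assign <<- fold_partition(length(tr_ids), inner_k, inner_seed)
    inner_assign
  }

  if (need_lin) {
    fit <- fit_gblup(y, G, test = test_ids, settings = settings)
    preds_test <- predict(fit, test_ids)
    if ("RC" %in% models) {
      rc <- classify_rc(y[test_ids], preds_test, rule_base,
                        line_ids = test_ids)
      out$RC <- list(observed = rc$observed, predicted = rc$predicted,
                     rule = rule_base)
    }
    if ("R" %in% models)
      out$R <- list(observed = observed_labels(y[test_ids], rule_base),
                    predicted = classify_r(preds_test, rule_base),
                    rule = rule_base)
    if ("RO" %in% models) {
      if (method == "O") {
        assign <- get_inner_folds()
        inner_cv <- lapply(seq_len(inner_k), function(f) {
          val_ids <- tr_ids[assign == f]
          ifit <- fit_gblup(y, G, test = c(val_ids, test_ids),
                            settings = settings)
          list(scores = unname(predict(ifit, val_ids)),
               labels = observed_labels(y[val_ids], rule_base))
        })
        rule_opt <- optimize_regression_threshold(inner_cv, rule_base)
      } else {
        inner_cv <- simple_tuning_scores(fit, labels_tr, k_folds = inner_k,
                                         seed = inner_seed)
        rule_opt <- optimize_regression_threshold(inner_cv, rule_base,
                                                  simple = TRUE)
      }
      out$RO <- list(observed = observed_labels(y[test_ids], rule_base),
                     predicted = classify_r(preds_test, rule_opt),
                     rule = rule_opt)
    }
  }

  if (need_bin) {
    yb <- stats::setNames(rep(NA_integer_, length(ids)), ids)
    yb[tr_ids] <- labels_tr
    if (length(unique(labels_tr)) < 2)
      stop("binarized training labels contain a single class")
    bfit <- fit_probit(yb, G, test = test_ids, settings = settings)
    probs_test <- predict(bfit, test_ids)
    obs_test <- observed_labels(y[test_ids], rule_base)
    if ("B" %in% models)
      out$B <- list(observed = obs_test,
                    predicted = classify_b(probs_test),
                    rule = new_threshold_rule("probability", 0.5,
                                              direction, tau, "fixed_half"))
    if ("BO" %in% models) {
      if (method == "O") {
        assign <- get_inner_folds()
        inner_cv <- lapply(seq_len(inner_k), function(f) {
          val_ids <- tr_ids[assign == f]
          ybi <- yb
          ybi[val_ids] <- NA_integer_
          ifit <- fit_probit(ybi, G, test = c(val_ids, test_ids),
                             settings = settings)
          list(scores = unname(predict(ifit, val_ids)),
               labels = observed_labels(y[val_ids], rule_base))
        })
        rule_tau0 <- optimize_probability_threshold(inner_cv, direction)
      } else {
        inner_cv <- simple_tuning_scores(bfit, labels_tr, k_folds = inner_k,
                                         seed = inner_seed)
        rule_tau0 <- optimize_probability_threshold(inner_cv, direction,
                                                    simple = TRUE)
      }
      out$BO <- list(observed = obs_test,
                     predicted = classify_prob(probs_test, rule_tau0),
                     rule = rule_tau0)
    }
  }

  for (m in names(out))
    out[[m]]$metrics <- metric_set(confusion(out[[m]]$observed,
                                             out[[m]]$predicted))
  out[models[models %in% names(out)]]
}

#' Nested cross-validation benchmark for one (environment, trait) slice
#'
#' Runs the 5x10 nested cross-validation over a single response vector:
#' for each outer fold the base quantile threshold is computed from the
#' outer-training responses, the required models are fitted with the test
#' lines masked, tuned thresholds are found on inner splits of the
#' training set (refitting per inner fold for method "O", reusing the
#' single training fit for method "S"), the test lines are classified,
#' and a metric set is emitted per fold and model.  Test labels never
#' influence any threshold.
#'
#' @param y Named response vector (one value per line).
#' @param G Relationship matrix with matching rownames.
#' @param models Subset of `c("RC", "R", "RO", "B", "BO")`; models that
#'   share a fit (RC/R/RO; B/BO) are evaluated from one fit per fold.
#' @param method `"O"` or `"S"`.
#' @param plan A [cv_plan()]; built from `rownames(G)` and `seed` if
#'   omitted.
#' @param tau,direction Base threshold level and selection direction.
#' @param settings [mcmc_settings()] used for every fit.
#' @param dataset,environment,trait Labels copied into the output rows.
#' @param seed Seed for the plan when `plan` is missing.
#' @param return_details Keep per-fold threshold rules as an attribute.
#' @return A data.frame with columns dataset, environment, trait, model,
#'   method, fold, metric, value (5 metrics per fold and model).  With
#'   `return_details = TRUE` an attribute `"thresholds"` lists the rules.
#' @export
run_nested_cv <- function(y, G, models = c("RC", "R", "RO", "B", "BO"),
                          method = c("O", "S"), plan = NULL, tau = 0.8,
                          direction = "top", settings,
                          dataset = "data", environment = "env",
                          trait = "trait", seed = NULL,
                          return_details = FALSE) {
  method <- match.arg(method)
  ids <- rownames(G)
  if (is.null(plan)) {
    if (is.null(seed)) stop("supply a cv_plan or a seed")
    plan <- cv_plan(ids, seed = seed)
  }
  stopifnot(inherits(plan, "cv_plan"), setequal(plan$line_ids, ids))
  min_needed <- 2 * plan$inner_k
  rows <- list()
  details <- list()
  for (f in seq_len(plan$outer_k)) {
    test_ids <- plan$outer[[f]]
    if (length(ids) - length(test_ids) < min_needed)
      stop("outer training fold ", f, " has fewer than ",
           min_needed, " lines")
    res <- holdout_selection(y, G, test_ids, models, method, tau,
                             direction, settings,
                             inner_k = plan$inner_k,
                             inner_seed = plan$inner_seeds[f])
    for (m in names(res)) {
      ms <- res[[m]]$metrics
      rows[[length(rows) + 1L]] <- data.frame(
        dataset = dataset, environment = environment, trait = trait,
        model = m, method = method, fold = f,
        metric = names(ms), value = unlist(ms, use.names = FALSE),
        stringsAsFactors = FALSE)
      if (return_details)
        details[[length(details) + 1L]] <-
          list(fold = f, model = m, rule = res[[m]]$rule)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (return_details) attr(out, "thresholds") <- details
  out
}

#' Benchmark every (environment, trait) slice of a dataset
#'
#' Applies [run_nested_cv()] to each environment x trait combination of a
#' phenotype table (models are fitted per environment; environments are
#' not modeled jointly).
#'
#' @param phenotypes A `phenotype_table`.
#' @param G Relationship matrix covering all phenotyped lines.
#' @param dataset Dataset label for the output rows.
#' @param ... Passed to [run_nested_cv()] (models, method, tau,
#'   direction, settings, seed, ...).
#' @return Row-bound benchmark data.frame across all slices.
#' @export
benchmark_dataset <- function(phenotypes, G, dataset = "data", ...) {
  stopifnot(inherits(phenotypes, "phenotype_table"))
  combos <- unique(phenotypes[, c("environment", "trait")])
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    env <- combos$environment[i]; trt <- combos$trait[i]
    sl <- phenotypes[phenotypes$environment == env &
                     phenotypes$trait == trt & !phenotypes$missing, ]
    yv <- stats::setNames(sl$value, sl$line_id)
    Gs <- G[sl$line_id, sl$line_id, drop = FALSE]
    run_nested_cv(yv, Gs, dataset = dataset, environment = env,
                  trait = trt, ...)
  })
  do.call(rbind, rows)
}

#' Hierarchical aggregation of benchmark rows
#'
#' Collapses the benchmark table the way multi-dataset summaries are
#' reported: fold means per (dataset, environment, trait); then mean and
#' standard error across the environment x trait combinations per
#' dataset (SE = sd across combos / sqrt(number of combos)); then an
#' unweighted mean across datasets (labeled `Across_Data`).  Undefined
#' (`NA`) metric values are excluded and counted.
#'
#' @param rows Benchmark data.frame from [run_nested_cv()].
#' @param level `"trait_env"`, `"dataset"` or `"across"`.
#' @return A data.frame of means (plus `se` and `n` at dataset level,
#'   and `n_excluded` counts of dropped undefined values).
#' @export
aggregate_metrics <- function(rows,
                              level = c("trait_env", "dataset", "across")) {
  level <- match.arg(level)
  if (nrow(rows) < 1) stop("empty benchmark table")
  rows$excluded <- is.na(rows$value)
  grp <- c("dataset", "environment", "trait", "model", "method", "metric")
  te <- stats::aggregate(rows["value"], by = rows[grp],
                         FUN = mean, na.rm = TRUE)
  te$n_excluded <- stats::aggregate(rows["excluded"], by = rows[grp],
                                    FUN = sum)$excluded
  te$value[is.nan(te$value)] <- NA_real_
  if (level == "trait_env") return(te)
  grp2 <- c("dataset", "model", "method", "metric")
  ds <- stats::aggregate(te["value"], by = te[grp2],
                         FUN = mean, na.rm = TRUE)
  ds$se <- stats::aggregate(te["value"], by = te[grp2],
                            FUN = function(v) {
                              v <- v[!is.na(v)]
                              if (length(v) < 2) NA_real_
                              else stats::sd(v) / sqrt(length(v))
                            })$value
  ds$n <- stats::aggregate(list(n = !is.na(te$value)), by = te[grp2],
                           FUN = sum)$n
  ds$value[is.nan(ds$value)] <- NA_real_
  if (level == "dataset") return(ds)
  across <- stats::aggregate(ds["value"],
                             by = ds[c("model", "method", "metric")],
                             FUN = mean, na.rm = TRUE)
  across$value[is.nan(across$value)] <- NA_real_
  across$dataset <- "Across_Data"
  across[, c("dataset", "model", "method", "metric", "value")]
}

#' Relative efficiency of one method over another
#'
#' \eqn{RE = m_y / m_z} for a shared metric.  Expressed either as a
#' percentage improvement of y over z, \eqn{(RE - 1) \times 100}, or as
#' the percentage decrease of y below z, \eqn{(1 - RE) \times 100}
#' (used when reporting how far a weaker method falls short).
#' Percentages are rounded to two decimals for reporting.
#'
#' @param metric_y,metric_z Positive metric values (y is the method being
#'   assessed, z the reference).
#' @param form `"improvement"` or `"decrease"`.
#' @return List of class `relative_efficiency` with `re`, `percent`,
#'   `form`.
#' @export
relative_efficiency <- function(metric_y, metric_z,
                                form = c("improvement", "decrease")) {
  form <- match.arg(form)
  if (!is.finite(metric_z) || metric_z <= 0)
    stop("reference metric must be strictly positive")
  if (!is.finite(metric_y) || metric_y <= 0)
    stop("metric_y must be strictly positive")
  re <- metric_y / metric_z
  pct <- if (form == "improvement") (re - 1) * 100 else (1 - re) * 100
  structure(list(re = re, percent = round(pct, 2), form = form),
            class = "relative_efficiency")
}

#' @export
print.relative_efficiency <- function(x, ...) {
  sign <- if (x$form == "improvement") "+" else "-"
  cat(sprintf("RE = %.4f (%s%.2f%% %s)\n", x$re, sign, abs(x$percent),
              x$form))
  invisible(x)
}
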