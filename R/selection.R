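#' Base quantile threshold on the trait scale
#'
#' The base selection threshold \eqn{Y_\tau} is the empirical quantile of
#' the training responses at level `tau` for top-line selection, or at
#' `1 - tau` for bottom-line selection (traits where low is good, e.g.
#' disease scores).  The linear-interpolation (type 7) quantile definition
#' is used.
#'
#' @param y_train Training responses (>= 5 values).
#' @param tau Quantile level in (0, 1); default 0.8.
#' @param direction `"top"` or `"bottom"`.
#' @return A `threshold_rule`: list with `scale` ("phenotype"), `value`,
#'   `tau`, `direction` and `provenance = "fixed_quantile"`.
#' @export
quantile_threshold <- function(y_train, tau = 0.8, direction = c("top", "bottom")) {
  direction <- match.arg(direction)
  if (!is.numeric(tau) || length(tau) != 1 || tau <= 0 || tau >= 1)
    stop("tau must lie strictly inside (0, 1)")
  y_train <- y_train[is.finite(y_train)]
  if (length(y_train) < 5) stop("need at least 5 training values")
  level <- if (direction == "top") tau else 1 - tau
  new_threshold_rule(scale = "phenotype",
                     value = unname(stats::quantile(y_train, level, type = 7)),
                     direction = direction, tau = tau,
                     provenance = "fixed_quantile")
}

new_threshold_rule <- function(scale, value, direction, tau = NA_real_,
                               provenance, per_fold = NULL) {
  stopifnot(scale %in% c("phenotype", "probability"),
            direction %in% c("top", "bottom"))
  if (scale == "probability" && (value <= 0 || value >= 1))
    stop("probability-scale threshold must lie in (0, 1)")
  structure(list(scale = scale, value = value, direction = direction,
                 tau = tau, provenance = provenance, per_fold = per_fold),
            class = "threshold_rule")
}

#' @export
print.threshold_rule <- function(x, ...) {
  cat(sprintf("<threshold_rule> %s scale, %s lines: value = %.6g (%s)\n",
              x$scale, x$direction, x$value, x$provenance))
  if (!is.null(x$per_fold))
    cat("  inner-fold thresholds:",
        paste(signif(x$per_fold, 5), collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a threshold rule to JSON
#'
#' @param rule A `threshold_rule`.
#' @return A JSON string with scale, value, tau, direction, provenance and
#'   any per-inner-fold thresholds.
#' @export
threshold_rule_json <- function(rule) {
  stopifnot(inherits(rule, "threshold_rule"))
  jsonlite::toJSON(rule[c("scale", "value", "direction", "tau",
                          "provenance", "per_fold")],
                   auto_unbox = TRUE, digits = NA, null = "null")
}

#' Label observed responses as selected (1) or not (0)
#'
#' A line is a top line iff its response strictly exceeds the threshold
#' (strictly below it, for bottom-line selection); values exactly at the
#' threshold are labeled 0.
#'
#' @param y Observed responses.
#' @param rule A phenotype-scale `threshold_rule`.
#' @return Integer 0/1 vector.
#' @export
observed_labels <- function(y, rule) {
  stopifnot(inherits(rule, "threshold_rule"))
  if (rule$scale != "phenotype")
    stop("observed labels require a phenotype-scale rule")
  as.integer(if (rule$direction == "top") y > rule$value else y < rule$value)
}

#' Threshold classification of continuous predictions (method R)
#'
#' Predicted label 1 iff the predicted value strictly exceeds the
#' threshold (strictly below, for bottom selection).  With the base
#' quantile rule this is the R method; with an optimized rule it is the
#' classification step of RO.
#'
#' @param y_pred Predicted values on the trait scale.
#' @param rule A phenotype-scale `threshold_rule`.
#' @return Integer 0/1 vector.
#' @export
classify_r <- function(y_pred, rule) {
  stopifnot(inherits(rule, "threshold_rule"))
  if (rule$scale != "phenotype")
    stop("classify_r requires a phenotype-scale rule")
  as.integer(if (rule$direction == "top") y_pred > rule$value
             else y_pred < rule$value)
}

#' Count-matching classification (method RC)
#'
#' The conventional GBLUP selector: count how many observed test
#' responses are beyond the threshold (k), then predict label 1 for the k
#' test lines with the most extreme predicted values.  Predicted and
#' observed positive counts are equal by construction, which forces
#' FP = FN and hence Sensitivity = Precision.  Ties at rank k are broken
#' by line id order (lexicographic), so the rule is deterministic.
#'
#' @param y_obs Observed test responses.
#' @param y_pred Predicted test values, same length.
#' @param rule A phenotype-scale `threshold_rule`.
#' @param line_ids Optional ids used for the tie-break; defaults to input
#'   order.
#' @return List with integer vectors `observed` and `predicted`, the
#'   count `k`, and `line_ids`.
#' @export
classify_rc <- function(y_obs, y_pred, rule, line_ids = NULL) {
  stopifnot(length(y_obs) == length(y_pred), length(y_obs) >= 1)
  if (is.null(line_ids)) line_ids <- sprintf("L%06d", seq_along(y_obs))
  obs <- observed_labels(y_obs, rule)
  k <- sum(obs)
  pred <- integer(length(y_pred))
  if (k > 0) {
    ord <- if (rule$direction == "top") order(-y_pred, line_ids)
           else order(y_pred, line_ids)
    pred[ord[seq_len(k)]] <- 1L
  }
  list(observed = obs, predicted = pred, k = k, line_ids = line_ids)
}

#' Probability classification at the fixed 0.5 rule (method B)
#'
#' @param p_hat Predicted class probabilities in (0, 1).
#' @return Integer 0/1 vector: 1 iff probability strictly exceeds 0.5.
#' @export
classify_b <- function(p_hat) {
  stopifnot(all(p_hat > 0 & p_hat < 1))
  as.integer(p_hat > 0.5)
}

#' Probability classification at an arbitrary threshold (method BO)
#'
#' @param p_hat Predicted class probabilities.
#' @param rule A probability-scale `threshold_rule`.
#' @return Integer 0/1 vector: 1 iff probability strictly exceeds the
#'   threshold.
#' @export
classify_prob <- function(p_hat, rule) {
  stopifnot(inherits(rule, "threshold_rule"))
  if (rule$scale != "probability")
    stop("classify_prob requires a probability-scale rule")
  as.integer(p_hat > rule$value)
}

# Sensitivity/specificity of thresholding `scores` at `t` against 0/1
# labels.  `flip` reverses the inequality for bottom-line trait scores.
sens_spec_at <- function(scores, labels, t, flip = FALSE) {
  pred <- if (flip) scores < t else scores > t
  pos <- labels == 1
  c(sens = sum(pred & pos) / sum(pos),
    spec = sum(!pred & !pos) / sum(!pos))
}

# Shared engine for both threshold optimizers.  For each inner fold,
# every candidate threshold is evaluated and the one minimizing
# (Sensitivity - Specificity)^2 is kept; ties go to the candidate closest
# to the base threshold (minimal deviation from the default rule), then
# to the smaller value.  Folds with a single label class carry no
# sensitivity/specificity information and are skipped; if every fold is
# degenerate the base rule is returned with a warning.
optimize_threshold_engine <- function(inner_cv, base_value, candidates_fun,
                                      flip, scale, direction, tau,
                                      provenance) {
  stopifnot(is.list(inner_cv), length(inner_cv) >= 1)
  per_fold <- numeric(0)
  skipped <- 0L
  for (fold in inner_cv) {
    scores <- fold$scores; labels <- fold$labels
    stopifnot(length(scores) == length(labels))
    if (length(unique(labels)) < 2) { skipped <- skipped + 1L; next }
    cand <- candidates_fun(scores)
    obj <- vapply(cand, function(t) {
      ss <- sens_spec_at(scores, labels, t, flip)
      (ss["sens"] - ss["spec"])^2
    }, numeric(1))
    best <- which(obj <= min(obj) + 1e-12)
    if (length(best) > 1) {
      dist <- abs(cand[best] - base_value)
      best <- best[order(dist, cand[best])][1]
    }
    per_fold <- c(per_fold, cand[best])
  }
  if (!length(per_fold)) {
    warning("all inner folds degenerate (single class); ",
            "falling back to the base threshold")
    return(new_threshold_rule(scale, base_value, direction, tau,
                              provenance = "fixed_fallback"))
  }
  if (skipped > 0)
    message(skipped, " degenerate inner fold(s) skipped during threshold tuning")
  new_threshold_rule(scale, mean(per_fold), direction, tau,
                     provenance = provenance, per_fold = per_fold)
}

# Candidate cuts on a continuous score axis: midpoints of adjacent sorted
# unique scores plus one cut below the minimum and one above the maximum.
# Any threshold between two consecutive scores yields the same confusion
# matrix as the midpoint, so this set covers every achievable one.
score_candidates <- function(scores) {
  s <- sort(unique(scores))
  if (length(s) == 1) return(c(s - 0.5, s + 0.5))
  pad <- (s[length(s)] - s[1]) / 2
  c(s[1] - pad, (s[-1] + s[-length(s)]) / 2, s[length(s)] + pad)
}

#' Tune the trait-scale threshold to balance sensitivity and specificity
#'
#' For each inner-validation fold, finds the cut on the predicted values
#' that minimizes the squared gap between sensitivity and specificity;
#' the optimized threshold \eqn{Y_o} is the mean of the per-fold optima.
#' This is the tuning step of the RO (Regression Optimum) method.
#'
#' @param inner_cv List of folds, each a list with numeric `scores`
#'   (validation predictions) and integer 0/1 `labels` (observed labels of
#'   the validation lines).
#' @param base_rule The base phenotype-scale `threshold_rule` (used for
#'   tie-breaking among equally good candidates, and as fallback if every
#'   fold is degenerate).
#' @param simple Logical; marks the provenance as `optimized_simple` when
#'   the scores came from a single-fit Simple tuning pass.
#' @return A phenotype-scale `threshold_rule` with
#'   `provenance = "optimized"` (or `"optimized_simple"`) carrying the
#'   per-fold thresholds.
#' @export
optimize_regression_threshold <- function(inner_cv, base_rule,
                                          simple = FALSE) {
  stopifnot(inherits(base_rule, "threshold_rule"),
            base_rule$scale == "phenotype")
  optimize_threshold_engine(
    inner_cv, base_value = base_rule$value,
    candidates_fun = score_candidates,
    flip = base_rule$direction == "bottom",
    scale = "phenotype", direction = base_rule$direction,
    tau = base_rule$tau,
    provenance = if (simple) "optimized_simple" else "optimized")
}

#' Tune the probability threshold to balance sensitivity and specificity
#'
#' Same contract as [optimize_regression_threshold()] but on the
#' probability scale: candidates are midpoints of adjacent sorted unique
#' validation probabilities together with the default 0.5, which is also
#' the tie-break anchor.  This is the tuning step of the BO method.
#'
#' @param inner_cv List of folds with `scores` (validation probabilities)
#'   and `labels`.
#' @param direction `"top"` or `"bottom"` (label semantics already encode
#'   the direction; recorded for provenance only).
#' @param simple Logical; see [optimize_regression_threshold()].
#' @return A probability-scale `threshold_rule` with the optimized
#'   \eqn{\tau_0} in (0, 1).
#' @export
optimize_probability_threshold <- function(inner_cv,
                                           direction = c("top", "bottom"),
                                           simple = FALSE) {
  direction <- match.arg(direction)
  rule <- optimize_threshold_engine(
    inner_cv, base_value = 0.5,
    candidates_fun = function(scores) {
      s <- sort(unique(scores))
      mids <- if (length(s) > 1) (s[-1] + s[-length(s)]) / 2 else numeric(0)
      sort(unique(c(mids, 0.5)))
    },
    flip = FALSE, scale = "probability", direction = direction,
    tau = NA_real_,
    provenance = if (simple) "optimized_simple" else "optimized")
  if (rule$value <= 0 || rule$value >= 1) {  # cannot occur for prob scores
    rule$value <- min(max(rule$value, 1e-6), 1 - 1e-6)
  }
  rule
}

#' Rescale predictions so the base threshold reproduces the tuned rule
#'
#' Adjusted predictions \eqn{\hat Y^*_i = \hat Y_i (Y_\tau / Y_o)} let the
#' tuned classification be expressed against the familiar base threshold:
#' classifying \eqn{\hat Y^*} against \eqn{Y_\tau} equals classifying
#' \eqn{\hat Y} against \eqn{Y_o} whenever \eqn{Y_\tau / Y_o > 0}.  If the
#' two thresholds differ in sign the equivalence fails; a warning is
#' emitted and the direct \eqn{Y_o} rule remains authoritative.
#'
#' @param y_pred Predicted values.
#' @param rule_base Base phenotype-scale rule (\eqn{Y_\tau}).
#' @param rule_opt Optimized phenotype-scale rule (\eqn{Y_o}), nonzero.
#' @return Numeric vector of adjusted predictions.
#' @export
adjusted_predictions <- function(y_pred, rule_base, rule_opt) {
  stopifnot(inherits(rule_base, "threshold_rule"),
            inherits(rule_opt, "threshold_rule"))
  if (rule_opt$value == 0)
    stop("optimized threshold is zero; rescaling undefined")
  ratio <- rule_base$value / rule_opt$value
  if (ratio < 0)
    warning("base and optimized thresholds differ in sign; ",
            "adjusted predictions do not reproduce the tuned rule")
  y_pred * ratio
}

#' Build inner-CV tuning folds from a single model fit (Simple variants)
#'
#' The Simple RO/BO methods fit the expensive model once on the complete
#' training set and tune the threshold on that fit's in-sample fitted
#' values, partitioned into `k_folds` seeded folds, instead of refitting
#' the model per inner fold.
#'
#' @param fit A `gblup_fit` or `probit_fit` trained on the full training
#'   set.
#' @param labels Integer 0/1 observed labels for the training lines, in
#'   the order of `fit$train_ids`.
#' @param k_folds Number of tuning folds (default 10).
#' @param seed RNG seed for the partition (required).
#' @return A list of folds, each with `scores` and `labels`, suitable for
#'   the threshold optimizers.
#' @export
simple_tuning_scores <- function(fit, labels, k_folds = 10, seed) {
  if (missing(seed)) stop("an explicit seed is required for the partition")
  scores <- fitted_values(fit)
  n <- length(scores)
  stopifnot(length(labels) == n, all(labels %in% c(0L, 1L)))
  if (n < 2 * k_folds)
    stop("fewer than 2 lines per tuning fold (n = ", n, ", k = ", k_folds, ")")
  assign <- fold_partition(n, k_folds, seed)
  lapply(seq_len(k_folds), function(f) {
    idx <- which(assign == f)
    list(scores = unname(scores[idx]), labels = labels[idx])
  })
}

# Balanced random partition of n items into k folds (sizes differ by at
# most one), deterministic under the seed.
fold_partition <- function(n, k, seed) {
  set.seed(seed)
  sample(rep(seq_len(k), length.out = n))
}
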