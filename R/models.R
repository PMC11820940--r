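#' Gibbs sampler control settings
#'
#' The seed is mandatory: MCMC output is otherwise irreproducible.
#'
#' @param n_iter Total Gibbs iterations (default 6000).
#' @param burn_in Iterations discarded before summarizing (default 1000).
#' @param thin Keep every `thin`-th post-burn-in draw (default 5).
#' @param seed Integer RNG seed (required).
#' @return A list of class `mcmc_settings`.
#' @export
mcmc_settings <- function(n_iter = 6000, burn_in = 1000, thin = 5, seed) {
  if (missing(seed) || is.null(seed))
    stop("an explicit seed is required for MCMC settings")
  stopifnot(n_iter > burn_in, burn_in >= 0, thin >= 1)
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), seed = as.integer(seed)),
            class = "mcmc_settings")
}

# Eigen machinery shared by both samplers.  Decomposes G on the training
# block, drops numerically null components, and precomputes the
# projection of test-line genetic values onto the rotated training
# effects:  E[g_test | g_train] = G[test,train] G[tt]^{-1} g_train
#                              = (G[test,train] U D^{-1}) a.
# The Schur-complement diagonal gives the conditional prediction
# variance needed for probit probabilities.
prepare_eigen <- function(G, train_idx, test_idx, tol = 1e-8) {
  Gtt <- G[train_idx, train_idx, drop = FALSE]
  eg <- eigen(Gtt, symmetric = TRUE)
  keep <- eg$values > tol * max(eg$values)
  if (!any(keep)) stop("training block of G is numerically zero; stabilize G")
  U <- eg$vectors[, keep, drop = FALSE]
  d <- eg$values[keep]
  out <- list(U = U, d = d, k = length(d), min_eigen = min(eg$values))
  if (length(test_idx)) {
    B <- G[test_idx, train_idx, drop = FALSE] %*% U        # n_test x k
    out$P <- sweep(B, 2, d, "/")                           # projection onto a
    s <- diag(G[test_idx, test_idx, drop = FALSE]) -
      rowSums(sweep(B^2, 2, d, "/"))
    out$schur <- pmax(s, 0)
  }
  out
}

resolve_mask <- function(y, G, test) {
  n <- nrow(G)
  ids <- rownames(G)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  if (length(y) != n) stop("length(y) must equal nrow(G)")
  if (is.null(test)) {
    mask <- rep(FALSE, n)
  } else if (is.logical(test)) {
    stopifnot(length(test) == n)
    mask <- test
  } else if (is.character(test)) {
    if (!all(test %in% ids)) stop("unknown test line id(s)")
    mask <- ids %in% test
  } else {
    mask <- seq_len(n) %in% as.integer(test)
  }
  list(ids = ids, mask = mask, train = which(!mask), test = which(mask))
}

#' Fit the GBLUP regression model by Gibbs sampling
#'
#' Linear mixed model \eqn{Y_i = \mu + g_i + \epsilon_i} with
#' \eqn{g \sim N(0, \sigma_g^2 G)} and \eqn{\epsilon_i \sim N(0, \sigma^2)}.
#' The training block of G is eigendecomposed once and the genetic effects
#' are sampled in the rotated basis, where the conditional updates are
#' independent and fully vectorized.  Masked (test) lines contribute no
#' likelihood and enter only through G; their predictions are posterior
#' means of \eqn{\mu + g_i} obtained by projecting the rotated effects
#' through \eqn{G[test,train] G[train,train]^{-1}}.
#'
#' Priors: flat on \eqn{\mu}; scaled-inverse-chi-squared on both variance
#' components with `df = 5` and scales splitting the sample variance of
#' the training response 50/50 between genetic and residual (genetic scale
#' divided by the mean training diagonal of G).  Either variance can be
#' fixed instead of sampled, which is how the closed-form BLUP oracle is
#' matched in tests.
#'
#' @param y Numeric response, one entry per row of `G`; entries for masked
#'   lines are ignored (may be NA).
#' @param G Relationship matrix covering all lines (train + test),
#'   positive semi-definite; see [stabilize_grm()].
#' @param test Lines to mask: logical vector, integer indices, or line ids
#'   matching `rownames(G)`.  `NULL` means all lines train.
#' @param settings An [mcmc_settings()] object.
#' @param sigma2_g,sigma2_e Optional fixed variance components; `NULL`
#'   (default) samples them.
#' @param mu_fixed Optional fixed intercept; `NULL` samples it.
#' @param min_train Minimum number of unmasked lines (default 20; lowered
#'   only in oracle tests).
#' @return An object of class `gblup_fit` with posterior means `mu_hat`,
#'   `g_hat` (all lines), `sigma2_g_hat`, `sigma2_e_hat`, `h2_hat`,
#'   per-masked-line `predictions`, effective sample sizes and the
#'   settings used.
#' @export
fit_gblup <- function(y, G, test = NULL, settings,
                      sigma2_g = NULL, sigma2_e = NULL, mu_fixed = NULL,
                      min_train = 20) {
  stopifnot(inherits(settings, "mcmc_settings"))
  mk <- resolve_mask(y, G, test)
  tr <- mk$train; te <- mk$test
  if (length(tr) < min_train)
    stop("too few unmasked lines (", length(tr), ") to fit GBLUP")
  y_tr <- y[tr]
  if (anyNA(y_tr)) stop("training response contains missing values")
  ev <- prepare_eigen(G, tr, te)
  if (ev$min_eigen < -1e-6)
    stop("G is not positive semi-definite; call stabilize_grm() first")
  U <- ev$U; d <- ev$d; k <- ev$k
  n_tr <- length(tr)
  ystar <- drop(crossprod(U, y_tr))            # rotated response
  ones_star <- drop(crossprod(U, rep(1, n_tr)))

  vy <- max(stats::var(y_tr), 1e-8)   # guard: constant response
  df0 <- 5
  S_g <- 0.5 * vy * (df0 + 2) / mean(diag(G)[tr])
  S_e <- 0.5 * vy * (df0 + 2)

  set.seed(settings$seed)
  s2g <- if (is.null(sigma2_g)) 0.5 * vy / mean(diag(G)[tr]) else sigma2_g
  s2e <- if (is.null(sigma2_e)) 0.5 * vy else sigma2_e
  mu <- if (is.null(mu_fixed)) mean(y_tr) else mu_fixed
  a <- rep(0, k)

  keep_it <- seq(settings$burn_in + 1, settings$n_iter, by = settings$thin)
  n_keep <- length(keep_it)
  a_sum <- rep(0, k)
  mu_keep <- s2g_keep <- s2e_keep <- numeric(n_keep)
  g_tr_sum <- rep(0, n_tr)
  slot <- 0L

  for (it in seq_len(settings$n_iter)) {
    # rotated genetic effects: independent normal conditionals
    prec <- 1 / s2e + 1 / (s2g * d)
    v <- 1 / prec
    m <- v * (ystar - mu * ones_star) / s2e
    a <- m + sqrt(v) * stats::rnorm(k)
    g_tr <- drop(U %*% a)
    # intercept (flat prior)
    if (is.null(mu_fixed))
      mu <- stats::rnorm(1, mean(y_tr - g_tr), sqrt(s2e / n_tr))
    res <- y_tr - mu - g_tr
    # variance components (scaled-inverse-chi-squared conditionals)
    if (is.null(sigma2_g))
      s2g <- (S_g + sum(a^2 / d)) / stats::rchisq(1, df0 + k)
    if (is.null(sigma2_e))
      s2e <- (S_e + sum(res^2)) / stats::rchisq(1, df0 + n_tr)
    if (it > settings$burn_in &&
        (it - settings$burn_in - 1L) %% settings$thin == 0L) {
      slot <- slot + 1L
      a_sum <- a_sum + a
      g_tr_sum <- g_tr_sum + g_tr
      mu_keep[slot] <- mu; s2g_keep[slot] <- s2g; s2e_keep[slot] <- s2e
    }
  }

  a_bar <- a_sum / n_keep
  g_hat <- rep(NA_real_, length(y))
  g_hat[tr] <- g_tr_sum / n_keep
  if (length(te)) g_hat[te] <- drop(ev$P %*% a_bar)
  mu_hat <- mean(mu_keep)
  s2g_hat <- mean(s2g_keep)
  s2e_hat <- mean(s2e_keep)
  preds <- if (length(te)) {
    stats::setNames(mu_hat + g_hat[te], mk$ids[te])
  } else stats::setNames(numeric(0), character(0))

  structure(list(
    mu_hat = mu_hat, g_hat = stats::setNames(g_hat, mk$ids),
    sigma2_g_hat = s2g_hat, sigma2_e_hat = s2e_hat,
    h2_hat = s2g_hat / (s2g_hat + s2e_hat),
    predictions = preds,
    train_ids = mk$ids[tr], test_ids = mk$ids[te],
    fitted_train = stats::setNames(mu_hat + g_hat[tr], mk$ids[tr]),
    ess = c(mu = ess(mu_keep), sigma2_g = ess(s2g_keep),
            sigma2_e = ess(s2e_keep)),
    settings = settings), class = "gblup_fit")
}

#' Closed-form BLUP with known variance components
#'
#' Deterministic oracle for the Gibbs sampler:
#' \deqn{\hat g = \sigma_g^2 G_{\cdot,train}
#'   (\sigma_g^2 G_{train,train} + \sigma^2 I)^{-1} (y_{train} - \bar y_{train})}
#' and predictions \eqn{\bar y_{train} + \hat g}.
#'
#' @param y Response vector (entries for test lines ignored).
#' @param G Relationship matrix over all lines.
#' @param sigma2_g,sigma2_e Known variance components.
#' @param test Test-line specification as in [fit_gblup()].
#' @return Named list with `g_hat` (all lines) and `predictions`
#'   (test lines; all lines when `test` is NULL).
#' @export
blup_closed_form <- function(y, G, sigma2_g, sigma2_e, test = NULL) {
  mk <- resolve_mask(y, G, test)
  tr <- mk$train
  if (!length(tr)) stop("no unmasked lines")
  y_tr <- y[tr]
  V <- sigma2_g * G[tr, tr, drop = FALSE] + diag(sigma2_e, length(tr))
  rhs <- tryCatch(solve(V, y_tr - mean(y_tr)),
                  error = function(e) stop("singular BLUP system: ",
                                           conditionMessage(e)))
  g_hat <- drop(sigma2_g * G[, tr, drop = FALSE] %*% rhs)
  names(g_hat) <- mk$ids
  idx <- if (length(mk$test)) mk$test else seq_along(y)
  list(g_hat = g_hat,
       predictions = stats::setNames(mean(y_tr) + g_hat[idx], mk$ids[idx]))
}

#' Fit the probit threshold GBLUP by Gibbs sampling
#'
#' Binary-response threshold model
#' \eqn{P(Y_{bi} = 1 \mid g_i) = \Phi(\beta_0 + g_i)} with latent
#' liabilities \eqn{l_i = \beta_0 + g_i + \epsilon_i},
#' \eqn{\epsilon_i \sim N(0, 1)} (residual liability variance fixed at 1),
#' flat prior on \eqn{\beta_0}, and \eqn{g \sim N(0, \sigma_g^2 G)}.
#' Liabilities are sampled from truncated normals (positive iff the label
#' is 1).  Masked-line class probabilities are posterior means of
#' \eqn{\Phi(\beta_0 + g_i)}, integrating the conditional prediction
#' variance of \eqn{g_i} given the training effects analytically via
#' \eqn{\Phi((\beta_0 + m_i)/\sqrt{1 + v_i})}.
#'
#' @param yb 0/1 labels, one per row of `G` (masked entries may be NA).
#' @param G Relationship matrix covering all lines.
#' @param test Masked lines, as in [fit_gblup()].
#' @param settings An [mcmc_settings()] object.
#' @param min_train Minimum number of unmasked lines (default 20).
#' @return An object of class `probit_fit` with `beta0_hat`, `g_hat`,
#'   `sigma2_g_hat`, masked-line `probabilities`, in-sample
#'   `fitted_train` probabilities and the settings used.
#' @export
fit_probit <- function(yb, G, test = NULL, settings, min_train = 20) {
  stopifnot(inherits(settings, "mcmc_settings"))
  mk <- resolve_mask(yb, G, test)
  tr <- mk$train; te <- mk$test
  if (length(tr) < min_train)
    stop("too few unmasked lines (", length(tr), ") to fit the probit model")
  yb_tr <- yb[tr]
  if (anyNA(yb_tr) || !all(yb_tr %in% c(0, 1)))
    stop("training labels must be 0/1 without missing values")
  if (length(unique(yb_tr)) < 2)
    stop("training labels contain a single class; liability truncation is degenerate")
  ev <- prepare_eigen(G, tr, te)
  U <- ev$U; d <- ev$d; k <- ev$k
  n_tr <- length(tr)

  df0 <- 5
  S_g <- 0.5 * (df0 + 2) / mean(diag(G)[tr])   # liability variance is 1

  set.seed(settings$seed)
  s2g <- 0.5 / mean(diag(G)[tr])
  beta0 <- stats::qnorm(pmin(pmax(mean(yb_tr), 0.05), 0.95))
  a <- rep(0, k)
  g_tr <- rep(0, n_tr)
  pos <- yb_tr == 1

  keep_it <- seq(settings$burn_in + 1, settings$n_iter, by = settings$thin)
  n_keep <- length(keep_it)
  slot <- 0L
  beta0_keep <- s2g_keep <- numeric(n_keep)
  g_tr_sum <- rep(0, n_tr)
  a_sum <- rep(0, k)
  p_te_sum <- if (length(te)) rep(0, length(te)) else NULL
  p_tr_sum <- rep(0, n_tr)
  ones_star <- drop(crossprod(U, rep(1, n_tr)))

  for (it in seq_len(settings$n_iter)) {
    # latent liabilities: truncated normal at 0, unit residual variance
    eta <- beta0 + g_tr
    plo <- stats::pnorm(-eta)                  # P(l < 0 | eta)
    u <- stats::runif(n_tr)
    uu <- ifelse(pos, plo + u * (1 - plo), u * plo)
    uu <- pmin(pmax(uu, 1e-12), 1 - 1e-12)
    l <- eta + stats::qnorm(uu)
    # rotated genetic effects (residual variance 1)
    lstar <- drop(crossprod(U, l))
    v <- 1 / (1 + 1 / (s2g * d))
    m <- v * (lstar - beta0 * ones_star)
    a <- m + sqrt(v) * stats::rnorm(k)
    g_tr <- drop(U %*% a)
    # intercept, flat prior
    beta0 <- stats::rnorm(1, mean(l - g_tr), sqrt(1 / n_tr))
    # genetic variance
    s2g <- (S_g + sum(a^2 / d)) / stats::rchisq(1, df0 + k)
    if (it > settings$burn_in &&
        (it - settings$burn_in - 1L) %% settings$thin == 0L) {
      slot <- slot + 1L
      beta0_keep[slot] <- beta0; s2g_keep[slot] <- s2g
      g_tr_sum <- g_tr_sum + g_tr
      a_sum <- a_sum + a
      p_tr_sum <- p_tr_sum + stats::pnorm(beta0 + g_tr)
      if (length(te)) {
        m_te <- drop(ev$P %*% a)
        p_te_sum <- p_te_sum +
          stats::pnorm((beta0 + m_te) / sqrt(1 + s2g * ev$schur))
      }
    }
  }

  g_hat <- rep(NA_real_, length(yb))
  g_hat[tr] <- g_tr_sum / n_keep
  if (length(te)) g_hat[te] <- drop(ev$P %*% (a_sum / n_keep))
  probs <- if (length(te)) {
    stats::setNames(pmin(pmax(p_te_sum / n_keep, 1e-12), 1 - 1e-12),
                    mk$ids[te])
  } else stats::setNames(numeric(0), character(0))

  structure(list(
    beta0_hat = mean(beta0_keep),
    g_hat = stats::setNames(g_hat, mk$ids),
    sigma2_g_hat = mean(s2g_keep),
    probabilities = probs,
    train_ids = mk$ids[tr], test_ids = mk$ids[te],
    fitted_train = stats::setNames(
      pmin(pmax(p_tr_sum / n_keep, 1e-12), 1 - 1e-12), mk$ids[tr]),
    ess = c(beta0 = ess(beta0_keep), sigma2_g = ess(s2g_keep)),
    settings = settings), class = "probit_fit")
}

#' Out-of-sample scores for masked lines
#'
#' Returns the fit's stored posterior-mean scores for the requested masked
#' lines: continuous predictions for a `gblup_fit`, class probabilities
#' for a `probit_fit`.  Requesting a line that trained the model is an
#' error -- in-sample scores are available only through the explicitly
#' labeled [fitted_values()] (used by the Simple tuning variants).
#'
#' @param object A `gblup_fit` or `probit_fit`.
#' @param line_ids Character ids of masked lines; default all masked lines.
#' @param ... Unused.
#' @return Named numeric vector of scores in the requested order.
#' @export
predict.gblup_fit <- function(object, line_ids = NULL, ...) {
  extract_scores(object$predictions, object$train_ids, line_ids)
}

#' @rdname predict.gblup_fit
#' @export
predict.probit_fit <- function(object, line_ids = NULL, ...) {
  extract_scores(object$probabilities, object$train_ids, line_ids)
}

extract_scores <- function(stored, train_ids, line_ids) {
  if (is.null(line_ids)) return(stored)
  leak <- intersect(line_ids, train_ids)
  if (length(leak))
    stop("line(s) were unmasked at fit time (in-sample leakage): ",
         paste(utils::head(leak, 5), collapse = ", "))
  unknown <- setdiff(line_ids, names(stored))
  if (length(unknown))
    stop("unknown line id(s): ", paste(utils::head(unknown, 5), collapse = ", "))
  stored[line_ids]
}

#' In-sample scores for the training lines
#'
#' Explicitly labeled in-sample: posterior means of \eqn{\mu + g_i} for
#' the linear model, \eqn{\Phi(\beta_0 + g_i)} for the probit model.
#' These feed the Simple threshold-tuning variants, which tune on the
#' single training fit instead of refitting per inner fold.
#'
#' @param fit A `gblup_fit` or `probit_fit`.
#' @return Named numeric vector over the training lines.
#' @export
fitted_values <- function(fit) {
  stopifnot(inherits(fit, c("gblup_fit", "probit_fit")))
  fit$fitted_train
}

# Effective sample size via the initial-positive-sequence autocorrelation
# sum; cheap and adequate for reporting mixing.
ess <- function(x) {
  n <- length(x)
  v <- stats::var(x)
  if (n < 10 || !is.finite(v) || v == 0) return(as.numeric(n))
  ac <- stats::acf(x, lag.max = min(n - 1, 100), plot = FALSE)$acf[-1]
  neg <- which(ac < 0)
  if (length(neg)) ac <- ac[seq_len(neg[1] - 1)]
  max(1, n / (1 + 2 * sum(ac)))
}
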