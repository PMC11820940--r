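# Shared fixtures: everything is generated in code, seeded.

# Simulated dataset with its relationship matrix, single env/trait slice.
make_sim_data <- function(n = 100, p = 300, h2 = 0.5, n_qtl = 50, seed = 1) {
  m <- simulate_markers(n, p, seed = seed)
  sim <- simulate_phenotypes(m, h2 = h2, n_qtl = n_qtl, seed = seed + 1L)
  y <- stats::setNames(sim$phenotypes$value, sim$phenotypes$line_id)
  G <- stabilize_grm(compute_grm(impute_markers(m)))
  list(y = y, G = G, markers = m, truth = sim$truth[[1]])
}

# Short chains for tests that only need a working sampler, not tight
# posterior summaries.
tiny_mcmc <- function(seed = 99) mcmc_settings(600, 200, 2, seed = seed)

# A block-structured PSD relationship matrix: two clusters plus test
# lines whose loading interpolates between them.
cluster_grm <- function(n_pos = 10, n_neg = 12, alphas = c(0.1, 0.5, 0.9)) {
  Z <- rbind(matrix(rep(c(1, 0), each = n_pos), ncol = 2),
             matrix(rep(c(0, 1), each = n_neg), ncol = 2),
             cbind(alphas, 1 - alphas))
  G <- tcrossprod(Z) + diag(0.05, nrow(Z))
  ids <- c(sprintf("P%02d", seq_len(n_pos)), sprintf("N%02d", seq_len(n_neg)),
           sprintf("A%02d", seq_along(alphas)))
  dimnames(G) <- list(ids, ids)
  list(G = G, labels = c(rep(1L, n_pos), rep(0L, n_neg),
                         rep(NA_integer_, length(alphas))),
       test_ids = ids[seq(n_pos + n_neg + 1, nrow(Z))])
}

# One draw from N(0, s2 * G) via Cholesky (G must be positive definite).
chol_sim <- function(G, s2, seed) {
  set.seed(seed)
  drop(crossprod(chol(s2 * G), stats::rnorm(nrow(G))))
}

write_temp_csv <- function(df, ...) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE, ...)
  path
}
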