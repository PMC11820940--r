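#' Simulate a biallelic marker panel
#'
#' Per marker, an allele frequency is drawn uniformly from `maf_range`
#' and line dosages are drawn as Binomial(2, p) — Hardy-Weinberg
#' proportions, no linkage disequilibrium.  Linkage is deliberately not
#' simulated: the relationship matrix captures realized genomic
#' relationships regardless, which is what the selection methods consume.
#'
#' @param n_lines,n_markers Panel dimensions.
#' @param maf_range Allele-frequency interval, a subset of (0, 0.5].
#' @param seed Integer RNG seed (required).
#' @return Integer dosage matrix (lines x markers) with ids
#'   `L0001...`/`M0001...`.
#' @export
simulate_markers <- function(n_lines, n_markers, maf_range = c(0.05, 0.5),
                             seed) {
  if (missing(seed)) stop("an explicit seed is required")
  stopifnot(n_lines >= 2, n_markers >= 1,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2])
  set.seed(seed)
  p <- stats::runif(n_markers, maf_range[1], maf_range[2])
  m <- matrix(stats::rbinom(n_lines * n_markers, 2, rep(p, each = n_lines)),
              nrow = n_lines)
  dimnames(m) <- list(sprintf("L%04d", seq_len(n_lines)),
                      sprintf("M%04d", seq_len(n_markers)))
  m
}

#' Simulate additive polygenic phenotypes with exact in-sample heritability
#'
#' For each environment x trait combination, `n_qtl` markers are chosen
#' at random, standard-normal additive effects are drawn, and the genetic
#' value is the centered dosage score \eqn{W\beta}.  Gaussian noise is
#' rescaled so the realized in-sample variance ratio
#' \eqn{var(W\beta) / (var(W\beta) + var(e))} equals `h2` exactly — not
#' just in expectation — so heritability-recovery tests have a sharp
#' truth value.  Effect draws are independent across environments and
#' traits (no genotype x environment correlation).
#'
#' @param m Marker matrix from [simulate_markers()] (or real dosages).
#' @param h2 Target narrow-sense heritability in (0, 1).
#' @param n_qtl Number of causal markers (> 0 when `h2 > 0`).
#' @param mu Trait mean.
#' @param n_traits,n_environments Number of traits / environments.
#' @param seed Integer RNG seed (required).
#' @return List with `phenotypes` (a `phenotype_table`) and `truth`
#'   (per-slice QTL indices, effects, true genetic values, realized h2).
#' @export
simulate_phenotypes <- function(m, h2 = 0.5, n_qtl = 100, mu = 10,
                                n_traits = 1, n_environments = 1, seed) {
  if (missing(seed)) stop("an explicit seed is required")
  stopifnot(h2 > 0, h2 < 1, n_traits >= 1, n_environments >= 1)
  if (n_qtl < 1) stop("n_qtl must be positive when h2 > 0")
  n_qtl <- min(n_qtl, ncol(m))
  set.seed(seed)
  W <- scale(m, center = TRUE, scale = FALSE)
  n <- nrow(m)
  records <- list()
  truth <- list()
  for (env in seq_len(n_environments)) {
    for (trt in seq_len(n_traits)) {
      qtl <- sort(sample(ncol(m), n_qtl))
      beta <- stats::rnorm(n_qtl)
      g <- drop(W[, qtl, drop = FALSE] %*% beta)
      e <- stats::rnorm(n)
      e <- e - mean(e)
      vg <- stats::var(g)
      if (vg == 0) stop("genetic variance is zero; panel too monomorphic")
      e <- e * sqrt(vg * (1 - h2) / (h2 * stats::var(e)))
      y <- mu + g + e
      env_id <- sprintf("E%02d", env)
      trt_id <- sprintf("T%02d", trt)
      records[[length(records) + 1L]] <- data.frame(
        line_id = rownames(m), environment = env_id, trait = trt_id,
        value = y, stringsAsFactors = FALSE)
      truth[[paste(env_id, trt_id, sep = ".")]] <- list(
        qtl = qtl, effects = beta,
        genetic_values = stats::setNames(g, rownames(m)),
        realized_h2 = vg / (vg + stats::var(e)))
    }
  }
  list(phenotypes = as_phenotype_table(do.call(rbind, records)),
       truth = truth)
}

#' Write a ready-made synthetic dataset bundle to disk
#'
#' Presets: `"tiny"` is 60 lines x 200 markers x 1 environment x 1 trait
#' (an end-to-end pipeline runs in seconds); `"paper_shape"` is
#' 1000 lines x 4085 markers x 11 environments x 4 traits, mirroring the
#' shape of a typical maize genomic-selection dataset.  Files are a
#' marker CSV and phenotype CSV in the dialects the readers expect, plus
#' a truth JSON recording seed, QTL indices and effects.
#'
#' @param preset `"tiny"` or `"paper_shape"`.
#' @param seed Integer RNG seed (required).
#' @param dir Output directory (created if needed).
#' @param h2 Heritability passed to the phenotype simulator.
#' @return Named character vector of the three file paths.
#' @export
make_fixture_bundle <- function(preset = c("tiny", "paper_shape"), seed,
                                dir = tempfile("fixture_"), h2 = 0.5) {
  preset <- match.arg(preset)
  if (missing(seed)) stop("an explicit seed is required")
  cfg <- switch(preset,
    tiny = list(n = 60, p = 200, n_env = 1, n_trait = 1, n_qtl = 40),
    paper_shape = list(n = 1000, p = 4085, n_env = 11, n_trait = 4,
                       n_qtl = 300))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- simulate_markers(cfg$n, cfg$p, seed = seed)
  sim <- simulate_phenotypes(m, h2 = h2, n_qtl = cfg$n_qtl,
                             n_traits = cfg$n_trait,
                             n_environments = cfg$n_env, seed = seed + 1L)
  marker_path <- file.path(dir, "markers.csv")
  pheno_path <- file.path(dir, "phenotypes.csv")
  truth_path <- file.path(dir, "truth.json")
  utils::write.csv(data.frame(line_id = rownames(m),
                              as.data.frame(m, check.names = FALSE),
                              check.names = FALSE),
                   marker_path, row.names = FALSE, quote = TRUE)
  ph <- sim$phenotypes
  ph$value <- vapply(ph$value, function(v) format(v, digits = 17),
                     character(1))
  utils::write.csv(ph[, c("line_id", "environment", "trait", "value")],
                   pheno_path, row.names = FALSE, quote = TRUE)
  truth <- list(preset = preset, seed = seed, h2 = h2,
                slices = lapply(sim$truth, function(s)
                  list(qtl = s$qtl, effects = s$effects,
                       realized_h2 = s$realized_h2)))
  writeLines(jsonlite::toJSON(truth, auto_unbox = TRUE, digits = NA),
             truth_path)
  c(markers = marker_path, phenotypes = pheno_path, truth = truth_path)
}
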