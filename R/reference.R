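#' Published benchmark metric means bundled for worked examples
#'
#' Mean classification metrics (over traits, environments and outer
#' folds) reported for the five selection methods on a published
#' multi-environment maize/soybean genomic-selection benchmark, for the
#' per-dataset and across-dataset summaries.  These are reference inputs
#' for relative-efficiency worked examples — reproducing the underlying
#' benchmark itself requires the external genotype/phenotype data and is
#' out of scope here.
#'
#' @return Data.frame with columns dataset, model (B, BO, R, RC, RO),
#'   method (O = original tuning, S = simple tuning), metric
#'   (f1, kappa, sensitivity, specificity) and value.
#' @export
reported_benchmark_means <- function() {
  path <- system.file("extdata", "reported_metric_means.csv",
                      package = "topsel", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Look up one bundled reference mean
#'
#' @param dataset,model,method,metric Keys into
#'   [reported_benchmark_means()].
#' @return A single numeric value.
#' @export
reported_mean <- function(dataset, model, method, metric) {
  tab <- reported_benchmark_means()
  hit <- tab[tab$dataset == dataset & tab$model == model &
               tab$method == method & tab$metric == metric, "value"]
  if (length(hit) != 1)
    stop("no unique reference mean for ", dataset, "/", model, "/",
         method, "/", metric)
  hit
}
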