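#' Mean-impute missing marker dosages
#'
#' Each missing entry is replaced by the mean dosage of its marker over
#' the non-missing lines.  Markers with no observed genotype at all are an
#' error: there is no information to impute from.
#'
#' @param m Marker matrix (lines x markers) possibly containing `NA`.
#' @return The matrix with no missing entries.
#' @export
impute_markers <- function(m) {
  stopifnot(is.matrix(m))
  if (!anyNA(m)) return(m)
  all_missing <- colSums(!is.na(m)) == 0
  if (any(all_missing))
    stop("marker(s) entirely missing: ",
         paste(colnames(m)[all_missing], collapse = ", "))
  mu <- colMeans(m, na.rm = TRUE)
  idx <- which(is.na(m), arr.ind = TRUE)
  m[idx] <- mu[idx[, 2]]
  m
}

#' VanRaden genomic relationship matrix
#'
#' Builds the additive relationship kernel
#' \deqn{G = \frac{W W^\top}{2 \sum_j p_j (1 - p_j)}}
#' where \eqn{p_j} is the observed allele frequency of marker \eqn{j}
#' (mean dosage divided by 2) and \eqn{W = M - 2P} centers each marker
#' column at \eqn{2 p_j} (VanRaden's first method, observed-frequency
#' centering and scaling).  Monomorphic markers carry no information:
#' their centered column is zero and they are excluded from the
#' denominator sum.
#'
#' Allele frequencies are taken from the full matrix supplied here, train
#' and test lines together, so a single G serves a whole cross-validation.
#'
#' @param m Imputed marker matrix (no missing entries), >= 2 lines.
#' @return Symmetric n x n relationship matrix with line ids as dimnames.
#' @export
compute_grm <- function(m) {
  stopifnot(is.matrix(m), nrow(m) >= 2)
  if (anyNA(m)) stop("marker matrix contains missing values; impute first")
  p <- colMeans(m) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("all markers are monomorphic; G denominator is zero")
  W <- sweep(m, 2, 2 * p, "-")
  denom <- 2 * sum(p[poly] * (1 - p[poly]))
  G <- tcrossprod(W) / denom
  G <- (G + t(G)) / 2
  dimnames(G) <- list(rownames(m), rownames(m))
  G
}

#' Ridge-stabilize a relationship matrix
#'
#' Adds `ridge` to the diagonal.  G built from finite marker panels is
#' frequently numerically singular (duplicate lines, p < n); a tiny ridge
#' makes eigenvalues strictly non-negative so downstream factorizations
#' are safe.
#'
#' @param G Symmetric relationship matrix.
#' @param ridge Non-negative scalar added to the diagonal (default 1e-6).
#' @return The stabilized matrix.
#' @export
stabilize_grm <- function(G, ridge = 1e-6) {
  stopifnot(is.matrix(G), nrow(G) == ncol(G), ridge >= 0)
  if (max(abs(G - t(G))) > 1e-8) stop("G must be symmetric")
  G + diag(ridge, nrow(G))
}
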