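#' Read a long-format phenotype table
#'
#' Reads adjusted line means (BLUEs) stored one record per
#' (line, environment, trait) combination.  The value column holds the
#' response on the trait scale; `NA` and empty cells are accepted as
#' missing and flagged rather than dropped, so the table round-trips.
#'
#' @param path Path to a CSV file with a header row.
#' @param schema Named character vector mapping the canonical column names
#'   `line_id`, `environment`, `trait`, `value` to the columns actually
#'   present in the file.
#' @return A `data.frame` of class `phenotype_table` with columns
#'   `line_id`, `environment`, `trait`, `value` and a logical `missing`
#'   column flagging records without a finite value.
#' @export
read_phenotypes <- function(path,
                            schema = c(line_id = "line_id",
                                       environment = "environment",
                                       trait = "trait",
                                       value = "value")) {
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  needed <- c("line_id", "environment", "trait", "value")
  if (!all(needed %in% names(schema)))
    stop("schema must map all of: ", paste(needed, collapse = ", "))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         check.names = FALSE, na.strings = c("NA", ""))
  absent <- setdiff(unname(schema[needed]), names(raw))
  if (length(absent))
    stop("phenotype file lacks declared column(s): ",
         paste(absent, collapse = ", "))
  tab <- data.frame(line_id     = as.character(raw[[schema[["line_id"]]]]),
                    environment = as.character(raw[[schema[["environment"]]]]),
                    trait       = as.character(raw[[schema[["trait"]]]]),
                    value       = as.numeric(raw[[schema[["value"]]]]),
                    stringsAsFactors = FALSE)
  as_phenotype_table(tab)
}

#' Construct and validate a phenotype table
#'
#' @param tab A data.frame with columns `line_id`, `environment`, `trait`,
#'   `value`.
#' @return The validated table with class `phenotype_table` and a
#'   `missing` flag column.
#' @export
as_phenotype_table <- function(tab) {
  stopifnot(is.data.frame(tab),
            all(c("line_id", "environment", "trait", "value") %in% names(tab)))
  key <- paste(tab$line_id, tab$environment, tab$trait, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    bad <- unique(paste0("(", tab$line_id[dup], ", ", tab$environment[dup],
                         ", ", tab$trait[dup], ")"))
    stop("duplicate (line, environment, trait) records: ",
         paste(utils::head(bad, 5), collapse = "; "))
  }
  if (any(is.infinite(tab$value)))
    stop("phenotype values must be finite or missing")
  tab$missing <- !is.finite(tab$value)
  class(tab) <- c("phenotype_table", "data.frame")
  tab
}

#' Read a marker dosage matrix
#'
#' The expected layout is one line per row: first column the line
#' identifier, remaining columns one SNP each with additive dosage codes
#' 0/1/2.  Missing genotypes (`NA` or empty cells) are kept as `NA`;
#' imputation is a separate, explicit step (see [impute_markers()]) so
#' raw files round-trip unchanged.
#'
#' @param path Path to the CSV file.
#' @return A numeric matrix (lines x markers) with line ids as rownames
#'   and marker ids as colnames, possibly containing `NA`.
#' @export
read_markers <- function(path) {
  if (!file.exists(path)) stop("marker file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         check.names = FALSE, na.strings = c("NA", ""))
  if (ncol(raw) < 2) stop("marker file needs a line_id column plus markers")
  ids <- as.character(raw[[1]])
  if (anyDuplicated(ids))
    stop("duplicated line ids in marker file: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  body <- raw[, -1, drop = FALSE]
  for (j in seq_along(body)) {
    col <- body[[j]]
    if (!is.numeric(col)) {
      conv <- suppressWarnings(as.numeric(col))
      bad <- which(!is.na(col) & is.na(conv))
      if (length(bad))
        stop(sprintf("non-numeric genotype code at row %d, marker '%s'",
                     bad[1], names(body)[j]))
      body[[j]] <- conv
    }
  }
  m <- as.matrix(body)
  rownames(m) <- ids
  out <- which(!is.na(m) & (m < 0 | m > 2), arr.ind = TRUE)
  if (nrow(out))
    stop(sprintf("genotype code outside [0, 2] at line '%s', marker '%s'",
                 ids[out[1, 1]], colnames(m)[out[1, 2]]))
  if (anyDuplicated(colnames(m)))
    stop("duplicated marker ids in marker file")
  m
}

#' Check that phenotype lines are covered by the marker matrix
#'
#' Reports every mismatch; nothing is silently dropped.
#'
#' @param phenotypes A `phenotype_table`.
#' @param markers A marker matrix with line ids as rownames.
#' @return Invisibly `TRUE`; errors listing all unmatched line ids otherwise.
#' @export
check_line_consistency <- function(phenotypes, markers) {
  miss <- setdiff(unique(phenotypes$line_id), rownames(markers))
  if (length(miss))
    stop("phenotype lines absent from marker matrix: ",
         paste(miss, collapse = ", "))
  invisible(TRUE)
}

#' Write / read a benchmark metric table
#'
#' Long-format CSV with fixed column order
#' (dataset, environment, trait, model, method, fold, metric, value) so
#' diffs between runs are stable.  Values are written with full double
#' precision and round-trip bit-identically through [read_metrics()].
#'
#' @param results A data.frame of benchmark rows (see [run_nested_cv()]).
#' @param path Output CSV path.
#' @return Invisibly, the path written.
#' @export
write_metrics <- function(results, path) {
  stopifnot(is.data.frame(results), nrow(results) >= 1)
  cols <- c("dataset", "environment", "trait", "model", "method",
            "fold", "metric", "value")
  stopifnot(all(cols %in% names(results)))
  out <- results[, cols]
  out$value <- vapply(out$value, function(v)
    if (is.na(v)) NA_character_ else format(v, digits = 17), character(1))
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "NA")
  invisible(path)
}

#' @rdname write_metrics
#' @export
read_metrics <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  raw$value <- as.numeric(raw$value)
  raw
}

#' Write / read a genomic relationship matrix as CSV
#'
#' Symmetric matrix with a line_id header row and first column.
#'
#' @param G Symmetric relationship matrix with line ids as dimnames.
#' @param path CSV path.
#' @return `write_grm` invisibly returns the path; `read_grm` returns the
#'   matrix.
#' @export
write_grm <- function(G, path) {
  stopifnot(is.matrix(G), nrow(G) == ncol(G), !is.null(rownames(G)))
  df <- data.frame(line_id = rownames(G),
                   as.data.frame(G, check.names = FALSE),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_grm
#' @export
read_grm <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  ids <- as.character(raw[[1]])
  G <- as.matrix(raw[, -1, drop = FALSE])
  rownames(G) <- ids
  if (!identical(colnames(G), ids))
    stop("relationship matrix header does not match line_id column")
  if (max(abs(G - t(G))) > 1e-8) stop("relationship matrix is not symmetric")
  G
}

#' Write / read outer-fold assignments
#'
#' @param plan A `cv_plan` (see [cv_plan()]).
#' @param path CSV path (columns line_id, outer_fold).
#' @return `write_folds` invisibly returns the path; `read_folds` returns
#'   a data.frame (line_id, outer_fold).
#' @export
write_folds <- function(plan, path) {
  stopifnot(inherits(plan, "cv_plan"))
  rows <- do.call(rbind, lapply(seq_along(plan$outer), function(f)
    data.frame(line_id = plan$outer[[f]], outer_fold = f,
               stringsAsFactors = FALSE)))
  utils::write.csv(rows, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_folds
#' @export
read_folds <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("line_id", "outer_fold") %in% names(raw)))
  raw
}
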