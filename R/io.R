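#' @useDynLib chemomics, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Tabular interchange is TSV: tab separated, UTF-8, "." decimal point.
# Numbers are written with 15 significant digits, which round-trips through
# read_tsv/write_tsv to identical bytes.

format_num <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.15g", x))
}

#' Write a data frame as canonical TSV
#'
#' @param df Data frame.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_tsv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- format_num(out[[j]])
  }
  utils::write.table(out, path,
    sep = "\t", quote = FALSE, row.names = FALSE,
    fileEncoding = "UTF-8"
  )
  invisible(path)
}

#' Read a TSV file
#'
#' @param path Input file.
#' @return Data frame with columns as in the file (no name mangling).
#' @export
read_tsv <- function(path) {
  utils::read.delim(path,
    sep = "\t", header = TRUE, check.names = FALSE,
    stringsAsFactors = FALSE, comment.char = ""
  )
}

validate_sample_sheet <- function(samples) {
  need <- c("sample_id", "strain", "growth", "replicate")
  miss <- setdiff(need, names(samples))
  if (length(miss) > 0) {
    fail_input("sample sheet is missing column(s): %s", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(samples$sample_id)) {
    fail_input("duplicated sample_id in sample sheet")
  }
  if (!all(samples$growth %in% c("high", "low"))) {
    fail_input("growth must be 'high' or 'low'")
  }
  if (anyDuplicated(samples[, c("strain", "growth", "replicate")])) {
    fail_input("duplicated (strain, growth, replicate) triple in sample sheet")
  }
  samples$sample_id <- as.character(samples$sample_id)
  samples$strain <- as.character(samples$strain)
  samples$replicate <- as.integer(samples$replicate)
  samples
}

#' Read a sample sheet
#'
#' Expected columns: `sample_id`, `strain`, `growth` (high/low), `replicate`.
#'
#' @param path TSV file.
#' @return Validated data frame.
#' @export
read_sample_sheet <- function(path) {
  validate_sample_sheet(read_tsv(path))
}

#' Construct an expression matrix
#'
#' Container for a features x samples matrix of (typically log2) values with
#' aligned sample metadata and optional per-feature annotation.
#'
#' @param values Numeric matrix, features in rows (rownames = feature ids),
#'   samples in columns (colnames = sample ids).
#' @param samples Sample sheet data frame (`sample_id`, `strain`, `growth`,
#'   `replicate`); rows are reordered to the column order of `values`.
#' @param features Optional per-feature annotation data frame with a
#'   `feature_id` column (e.g. `length_bp`, `is_rRNA`, `product`).
#' @return Object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, samples, features = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    fail_input("values must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    fail_input("values must have feature ids as rownames and sample ids as colnames")
  }
  if (anyDuplicated(rownames(values))) fail_input("duplicated feature id")
  samples <- validate_sample_sheet(samples)
  if (!setequal(colnames(values), samples$sample_id) ||
    ncol(values) != nrow(samples)) {
    fail_input("matrix columns and sample sheet ids do not match")
  }
  samples <- samples[match(colnames(values), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  if (!is.null(features)) {
    if (!"feature_id" %in% names(features)) {
      fail_input("feature annotation needs a feature_id column")
    }
    idx <- match(rownames(values), features$feature_id)
    if (anyNA(idx)) fail_input("feature annotation does not cover all features")
    features <- features[idx, , drop = FALSE]
    rownames(features) <- NULL
  }
  structure(
    list(values = values, samples = samples, features = features),
    class = "expression_matrix"
  )
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf(
    "expression_matrix: %d features x %d samples (%d strain(s), growth: %s)\n",
    nrow(x$values), ncol(x$values),
    length(unique(x$samples$strain)),
    paste(sort(unique(x$samples$growth)), collapse = "/")
  ))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Read a features x samples matrix with aligned metadata
#'
#' The first column of the TSV holds feature ids; remaining column names must
#' exactly match the sample sheet ids. Columns are reordered to the sample
#' sheet order.
#'
#' @param path Matrix TSV.
#' @param sample_sheet Sample sheet data frame or path to one.
#' @param features Optional feature annotation data frame.
#' @return An [expression_matrix()].
#' @export
read_matrix <- function(path, sample_sheet, features = NULL) {
  if (is.character(sample_sheet)) sample_sheet <- read_sample_sheet(sample_sheet)
  sample_sheet <- validate_sample_sheet(sample_sheet)
  tab <- read_tsv(path)
  ids <- as.character(tab[[1L]])
  if (anyDuplicated(ids)) {
    fail_input(
      "duplicate feature id in %s: %s", path,
      paste(unique(ids[duplicated(ids)]), collapse = ", ")
    )
  }
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- ids
  unknown <- setdiff(colnames(vals), sample_sheet$sample_id)
  if (length(unknown) > 0) {
    fail_input(
      "column(s) not in sample sheet: %s",
      paste(unknown, collapse = ", ")
    )
  }
  missing <- setdiff(sample_sheet$sample_id, colnames(vals))
  if (length(missing) > 0) {
    fail_input(
      "sample(s) missing from matrix: %s",
      paste(missing, collapse = ", ")
    )
  }
  vals <- vals[, sample_sheet$sample_id, drop = FALSE]
  expression_matrix(vals, sample_sheet, features)
}

#' Write an expression matrix (or plain matrix) as canonical TSV
#'
#' @param x An `expression_matrix` or a numeric matrix with dimnames.
#' @param path Output file.
#' @param id_col Name for the feature id column.
#' @return Invisibly, `path`.
#' @export
write_matrix <- function(x, path, id_col = "feature_id") {
  m <- if (inherits(x, "expression_matrix")) x$values else x
  df <- data.frame(id = rownames(m), stringsAsFactors = FALSE)
  names(df) <- id_col
  df <- cbind(df, as.data.frame(m, check.names = FALSE))
  write_tsv(df, path)
}

#' Read a chemostat metabolite table
#'
#' Expected columns: `sample_id`, `strain`, `dilution_rate`, `dry_weight`,
#' `glucose_feed`, `residual_glucose` (optional, defaults to 0: glucose is
#' completely consumed in glucose-limited steady state), and mM
#' concentrations `lactate`, `formate`, `acetate`, `ethanol`.
#'
#' @param path TSV file.
#' @return Validated data frame (one row per steady-state observation).
#' @export
read_metabolite_table <- function(path) {
  tab <- read_tsv(path)
  need <- c(
    "sample_id", "strain", "dilution_rate", "dry_weight", "glucose_feed",
    "lactate", "formate", "acetate", "ethanol"
  )
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0) {
    fail_input("metabolite table is missing column(s): %s", paste(miss, collapse = ", "))
  }
  if (!"residual_glucose" %in% names(tab)) tab$residual_glucose <- 0
  num <- c(
    "dilution_rate", "dry_weight", "glucose_feed", "residual_glucose",
    "lactate", "formate", "acetate", "ethanol"
  )
  for (v in num) tab[[v]] <- as.numeric(tab[[v]])
  if (any(tab$dilution_rate <= 0)) fail_input("dilution_rate must be > 0")
  if (any(tab$dry_weight <= 0)) fail_input("dry_weight must be > 0")
  if (any(tab[unlist(c("lactate", "formate", "acetate", "ethanol", "residual_glucose"))] < 0)) {
    fail_input("concentrations must be >= 0")
  }
  if (any(tab$residual_glucose > tab$glucose_feed)) {
    fail_input("residual_glucose exceeds glucose_feed")
  }
  tab
}

#' Read a gene annotation table
#'
#' Expected columns: `feature_id`, `length_bp`, `is_rRNA` (0/1), `product`.
#'
#' @param path TSV file.
#' @return Data frame.
#' @export
read_annotation <- function(path) {
  tab <- read_tsv(path)
  need <- c("feature_id", "length_bp", "is_rRNA")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0) {
    fail_input("annotation is missing column(s): %s", paste(miss, collapse = ", "))
  }
  tab$length_bp <- as.numeric(tab$length_bp)
  if (any(tab$length_bp <= 0)) fail_input("gene length must be > 0")
  tab$is_rRNA <- as.integer(tab$is_rRNA) != 0L
  tab
}

#' Read a YAML run configuration
#'
#' Configuration files mirror the function arguments of the pipeline steps
#' (e.g. `alpha`, `n_repeats`, `cv_folds`, `selection_threshold`, `seed`).
#'
#' @param path YAML file.
#' @return Named list.
#' @export
read_config <- function(path) {
  yaml::read_yaml(path)
}

#' Reference steady-state chemostat phenotypes of L. sakei 23K and LS25
#'
#' Published replicate means and standard deviations for the two strains
#' grown anaerobically in glucose-limited chemostats (55.5 mM feed glucose)
#' at dilution rates 0.357 and 0.045 h^-1: dry weight, end-product
#' concentrations (lactate, formate, acetate, ethanol; mM), and the printed
#' per-product fluxes, specific productions and carbon balances. These values
#' parameterize the synthetic phenome generator and serve as the comparison
#' standard for the stoichiometry module.
#'
#' @return Data frame with one row per strain x growth condition.
#' @export
reference_phenotypes <- function() {
  path <- system.file("extdata", "chemostat_reference.tsv",
    package = "chemomics", mustWork = TRUE
  )
  read_tsv(path)
}
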