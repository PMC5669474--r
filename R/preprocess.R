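# Transcript counts -> log2 RPKM with rRNA exclusion; protein abundances ->
# log2. rRNA loci dominate microbial RNA-seq library depth even after
# wet-lab depletion, so they are removed BEFORE library sizes are computed
# and normalization follows the reduced library.

#' Drop rRNA features from a count matrix
#'
#' @param counts Features x samples matrix of non-negative integer counts
#'   (rownames = feature ids).
#' @param is_rrna Logical flag per feature (same order as rows).
#' @return Count matrix restricted to non-rRNA features.
#' @export
drop_rrna <- function(counts, is_rrna) {
  if (length(is_rrna) != nrow(counts)) {
    fail_input("is_rrna must have one flag per feature")
  }
  is_rrna <- as.logical(is_rrna)
  if (all(is_rrna)) fail_input("all features are flagged rRNA; nothing left")
  n_drop <- sum(is_rrna)
  if (n_drop > 0) {
    pipeline_log("dropping %d rRNA feature(s) before library-size computation", n_drop)
  }
  counts[!is_rrna, , drop = FALSE]
}

#' RPKM normalization
#'
#' Reads per kilobase of gene per million mapped reads:
#' `count / (length_bp/1000) / (library_size/1e6)` with the library size
#' taken as the per-sample sum of the retained counts. RPKM is invariant to
#' scaling all counts of a sample jointly, and for every sample
#' `sum(rpkm * length_kb) == 1e6` exactly (up to floating point).
#'
#' @param counts Features x samples count matrix (rRNA already removed).
#' @param length_bp Gene length in bp per feature, > 0.
#' @return Matrix of RPKM values, same dimnames as `counts`.
#' @export
rpkm <- function(counts, length_bp) {
  if (length(length_bp) != nrow(counts)) {
    fail_input("length_bp must have one length per feature")
  }
  if (any(length_bp <= 0)) fail_input("gene length must be > 0")
  if (any(counts < 0)) fail_input("counts must be >= 0")
  lib <- colSums(counts)
  if (any(lib <= 0)) {
    fail_input(
      "zero library size in sample(s): %s",
      paste(colnames(counts)[lib <= 0], collapse = ", ")
    )
  }
  sweep(counts / (length_bp / 1000), 2, lib / 1e6, "/")
}

#' Elementwise log2 with offset
#'
#' `log2(x + offset)`. The offset used is recorded as attribute
#' `log2_offset` on the result.
#'
#' @param x Numeric matrix.
#' @param offset Non-negative pseudo-value added before the log; must make
#'   every element strictly positive.
#' @return log2-transformed matrix.
#' @export
log2_with_offset <- function(x, offset = 1) {
  if (any(!is.finite(x))) fail_input("non-finite values in input")
  if (any(x + offset <= 0)) {
    fail_input("log2 undefined: value + offset <= 0 (offset = %g)", offset)
  }
  out <- log2(x + offset)
  attr(out, "log2_offset") <- offset
  out
}

#' Per-strain read coverage summary
#'
#' Mean and median of per-gene total read counts across the samples of each
#' strain.
#'
#' @param counts Features x samples count matrix.
#' @param strain Strain label per sample (column).
#' @return Data frame with columns `strain`, `n_genes`, `mean_reads_per_gene`,
#'   `median_reads_per_gene`.
#' @export
coverage_summary <- function(counts, strain) {
  if (length(strain) != ncol(counts)) {
    fail_input("strain must have one label per sample")
  }
  rows <- lapply(unique(strain), function(s) {
    tot <- rowSums(counts[, strain == s, drop = FALSE])
    data.frame(
      strain = s,
      n_genes = nrow(counts),
      mean_reads_per_gene = mean(tot),
      median_reads_per_gene = stats::median(tot),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Preprocess transcript counts to a log2 RPKM expression matrix
#'
#' Removes rRNA loci, computes RPKM against the reduced library, and applies
#' `log2(RPKM + offset)`. The default offset of 1 RPKM unit handles zero
#' counts; it is recorded on the result.
#'
#' @param counts Features x samples integer count matrix.
#' @param annotation Annotation data frame (`feature_id`, `length_bp`,
#'   `is_rRNA`, optionally `product`) covering all rows of `counts`.
#' @param samples Sample sheet data frame.
#' @param offset Pseudo-RPKM added before the log2 (default 1).
#' @return [expression_matrix()] of log2 RPKM values (non-rRNA features).
#' @export
preprocess_transcripts <- function(counts, annotation, samples, offset = 1) {
  idx <- match(rownames(counts), annotation$feature_id)
  if (anyNA(idx)) fail_input("annotation does not cover all count features")
  ann <- annotation[idx, , drop = FALSE]
  kept <- drop_rrna(counts, ann$is_rRNA)
  ann <- ann[!as.logical(ann$is_rRNA), , drop = FALSE]
  vals <- log2_with_offset(rpkm(kept, ann$length_bp), offset)
  em <- expression_matrix(vals, samples, ann)
  attr(em, "log2_offset") <- offset
  em
}

#' Preprocess protein abundances to a log2 expression matrix
#'
#' Label-free normalized abundances are strictly positive, so the default
#' offset is 0.
#'
#' @param abundance Features x samples matrix of normalized abundances.
#' @param samples Sample sheet data frame.
#' @param offset Pseudo-abundance added before the log2 (default 0).
#' @param features Optional feature annotation.
#' @return [expression_matrix()] of log2 abundances.
#' @export
preprocess_proteins <- function(abundance, samples, offset = 0, features = NULL) {
  vals <- log2_with_offset(abundance, offset)
  em <- expression_matrix(vals, samples, features)
  attr(em, "log2_offset") <- offset
  em
}
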