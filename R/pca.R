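# PCA by singular value decomposition on mean-centered, optionally
# unit-variance-scaled data. Thin deterministic layer over stats::prcomp:
# zero-variance variables are dropped under scaling (unit variance is
# undefined for them), and the sign indeterminacy of each component is
# resolved by making its largest-magnitude loading positive, so repeated
# runs on identical input are bit-identical.

#' Fit a principal component analysis
#'
#' @param x Samples x variables numeric matrix (>= 2 samples).
#' @param scale Standardize variables to unit variance (default TRUE, the
#'   convention used throughout this workflow).
#' @param ncomp Number of components to keep; default `min(n - 1, p)`, the
#'   maximal rank of the centered data.
#' @return Object of class `pca_model` with elements `scores` (samples x
#'   components), `loadings` (variables x components, orthonormal),
#'   `explained_fraction` (per component, fractions of total variance,
#'   non-increasing), `center`, `scale`, `dropped` (zero-variance variables
#'   removed under scaling).
#' @export
fit_pca <- function(x, scale = TRUE, ncomp = NULL) {
  x <- as.matrix(x)
  if (nrow(x) < 2) fail_input("PCA needs at least 2 samples")
  if (any(!is.finite(x))) fail_input("non-finite values in input")
  dropped <- character(0)
  if (scale) {
    v <- apply(x, 2, stats::var)
    zero <- v <= .Machine$double.eps
    if (all(zero)) fail_input("all variables have zero variance")
    if (any(zero)) {
      dropped <- colnames(x)[zero]
      if (is.null(dropped)) dropped <- which(zero)
      warning(sprintf(
        "dropping %d zero-variance variable(s) before unit-variance scaling",
        sum(zero)
      ))
      pipeline_log("PCA dropped %d zero-variance variable(s)", sum(zero))
      x <- x[, !zero, drop = FALSE]
    }
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = scale)
  k_full <- length(pc$sdev)
  k <- min(nrow(x) - 1L, ncol(x))
  if (!is.null(ncomp)) k <- min(k, ncomp)
  total_var <- sum(pc$sdev^2)
  frac <- (pc$sdev^2 / total_var)[seq_len(k)]
  scores <- pc$x[, seq_len(k), drop = FALSE]
  loadings <- pc$rotation[, seq_len(k), drop = FALSE]
  # deterministic sign: largest |loading| per component is positive
  for (j in seq_len(k)) {
    i_max <- which.max(abs(loadings[, j]))
    if (loadings[i_max, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  structure(
    list(
      scores = scores,
      loadings = loadings,
      explained_fraction = frac,
      center = pc$center,
      scale = if (scale) pc$scale else NULL,
      dropped = dropped,
      n_samples = nrow(x)
    ),
    class = "pca_model"
  )
}

#' @export
print.pca_model <- function(x, ...) {
  pct <- round(100 * x$explained_fraction, 1)
  cat(sprintf(
    "pca_model: %d samples, %d variables, %d components (%s%%)\n",
    x$n_samples, nrow(x$loadings), ncol(x$loadings),
    paste(pct[seq_len(min(3, length(pct)))], collapse = "/")
  ))
  invisible(x)
}

#' Explained variance fractions
#'
#' @param model A fitted [fit_pca()] model.
#' @return Numeric vector of per-component fractions of total variance,
#'   sorted non-increasing; sums to 1 over the full rank.
#' @export
explained_variance <- function(model) {
  stopifnot(inherits(model, "pca_model"))
  model$explained_fraction
}

#' Reconstruct the (retained-variable) data from a PCA model
#'
#' With all components kept, reconstruction reproduces the input exactly up
#' to floating point.
#'
#' @param model A fitted [fit_pca()] model.
#' @param ncomp Number of leading components to use (default all kept).
#' @return Samples x variables matrix on the original scale.
#' @export
pca_reconstruct <- function(model, ncomp = ncol(model$scores)) {
  idx <- seq_len(ncomp)
  rec <- model$scores[, idx, drop = FALSE] %*% t(model$loadings[, idx, drop = FALSE])
  if (!is.null(model$scale)) rec <- sweep(rec, 2, model$scale, "*")
  sweep(rec, 2, model$center, "+")
}

#' Flip the sign of one principal component
#'
#' Scores and loadings are negated together, so the model still reproduces
#' the same data. Used to pin component orientation to an external
#' convention (e.g. low-growth samples scoring positive on PC1).
#'
#' @param model A `pca_model`.
#' @param comp Component index.
#' @return The model with component `comp` flipped.
#' @export
flip_component <- function(model, comp) {
  model$scores[, comp] <- -model$scores[, comp]
  model$loadings[, comp] <- -model$loadings[, comp]
  model
}

#' Export PCA scores and loadings as TSV
#'
#' Writes `<prefix>_scores.tsv` and `<prefix>_loadings.tsv` with components
#' labelled PC1..PCk; a comment line records the explained percentages.
#'
#' @param model A `pca_model`.
#' @param prefix Output path prefix.
#' @return Invisibly, the two paths written.
#' @export
write_pca <- function(model, prefix) {
  k <- ncol(model$scores)
  pcs <- paste0("PC", seq_len(k))
  hdr <- sprintf(
    "# explained variance (%%): %s",
    paste(sprintf("%s=%.2f", pcs, 100 * model$explained_fraction), collapse = " ")
  )
  paths <- paste0(prefix, c("_scores.tsv", "_loadings.tsv"))
  for (i in 1:2) {
    m <- if (i == 1) model$scores else model$loadings
    df <- data.frame(id = rownames(m), stringsAsFactors = FALSE)
    names(df) <- if (i == 1) "sample_id" else "variable"
    df <- cbind(df, as.data.frame(m, check.names = FALSE))
    names(df)[-1] <- pcs
    con <- file(paths[i], open = "wt", encoding = "UTF-8")
    writeLines(hdr, con)
    close(con)
    for (j in seq_along(df)) {
      if (is.double(df[[j]])) df[[j]] <- format_num(df[[j]])
    }
    suppressWarnings(utils::write.table(df, paths[i],
      sep = "\t", quote = FALSE,
      row.names = FALSE, append = TRUE, fileEncoding = "UTF-8"
    ))
  }
  invisible(paths)
}
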