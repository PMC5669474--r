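# Fold-change confidence-interval validation of selected features within
# each strain, phenome correlations, and assignment of validated features
# to four principal-component pattern groups. This is the step that removes
# features whose apparent relevance only reflects variation among the
# biological replicates.

#' Log2 fold change with pooled-t confidence interval
#'
#' Fold change from high to low growth rate on the log2 scale:
#' `mean(low) - mean(high)`, with a two-sample pooled-variance t interval
#' (df = n_low + n_high - 2). A zero pooled variance yields an
#' infinite-width interval and a non-significant call (conservative; no
#' division by zero).
#'
#' @param values Numeric vector of log2 values for one feature within one
#'   strain.
#' @param growth Character/factor vector ("high"/"low") aligned with
#'   `values`; at least 2 replicates per level.
#' @param conf_level Confidence level (default 0.95).
#' @return List with `fc`, `ci_lower`, `ci_upper`, `p`, `significant`.
#' @export
log2_fold_change <- function(values, growth, conf_level = 0.95) {
  lo <- values[growth == "low"]
  hi <- values[growth == "high"]
  n1 <- length(lo)
  n0 <- length(hi)
  if (n1 < 2 || n0 < 2) fail_input("need >= 2 replicates per growth level")
  fc <- mean(lo) - mean(hi)
  df <- n1 + n0 - 2
  sp2 <- ((n1 - 1) * stats::var(lo) + (n0 - 1) * stats::var(hi)) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n0))
  if (se == 0) {
    return(list(
      fc = fc, ci_lower = -Inf, ci_upper = Inf,
      p = NA_real_, significant = FALSE
    ))
  }
  tq <- stats::qt(1 - (1 - conf_level) / 2, df)
  p <- 2 * stats::pt(-abs(fc / se), df)
  list(
    fc = fc,
    ci_lower = fc - tq * se,
    ci_upper = fc + tq * se,
    p = p,
    significant = (fc - tq * se > 0) || (fc + tq * se < 0)
  )
}

#' Per-strain fold-change table for a set of features
#'
#' @param em An [expression_matrix()] whose samples cover both growth
#'   levels within each strain.
#' @param features Feature ids to evaluate (default all).
#' @param conf_level Confidence level (default 0.95).
#' @return Data frame with one row per feature x strain: `feature`,
#'   `strain`, `fc`, `ci_lower`, `ci_upper`, `p`, `significant`.
#' @export
fold_change_table <- function(em, features = rownames(em$values), conf_level = 0.95) {
  strains <- unique(em$samples$strain)
  rows <- list()
  for (s in strains) {
    sel <- em$samples$strain == s
    growth <- em$samples$growth[sel]
    vals <- em$values[features, sel, drop = FALSE]
    for (f in features) {
      r <- log2_fold_change(vals[f, ], growth, conf_level)
      rows[[length(rows) + 1]] <- data.frame(
        feature = f, strain = s, fc = r$fc,
        ci_lower = r$ci_lower, ci_upper = r$ci_upper,
        p = r$p, significant = r$significant,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Validate selected features by fold-change confidence intervals
#'
#' A selected feature is retained when its growth-rate fold-change interval
#' excludes zero in at least one strain; features that only describe
#' replicate variation are dropped. Features absent from the expression
#' matrix are excluded with a logged warning.
#'
#' @param selection A `selection_result` from [stability_select()] (or a
#'   character vector of feature ids).
#' @param em [expression_matrix()] with both strains and growth levels.
#' @param conf_level Confidence level (default 0.95).
#' @return Character vector of retained feature ids (a subset of the
#'   selected set); the full fold-change table is attached as attribute
#'   `fold_changes`.
#' @export
validate_selection <- function(selection, em, conf_level = 0.95) {
  feats <- if (is.character(selection)) selection else selected_features(selection)
  known <- feats %in% rownames(em$values)
  if (any(!known)) {
    warning(sprintf(
      "%d selected feature(s) not present in the expression matrix; excluded",
      sum(!known)
    ))
    pipeline_log("excluded %d unpaired selected feature(s)", sum(!known))
    feats <- feats[known]
  }
  if (length(feats) == 0) {
    out <- character(0)
    attr(out, "fold_changes") <- NULL
    return(out)
  }
  fc <- fold_change_table(em, feats, conf_level)
  sig_any <- tapply(fc$significant, fc$feature, any)
  retained <- feats[feats %in% names(sig_any)[sig_any]]
  attr(retained, "fold_changes") <- fc
  retained
}

#' Pearson correlation of features with the phenome end-products
#'
#' Simple correlation coefficient between each feature and each end-product
#' across all samples (both strains pooled).
#'
#' @param em [expression_matrix()] (or features x samples matrix).
#' @param phenome Samples x products numeric matrix (e.g. the four
#'   end-product concentrations or yields), rows aligned with the samples.
#' @return Features x products matrix of correlations; a zero-variance
#'   feature or product gives `NA` with a warning.
#' @export
correlate_phenome <- function(em, phenome) {
  vals <- if (inherits(em, "expression_matrix")) em$values else em
  phenome <- as.matrix(phenome)
  if (ncol(vals) != nrow(phenome)) {
    fail_input("feature matrix and phenome differ in sample count")
  }
  const_f <- apply(vals, 1, stats::var) == 0
  const_p <- apply(phenome, 2, stats::var) == 0
  if (any(const_f) || any(const_p)) {
    warning("zero-variance feature(s) or product(s): correlation undefined, reported as NA")
  }
  r <- suppressWarnings(stats::cor(t(vals), phenome))
  r[const_f, ] <- NA_real_
  r[, const_p] <- NA_real_
  r
}

#' Assign validated features to four principal-component pattern groups
#'
#' Fits a PCA on the samples x validated-features matrix (mean centered,
#' unit variance), orients PC1 so low-growth samples score positive and PC2
#' so that, within the low-growth cells, the second strain (alphabetically;
#' LS25 in the reference design) scores above the first. The PC2 convention
#' uses only the low-growth cells because the strain asymmetry that
#' separates the pattern groups lives there. Each feature's group is the quadrant of
#' its (PC1, PC2) loading signs: (+,+) group 1, (+,-) group 2, (-,+)
#' group 3, (-,-) group 4. Under this convention group 1 holds features
#' elevated at low growth with the stronger shift in the second strain,
#' group 2 features elevated in both strains, and groups 3/4 their
#' mirrored, reduced-at-low-growth counterparts. A loading of exactly zero
#' ties toward positive (logged).
#'
#' @param em [expression_matrix()] restricted to the validated features (or
#'   any features x samples matrix plus `samples` metadata).
#' @param samples Optional sample sheet when `em` is a plain matrix.
#' @return Data frame `feature`, `group` (1-4), `pc1_loading`,
#'   `pc2_loading`; the oriented `pca_model` is attached as attribute
#'   `pca`.
#' @export
assign_groups <- function(em, samples = NULL) {
  if (inherits(em, "expression_matrix")) {
    vals <- em$values
    samples <- em$samples
  } else {
    vals <- em
    if (is.null(samples)) fail_input("samples metadata required for a plain matrix")
  }
  if (nrow(vals) < 2) fail_input("need at least 2 features to group")
  model <- fit_pca(t(vals), scale = TRUE)
  if (ncol(model$scores) < 2) fail_input("need at least 2 principal components to group")
  low <- samples$growth == "low"
  if (mean(model$scores[low, 1]) < mean(model$scores[!low, 1])) {
    model <- flip_component(model, 1)
  }
  strains <- sort(unique(samples$strain))
  second <- samples$strain == strains[length(strains)]
  # PC2 separates the strain-asymmetric from the strain-symmetric response;
  # that asymmetry lives in the low-growth cells only, so the orientation
  # compares the two strains' low-growth scores (high-growth cells would
  # leak strain main effects into the convention)
  if (mean(model$scores[low & second, 2]) < mean(model$scores[low & !second, 2])) {
    model <- flip_component(model, 2)
  }
  l1 <- model$loadings[, 1]
  l2 <- model$loadings[, 2]
  if (any(l1 == 0) || any(l2 == 0)) {
    pipeline_log("zero loading encountered; tie broken toward positive")
  }
  group <- ifelse(l1 >= 0,
    ifelse(l2 >= 0, 1L, 2L),
    ifelse(l2 >= 0, 3L, 4L)
  )
  out <- data.frame(
    feature = rownames(vals),
    group = group,
    pc1_loading = unname(l1),
    pc2_loading = unname(l2),
    stringsAsFactors = FALSE
  )
  attr(out, "pca") <- model
  out
}

#' Full feature report: fold changes, significance, correlations, groups
#'
#' Combines the validated selection into the standard report layout: one
#' row per validated feature with its group, per-strain fold changes and
#' significance calls, and Pearson correlations with each end-product over
#' all samples. Mirrors the published per-feature report tables.
#'
#' @param retained Validated feature ids from [validate_selection()] (with
#'   the `fold_changes` attribute), or a character vector (fold changes are
#'   then recomputed).
#' @param em [expression_matrix()] holding those features.
#' @param phenome Samples x 4 matrix of end-product values with columns
#'   `lactate`, `formate`, `acetate`, `ethanol`.
#' @param mapping Optional data frame mapping `feature` to per-strain locus
#'   tags / product names, merged into the report.
#' @return Data frame sorted by group with columns `group`, `feature`,
#'   `fc_<strain>`, `sig_<strain>`, and `r_<product>`.
#' @export
feature_report <- function(retained, em, phenome, mapping = NULL) {
  feats <- as.character(retained)
  if (length(feats) == 0) fail_input("no validated features to report")
  fc <- attr(retained, "fold_changes")
  if (is.null(fc)) {
    fc <- fold_change_table(em, feats)
  }
  fc <- fc[fc$feature %in% feats, , drop = FALSE]
  strains <- unique(fc$strain)
  sub <- expression_matrix(
    em$values[feats, , drop = FALSE],
    em$samples, em$features
  )
  grp <- assign_groups(sub)
  r <- correlate_phenome(sub, phenome)
  out <- data.frame(
    group = grp$group[match(feats, grp$feature)],
    feature = feats, stringsAsFactors = FALSE
  )
  for (s in strains) {
    fcs <- fc[fc$strain == s, ]
    i <- match(feats, fcs$feature)
    out[[paste0("fc_", s)]] <- fcs$fc[i]
    out[[paste0("sig_", s)]] <- fcs$significant[i]
  }
  for (pp in colnames(r)) out[[paste0("r_", pp)]] <- r[feats, pp]
  if (!is.null(mapping)) {
    out <- merge(mapping, out, by = "feature", sort = FALSE)
  }
  out <- out[order(out$group, out$feature), , drop = FALSE]
  rownames(out) <- NULL
  # discordant fold-change signs between strains are reported, not dropped
  fc_cols <- grep("^fc_", names(out))
  if (length(fc_cols) == 2) {
    disc <- sum(sign(out[[fc_cols[1]]]) * sign(out[[fc_cols[2]]]) < 0)
    if (disc > 0) {
      pipeline_log("%d feature(s) with discordant fold-change sign between strains", disc)
    }
  }
  attr(out, "pca") <- attr(grp, "pca")
  out
}
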