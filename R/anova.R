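# Two-factor fixed-effects ANOVA for the balanced 2 strains x 2 growth
# levels x r replicates design, with a rotation-test FDR adjustment across
# responses. In the balanced orthogonal layout the three effect subspaces
# (strain, growth, interaction) are mutually orthogonal one-dimensional
# contrasts, so Type I/II/III sums of squares coincide and each term's F is
# a simple projection ratio.

check_design <- function(meta) {
  need <- c("strain", "growth")
  if (!all(need %in% names(meta))) fail_input("meta needs strain and growth columns")
  strain <- factor(meta$strain)
  growth <- factor(meta$growth, levels = intersect(c("high", "low"), unique(meta$growth)))
  if (nlevels(strain) != 2 || nlevels(growth) != 2) {
    fail_input("design must have exactly 2 strains and 2 growth levels")
  }
  tab <- table(strain, growth)
  r <- tab[1, 1]
  if (any(tab != r)) fail_input("unbalanced design: all four cells must have equal replication")
  if (r < 2) fail_input("need at least 2 replicates per cell")
  list(strain = strain, growth = growth, r = r)
}

# orthonormal contrast vectors for the three terms plus intercept; residual
# basis is the orthogonal complement
design_basis <- function(meta) {
  d <- check_design(meta)
  n <- length(d$strain)
  s <- ifelse(d$strain == levels(d$strain)[2], 1, -1)
  g <- ifelse(d$growth == levels(d$growth)[2], 1, -1)
  contrasts <- cbind(
    strain = s / sqrt(n),
    growth = g / sqrt(n),
    `strain:growth` = s * g / sqrt(n)
  )
  mean_vec <- rep(1 / sqrt(n), n)
  qrX <- qr(cbind(mean_vec, contrasts))
  Qfull <- qr.Q(qrX, complete = TRUE)
  list(
    contrasts = contrasts,
    residual_basis = Qfull[, -(1:4), drop = FALSE],
    df_error = n - 4L,
    n = n
  )
}

#' Two-factor F-tests per response
#'
#' Fixed-effects decomposition of a response over the balanced
#' 2 x 2 x r design into strain, growth and interaction terms, each tested
#' against the within-cell residual.
#'
#' Degenerate cases follow the conventions: a constant response gives F = 0
#' and p = 1 for every term; an effect with zero residual variance gives
#' F = Inf and p = 0.
#'
#' @param values Numeric vector (one response) or samples x responses
#'   matrix.
#' @param meta Data frame with `strain` and `growth` per sample (rows
#'   aligned with `values`).
#' @return Data frame with columns `response`, `term`, `F`, `p`
#'   (`df1 = 1`, `df2 = n - 4`).
#' @export
two_factor_f <- function(values, meta) {
  if (is.null(dim(values))) values <- matrix(values, ncol = 1)
  values <- as.matrix(values)
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("response", seq_len(ncol(values)))
  }
  if (nrow(values) != nrow(meta)) fail_input("values and meta differ in sample count")
  b <- design_basis(meta)
  proj <- t(b$contrasts) %*% values # 3 x m term coordinates
  ss_term <- proj^2
  resid <- t(b$residual_basis) %*% values
  ss_err <- colSums(resid^2)
  fstat <- sweep(ss_term, 2, ss_err / b$df_error, "/")
  # degenerate responses: a (numerically) zero residual makes a non-zero
  # effect infinitely significant (F = Inf, p = 0); a constant response
  # has no effect at all (F = 0, p = 1)
  ss_tot <- colSums(values^2)
  err_zero <- ss_err <= ss_tot * 1e-12
  if (any(err_zero)) {
    fstat[, err_zero] <- ifelse(ss_term[, err_zero, drop = FALSE] >
      rep(ss_tot[err_zero] * 1e-12, each = 3), Inf, 0)
  }
  fstat[ss_term == 0] <- 0
  pval <- stats::pf(fstat, 1, b$df_error, lower.tail = FALSE)
  data.frame(
    response = rep(colnames(values), each = 3),
    term = rep(rownames(ss_term), times = ncol(values)),
    F = as.vector(fstat),
    p = as.vector(pval),
    stringsAsFactors = FALSE
  )
}

# Haar-distributed random orthogonal matrix (QR of a Gaussian matrix with
# the sign of R's diagonal fixed, which makes the distribution uniform)
random_rotation <- function(d) {
  qrz <- qr(matrix(stats::rnorm(d * d), d, d))
  q <- qr.Q(qrz)
  q * rep(sign(diag(qr.R(qrz))), each = d)
}

#' Rotation-test FDR adjustment for multi-response ANOVA
#'
#' For every term, null resamples are generated by applying uniformly random
#' orthogonal rotations to each response's coordinates in the joint
#' hypothesis-plus-residual subspace. The same rotation is applied to all
#' responses, so the inter-response correlation of the residuals is
#' preserved, and the rotation is orthogonal, so each response's total sum
#' of squares in that subspace is preserved exactly. FDR-adjusted p-values
#' are a resampling step-up estimate within each term: at the observed
#' threshold p_(i), the expected number of null exceedances (averaged over
#' rotations, counted across responses) is divided by the observed rejection
#' count i, then monotonized from the largest p down and floored at the raw
#' p. In the independence limit the estimate converges to
#' Benjamini-Hochberg.
#'
#' @param values Samples x responses matrix (>= 2 responses).
#' @param meta Data frame with `strain` and `growth` per sample.
#' @param n_rotations Number of random rotations (default 10000; a warning
#'   is issued below 100).
#' @param seed Optional seed; a fixed seed gives bit-identical output.
#' @return Data frame as [two_factor_f()] with an additional `p_fdr`
#'   column (monotone in the raw p within each term).
#' @export
rotation_fdr <- function(values, meta, n_rotations = 10000, seed = NULL) {
  values <- as.matrix(values)
  if (ncol(values) < 2) fail_input("rotation FDR needs at least 2 responses")
  if (n_rotations < 100) {
    warning("fewer than 100 rotations: FDR estimate will be noisy")
  }
  b <- design_basis(meta)
  if (b$df_error < 1) fail_input("no residual degrees of freedom")
  resid <- t(b$residual_basis) %*% values
  if (any(colSums(resid^2) <= .Machine$double.eps * b$n)) {
    fail_input("degenerate residuals: a response has (numerically) zero residual variance")
  }
  obs <- two_factor_f(values, meta)
  pipeline_log(
    "rotation FDR: %d responses, %d rotations, seed=%s",
    ncol(values), n_rotations, ifelse(is.null(seed), "NULL", seed)
  )
  m <- ncol(values)
  d <- 1L + b$df_error
  terms <- c("strain", "growth", "strain:growth")
  obs$p_fdr <- NA_real_
  # per-term coordinates in the hypothesis (+) residual subspace
  coords <- lapply(terms, function(tt) {
    rbind(t(b$contrasts[, tt, drop = FALSE]) %*% values, resid)
  })
  names(coords) <- terms
  acc <- lapply(terms, function(tt) matrix(NA_real_, n_rotations, m))
  names(acc) <- terms
  with_seed(seed, {
    # one rotation per resample, shared across terms (a joint resample)
    for (bb in seq_len(n_rotations)) {
      rot <- random_rotation(d)
      for (tt in terms) {
        cs <- rot %*% coords[[tt]]
        ss_t <- cs[1, ]^2
        ss_e <- colSums(cs[-1, , drop = FALSE]^2)
        acc[[tt]][bb, ] <- ss_t / (ss_e / b$df_error)
      }
    }
  })
  for (tt in terms) {
    sel <- obs$term == tt
    f_obs <- obs$F[sel]
    null_sorted <- sort(acc[[tt]])
    n_null <- length(null_sorted)
    # expected null exceedance count at each observed F threshold
    exceed <- n_null - findInterval(f_obs - .Machine$double.eps^0.5, null_sorted)
    ev <- exceed / n_rotations
    ord <- order(obs$p[sel]) # ascending raw p = descending F
    q <- ev[ord] / seq_along(ord)
    q <- rev(cummin(rev(q))) # step-up monotonization
    adj <- numeric(length(ord))
    adj[ord] <- pmin(1, q)
    obs$p_fdr[sel] <- pmax(adj, obs$p[sel])
  }
  obs
}

#' Write an ANOVA/FDR result table as TSV
#'
#' Adds a significance star at `p_fdr < 0.05`.
#'
#' @param res Result of [rotation_fdr()].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_anova <- function(res, path) {
  res$significant <- ifelse(res$p_fdr < 0.05, "*", "")
  write_tsv(res, path)
}
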