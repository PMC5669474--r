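# Multi-response elastic net with a grouped row penalty, cross-validated
# regularization, and repeated (stability) selection. The solver is a
# pathwise block coordinate descent implemented in C++ (src/enet.cpp); the
# functions here own standardization, the lambda path, fold handling and
# the repeat loop.

#' Elastic net / stability selection configuration
#'
#' @param alpha Mixing weight between the lasso (L1, `alpha = 1`) and ridge
#'   (L2, `alpha = 0`) penalties; 0.5 gives them equal weight.
#' @param n_repeats Number of repeated cross-validated fits aggregated into
#'   selection frequencies (default 1000).
#' @param cv_folds Folds for cross-validation of lambda (default 4; with 12
#'   samples each fold holds 3).
#' @param n_lambda Length of the lambda path (default 100).
#' @param lambda_min_ratio Smallest path lambda as a fraction of
#'   `lambda_max`; default 0.01 when there are fewer samples than features,
#'   else 0.0001.
#' @param selection_threshold Selection-frequency cutoff for the final
#'   feature set (default 0.5 of repeats).
#' @param tol Coordinate-descent convergence tolerance on the maximum
#'   coefficient update (default 1e-7).
#' @param max_iter Maximum coordinate-descent sweeps per lambda.
#' @param seed Seed for the fold-assignment stream (the only source of
#'   randomness across repeats; the data are fixed).
#' @return Object of class `enet_config`.
#' @export
enet_config <- function(alpha = 0.5, n_repeats = 1000, cv_folds = 4,
                        n_lambda = 100, lambda_min_ratio = NULL,
                        selection_threshold = 0.5, tol = 1e-7,
                        max_iter = 100000, seed = NULL) {
  if (alpha < 0 || alpha > 1) fail_input("alpha must be in [0, 1]")
  if (cv_folds < 2) fail_input("cv_folds must be >= 2")
  if (selection_threshold <= 0 || selection_threshold > 1) {
    fail_input("selection_threshold must be in (0, 1]")
  }
  structure(
    list(
      alpha = alpha, n_repeats = as.integer(n_repeats),
      cv_folds = as.integer(cv_folds), n_lambda = as.integer(n_lambda),
      lambda_min_ratio = lambda_min_ratio,
      selection_threshold = selection_threshold,
      tol = tol, max_iter = as.integer(max_iter), seed = seed
    ),
    class = "enet_config"
  )
}

# column standardization with the 1/n variance convention, matching the
# (1/2n) loss scaling so standardized columns have v_j = 1
standardize_columns <- function(x) {
  x <- as.matrix(x)
  ctr <- colMeans(x)
  xc <- sweep(x, 2, ctr)
  sds <- sqrt(colMeans(xc^2))
  keep <- sds > .Machine$double.eps^0.5
  structure(
    sweep(xc[, keep, drop = FALSE], 2, sds[keep], "/"),
    center = ctr, sd = sds, kept = keep
  )
}

#' Largest penalty with an all-zero solution
#'
#' `lambda_max = max_j ||x_j' Y|| / (n * alpha)`: at and above this value
#' every coefficient row's group score is inside the L1 threshold, so the
#' all-zero matrix satisfies the optimality conditions.
#'
#' @param x Centered/standardized predictor matrix.
#' @param y Centered response matrix.
#' @param alpha Elastic net mixing weight (for `alpha < 0.001` the value at
#'   0.001 is used, as a pure-ridge path has no finite zero point).
#' @return Scalar lambda.
#' @export
lambda_max <- function(x, y, alpha) {
  y <- as.matrix(y)
  g <- crossprod(x, y) / nrow(x)
  max(sqrt(rowSums(g^2))) / max(alpha, 1e-3)
}

default_lambda_path <- function(x, y, config) {
  ratio <- config$lambda_min_ratio
  if (is.null(ratio)) ratio <- if (nrow(x) < ncol(x)) 0.01 else 1e-4
  lmax <- lambda_max(x, y, config$alpha)
  exp(seq(log(lmax), log(lmax * ratio), length.out = config$n_lambda))
}

# core fit: centers X and Y, runs the C++ path, restores intercepts
fit_enet_path <- function(x, y, alpha, lambdas, tol = 1e-7, max_iter = 100000) {
  x <- as.matrix(x)
  y <- as.matrix(y)
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    fail_input("non-finite values in predictors or responses")
  }
  x_ctr <- colMeans(x)
  y_ctr <- colMeans(y)
  xc <- sweep(x, 2, x_ctr)
  yc <- sweep(y, 2, y_ctr)
  beta <- enet_path_cpp(xc, yc, alpha, lambdas, tol, as.integer(max_iter))
  # intercepts: b0 = ybar - xbar' B per lambda
  icpt <- vapply(
    seq_along(lambdas),
    function(l) y_ctr - drop(crossprod(beta[, , l, drop = FALSE][, , 1], x_ctr)),
    numeric(ncol(y))
  )
  icpt <- matrix(icpt, nrow = ncol(y))
  dimnames(beta) <- list(colnames(x), colnames(y), NULL)
  list(lambda = lambdas, beta = beta, intercept = icpt)
}

#' Solve the multi-response elastic net at one penalty
#'
#' Minimizes `(1/2n) ||Y - XB||^2 + lambda * sum_j [alpha ||B_j.|| +
#' (1-alpha)/2 ||B_j.||^2]` with the grouped row penalty, so each feature
#' is active for all responses jointly. For a single response this is the
#' ordinary elastic net. Predictors are expected standardized (the
#' single-feature update then reduces to the familiar soft-threshold /
#' ridge-shrinkage closed form); responses are centered internally and the
#' intercept returned.
#'
#' @param x n x p predictor matrix (columns standardized).
#' @param y n x q response matrix (or vector).
#' @param alpha Elastic net mixing weight between 0 and 1.
#' @param lambda Penalty strength (scalar).
#' @param tol Convergence tolerance on the maximum coefficient update.
#' @param max_iter Maximum coordinate-descent sweeps.
#' @return List with `beta` (p x q matrix) and `intercept` (length-q
#'   vector).
#' @export
solve_enet <- function(x, y, alpha = 0.5, lambda, tol = 1e-7, max_iter = 100000) {
  y <- as.matrix(y)
  if (length(lambda) != 1) fail_input("lambda must be a single value")
  fit <- fit_enet_path(x, y, alpha, lambda, tol, max_iter)
  beta <- matrix(fit$beta[, , 1],
    nrow = dim(fit$beta)[1], ncol = dim(fit$beta)[2],
    dimnames = dimnames(fit$beta)[1:2]
  )
  list(beta = beta, intercept = drop(fit$intercept))
}

# stratified fold assignment: with the 2x2xr design, no fold may swallow a
# whole strain-by-growth cell, so every training set spans both strains and
# both growth levels
make_folds <- function(n, k, meta = NULL, max_tries = 200) {
  base <- rep(seq_len(k), length.out = n)
  if (is.null(meta)) {
    return(sample(base))
  }
  cells <- interaction(meta$strain, meta$growth, drop = TRUE)
  for (i in seq_len(max_tries)) {
    f <- sample(base)
    # every training set (complement of each fold) must retain at least
    # one sample from each cell
    ok <- all(vapply(seq_len(k), function(fold) {
      all(table(cells[f != fold]) > 0)
    }, logical(1)))
    if (ok) {
      return(f)
    }
  }
  pipeline_log("stratified fold draw failed %d times; using unconstrained folds", max_tries)
  sample(base)
}

#' Cross-validate the penalty strength
#'
#' Fits the lambda path on each training fold and picks `lambda_min`, the
#' path value minimizing the mean squared prediction error summed over
#' responses across all held-out samples. Ties take the larger (more
#' penalized) lambda. If a fold draw leaves a response without variance in
#' some training set, the folds are redrawn (logged).
#'
#' @param x Standardized predictor matrix.
#' @param y Response matrix.
#' @param config An [enet_config()].
#' @param meta Optional sample metadata for stratified folds.
#' @param folds Optional explicit fold assignment (overrides drawing).
#' @param lambdas Optional lambda path (default computed from the data).
#' @return List with `lambda` (path), `cvm` (CV error per lambda),
#'   `lambda_min`, `index_min`, `folds`.
#' @export
cv_lambda <- function(x, y, config = enet_config(), meta = NULL, folds = NULL,
                      lambdas = NULL) {
  x <- as.matrix(x)
  y <- as.matrix(y)
  n <- nrow(x)
  if (n < config$cv_folds) fail_input("fewer samples than folds")
  if (is.null(lambdas)) lambdas <- default_lambda_path(x, y, config)
  if (is.null(folds)) {
    for (try in 1:20) {
      folds <- make_folds(n, config$cv_folds, meta)
      ok <- all(vapply(seq_len(config$cv_folds), function(fold) {
        all(apply(y[folds != fold, , drop = FALSE], 2, stats::var) > 0)
      }, logical(1)))
      if (ok) break
      pipeline_log("fold draw left a zero-variance response; redrawing folds")
    }
  }
  sse <- numeric(length(lambdas))
  for (fold in seq_len(config$cv_folds)) {
    tr <- folds != fold
    fit <- fit_enet_path(
      x[tr, , drop = FALSE], y[tr, , drop = FALSE],
      config$alpha, lambdas, config$tol, config$max_iter
    )
    xte <- x[!tr, , drop = FALSE]
    for (l in seq_along(lambdas)) {
      pred <- xte %*% fit$beta[, , l] +
        matrix(fit$intercept[, l], nrow(xte), ncol(y), byrow = TRUE)
      sse[l] <- sse[l] + sum((y[!tr, , drop = FALSE] - pred)^2)
    }
  }
  cvm <- sse / n
  idx <- which.min(cvm) # first minimum = largest lambda on the descending path
  list(
    lambda = lambdas, cvm = cvm,
    lambda_min = lambdas[idx], index_min = idx, folds = folds
  )
}

#' Repeated elastic net stability selection
#'
#' Standardizes predictors and responses, then repeats `n_repeats` times:
#' draw cross-validation folds, find `lambda_min`, and record which feature
#' rows are non-zero in the full-data path fit at that penalty. The data are
#' fixed; the fold assignment is the only source of run-to-run variation.
#' A feature's selection frequency is the fraction of repeats in which it
#' was active; features at or above `selection_threshold` form the selected
#' set.
#'
#' @param x n x p predictor matrix (raw scale; standardized internally,
#'   zero-variance features dropped with a log note).
#' @param y n x q response matrix (standardized to unit variance
#'   internally).
#' @param config An [enet_config()]; `config$seed` fixes the fold stream.
#' @param meta Optional sample metadata for stratified folds.
#' @return Object of class `selection_result`: data frame with `feature`,
#'   `frequency`, `selected`, and `coef_<response>` columns (mean
#'   coefficient over repeats, standardized scale), plus attributes
#'   `config` and `lambda_path`.
#' @export
stability_select <- function(x, y, config = enet_config(), meta = NULL) {
  x <- as.matrix(x)
  y <- as.matrix(y)
  if (is.null(colnames(x))) colnames(x) <- paste0("X", seq_len(ncol(x)))
  if (is.null(colnames(y))) colnames(y) <- paste0("Y", seq_len(ncol(y)))
  xs <- standardize_columns(x)
  if (!all(attr(xs, "kept"))) {
    pipeline_log(
      "dropping %d zero-variance feature(s) before selection",
      sum(!attr(xs, "kept"))
    )
  }
  ys <- standardize_columns(y)
  if (!all(attr(ys, "kept"))) fail_input("a response has zero variance")
  pipeline_log(
    "stability selection: %d features, %d responses, alpha=%g, repeats=%d, folds=%d, threshold=%g, seed=%s",
    ncol(xs), ncol(ys), config$alpha, config$n_repeats, config$cv_folds,
    config$selection_threshold, ifelse(is.null(config$seed), "NULL", config$seed)
  )
  lambdas <- default_lambda_path(xs, ys, config)
  full <- fit_enet_path(xs, ys, config$alpha, lambdas, config$tol, config$max_iter)
  p <- ncol(xs)
  q <- ncol(ys)
  support_count <- numeric(p)
  coef_sum <- matrix(0, p, q)
  lambda_min_used <- numeric(config$n_repeats)
  with_seed(config$seed, {
    for (r in seq_len(config$n_repeats)) {
      cv <- cv_lambda(xs, ys, config, meta = meta, lambdas = lambdas)
      bsel <- full$beta[, , cv$index_min]
      bsel <- matrix(bsel, p, q)
      active <- rowSums(abs(bsel)) > 0
      support_count <- support_count + active
      coef_sum <- coef_sum + bsel
      lambda_min_used[r] <- cv$lambda_min
    }
  })
  freq <- support_count / config$n_repeats
  res <- data.frame(
    feature = colnames(xs),
    frequency = freq,
    selected = freq >= config$selection_threshold,
    stringsAsFactors = FALSE
  )
  mean_coef <- coef_sum / config$n_repeats
  colnames(mean_coef) <- paste0("coef_", colnames(ys))
  res <- cbind(res, as.data.frame(mean_coef))
  rownames(res) <- NULL
  attr(res, "config") <- config
  attr(res, "lambda_path") <- lambdas
  attr(res, "lambda_min_used") <- lambda_min_used
  class(res) <- c("selection_result", "data.frame")
  res
}

#' Selected feature ids from a selection result
#'
#' @param selection A `selection_result`.
#' @param threshold Optional override of the configured frequency cutoff.
#' @return Character vector of feature ids.
#' @export
selected_features <- function(selection, threshold = NULL) {
  if (is.null(threshold)) {
    return(selection$feature[selection$selected])
  }
  selection$feature[selection$frequency >= threshold]
}

#' Objective value of the grouped elastic net
#'
#' Exposed for optimality checks and tests.
#'
#' @param beta p x q coefficient matrix.
#' @param x Centered/standardized predictors.
#' @param y Centered responses.
#' @param alpha,lambda Penalty parameters.
#' @return Scalar objective value.
#' @export
enet_objective <- function(beta, x, y, alpha, lambda) {
  beta <- as.matrix(beta)
  r <- as.matrix(y) - x %*% beta
  rn <- sqrt(rowSums(beta^2))
  sum(r^2) / (2 * nrow(x)) +
    lambda * sum(alpha * rn + (1 - alpha) / 2 * rn^2)
}
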