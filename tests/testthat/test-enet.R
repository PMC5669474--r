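# independent objective evaluation for oracle comparisons
objective_direct <- function(beta, x, y, alpha, lambda) {
  r <- y - x %*% beta
  rn <- sqrt(rowSums(matrix(beta, ncol = ncol(y))^2))
  sum(r^2) / (2 * nrow(x)) + lambda * sum(alpha * rn + (1 - alpha) / 2 * rn^2)
}

test_that("the path endpoint at lambda_max is the all-zero solution", {
  x <- fixture_standardized_x(20, 6, seed = 41)
  with_seed(42, y <- matrix(rnorm(40), 20, 2))
  yc <- sweep(y, 2, colMeans(y))
  lmax <- lambda_max(x, yc, 0.5)
  fit <- solve_enet(x, y, 0.5, lmax * (1 + 1e-8))
  expect_equal(max(abs(fit$beta)), 0)
  fit2 <- solve_enet(x, y, 0.5, lmax * 0.9)
  expect_gt(max(abs(fit2$beta)), 0)
})

test_that("orthonormal single-response solution matches the soft-threshold closed form", {
  n <- 16
  x <- fixture_orthonormal_x(n, 7, seed = 43)
  with_seed(44, y <- rnorm(n))
  b_ols <- crossprod(x, y - mean(y)) / n
  soft <- function(z, t) sign(z) * pmax(abs(z) - t, 0)
  for (lambda in c(0.05, 0.2, 0.6)) {
    for (alpha in c(0.3, 0.5, 1)) {
      fit <- solve_enet(x, y, alpha, lambda, tol = 1e-12)
      expect_equal(
        drop(fit$beta),
        drop(soft(b_ols, lambda * alpha) / (1 + lambda * (1 - alpha))),
        tolerance = 1e-8, ignore_attr = TRUE
      )
    }
  }
})

test_that("ridge limit matches its closed form", {
  x <- fixture_standardized_x(25, 5, seed = 45)
  with_seed(46, y <- rnorm(25))
  lambda <- 0.3
  fit <- solve_enet(x, y, 0, lambda, tol = 1e-12)
  yc <- y - mean(y)
  b_ridge <- solve(crossprod(x) + 25 * lambda * diag(5), crossprod(x, yc))
  expect_equal(drop(fit$beta), drop(b_ridge), tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("solutions beat a dense numeric minimizer on small multi-response problems", {
  with_seed(47, {
    for (i in 1:5) {
      x <- matrix(rnorm(18), 6, 3)
      xc <- sweep(x, 2, colMeans(x))
      xs <- sweep(xc, 2, sqrt(colMeans(xc^2)), "/")
      y <- matrix(rnorm(12), 6, 2)
      yc <- sweep(y, 2, colMeans(y))
      lambda <- runif(1, 0.05, 0.4)
      fit <- solve_enet(xs, y, 0.5, lambda, tol = 1e-10)
      obj_cd <- objective_direct(fit$beta, xs, yc, 0.5, lambda)
      for (start in list(rep(0, 6), rnorm(6, sd = 0.3))) {
        num <- stats::optim(start,
          function(b) objective_direct(matrix(b, 3, 2), xs, yc, 0.5, lambda),
          method = "BFGS", control = list(maxit = 2000, reltol = 1e-14)
        )
        expect_lte(obj_cd, num$value + 1e-6)
      }
    }
  })
})

test_that("KKT conditions hold at the solution", {
  x <- fixture_standardized_x(12, 30, seed = 48)
  with_seed(49, y <- x[, 1:2] %*% matrix(c(1, 0.5, -0.3, 0.8), 2, 2) +
    matrix(rnorm(24), 12, 2) * 0.3)
  alpha <- 0.5
  lambda <- 0.15
  fit <- solve_enet(x, y, alpha, lambda, tol = 1e-10)
  yc <- sweep(y, 2, colMeans(y))
  grad <- crossprod(x, yc - x %*% fit$beta) / 12 # p x q
  rn <- sqrt(rowSums(fit$beta^2))
  active <- rn > 0
  expect_gt(sum(active), 0)
  expect_lt(sum(active), 30)
  # active rows: gradient = lambda*(1-alpha)*beta + lambda*alpha*beta/||beta||
  for (j in which(active)) {
    expected <- lambda * (1 - alpha) * fit$beta[j, ] +
      lambda * alpha * fit$beta[j, ] / rn[j]
    expect_lt(max(abs(grad[j, ] - expected)), 1e-6)
  }
  # inactive rows: gradient group norm below the L1 threshold
  for (j in which(!active)) {
    expect_lte(sqrt(sum(grad[j, ]^2)), lambda * alpha + 1e-6)
  }
})

test_that("warm-started path solutions equal cold starts and the objective is monotone in lambda", {
  x <- fixture_standardized_x(15, 20, seed = 50)
  with_seed(51, y <- x[, 1:3] %*% c(1.2, -0.8, 0.5) + rnorm(15) * 0.4)
  cfg <- enet_config()
  lambdas <- chemomics:::default_lambda_path(x, matrix(y - mean(y)), cfg)[seq(1, 100, 7)]
  path <- chemomics:::fit_enet_path(x, matrix(y), 0.5, lambdas, tol = 1e-10)
  for (i in seq_along(lambdas)) {
    cold <- solve_enet(x, y, 0.5, lambdas[i], tol = 1e-10)
    expect_equal(path$beta[, , i], unname(cold$beta)[, 1], tolerance = 1e-8)
  }
  # the densest fit sits at the small-lambda end of the path
  supp <- apply(path$beta, 3, function(b) sum(abs(b) > 0))
  expect_equal(supp[1], 0)
  expect_equal(max(supp), supp[length(supp)])
})

test_that("agreement with an independent grouped multi-response implementation", {
  skip_if_not_installed("glmnet")
  x <- fixture_standardized_x(30, 8, seed = 52)
  with_seed(53, y <- x[, 1:3] %*% matrix(rnorm(9), 3, 3) + matrix(rnorm(90), 30, 3) * 0.5)
  lambdas <- c(0.4, 0.15, 0.05)
  fit <- chemomics:::fit_enet_path(x, y, 0.5, lambdas, tol = 1e-12)
  g <- glmnet::glmnet(x, y,
    family = "mgaussian", alpha = 0.5, lambda = lambdas,
    standardize = FALSE, standardize.response = FALSE, thresh = 1e-14
  )
  for (i in seq_along(lambdas)) {
    cg <- glmnet::coef.glmnet(g, s = lambdas[i], exact = TRUE, x = x, y = y)
    bg <- do.call(cbind, lapply(cg, function(b) as.matrix(b)[-1, 1]))
    expect_equal(unname(fit$beta[, , i]), unname(bg), tolerance = 1e-6)
  }
})

test_that("cross-validation finds signal and is deterministic under a seed", {
  cfg <- enet_config(cv_folds = 4, n_lambda = 50)
  # a planted feature with high R^2 is active at lambda_min
  hits <- 0
  with_seed(54, {
    for (i in 1:10) {
      x <- fixture_standardized_x(40, 25, seed = 500 + i)
      y <- x[, 7] * 2 + rnorm(40) * sqrt(4 / 9) # R^2 ~ 0.9
      cv <- cv_lambda(x, matrix(y), cfg)
      fit <- solve_enet(x, y, 0.5, cv$lambda_min)
      if (abs(fit$beta[7, 1]) > 0) hits <- hits + 1
    }
  })
  expect_gte(hits, 9)
  # determinism: identical RNG state -> identical lambda_min
  x <- fixture_standardized_x(24, 15, seed = 55)
  with_seed(56, y <- matrix(rnorm(24)))
  cv1 <- with_seed(77, cv_lambda(x, y, cfg))
  cv2 <- with_seed(77, cv_lambda(x, y, cfg))
  expect_identical(cv1$lambda_min, cv2$lambda_min)
  expect_identical(cv1$cvm, cv2$cvm)
})

test_that("pure-noise responses select few features at lambda_min", {
  cfg <- enet_config(cv_folds = 4, n_lambda = 50)
  counts <- integer(20)
  with_seed(57, {
    for (i in 1:20) {
      x <- fixture_standardized_x(30, 40, seed = 700 + i)
      y <- matrix(rnorm(30))
      cv <- cv_lambda(x, y, cfg)
      fit <- solve_enet(x, y, 0.5, cv$lambda_min)
      counts[i] <- sum(abs(fit$beta) > 0)
    }
  })
  expect_lte(stats::median(counts), 4) # p/10
})

test_that("stability selection has the stated aggregation properties", {
  des <- synthetic_design(n_features = 60, n_planted_per_group = 3)
  met <- generate_phenome(des, 61)
  om <- generate_omics(des, 61)
  y <- phenome_yields(met)
  em <- preprocess_proteins(om$proteins, om$samples)
  x <- t(em$values)
  cfg1 <- enet_config(n_repeats = 1, seed = 9)
  s1 <- stability_select(x, y, cfg1, meta = em$samples)
  expect_true(all(s1$frequency %in% c(0, 1)))
  cfg <- enet_config(n_repeats = 12, seed = 9)
  s <- stability_select(x, y, cfg, meta = em$samples)
  expect_true(all(s$frequency >= 0 & s$frequency <= 1))
  # threshold monotonicity: the 1.0-threshold set is inside the 0.5 set
  expect_true(all(selected_features(s, 1.0) %in% selected_features(s, 0.5)))
  # determinism
  s2 <- stability_select(x, y, cfg, meta = em$samples)
  expect_identical(s$frequency, s2$frequency)
})
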