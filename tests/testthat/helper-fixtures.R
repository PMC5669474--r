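# Shared fixtures: small designs and matrices built in code.

options(chemomics.quiet = TRUE)

# the standard 2 strains x 2 growth levels x r replicates sample sheet
fixture_samples <- function(r = 3, strains = c("23K", "LS25")) {
  design_samples(synthetic_design(replicates = r, strains = strains))
}

# orthonormal predictor design with mean-zero columns and (1/n) X'X = I,
# the setting where the elastic net block update has a closed form
fixture_orthonormal_x <- function(n, p, seed = 1) {
  stopifnot(p < n)
  with_seed(seed, {
    qf <- qr.Q(qr(cbind(1, matrix(rnorm(n * p), n, p))))
    qf[, -1, drop = FALSE] * sqrt(n)
  })
}

# standardized Gaussian predictors (population-sd convention)
fixture_standardized_x <- function(n, p, seed = 1) {
  with_seed(seed, {
    x <- matrix(rnorm(n * p), n, p)
    xc <- sweep(x, 2, colMeans(x))
    sweep(xc, 2, sqrt(colMeans(xc^2)), "/")
  })
}

# reference phenotype row lookup
ref_row <- function(ref, strain, growth) {
  ref[ref$strain == strain & ref$growth == growth, , drop = FALSE]
}
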