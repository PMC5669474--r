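test_that("log2 fold change and pooled-t interval match the textbook formula", {
  growth <- rep(c("high", "low"), each = 3)
  # identical means: FC 0, CI contains 0
  r0 <- log2_fold_change(c(1, 2, 3, 1, 2, 3), growth)
  expect_equal(r0$fc, 0)
  expect_false(r0$significant)
  # zero variance: degenerate interval, conservative non-significant call
  rd <- log2_fold_change(c(1, 1, 1, 2, 2, 2), growth)
  expect_equal(rd$fc, 1)
  expect_equal(rd$ci_lower, -Inf)
  expect_false(rd$significant)
  # random replicates against an independent evaluation of the pooled-t CI
  with_seed(71, {
    for (i in 1:20) {
      hi <- rnorm(3, 5, 0.4)
      lo <- rnorm(3, 6, 0.4)
      r <- log2_fold_change(c(hi, lo), growth)
      sp <- sqrt((2 * var(lo) + 2 * var(hi)) / 4)
      hw <- qt(0.975, 4) * sp * sqrt(2 / 3)
      expect_equal(r$fc, mean(lo) - mean(hi), tolerance = 1e-12)
      expect_equal(r$ci_upper - r$ci_lower, 2 * hw, tolerance = 1e-10)
      # significance consistent with the two-sided t test
      tt <- t.test(lo, hi, var.equal = TRUE)
      expect_equal(r$p, tt$p.value, tolerance = 1e-12)
      expect_identical(r$significant, tt$p.value < 0.05)
    }
  })
  expect_error(log2_fold_change(c(1, 2, 3), c("high", "low", "low")), "replicates")
})

test_that("validation retains features significant in at least one strain", {
  samples <- fixture_samples()
  low <- samples$growth == "low"
  ls25 <- samples$strain == "LS25"
  with_seed(72, {
    vals <- matrix(rnorm(4 * 12, sd = 0.1), 4, 12)
    # f1: shifts in LS25 only; f2: shifts in both; f3, f4: null
    vals[1, low & ls25] <- vals[1, low & ls25] + 2
    vals[2, low] <- vals[2, low] + 2
  })
  rownames(vals) <- paste0("f", 1:4)
  colnames(vals) <- samples$sample_id
  em <- expression_matrix(vals, samples)
  kept <- validate_selection(paste0("f", 1:4), em)
  expect_true(all(c("f1", "f2") %in% kept))
  expect_false(any(c("f3", "f4") %in% kept))
  fc <- attr(kept, "fold_changes")
  expect_true(fc$significant[fc$feature == "f1" & fc$strain == "LS25"])
  expect_false(fc$significant[fc$feature == "f1" & fc$strain == "23K"])
  # unpaired features are excluded with a warning
  expect_warning(kept2 <- validate_selection(c("f1", "ghost"), em), "not present")
  expect_identical(as.character(kept2), "f1")
})

test_that("null features pass validation at roughly the nominal joint rate", {
  samples <- fixture_samples()
  n_feat <- 400
  with_seed(73, {
    vals <- matrix(rnorm(n_feat * 12), n_feat, 12)
  })
  rownames(vals) <- sprintf("n%03d", seq_len(n_feat))
  colnames(vals) <- samples$sample_id
  em <- expression_matrix(vals, samples)
  kept <- suppressWarnings(validate_selection(rownames(vals), em))
  rate <- length(kept) / n_feat
  # expected 1 - 0.95^2 = 0.0975; allow ~3 binomial SDs
  expect_lt(abs(rate - 0.0975), 3 * sqrt(0.0975 * 0.9025 / n_feat))
})

test_that("phenome correlations are exact on constructed examples", {
  samples <- fixture_samples()
  with_seed(74, lac <- rnorm(12))
  phen <- cbind(
    lactate = lac, formate = rnorm(12),
    acetate = rnorm(12), ethanol = rnorm(12)
  )
  vals <- rbind(feat_pos = lac, feat_neg = -lac)
  colnames(vals) <- samples$sample_id
  em <- expression_matrix(vals, samples)
  r <- correlate_phenome(em, phen)
  expect_equal(r["feat_pos", "lactate"], 1)
  expect_equal(r["feat_neg", "lactate"], -1)
  # 4-point hand examples
  expect_equal(unname(correlate_phenome(
    matrix(c(1, 2, 3, 4), 1, 4, dimnames = list("f", NULL)),
    matrix(c(2, 4, 6, 8), 4, 1)
  ))[1, 1], 1)
  expect_equal(unname(correlate_phenome(
    matrix(c(1, 2, 3, 4), 1, 4, dimnames = list("f", NULL)),
    matrix(c(4, 3, 2, 1), 4, 1)
  ))[1, 1], -1)
  # zero variance -> NA with warning
  expect_warning(
    rz <- correlate_phenome(
      matrix(1, 1, 12, dimnames = list("const", NULL)), phen
    ),
    "zero-variance"
  )
  expect_true(all(is.na(rz)))
})

test_that("group assignment lands planted patterns in their quadrants and mirrors flip diagonally", {
  des <- synthetic_design(n_features = 80, n_planted_per_group = 6, noise_sd = 0.1)
  om <- generate_omics(des, seed = 75)
  em <- preprocess_proteins(om$proteins, om$samples)
  truth <- om$truth
  planted <- truth$feature_id[truth$group > 0]
  sub <- expression_matrix(em$values[planted, , drop = FALSE], em$samples)
  grp <- assign_groups(sub)
  tg <- truth$group[match(grp$feature, truth$feature_id)]
  expect_gte(mean(grp$group == tg), 0.9)

  # mirrored features move to the diagonally opposite quadrant
  vals <- sub$values
  mirrored <- sweep(-vals, 1, 2 * rowMeans(vals), "+") # reflect around the mean
  both <- rbind(vals, `rownames<-`(mirrored, paste0(rownames(vals), "_mir")))
  g2 <- assign_groups(expression_matrix(both, em$samples))
  opposite <- c(`1` = 4L, `2` = 3L, `3` = 2L, `4` = 1L)
  base <- g2$group[seq_len(nrow(vals))]
  mir <- g2$group[nrow(vals) + seq_len(nrow(vals))]
  expect_gte(mean(mir == opposite[as.character(base)]), 0.9)
})

test_that("the feature report has the published layout and consistent content", {
  des <- synthetic_design(n_features = 60, n_planted_per_group = 3)
  met <- generate_phenome(des, 76)
  om <- generate_omics(des, 76)
  em <- preprocess_proteins(om$proteins, om$samples)
  truth <- om$truth
  planted <- truth$feature_id[truth$group > 0]
  kept <- validate_selection(planted, em)
  expect_true(length(kept) >= 2)
  phen <- phenome_yields(met)
  rep_tab <- feature_report(kept, em, phen)
  expect_identical(
    names(rep_tab),
    c(
      "group", "feature", "fc_23K", "sig_23K", "fc_LS25", "sig_LS25",
      "r_lactate", "r_formate", "r_acetate", "r_ethanol"
    )
  )
  expect_equal(nrow(rep_tab), length(kept))
  expect_true(all(rep_tab$group %in% 1:4))
  expect_true(all(abs(unlist(rep_tab[grep("^r_", names(rep_tab))])) <= 1))
  # every reported feature is significant in at least one strain
  expect_true(all(rep_tab$sig_23K | rep_tab$sig_LS25))
  # validation-retained set is a subset of the input selection
  expect_true(all(kept %in% planted))
})
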