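test_that("the design emits the 12-sample factorial layout", {
  s <- design_samples(synthetic_design())
  expect_equal(nrow(s), 12)
  expect_equal(sort(unique(s$strain)), c("23K", "LS25"))
  expect_equal(unname(table(s$strain, s$growth)), matrix(3L, 2, 2))
  expect_false(anyDuplicated(s$sample_id) > 0)
})

test_that("phenome generation is seeded, truncated and degenerates to the reference means", {
  des <- synthetic_design()
  m1 <- generate_phenome(des, 81)
  m2 <- generate_phenome(des, 81)
  expect_identical(m1, m2)
  m3 <- generate_phenome(des, 82)
  expect_false(identical(m1$lactate, m3$lactate))
  expect_true(all(m1[c("lactate", "formate", "acetate", "ethanol", "dry_weight")] >= 0))
  expect_equal(sort(unique(m1$dilution_rate)), c(0.045, 0.357))

  # SD -> 0 limit: generated values equal the reference means exactly
  ref0 <- reference_phenotypes()
  for (v in c("dry_weight", "lactate", "formate", "acetate", "ethanol")) {
    ref0[[paste0(v, "_sd")]] <- 1e-300
  }
  des0 <- synthetic_design(phenome = ref0)
  m0 <- generate_phenome(des0, 83)
  for (i in seq_len(nrow(ref0))) {
    sel <- m0$strain == ref0$strain[i] & m0$growth == ref0$growth[i]
    expect_equal(m0$lactate[sel], rep(ref0$lactate[i], 3), tolerance = 1e-9)
    expect_equal(m0$dry_weight[sel], rep(ref0$dry_weight[i], 3), tolerance = 1e-9)
  }
})

test_that("generated carbon balances stay in the physiological window", {
  des <- synthetic_design()
  frac_in <- vapply(1:100, function(s) {
    met <- generate_phenome(des, s)
    prof <- phenotype_profile(met)
    mean(prof$carbon_balance >= 90 & prof$carbon_balance <= 105)
  }, numeric(1))
  expect_gte(mean(frac_in), 0.95)
})

test_that("omics generation is reproducible and honors the planted truth", {
  des <- synthetic_design(n_features = 100, n_planted_per_group = 4)
  o1 <- generate_omics(des, 84)
  o2 <- generate_omics(des, 84)
  expect_identical(o1$counts, o2$counts)
  expect_identical(o1$proteins, o2$proteins)
  expect_identical(o1$truth, o2$truth)
  expect_equal(sum(o1$truth$group > 0), 16)
  expect_equal(as.vector(table(o1$truth$group[o1$truth$group > 0])), rep(4L, 4))

  # planted group-1 features: positive fold change in both strains,
  # larger in LS25, on the realized protein data
  em <- preprocess_proteins(o1$proteins, o1$samples)
  g1 <- o1$truth$feature_id[o1$truth$group == 1]
  fc <- fold_change_table(em, g1)
  fc23 <- fc$fc[fc$strain == "23K"]
  fc25 <- fc$fc[fc$strain == "LS25"]
  expect_true(all(fc23 > 0))
  expect_true(all(fc25 > fc23))
  expect_error(
    generate_omics(synthetic_design(n_features = 10, n_planted_per_group = 5), 1),
    "planted"
  )
})

test_that("rpkm applied to generated counts recovers the latent means within count noise", {
  des <- synthetic_design()
  om <- generate_omics(des, 85)
  kept <- om$counts[!om$annotation$is_rRNA, ]
  r <- rpkm(kept, om$annotation$length_bp[!om$annotation$is_rRNA])
  latent <- 2^om$latent_rpkm
  rel_err <- abs(r - latent) / latent
  expect_lte(stats::median(rel_err), 0.10)
})

test_that("strain dominates PC1 of the raw omics block", {
  des <- synthetic_design()
  om <- generate_omics(des, 86)
  em <- preprocess_proteins(om$proteins, om$samples)
  m <- fit_pca(t(em$values), scale = TRUE)
  s1 <- m$scores[, 1]
  is25 <- em$samples$strain == "LS25"
  # PC1 score sign separates the strains 12/12
  expect_true(
    all(s1[is25] > 0) && all(s1[!is25] < 0) ||
      all(s1[is25] < 0) && all(s1[!is25] > 0)
  )
})

test_that("null designs (no planted effect) yield few selections", {
  des <- synthetic_design(
    n_features = 120, n_planted_per_group = 3,
    effect_strong = 0, effect_weak = 0, strain_effect_frac = 0.5
  )
  met <- generate_phenome(des, 87)
  om <- generate_omics(des, 87)
  em <- preprocess_proteins(om$proteins, om$samples)
  cfg <- enet_config(n_repeats = 20, seed = 88)
  sel <- stability_select(t(em$values), phenome_yields(met), cfg, meta = em$samples)
  ret <- validate_selection(sel, em)
  expect_lte(length(ret), 0.05 * 120)
})

test_that("a written dataset round-trips through the readers", {
  dir <- withr::local_tempdir()
  des <- synthetic_design(n_features = 50, n_planted_per_group = 2)
  paths <- write_synthetic_dataset(des, 89, dir)
  expect_true(all(file.exists(paths)))
  samples <- read_sample_sheet(paths[["sample_sheet"]])
  met <- read_metabolite_table(paths[["metabolites"]])
  ann <- read_annotation(paths[["annotation"]])
  counts <- read_matrix(paths[["counts"]], samples)
  proteins <- read_matrix(paths[["proteins"]], samples)
  om <- generate_omics(des, 89)
  expect_equal(unname(counts$values), unname(om$counts), tolerance = 1e-14)
  expect_equal(unname(proteins$values), unname(om$proteins), tolerance = 1e-12)
  expect_equal(met$lactate, generate_phenome(des, 89)$lactate, tolerance = 1e-12)
  manifest <- read_config(paths[["manifest"]])
  expect_equal(manifest$seed, 89)
  expect_equal(manifest$n_features, 50)
})
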