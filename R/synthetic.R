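# Synthetic study generator: the full 2-strain x 2-growth-rate x
# 3-replicate design with (i) a phenome drawn from the packaged reference
# means and SDs and (ii) omics matrices carrying a dominant strain main
# effect, a minority of phenome-linked features planted in four
# interaction-pattern groups, and replicate noise. Ground truth is emitted
# alongside, so every pipeline stage can be scored without any downloads.

#' Synthetic study design parameters
#'
#' Defaults emulate the reference chemostat study: 12 samples (2 strains x
#' 2 growth rates x 3 biological replicates), phenome means/SDs from
#' [reference_phenotypes()], a strain main effect on a majority of features
#' (so strain dominates PC1 of the raw omics blocks), and 4 x 5 planted
#' features whose growth response follows the four pattern groups, with the
#' low-growth shift stronger for the second strain (LS25) than the first
#' (23K).
#'
#' Pattern groups (log2 shift at low growth, first/second strain):
#' group 1 `(+weak, +strong)`, group 2 `(+strong, +strong)`,
#' group 3 `(-strong, -strong)`, group 4 `(-weak, -strong)` -- groups 3/4
#' mirror 2/1, matching the loading-quadrant convention of
#' [assign_groups()].
#'
#' @param n_features Number of non-rRNA features per omics block (500).
#' @param n_planted_per_group Planted features per pattern group (5).
#' @param effect_strong Log2 shift magnitude for the stronger-responding
#'   strain (1.5).
#' @param effect_weak Log2 shift magnitude for the weaker strain in the
#'   asymmetric groups (0.75).
#' @param strain_effect_sd SD of the per-feature strain offset (log2, 1.0).
#' @param strain_effect_frac Fraction of features carrying a strain offset
#'   (0.6).
#' @param noise_sd Replicate noise SD on the log2 scale (0.25).
#' @param baseline_mean,baseline_sd Log2 baseline expression level drawn
#'   per feature (6.5 and 1.5 log2-RPKM units; with the default library
#'   size this puts the median expected reads per gene near the reference
#'   study's reported ~175).
#' @param protein_baseline_mean Log2 baseline for protein normalized
#'   abundances (20).
#' @param library_size Expected mapped reads per sample to non-rRNA genes
#'   (1e6).
#' @param n_rrna Number of rRNA loci added to the count matrix (4); they
#'   receive roughly half the total depth each, emulating rRNA dominance.
#' @param strains,dilution_rates,replicates Design labels.
#' @param phenome Reference phenome parameter table
#'   ([reference_phenotypes()] layout).
#' @return Object of class `synthetic_design`.
#' @export
synthetic_design <- function(n_features = 500,
                             n_planted_per_group = 5,
                             effect_strong = 1.5,
                             effect_weak = 0.75,
                             strain_effect_sd = 1.0,
                             strain_effect_frac = 0.6,
                             noise_sd = 0.25,
                             baseline_mean = 6.5,
                             baseline_sd = 1.5,
                             protein_baseline_mean = 20,
                             library_size = 1e6,
                             n_rrna = 4,
                             strains = c("23K", "LS25"),
                             dilution_rates = c(high = 0.357, low = 0.045),
                             replicates = 3,
                             phenome = reference_phenotypes()) {
  if (4 * n_planted_per_group > n_features) {
    fail_input("more planted features than features")
  }
  if (noise_sd <= 0 || strain_effect_sd <= 0) fail_input("SDs must be > 0")
  structure(
    list(
      n_features = as.integer(n_features),
      n_planted_per_group = as.integer(n_planted_per_group),
      effect_strong = effect_strong, effect_weak = effect_weak,
      strain_effect_sd = strain_effect_sd,
      strain_effect_frac = strain_effect_frac,
      noise_sd = noise_sd,
      baseline_mean = baseline_mean, baseline_sd = baseline_sd,
      protein_baseline_mean = protein_baseline_mean,
      library_size = library_size, n_rrna = as.integer(n_rrna),
      strains = strains, dilution_rates = dilution_rates,
      replicates = as.integer(replicates), phenome = phenome
    ),
    class = "synthetic_design"
  )
}

#' Sample sheet of a synthetic design
#'
#' @param design A [synthetic_design()].
#' @return Data frame `sample_id`, `strain`, `growth`, `replicate`.
#' @export
design_samples <- function(design) {
  grid <- expand.grid(
    replicate = seq_len(design$replicates),
    growth = c("high", "low"),
    strain = design$strains,
    stringsAsFactors = FALSE
  )
  grid <- grid[, c("strain", "growth", "replicate")]
  grid$sample_id <- sprintf("S%02d", seq_len(nrow(grid)))
  grid[, c("sample_id", "strain", "growth", "replicate")]
}

#' Generate a synthetic phenome (metabolite) table
#'
#' Concentrations and dry weights are drawn independently per sample from
#' normal distributions with the design's condition means and SDs
#' (truncated at 0); dilution rates are fixed at the design values and the
#' glucose feed is completely consumed.
#'
#' @param design A [synthetic_design()].
#' @param seed Seed; the same (design, seed) pair reproduces the table
#'   exactly.
#' @return Metabolite table in the [read_metabolite_table()] layout, plus
#'   `growth` and `replicate` columns.
#' @export
generate_phenome <- function(design, seed = NULL) {
  samples <- design_samples(design)
  ref <- design$phenome
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(samples)), function(i) {
      s <- samples[i, ]
      pr <- ref[ref$strain == s$strain & ref$growth == s$growth, ]
      if (nrow(pr) != 1) fail_input("phenome parameters missing for %s/%s", s$strain, s$growth)
      draw <- function(mu, sd) pmax(stats::rnorm(1, mu, sd), 0)
      data.frame(
        sample_id = s$sample_id, strain = s$strain, growth = s$growth,
        replicate = s$replicate,
        dilution_rate = pr$dilution_rate,
        dry_weight = draw(pr$dry_weight, pr$dry_weight_sd),
        glucose_feed = pr$glucose_feed, residual_glucose = 0,
        lactate = draw(pr$lactate, pr$lactate_sd),
        formate = draw(pr$formate, pr$formate_sd),
        acetate = draw(pr$acetate, pr$acetate_sd),
        ethanol = draw(pr$ethanol, pr$ethanol_sd),
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, rows)
  })
}

#' Molar end-product yields from a metabolite table
#'
#' Convenience accessor for the four-product phenome block used as the
#' response matrix of the selection step.
#'
#' @param metabolites Metabolite table.
#' @return Samples x 4 matrix (lactate, formate, acetate, ethanol yields,
#'   mol per mol glucose), rownames = sample ids.
#' @export
phenome_yields <- function(metabolites) {
  consumed <- metabolites$glucose_feed - metabolites$residual_glucose
  m <- sapply(PRODUCTS, function(p) product_yield(metabolites[[p]], consumed))
  rownames(m) <- metabolites$sample_id
  m
}

# per-sample condition shift for a planted pattern group
planted_shift <- function(design, group, strain_is_second, is_low) {
  e_s <- design$effect_strong
  e_w <- design$effect_weak
  shift <- switch(as.character(group),
    `1` = ifelse(strain_is_second, e_s, e_w),
    `2` = e_s,
    `3` = -e_s,
    `4` = ifelse(strain_is_second, -e_s, -e_w)
  )
  shift * is_low
}

#' Generate synthetic omics data with planted truth
#'
#' Builds log2-scale latent feature levels as baseline + strain main effect
#' (a majority fraction of features) + planted group patterns + replicate
#' noise, then realizes (i) a transcript count matrix by inverting RPKM
#' normalization (expected counts proportional to latent RPKM x gene
#' length, scaled to the design library size, Poisson-distributed) with
#' added high-abundance rRNA loci, and (ii) a strictly positive protein
#' normalized-abundance matrix from an independent latent draw of the same
#' design. The latent log2-RPKM means are renormalized per sample so that
#' applying [rpkm()] to the realized counts recovers them up to count
#' noise.
#'
#' @param design A [synthetic_design()].
#' @param seed Seed; (design, seed) reproduces everything.
#' @return List with `samples` (sample sheet), `counts` (integer matrix
#'   incl. rRNA rows), `annotation` (feature_id, length_bp, is_rRNA,
#'   product), `proteins` (abundance matrix), `truth` (feature_id, group
#'   0-4 where 0 = not planted, strain_effect flag), `latent_rpkm`
#'   (log2 latent RPKM means incl. the per-sample renormalization),
#'   `latent_protein`.
#' @export
generate_omics <- function(design, seed = NULL) {
  samples <- design_samples(design)
  n <- nrow(samples)
  p <- design$n_features
  feature_ids <- sprintf("F%04d", seq_len(p))
  is_second <- samples$strain == design$strains[2]
  is_low <- as.numeric(samples$growth == "low")
  with_seed(seed, {
    baseline <- stats::rnorm(p, design$baseline_mean, design$baseline_sd)
    planted <- sample.int(p, 4 * design$n_planted_per_group)
    group <- integer(p)
    group[planted] <- rep(1:4, each = design$n_planted_per_group)
    # the strain main effect sits on a majority of the background features;
    # the phenome-linked minority carries only its group pattern, so the
    # planted interaction structure is not confounded with the strain shift
    background <- setdiff(seq_len(p), planted)
    has_strain <- seq_len(p) %in% sample(background, min(
      length(background), round(design$strain_effect_frac * p)
    ))
    strain_offset <- ifelse(has_strain, stats::rnorm(p, 0, design$strain_effect_sd), 0)

    latent_mean <- matrix(baseline, p, n)
    latent_mean <- latent_mean + outer(strain_offset, as.numeric(is_second))
    for (g in 1:4) {
      idx <- which(group == g)
      shift <- planted_shift(design, g, is_second, is_low)
      latent_mean[idx, ] <- latent_mean[idx, ] + matrix(shift, length(idx), n, byrow = TRUE)
    }

    # transcript block
    latent_t <- latent_mean + matrix(stats::rnorm(p * n, 0, design$noise_sd), p, n)
    length_bp <- sample(300:3000, p, replace = TRUE)
    len_kb <- length_bp / 1000
    intensity <- 2^latent_t * len_kb
    # renormalize so each sample's latent RPKM integrates to 1e6 reads/kb:
    # then rpkm(counts) estimates the latent RPKM directly
    scale_s <- 1e6 / colSums(intensity)
    latent_rpkm <- sweep(2^latent_t, 2, scale_s, "*")
    mu_counts <- sweep(latent_rpkm * len_kb, 2, design$library_size / 1e6, "*")
    counts <- matrix(
      stats::rpois(p * n, lambda = as.vector(mu_counts)), p, n
    )
    # rRNA loci: roughly half the retained depth EACH, dwarfing the rest
    rrna_ids <- character(0)
    if (design$n_rrna > 0) {
      rrna_ids <- sprintf("RRNA%02d", seq_len(design$n_rrna))
      rrna_counts <- matrix(
        stats::rpois(design$n_rrna * n, design$library_size / 2),
        design$n_rrna, n
      )
      counts <- rbind(counts, rrna_counts)
    }
    rownames(counts) <- c(feature_ids, rrna_ids)
    colnames(counts) <- samples$sample_id
    annotation <- data.frame(
      feature_id = c(feature_ids, rrna_ids),
      length_bp = c(length_bp, rep(1500L, design$n_rrna)),
      is_rRNA = c(rep(FALSE, p), rep(TRUE, design$n_rrna)),
      product = c(
        ifelse(group > 0, sprintf("planted group %d protein", group)[seq_len(p)],
          "background protein"
        ),
        rep("ribosomal RNA", design$n_rrna)
      ),
      stringsAsFactors = FALSE
    )

    # protein block: same latent design, independent noise, linear scale
    latent_p <- latent_mean - design$baseline_mean + design$protein_baseline_mean +
      matrix(stats::rnorm(p * n, 0, design$noise_sd), p, n)
    proteins <- 2^latent_p
    dimnames(proteins) <- list(feature_ids, samples$sample_id)
    dimnames(latent_p) <- dimnames(proteins)
    dimnames(latent_rpkm) <- list(feature_ids, samples$sample_id)

    truth <- data.frame(
      feature_id = feature_ids,
      group = group,
      strain_effect = has_strain,
      stringsAsFactors = FALSE
    )
    list(
      samples = samples, counts = counts, annotation = annotation,
      proteins = proteins, truth = truth,
      latent_rpkm = log2(latent_rpkm), latent_protein = latent_p
    )
  })
}

#' Write a complete synthetic dataset to a directory
#'
#' Emits the metabolite table, sample sheet, transcript counts, gene
#' annotation, protein abundances, truth table and a YAML manifest
#' recording the design parameters and seed.
#'
#' @param design A [synthetic_design()].
#' @param seed Seed used for both the phenome and the omics draw.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of files written.
#' @export
write_synthetic_dataset <- function(design, seed, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  met <- generate_phenome(design, seed)
  om <- generate_omics(design, seed)
  paths <- c(
    metabolites = file.path(dir, "metabolites.tsv"),
    sample_sheet = file.path(dir, "sample_sheet.tsv"),
    counts = file.path(dir, "counts.tsv"),
    annotation = file.path(dir, "annotation.tsv"),
    proteins = file.path(dir, "proteins.tsv"),
    truth = file.path(dir, "truth.tsv"),
    manifest = file.path(dir, "manifest.yaml")
  )
  write_tsv(met, paths["metabolites"])
  write_tsv(om$samples, paths["sample_sheet"])
  write_matrix(om$counts, paths["counts"])
  write_tsv(om$annotation, paths["annotation"])
  write_matrix(om$proteins, paths["proteins"])
  write_tsv(om$truth, paths["truth"])
  manifest <- design[setdiff(names(design), "phenome")]
  manifest$seed <- seed
  yaml::write_yaml(manifest, paths["manifest"])
  pipeline_log("synthetic dataset written to %s (seed=%s)", dir, seed)
  invisible(paths)
}
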