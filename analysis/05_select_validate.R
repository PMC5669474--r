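#!/usr/bin/env Rscript
# Phenome-anchored feature selection on the omics blocks: repeated
# multi-response elastic net (alpha = 0.5, grouped penalty, lambda at the
# cross-validated minimum), fold-change confidence-interval validation per
# strain, PCA pattern grouping, and the per-feature correlation report.
# Scores the result against the planted truth.
#
# Usage: Rscript analysis/05_select_validate.R [datadir] [outdir] [seed] [repeats]

library(chemomics)

args <- commandArgs(trailingOnly = TRUE)
datadir <- if (length(args) >= 1) args[1] else "results/synthetic"
outdir <- if (length(args) >= 2) args[2] else "results"
seed <- if (length(args) >= 3) as.integer(args[3]) else 1L
repeats <- if (length(args) >= 4) as.integer(args[4]) else 100L
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

samples <- read_sample_sheet(file.path(datadir, "sample_sheet.tsv"))
ann <- read_annotation(file.path(datadir, "annotation.tsv"))
counts <- read_matrix(file.path(datadir, "counts.tsv"), samples)
proteins <- read_matrix(file.path(datadir, "proteins.tsv"), samples)
met <- read_metabolite_table(file.path(datadir, "metabolites.tsv"))
truth <- read_tsv(file.path(datadir, "truth.tsv"))

yields <- phenome_yields(met)
blocks <- list(
  proteome = preprocess_proteins(proteins$values, samples),
  transcriptome = preprocess_transcripts(counts$values, ann, samples)
)

for (nm in names(blocks)) {
  em <- blocks[[nm]]
  cfg <- enet_config(n_repeats = repeats, seed = seed)
  sel <- stability_select(t(em$values), yields, cfg, meta = em$samples)
  write_tsv(sel, file.path(outdir, paste0("selection_", nm, ".tsv")))
  kept <- validate_selection(sel, em)
  if (length(kept) < 2) {
    cat(sprintf("%s: %d feature(s) survived validation; no report written.\n", nm, length(kept)))
    next
  }
  report <- feature_report(kept, em, yields)
  write_tsv(report, file.path(outdir, paste0("feature_report_", nm, ".tsv")))

  planted <- truth$feature_id[truth$group > 0]
  sens <- mean(planted %in% kept)
  fdp <- mean(!(kept %in% planted))
  tg <- truth$group[match(report$feature, truth$feature_id)]
  acc <- mean(report$group[tg > 0] == tg[tg > 0])
  cat(sprintf(
    "%s: selected %d, validated %d | sensitivity %.2f, FDP %.2f, group accuracy %.2f\n",
    nm, sum(sel$selected), length(kept), sens, fdp, acc
  ))
}
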