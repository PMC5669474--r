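#!/usr/bin/env Rscript
# Preprocess the omics blocks (rRNA exclusion + RPKM + log2 for
# transcripts; log2 for protein abundances), summarize read coverage, and
# run the exploratory PCA within each data block (phenome, proteome,
# transcriptome) on mean-centered, unit-variance data.
#
# Usage: Rscript analysis/03_preprocess_pca.R [datadir] [outdir]

library(chemomics)

args <- commandArgs(trailingOnly = TRUE)
datadir <- if (length(args) >= 1) args[1] else "results/synthetic"
outdir <- if (length(args) >= 2) args[2] else "results"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

samples <- read_sample_sheet(file.path(datadir, "sample_sheet.tsv"))
ann <- read_annotation(file.path(datadir, "annotation.tsv"))
counts <- read_matrix(file.path(datadir, "counts.tsv"), samples)
proteins <- read_matrix(file.path(datadir, "proteins.tsv"), samples)
met <- read_metabolite_table(file.path(datadir, "metabolites.tsv"))

cov <- coverage_summary(
  counts$values[!ann$is_rRNA[match(rownames(counts$values), ann$feature_id)], ],
  samples$strain
)
write_tsv(cov, file.path(outdir, "coverage_summary.tsv"))
cat("Reads per gene (rRNA excluded):\n")
print(cov)

transcripts <- preprocess_transcripts(counts$values, ann, samples)
write_matrix(transcripts, file.path(outdir, "transcripts_log2rpkm.tsv"))
proteome <- preprocess_proteins(proteins$values, samples)
write_matrix(proteome, file.path(outdir, "proteome_log2.tsv"))

blocks <- list(
  phenome = phenome_yields(met),
  proteome = t(proteome$values),
  transcriptome = t(transcripts$values)
)
for (nm in names(blocks)) {
  m <- fit_pca(blocks[[nm]], scale = TRUE)
  write_pca(m, file.path(outdir, paste0("pca_", nm)))
  pct <- round(100 * explained_variance(m)[1:2], 1)
  s1 <- m$scores[, 1]
  sep_by <- function(f) {
    g <- split(s1, f)
    all(g[[1]] > max(g[[2]])) || all(g[[1]] < min(g[[2]]))
  }
  cat(sprintf(
    "%s PCA: PC1 %.1f%%, PC2 %.1f%%; PC1 separates growth rates: %s; strains: %s\n",
    nm, pct[1], pct[2], sep_by(samples$growth), sep_by(samples$strain)
  ))
}
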