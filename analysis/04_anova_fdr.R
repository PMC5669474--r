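#!/usr/bin/env Rscript
# Two-factor ANOVA (strain, growth, interaction) on the phenome
# end-products with rotation-test FDR adjustment across responses.
#
# Usage: Rscript analysis/04_anova_fdr.R [metabolites.tsv] [outdir] [seed]

library(chemomics)

args <- commandArgs(trailingOnly = TRUE)
met_path <- if (length(args) >= 1) args[1] else "results/synthetic/metabolites.tsv"
outdir <- if (length(args) >= 2) args[2] else "results"
seed <- if (length(args) >= 3) as.integer(args[3]) else 1L
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

met <- read_metabolite_table(met_path)
y <- cbind(
  lactate = met$lactate, formate = met$formate,
  acetate = met$acetate, ethanol = met$ethanol
)
res <- rotation_fdr(y, met, n_rotations = 10000, seed = seed)
write_anova(res, file.path(outdir, "anova_phenome.tsv"))

res$p <- signif(res$p, 3)
res$p_fdr <- signif(res$p_fdr, 3)
res$F <- round(res$F, 2)
print(res)
cat(sprintf(
  "\n%d of %d term-wise tests significant at p.FDR < 0.05.\n",
  sum(res$p_fdr < 0.05), nrow(res)
))
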