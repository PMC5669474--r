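#!/usr/bin/env Rscript
# Generate the synthetic study: 2 strains x 2 growth rates x 3 replicates,
# phenome replicates drawn from the packaged reference chemostat parameters,
# and proteome/transcriptome matrices with a dominant strain effect plus 20
# planted phenome-linked features in 4 interaction-pattern groups.
#
# Usage: Rscript analysis/01_simulate.R [seed] [outdir]

library(chemomics)

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 1L
outdir <- if (length(args) >= 2) args[2] else "results/synthetic"

design <- synthetic_design()
paths <- write_synthetic_dataset(design, seed, outdir)

met <- read_metabolite_table(paths[["metabolites"]])
truth <- read_tsv(paths[["truth"]])
cat(sprintf(
  "Wrote %d files to %s (seed %d): %d samples, %d features (%d planted in 4 groups), %d rRNA loci.\n",
  length(paths), outdir, seed, nrow(met),
  design$n_features, sum(truth$group > 0), design$n_rrna
))
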