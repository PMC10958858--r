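#!/usr/bin/env Rscript
# Step 1 — generate the synthetic ageing-methylome study.
#
# Emulates a pooled-individual WGBS ageing design in a sparsely methylated
# insect genome: 2 sexes x 3 timepoints (day 0, 8, 16) x 3 replicates, a
# mostly unmethylated genome with planted differentially methylated, drifting
# and clock CpGs, and an unmethylated lambda spike-in. Writes the per-sample
# coverage files, the sample sheet, the ground truth, and a synthetic gene
# annotation + GO map under results/simulated/.

library(methager)

seed <- 42
out <- "results/simulated"

cfg <- sim_config(seed = seed)
sim <- simulate_experiment(cfg, out)
ann <- simulate_annotation(sim$truth, out, seed = seed)

cat(sprintf("wrote %d coverage files under %s\n", nrow(sim$samples), out))
cat(sprintf("site classes: %s\n",
            paste(sprintf("%s=%d", names(table(sim$truth$class)),
                          table(sim$truth$class)), collapse = ", ")))
cat(sprintf("gene annotation: %d genes, GO map: %d annotated genes\n",
            nrow(ann$genes), length(ann$go)))
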