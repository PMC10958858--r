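#!/usr/bin/env Rscript
# Step 6 — GO-term over-representation of the gene sets of interest.
#
# VMP-bearing genes and clock genes are tested against the methylated-gene
# background (mean weighted methylation > 0.05 in at least one sex x age
# group); the consistently hyper-/hypomethylated gene sets are tested
# against all differentially methylated genes. Hypergeometric upper-tail
# tests, BH across terms, q < 0.05.

library(methager)

samples <- read_sample_sheet("results/simulated/samples.tsv")
mat <- read_matrix_tsv("results/matrix.tsv", samples)
mmat <- read_matrix_tsv("results/methylated_matrix.tsv", samples)
ann <- read_annotations("results/simulated/genes.gff3",
                        "results/simulated/go_map.tsv")
gene_dm <- read.delim("results/genes_dm.tsv")
cons <- read.delim("results/consistent_sets.tsv")
vmps <- read.delim("results/vmp.tsv")
clock <- read.delim("results/clock_model.tsv")

meth_bg <- methylated_background(mat, ann$genes)
dm_bg <- unique(gene_dm$gene_id[gene_dm$status == "dm"])
cat(sprintf("backgrounds: %d methylated genes, %d DM genes\n",
            length(meth_bg), length(dm_bg)))

studies <- list(
  vmp_genes = list(genes_of_sites(vmps$site_key[vmps$is_vmp], ann$genes), meth_bg),
  clock_genes = list(genes_of_sites(setdiff(clock$site_key, "(Intercept)"),
                                    ann$genes), meth_bg))
for (s in unique(cons$sex)) {
  for (set in unique(cons$set)) {
    studies[[paste(set, s, sep = "_")]] <-
      list(genes_of_sites(cons$site_key[cons$sex == s & cons$set == set],
                          ann$genes), dm_bg)
  }
}

rows <- list()
for (nm in names(studies)) {
  study <- intersect(studies[[nm]][[1]], studies[[nm]][[2]])
  bg <- studies[[nm]][[2]]
  if (length(study) == 0 || length(bg) == 0) {
    cat(sprintf("%s: empty study set, skipped\n", nm))
    next
  }
  enr <- hypergeometric_enrichment(study, bg, ann$go)
  cat(sprintf("%s: %d study genes, %d terms tested, %d significant\n",
              nm, length(study), nrow(enr), sum(enr$significant)))
  rows[[nm]] <- cbind(study_set = nm, enr)
}
out <- do.call(rbind, rows)
write.table(out, "results/enrichment.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
print(head(out[order(out$p), ], 5), row.names = FALSE)
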