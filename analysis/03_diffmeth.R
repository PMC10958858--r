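#!/usr/bin/env Rscript
# Step 3 — differential methylation across age within each sex.
#
# Per-CpG logistic-regression likelihood-ratio tests for every age pair
# within each sex (BH within comparison; a call needs q < 0.05 and a
# methylation difference strictly above 15%), direction-consistency sets
# across the successive comparisons, and gene-level aggregation (>= 2 DMPs
# and a >= 15% weighted methylation difference across the feature).

library(methager)

samples <- read_sample_sheet("results/simulated/samples.tsv")
mmat <- read_matrix_tsv("results/methylated_matrix.tsv", samples)
ann <- read_annotations("results/simulated/genes.gff3",
                        "results/simulated/go_map.tsv")

dmps <- call_dmps(mmat)
for (cmp in unique(dmps$comparison)) {
  d <- dmps[dmps$comparison == cmp, ]
  cat(sprintf("%s: %d hyper, %d hypo of %d sites\n", cmp,
              sum(d$status == "hyper"), sum(d$status == "hypo"), nrow(d)))
}
union_sites <- dmp_union_sites(dmps)
cat(sprintf("CpGs significant in >= 1 comparison: %d\n", length(union_sites)))

cons <- lapply(c("F", "M"), function(s) classify_consistent(dmps, s))
names(cons) <- c("F", "M")
for (s in names(cons)) {
  cat(sprintf("sex %s: consistently hyper %d, hypo %d\n", s,
              length(cons[[s]]$consistent_hyper),
              length(cons[[s]]$consistent_hypo)))
}

gene_dm <- gene_level_dm(dmps, ann$genes, mmat)
cat(sprintf("differentially methylated genes (any comparison): %d\n",
            length(unique(gene_dm$gene_id[gene_dm$status == "dm"]))))

write.table(dmps, "results/dmp.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
writeLines(union_sites, "results/dmp_union_sites.txt")
write.table(gene_dm, "results/genes_dm.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cons_tab <- do.call(rbind, lapply(names(cons), function(s) {
  rbind(data.frame(sex = s, set = "consistent_hyper",
                   site_key = cons[[s]]$consistent_hyper),
        data.frame(sex = s, set = "consistent_hypo",
                   site_key = cons[[s]]$consistent_hypo))
}))
write.table(cons_tab, "results/consistent_sets.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(weighted_methylation_summary(mmat),
            "results/weighted_methylation_by_group.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
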