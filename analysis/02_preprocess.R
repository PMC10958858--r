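#!/usr/bin/env Rscript
# Step 2 — from raw per-CpG counts to the methylated-CpG analysis set.
#
# Estimates the bisulfite non-conversion error from the lambda spike, filters
# each library by coverage (>= 10 and <= its 99th percentile), unites the
# libraries over the sites every one observed, median-normalizes coverage and
# calls methylated CpGs with the one-sided binomial test against the
# conversion error (BH, q < 0.05). Writes results/matrix.tsv (all united
# sites), results/methylated_matrix.tsv (the analysis set) and calls.tsv.

library(methager)

samples <- read_sample_sheet("results/simulated/samples.tsv")
site_lists <- lapply(samples$path, read_coverage_file)
prep <- preprocess_samples(site_lists, samples)

cat(sprintf("conversion error: %.5f (total spike coverage %d)\n",
            prep$conversion$rate, prep$conversion$total_coverage))
cat(sprintf("united sites: %d; methylated in >= 1 sample: %d (%.1f%%)\n",
            prep$n_united, prep$n_methylated,
            100 * prep$n_methylated / prep$n_united))

dir.create("results", showWarnings = FALSE)
write_matrix_tsv(prep$matrix, "results/matrix.tsv")
write_matrix_tsv(prep$methylated, "results/methylated_matrix.tsv")
write.table(data.frame(site_key = rownames(prep$calls$q),
                       min_q = apply(prep$calls$q, 1, min),
                       n_methylated_samples = rowSums(prep$calls$methylated),
                       methylated_in_any = prep$calls$methylated_in_any),
            "results/calls.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
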