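# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

# Small, fast methylome for unit tests.
small_sim_config <- function(seed = 101) {
  sim_config(seed = seed,
             n_null_unmethylated = 500,
             n_stable_methylated = 400,
             n_dmp_hyper = 80,
             n_dmp_hypo = 80,
             n_vmp = 250,
             n_clock = 30,
             lambda_n_sites = 60)
}

small_fixture <- function() {
  if (is.null(.fixture_cache$small)) {
    dir <- file.path(tempdir(), "methager-small-fixture")
    sim <- simulate_experiment(small_sim_config(), dir)
    ann <- simulate_annotation(sim$truth, dir, seed = 101)
    prep <- preprocess_samples(sim$site_lists, sim$samples)
    .fixture_cache$small <- list(sim = sim, ann = ann, prep = prep, dir = dir)
  }
  .fixture_cache$small
}

# Full-scale study fixture (default generator settings) for the acceptance
# checks: one complete pipeline run plus the truth table.
study_fixture <- function() {
  if (is.null(.fixture_cache$study)) {
    dir <- file.path(tempdir(), "methager-study-fixture")
    sim <- simulate_experiment(sim_config(seed = 4242), dir)
    ann <- simulate_annotation(sim$truth, dir, seed = 4242)
    cfg <- pipeline_config(sample_sheet = sim$paths$sample_sheet,
                           genes_path = ann$paths$gff,
                           go_path = ann$paths$go,
                           out_dir = file.path(dir, "out"),
                           seed = 4242)
    res <- suppressMessages(run_pipeline(cfg))
    .fixture_cache$study <- list(sim = sim, ann = ann, cfg = cfg, res = res,
                                 dir = dir)
  }
  .fixture_cache$study
}

# Truth classes aligned to the rows of a count matrix.
truth_classes <- function(truth, mat) {
  truth$class[match(rownames(mat$meth), truth$site_key)]
}

# Hand-rolled meth_matrix for crafted-count tests.
make_matrix <- function(meth, cov, samples, chrom = "chr1",
                        pos = seq_len(nrow(meth)) * 10L) {
  sites <- data.frame(chrom = chrom, pos = pos, stringsAsFactors = FALSE)
  keys <- paste(sites$chrom, sites$pos, sep = ":")
  dimnames(meth) <- dimnames(cov) <- list(keys, samples$sample_id)
  structure(list(sites = sites, samples = samples,
                 meth = meth, cov = cov),
            class = "meth_matrix")
}

make_samples <- function(sex, age, rep = seq_along(sex)) {
  data.frame(sample_id = sprintf("%s_d%d_r%d", sex, age, rep),
             sex = sex, age_days = age, replicate = rep,
             path = NA_character_, stringsAsFactors = FALSE)
}
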