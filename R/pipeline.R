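#' Pipeline configuration
#'
#' Collects paths and thresholds for a full run, with the study's default
#' thresholds: coverage >= 10 and <= the per-sample 99th percentile, a
#' binomial methylation call at FDR 0.05 against the spike-derived
#' conversion error, DMP calls at q < 0.05 with |delta| > 0.15, VMPs at
#' Holm-adjusted p < 0.05, enrichment at q < 0.05 with a weighted-methylation
#' background cutoff of 0.05.
#'
#' @param sample_sheet Path to the sample sheet TSV.
#' @param genes_path Gene annotation (GFF3 or TSV).
#' @param go_path GO map TSV.
#' @param out_dir Output directory.
#' @param lambda_chrom Spike chromosome name.
#' @param min_cov,upper_percentile,call_fdr,dmp_q,min_delta,vmp_alpha,enrich_q,background_threshold
#'   Stage thresholds (see the stage functions).
#' @param clock_alpha,clock_folds,seed Clock settings.
#' @return Validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(sample_sheet, genes_path, go_path, out_dir,
                            lambda_chrom = "lambda",
                            min_cov = 10, upper_percentile = 99,
                            call_fdr = 0.05, dmp_q = 0.05, min_delta = 0.15,
                            vmp_alpha = 0.05, enrich_q = 0.05,
                            background_threshold = 0.05,
                            clock_alpha = 0.5, clock_folds = 3, seed = 1) {
  cfg <- list(sample_sheet = sample_sheet, genes_path = genes_path,
              go_path = go_path, out_dir = out_dir,
              lambda_chrom = lambda_chrom, min_cov = min_cov,
              upper_percentile = upper_percentile, call_fdr = call_fdr,
              dmp_q = dmp_q, min_delta = min_delta, vmp_alpha = vmp_alpha,
              enrich_q = enrich_q, background_threshold = background_threshold,
              clock_alpha = clock_alpha, clock_folds = clock_folds,
              seed = as.integer(seed))
  probs <- c(call_fdr = call_fdr, dmp_q = dmp_q, vmp_alpha = vmp_alpha,
             enrich_q = enrich_q)
  bad <- probs[probs <= 0 | probs >= 1]
  if (length(bad) > 0L) {
    stop("probability thresholds must lie in (0,1): ",
         paste(names(bad), collapse = ", "))
  }
  if (min_delta < 0 || min_delta > 1) stop("min_delta must lie in [0,1]")
  if (clock_alpha < 0 || clock_alpha > 1) stop("clock_alpha must lie in [0,1]")
  if (min_cov < 1) stop("min_cov must be >= 1")
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with keys matching [pipeline_config()] arguments.
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

wt <- function(x, dir, name) {
  utils::write.table(x, file.path(dir, name), sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Run the full ageing-methylome pipeline
#'
#' Orchestrates preprocess -> DMP -> gene-level DM -> VMP -> entropy ->
#' clock -> enrichment on real or simulated coverage files and writes every
#' stage's table under `config$out_dir` together with a manifest of the
#' thresholds used. All stages are pure functions of (inputs, config, seed):
#' a rerun with identical inputs is bit-identical.
#'
#' @param config A [pipeline_config()] (or a YAML path).
#' @return Invisibly, a list with the main in-memory results.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "pipeline_config")) stop("config must be a pipeline_config")
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character()
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    message(line)
    log_lines <<- c(log_lines, line)
  }

  say("stage preprocess: reading sample sheet %s", config$sample_sheet)
  samples <- read_sample_sheet(config$sample_sheet)
  site_lists <- lapply(samples$path, read_coverage_file)
  say("read %d samples", nrow(samples))
  prep <- preprocess_samples(site_lists, samples,
                             lambda_chrom = config$lambda_chrom,
                             min_cov = config$min_cov,
                             upper_percentile = config$upper_percentile,
                             fdr = config$call_fdr)
  say("conversion error: %.6f (spike coverage %d)",
      prep$conversion$rate, prep$conversion$total_coverage)
  say("coverage filter kept %d-%d sites per sample; united matrix: %d sites; methylated in >=1 sample: %d",
      min(prep$counts$sites_kept), max(prep$counts$sites_kept),
      prep$n_united, prep$n_methylated)
  write_matrix_tsv(prep$matrix, file.path(out, "matrix.tsv"))
  calls_tab <- data.frame(site_key = rownames(prep$calls$q),
                          min_q = apply(prep$calls$q, 1, min),
                          n_methylated_samples = rowSums(prep$calls$methylated),
                          methylated_in_any = prep$calls$methylated_in_any,
                          row.names = NULL)
  wt(calls_tab, out, "calls.tsv")

  say("stage diffmeth: logistic-regression DMP calls")
  mmat <- prep$methylated
  dmps <- call_dmps(mmat, q_max = config$dmp_q, min_delta = config$min_delta)
  union_sites <- dmp_union_sites(dmps)
  say("DMPs significant in >=1 comparison: %d of %d methylated sites",
      length(union_sites), nrow(mmat$sites))
  wt(dmps, out, "dmp.tsv")

  ann <- read_annotations(config$genes_path, config$go_path)
  gene_dm <- gene_level_dm(dmps, ann$genes, mmat,
                           min_delta = config$min_delta)
  say("gene-level DM calls: %d", sum(gene_dm$status == "dm"))
  wt(gene_dm, out, "genes_dm.tsv")

  sexes <- unique(samples$sex)
  cons <- lapply(sexes, function(s) classify_consistent(dmps, s))
  names(cons) <- sexes
  cons_tab <- do.call(rbind, lapply(sexes, function(s) {
    rbind(data.frame(sex = s, set = "consistent_hyper",
                     site_key = cons[[s]]$consistent_hyper),
          data.frame(sex = s, set = "consistent_hypo",
                     site_key = cons[[s]]$consistent_hypo))
  }))
  say("consistent sets: %s",
      paste(sprintf("%s hyper %d / hypo %d", sexes,
                    vapply(cons, function(x) length(x$consistent_hyper), integer(1)),
                    vapply(cons, function(x) length(x$consistent_hypo), integer(1))),
            collapse = "; "))
  wt(cons_tab, out, "consistent_sets.tsv")
  wt(weighted_methylation_summary(mmat), out, "weighted_methylation_by_group.tsv")

  say("stage drift: Breusch-Pagan VMP screen on %d methylated sites", nrow(mmat$sites))
  vmps <- detect_vmps(mmat, alpha = config$vmp_alpha)
  say("VMPs at Holm-adjusted p < %.2f: %d", config$vmp_alpha, sum(vmps$is_vmp))
  wt(vmps, out, "vmp.tsv")

  say("stage entropy: %d age-significant CpGs", length(union_sites))
  if (length(union_sites) == 0L) stop("stage entropy: no age-significant CpGs")
  entropies <- entropy_per_sample(mmat, union_sites)
  wt(entropies, out, "entropy.tsv")
  emodel <- entropy_age_model(entropies, samples)
  writeLines(utils::capture.output(print(emodel)), file.path(out, "entropy_model.txt"))

  say("stage clock: elastic net on %d CpGs, alpha %.2f, %d folds",
      length(union_sites), config$clock_alpha, config$clock_folds)
  frac <- t(meth_fractions(subset_sites(mmat, union_sites)))
  clock <- fit_elastic_net(frac, samples$age_days, alpha = config$clock_alpha,
                           cv_folds = config$clock_folds, seed = config$seed)
  pred <- predict_age(clock, frac)
  ev <- evaluate_clock(pred, samples$age_days)
  accel <- age_acceleration(pred, samples$age_days)
  wilcox <- rank_sum_test(accel[samples$sex == "F"], accel[samples$sex == "M"])
  say("clock: %d CpGs selected; in-sample Spearman rho %.3f, RMSE %.3f days",
      length(clock$sites), ev$spearman_rho, ev$rmse_days)
  wt(data.frame(site_key = c("(Intercept)", clock$sites),
                weight = c(clock$intercept, unname(clock$weights))),
     out, "clock_model.tsv")
  wt(data.frame(sample_id = samples$sample_id, sex = samples$sex,
                age_days = samples$age_days, epigenetic_age = unname(pred),
                acceleration = unname(accel)),
     out, "predictions.tsv")
  writeLines(c(sprintf("n_selected_cpgs\t%d", length(clock$sites)),
               sprintf("spearman_rho\t%.6f", ev$spearman_rho),
               sprintf("spearman_p\t%.6g", ev$spearman_p),
               sprintf("rmse_days\t%.6f", ev$rmse_days),
               sprintf("acceleration_wilcoxon_W\t%g", wilcox$W),
               sprintf("acceleration_wilcoxon_p\t%.6g", wilcox$p)),
             file.path(out, "evaluation.txt"))

  say("stage enrichment: hypergeometric GO tests")
  meth_bg <- methylated_background(prep$matrix, ann$genes,
                                   threshold = config$background_threshold)
  dm_bg <- unique(gene_dm$gene_id[gene_dm$status == "dm"])
  studies <- list(
    vmp_genes = list(study = intersect(genes_of_sites(vmps$site_key[vmps$is_vmp],
                                                      ann$genes), meth_bg),
                     background = meth_bg),
    clock_genes = list(study = intersect(genes_of_sites(clock$sites, ann$genes),
                                         meth_bg),
                       background = meth_bg))
  for (s in sexes) {
    studies[[paste0("consistent_hyper_", s)]] <-
      list(study = intersect(genes_of_sites(cons[[s]]$consistent_hyper, ann$genes), dm_bg),
           background = dm_bg)
    studies[[paste0("consistent_hypo_", s)]] <-
      list(study = intersect(genes_of_sites(cons[[s]]$consistent_hypo, ann$genes), dm_bg),
           background = dm_bg)
  }
  enr <- do.call(rbind, lapply(names(studies), function(nm) {
    st <- studies[[nm]]
    if (length(st$study) == 0L || length(st$background) == 0L) return(NULL)
    cbind(study_set = nm,
          hypergeometric_enrichment(st$study, st$background, ann$go,
                                    q_max = config$enrich_q))
  }))
  if (is.null(enr)) {
    enr <- data.frame(study_set = character(), term = character(),
                      k = integer(), K = integer(), n = integer(),
                      N = integer(), p = numeric(), q = numeric(),
                      significant = logical())
  }
  say("enrichment: %d significant term/set pairs", sum(enr$significant))
  wt(enr, out, "enrichment.tsv")

  manifest <- c(sprintf("methager_version\t%s",
                        as.character(utils::packageVersion("methager"))),
                vapply(setdiff(names(config), "design"), function(k)
                  sprintf("%s\t%s", k, paste(format(config[[k]]), collapse = ",")),
                  character(1)),
                "status\tcomplete")
  writeLines(manifest, file.path(out, "manifest.tsv"))
  writeLines(log_lines, file.path(out, "run_log.txt"))
  say("pipeline complete: outputs in %s", out)

  invisible(list(prep = prep, dmps = dmps, union_sites = union_sites,
                 gene_dm = gene_dm, consistent = cons, vmps = vmps,
                 entropies = entropies, entropy_model = emodel,
                 clock = clock, predictions = pred, evaluation = ev,
                 acceleration = accel, accel_test = wilcox,
                 enrichment = enr, annotations = ann))
}
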