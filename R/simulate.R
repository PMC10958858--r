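#' Simulation configuration for a synthetic ageing methylome
#'
#' Builds and validates the configuration of the beta-binomial methylome
#' simulator. The default design mirrors a pooled-individual WGBS ageing
#' study in an insect with a sparse methylome: 2 sexes x 3 timepoints
#' (day 0, 8, 16) x 3 replicates, a mostly unmethylated genome, and a 1%-style
#' unmethylated lambda spike for conversion-error estimation.
#'
#' Site classes and their beta-binomial models (mean `mu`, precision `phi`;
#' `shape1 = mu*phi`, `shape2 = (1-mu)*phi`):
#' \describe{
#'   \item{null_unmeth}{true methylation equals the conversion error
#'     (binomial at `conversion_error`).}
#'   \item{stable}{constant mid-range `mu`, precision `phi_stable`.}
#'   \item{dmp_hyper / dmp_hypo}{`logit(mu) = logit(base) +/- dmp_slope * age`;
#'     the default slope gives a day0 -> day16 difference of 0.30 on the
#'     proportion scale. Hyper sites start lowly methylated and gain,
#'     hypo sites start highly methylated and lose, so ageing moves both
#'     toward 0.5.}
#'   \item{vmp}{constant `mu`; precision interpolates linearly from
#'     `phi_young` at day 0 to `phi_old` at the oldest age (drift =
#'     pure precision loss).}
#'   \item{clock}{`mu = clip(base + clock_slope * age, 0.02, 0.98)` with high
#'     precision — a deterministic age signal plus small noise.}
#' }
#'
#' @param seed Integer master seed; every random draw derives from it.
#' @param design Data frame with columns `sex`, `age_days`, `n_replicates`.
#' @param n_null_unmethylated,n_stable_methylated,n_dmp_hyper,n_dmp_hypo,n_vmp,n_clock
#'   Site counts per class.
#' @param dmp_slope Age slope of the DMP logit-mean, logit units per day.
#' @param dmp_sexes Which sexes carry the DMP age trend (default both).
#' @param precision_schedule Named vector `c(phi_young=, phi_old=)` for VMP
#'   sites; must satisfy `phi_young > phi_old > 0`.
#' @param phi_stable,phi_clock Beta-binomial precision of stable/DMP sites
#'   and of clock sites.
#' @param clock_slope Clock mean trend, proportion per day.
#' @param coverage_mean,coverage_dispersion Negative-binomial coverage model
#'   (mean and size), truncated at 1.
#' @param conversion_error True bisulfite non-conversion rate, in (0, 0.05].
#' @param lambda_n_sites,lambda_coverage Unmethylated spike: number of CpGs
#'   on the `lambda` chromosome and their mean coverage.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       design = default_design(),
                       n_null_unmethylated = 20000,
                       n_stable_methylated = 2700,
                       n_dmp_hyper = 300,
                       n_dmp_hypo = 300,
                       n_vmp = 300,
                       n_clock = 40,
                       dmp_slope = (stats::qlogis(0.45) - stats::qlogis(0.15)) / 16,
                       dmp_sexes = c("F", "M"),
                       precision_schedule = c(phi_young = 80, phi_old = 10),
                       phi_stable = 100,
                       phi_clock = 200,
                       clock_slope = 0.02,
                       coverage_mean = 30,
                       coverage_dispersion = 15,
                       conversion_error = 0.005,
                       lambda_n_sites = 200,
                       lambda_coverage = 50) {
  cfg <- list(seed = as.integer(seed), design = design,
              n_null_unmethylated = n_null_unmethylated,
              n_stable_methylated = n_stable_methylated,
              n_dmp_hyper = n_dmp_hyper, n_dmp_hypo = n_dmp_hypo,
              n_vmp = n_vmp, n_clock = n_clock,
              dmp_slope = dmp_slope, dmp_sexes = dmp_sexes,
              precision_schedule = precision_schedule,
              phi_stable = phi_stable, phi_clock = phi_clock,
              clock_slope = clock_slope,
              coverage_mean = coverage_mean,
              coverage_dispersion = coverage_dispersion,
              conversion_error = conversion_error,
              lambda_n_sites = lambda_n_sites,
              lambda_coverage = lambda_coverage)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

#' @rdname sim_config
#' @export
default_design <- function() {
  expand.grid(sex = c("F", "M"), age_days = c(0L, 8L, 16L),
              stringsAsFactors = FALSE)[, 2:1] |>
    (\(d) data.frame(sex = d$sex, age_days = d$age_days, n_replicates = 3L))()
}

validate_sim_config <- function(cfg) {
  counts <- c(cfg$n_null_unmethylated, cfg$n_stable_methylated,
              cfg$n_dmp_hyper, cfg$n_dmp_hypo, cfg$n_vmp, cfg$n_clock,
              cfg$lambda_n_sites)
  if (any(counts < 0)) stop("site counts must be non-negative")
  if (!(cfg$conversion_error > 0 && cfg$conversion_error <= 0.05)) {
    stop("conversion_error must be in (0, 0.05]")
  }
  ps <- cfg$precision_schedule
  if (!(ps[["phi_young"]] > ps[["phi_old"]] && ps[["phi_old"]] > 0)) {
    stop("precision_schedule must satisfy phi_young > phi_old > 0")
  }
  if (cfg$coverage_mean <= 0) stop("coverage_mean must be positive")
  need <- c("sex", "age_days", "n_replicates")
  if (!all(need %in% names(cfg$design))) {
    stop("design needs columns sex, age_days, n_replicates")
  }
  if (any(cfg$design$n_replicates < 1)) stop("n_replicates must be >= 1")
  invisible(cfg)
}

sim_sample_sheet <- function(cfg, out_dir) {
  d <- cfg$design
  rows <- lapply(seq_len(nrow(d)), function(i) {
    data.frame(sample_id = sprintf("%s_d%d_r%d", d$sex[i], d$age_days[i],
                                   seq_len(d$n_replicates[i])),
               sex = d$sex[i], age_days = d$age_days[i],
               replicate = seq_len(d$n_replicates[i]),
               stringsAsFactors = FALSE)
  })
  sheet <- do.call(rbind, rows)
  sheet$path <- file.path(out_dir, paste0(sheet$sample_id, ".cov"))
  sheet
}

# Per-site reproducible substream: the draws of one site depend only on the
# master seed and the site's index, so changing one class's count never
# reshuffles another site's data.
site_substream_seed <- function(master, index) {
  as.integer((as.numeric(master) + 7919 * as.numeric(index)) %% 2147483629)
}

sim_truth_classes <- function(cfg) {
  classes <- c(rep("null_unmeth", cfg$n_null_unmethylated),
               rep("stable", cfg$n_stable_methylated),
               rep("dmp_hyper", cfg$n_dmp_hyper),
               rep("dmp_hypo", cfg$n_dmp_hypo),
               rep("vmp", cfg$n_vmp),
               rep("clock", cfg$n_clock))
  set.seed(cfg$seed)
  classes[sample.int(length(classes))]
}

#' Simulate a synthetic ageing-methylome experiment
#'
#' Generates per-sample CpG counts with the statistical structure the
#' downstream analyses assume (see [sim_config()]), writes one Bismark-style
#' coverage file per sample (main chromosome `chr1` plus the unmethylated
#' spike on chromosome `lambda`), a sample sheet and a ground-truth table.
#' Identical configurations (including the seed) produce byte-identical
#' files.
#'
#' @param cfg A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with `samples` (the sheet, including file
#'   paths), `truth` (per-site class and true parameters), `site_lists`
#'   (in-memory per-sample site data frames) and `paths`.
#' @export
simulate_experiment <- function(cfg, out_dir) {
  validate_sim_config(cfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  samples <- sim_sample_sheet(cfg, out_dir)
  n_samp <- nrow(samples)
  age <- samples$age_days
  sex <- samples$sex
  max_age <- max(cfg$design$age_days)

  classes <- sim_truth_classes(cfg)
  n_main <- length(classes)
  ps <- cfg$precision_schedule

  truth <- data.frame(site_key = site_key("chr1", seq_len(n_main) * 100L),
                      chrom = "chr1", pos = seq_len(n_main) * 100L,
                      class = classes,
                      mu_base = NA_real_, mu_slope = NA_real_,
                      phi_young = NA_real_, phi_old = NA_real_,
                      stringsAsFactors = FALSE)

  meth <- matrix(0L, n_main, n_samp)
  cov <- matrix(0L, n_main, n_samp)
  trend_sex <- sex %in% cfg$dmp_sexes

  for (i in seq_len(n_main)) {
    set.seed(site_substream_seed(cfg$seed, i))
    cl <- classes[i]
    cvg <- pmax(1L, stats::rnbinom(n_samp, size = cfg$coverage_dispersion,
                                   mu = cfg$coverage_mean))
    if (cl == "null_unmeth") {
      mu <- rep(cfg$conversion_error, n_samp)
      m <- stats::rbinom(n_samp, cvg, mu)
      truth$mu_base[i] <- cfg$conversion_error
      truth$mu_slope[i] <- 0
    } else if (cl == "stable") {
      base <- stats::runif(1, 0.2, 0.8)
      p <- stats::rbeta(n_samp, base * cfg$phi_stable, (1 - base) * cfg$phi_stable)
      m <- stats::rbinom(n_samp, cvg, p)
      truth$mu_base[i] <- base
      truth$mu_slope[i] <- 0
      truth$phi_young[i] <- truth$phi_old[i] <- cfg$phi_stable
    } else if (cl %in% c("dmp_hyper", "dmp_hypo")) {
      base <- if (cl == "dmp_hyper") stats::runif(1, 0.10, 0.20) else stats::runif(1, 0.80, 0.90)
      slope <- if (cl == "dmp_hyper") cfg$dmp_slope else -cfg$dmp_slope
      mu <- stats::plogis(stats::qlogis(base) + slope * age * trend_sex)
      p <- stats::rbeta(n_samp, mu * cfg$phi_stable, (1 - mu) * cfg$phi_stable)
      m <- stats::rbinom(n_samp, cvg, p)
      truth$mu_base[i] <- base
      truth$mu_slope[i] <- slope
      truth$phi_young[i] <- truth$phi_old[i] <- cfg$phi_stable
    } else if (cl == "vmp") {
      base <- stats::runif(1, 0.35, 0.65)
      phi <- ps[["phi_young"]] + (ps[["phi_old"]] - ps[["phi_young"]]) * age / max_age
      p <- stats::rbeta(n_samp, base * phi, (1 - base) * phi)
      m <- stats::rbinom(n_samp, cvg, p)
      truth$mu_base[i] <- base
      truth$mu_slope[i] <- 0
      truth$phi_young[i] <- ps[["phi_young"]]
      truth$phi_old[i] <- ps[["phi_old"]]
    } else { # clock
      base <- stats::runif(1, 0.10, 0.60)
      mu <- pmin(0.98, pmax(0.02, base + cfg$clock_slope * age))
      p <- stats::rbeta(n_samp, mu * cfg$phi_clock, (1 - mu) * cfg$phi_clock)
      m <- stats::rbinom(n_samp, cvg, p)
      truth$mu_base[i] <- base
      truth$mu_slope[i] <- cfg$clock_slope
      truth$phi_young[i] <- truth$phi_old[i] <- cfg$phi_clock
    }
    cov[i, ] <- cvg
    meth[i, ] <- m
  }

  # unmethylated lambda spike: separate chromosome in the same files
  n_lam <- cfg$lambda_n_sites
  lam_meth <- matrix(0L, n_lam, n_samp)
  lam_cov <- matrix(0L, n_lam, n_samp)
  for (j in seq_len(n_lam)) {
    set.seed(site_substream_seed(cfg$seed, n_main + j))
    cvg <- pmax(1L, stats::rnbinom(n_samp, size = cfg$coverage_dispersion,
                                   mu = cfg$lambda_coverage))
    lam_cov[j, ] <- cvg
    lam_meth[j, ] <- stats::rbinom(n_samp, cvg, cfg$conversion_error)
  }
  lam_truth <- data.frame(site_key = site_key("lambda", seq_len(n_lam) * 100L),
                          chrom = "lambda", pos = seq_len(n_lam) * 100L,
                          class = "lambda_spike",
                          mu_base = cfg$conversion_error, mu_slope = 0,
                          phi_young = NA_real_, phi_old = NA_real_,
                          stringsAsFactors = FALSE)
  truth <- rbind(truth, lam_truth)

  site_lists <- lapply(seq_len(n_samp), function(s) {
    data.frame(chrom = c(rep("chr1", n_main), rep("lambda", n_lam)),
               pos = c(seq_len(n_main) * 100L, seq_len(n_lam) * 100L),
               strand = "merged",
               meth = c(meth[, s], lam_meth[, s]),
               unmeth = c(cov[, s] - meth[, s], lam_cov[, s] - lam_meth[, s]),
               stringsAsFactors = FALSE)
  })
  for (s in seq_len(n_samp)) write_coverage_file(site_lists[[s]], samples$path[s])

  sheet_path <- file.path(out_dir, "samples.tsv")
  utils::write.table(samples, sheet_path, sep = "\t", quote = FALSE, row.names = FALSE)
  truth_path <- file.path(out_dir, "truth.tsv")
  write_truth(truth, truth_path)

  invisible(list(samples = samples, truth = truth, site_lists = site_lists,
                 paths = list(sample_sheet = sheet_path, truth = truth_path,
                              coverage = samples$path, dir = out_dir)))
}

#' Write / read the simulation ground-truth table
#'
#' Fixed schema `site_key, class, mu_params, phi_params`; the parameter
#' columns pack `base,slope` and `phi_young,phi_old` with full precision so
#' the round trip is lossless.
#'
#' @param truth Truth data frame from [simulate_experiment()].
#' @param path Output path.
#' @export
write_truth <- function(truth, path) {
  if (is.null(truth) || nrow(truth) == 0L) stop("empty truth table")
  num <- function(x) ifelse(is.na(x), "NA", format(x, digits = 17, trim = TRUE,
                                                   scientific = FALSE))
  out <- data.frame(site_key = truth$site_key, class = truth$class,
                    mu_params = paste(num(truth$mu_base), num(truth$mu_slope), sep = ","),
                    phi_params = paste(num(truth$phi_young), num(truth$phi_old), sep = ","),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  mu <- do.call(rbind, strsplit(tab$mu_params, ",", fixed = TRUE))
  phi <- do.call(rbind, strsplit(tab$phi_params, ",", fixed = TRUE))
  chrom_pos <- do.call(rbind, strsplit(tab$site_key, ":", fixed = TRUE))
  data.frame(site_key = tab$site_key,
             chrom = chrom_pos[, 1L], pos = as.integer(chrom_pos[, 2L]),
             class = tab$class,
             mu_base = suppressWarnings(as.numeric(mu[, 1L])),
             mu_slope = suppressWarnings(as.numeric(mu[, 2L])),
             phi_young = suppressWarnings(as.numeric(phi[, 1L])),
             phi_old = suppressWarnings(as.numeric(phi[, 2L])),
             stringsAsFactors = FALSE)
}

#' Simulate a gene annotation and GO map over the synthetic chromosome
#'
#' Tiles the simulated main chromosome with genes of `sites_per_gene`
#' consecutive CpGs each and assigns every gene 1-4 GO terms at random from a
#' synthetic vocabulary. One designed term (`GO:0009999`) is preferentially
#' attached to genes that contain hypermethylating DMP sites, giving the
#' enrichment stage a recoverable signal. Entirely synthetic: the identifiers
#' carry no biological meaning.
#'
#' @param truth Truth table from [simulate_experiment()].
#' @param out_dir Output directory.
#' @param seed Seed for the GO assignment.
#' @param sites_per_gene CpGs per gene (genes tile the chromosome).
#' @return Invisibly, list with `genes`, `go`, and file `paths` (GFF3 + TSV).
#' @export
simulate_annotation <- function(truth, out_dir, seed = 1, sites_per_gene = 10) {
  main <- truth[truth$chrom == "chr1", , drop = FALSE]
  n_main <- nrow(main)
  n_genes <- ceiling(n_main / sites_per_gene)
  gene_of_site <- ceiling(seq_len(n_main) / sites_per_gene)
  start <- (( seq_len(n_genes) - 1L) * sites_per_gene + 1L) * 100L - 50L
  end <- pmin(n_main, seq_len(n_genes) * sites_per_gene) * 100L + 50L
  genes <- data.frame(gene_id = sprintf("g%05d", seq_len(n_genes)),
                      chrom = "chr1", start = start, end = end,
                      strand = rep(c("+", "-"), length.out = n_genes),
                      stringsAsFactors = FALSE)
  set.seed(as.integer(seed) + 104729L)
  vocab <- sprintf("GO:%07d", 1:80)
  go_rows <- lapply(seq_len(n_genes), function(g) {
    data.frame(gene_id = genes$gene_id[g],
               go_id = sample(vocab, sample.int(4, 1)),
               stringsAsFactors = FALSE)
  })
  hyper_genes <- unique(gene_of_site[main$class == "dmp_hyper"])
  marked <- stats::runif(n_genes) < ifelse(seq_len(n_genes) %in% hyper_genes, 0.9, 0.05)
  go_tab <- rbind(do.call(rbind, go_rows),
                  data.frame(gene_id = genes$gene_id[marked], go_id = "GO:0009999",
                             stringsAsFactors = FALSE))
  go_tab <- go_tab[order(go_tab$gene_id, go_tab$go_id, method = "radix"), ]

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  gff_path <- file.path(out_dir, "genes.gff3")
  writeLines(c("##gff-version 3",
               sprintf("chr1\tmethager_sim\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       genes$start, genes$end, genes$strand, genes$gene_id)),
             gff_path)
  go_path <- file.path(out_dir, "go_map.tsv")
  utils::write.table(go_tab, go_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  go <- lapply(split(go_tab$go_id, go_tab$gene_id), unique)
  invisible(list(genes = genes, go = go,
                 paths = list(gff = gff_path, go = go_path)))
}
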