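test_that("identical config and seed give byte-identical outputs", {
  cfg <- small_sim_config(seed = 55)
  d1 <- file.path(tempdir(), "sim-det-1")
  d2 <- file.path(tempdir(), "sim-det-2")
  simulate_experiment(cfg, d1)
  simulate_experiment(cfg, d2)
  f1 <- sort(list.files(d1))
  expect_equal(f1, sort(list.files(d2)))
  for (f in setdiff(f1, "samples.tsv")) {  # sheet embeds the directory path
    expect_equal(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                 info = f)
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("truth table bookkeeping matches the configuration", {
  fx <- small_fixture()
  cfg <- small_sim_config()
  tab <- table(fx$sim$truth$class)
  expect_equal(unname(tab[["null_unmeth"]]), cfg$n_null_unmethylated)
  expect_equal(unname(tab[["stable"]]), cfg$n_stable_methylated)
  expect_equal(unname(tab[["dmp_hyper"]]), cfg$n_dmp_hyper)
  expect_equal(unname(tab[["dmp_hypo"]]), cfg$n_dmp_hypo)
  expect_equal(unname(tab[["vmp"]]), cfg$n_vmp)
  expect_equal(unname(tab[["clock"]]), cfg$n_clock)
  expect_equal(unname(tab[["lambda_spike"]]), cfg$lambda_n_sites)
})

test_that("default design yields 18 samples: 2 sexes x 3 ages x 3 replicates", {
  fx <- small_fixture()
  sheet <- fx$sim$samples
  expect_equal(nrow(sheet), 18L)
  expect_equal(as.integer(table(sheet$sex)), c(9L, 9L))
  expect_equal(sort(unique(sheet$age_days)), c(0L, 8L, 16L))
  expect_true(all(table(sheet$sex, sheet$age_days) == 3L))
})

test_that("counts respect coverage and the binomial law at null sites", {
  fx <- small_fixture()
  for (s in fx$sim$site_lists) {
    expect_true(all(s$meth >= 0 & s$unmeth >= 0))
  }
  # pooled null-site methylation within 3 binomial SE of the conversion error
  truth <- fx$sim$truth
  null_keys <- truth$site_key[truth$class == "null_unmeth"]
  pool_m <- 0; pool_c <- 0
  for (s in fx$sim$site_lists) {
    k <- paste(s$chrom, s$pos, sep = ":")
    sel <- k %in% null_keys
    pool_m <- pool_m + sum(s$meth[sel])
    pool_c <- pool_c + sum(s$meth[sel] + s$unmeth[sel])
  }
  p0 <- 0.005
  se <- sqrt(p0 * (1 - p0) / pool_c)
  expect_lt(abs(pool_m / pool_c - p0), 3 * se)
})

test_that("simulated files conform to the coverage dialect", {
  fx <- small_fixture()
  s <- read_coverage_file(fx$sim$samples$path[1])
  expect_equal(s[, c("chrom", "pos", "meth", "unmeth")],
               fx$sim$site_lists[[1]][, c("chrom", "pos", "meth", "unmeth")])
})

test_that("DMP sites carry an age trend of the configured sign (OLS oracle)", {
  fx <- small_fixture()
  truth <- fx$sim$truth
  sheet <- fx$sim$samples
  age <- sheet$age_days
  frac_of <- function(key) {
    vapply(fx$sim$site_lists, function(s) {
      i <- match(key, paste(s$chrom, s$pos, sep = ":"))
      s$meth[i] / (s$meth[i] + s$unmeth[i])
    }, numeric(1))
  }
  for (cls in c("dmp_hyper", "dmp_hypo")) {
    keys <- truth$site_key[truth$class == cls]
    slopes <- vapply(keys, function(k) coef(lm(frac_of(k) ~ age))[["age"]],
                     numeric(1))
    frac_ok <- if (cls == "dmp_hyper") mean(slopes > 0) else mean(slopes < 0)
    expect_gte(frac_ok, 0.95)
  }
})

test_that("VMP sites grow more variable with age (rank test, n >= 200 sites)", {
  fx <- small_fixture()
  truth <- fx$sim$truth
  sheet <- fx$sim$samples
  keys <- truth$site_key[truth$class == "vmp"]
  expect_gte(length(keys), 200L)
  var_by_age <- function(a) {
    cols <- which(sheet$age_days == a)
    vapply(keys, function(k) {
      f <- vapply(cols, function(j) {
        s <- fx$sim$site_lists[[j]]
        i <- match(k, paste(s$chrom, s$pos, sep = ":"))
        s$meth[i] / (s$meth[i] + s$unmeth[i])
      }, numeric(1))
      var(f)
    }, numeric(1))
  }
  v0 <- var_by_age(0); v16 <- var_by_age(16)
  ht <- wilcox.test(v16, v0, paired = TRUE, alternative = "greater")
  expect_lt(ht$p.value, 0.01)
})

test_that("truth tables round-trip losslessly and refuse empties", {
  fx <- small_fixture()
  f <- withr::local_tempfile()
  write_truth(fx$sim$truth, f)
  back <- read_truth(f)
  expect_equal(back$site_key, fx$sim$truth$site_key)
  expect_equal(back$class, fx$sim$truth$class)
  expect_equal(back$mu_base, fx$sim$truth$mu_base)
  expect_equal(back$mu_slope, fx$sim$truth$mu_slope)
  expect_equal(back$phi_young, fx$sim$truth$phi_young)
  expect_equal(names(read.delim(f, nrows = 1)),
               c("site_key", "class", "mu_params", "phi_params"))
  expect_error(write_truth(fx$sim$truth[0, ], f), "empty")
})

test_that("invalid configurations are rejected before any file is written", {
  expect_error(sim_config(conversion_error = 0), "conversion_error")
  expect_error(sim_config(conversion_error = 0.2), "conversion_error")
  expect_error(sim_config(precision_schedule = c(phi_young = 10, phi_old = 80)),
               "phi_young")
  expect_error(sim_config(n_vmp = -1), "non-negative")
  expect_error(sim_config(coverage_mean = 0), "coverage_mean")
})
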