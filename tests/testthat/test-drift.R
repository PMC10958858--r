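test_that("boundary transform is an order-preserving map into (0,1)", {
  y <- c(0, 0.2, 0.5, 0.7, 1)
  z <- boundary_transform(y, n = 10)
  expect_true(all(z > 0 & z < 1))
  expect_true(all(diff(z) > 0))
  expect_error(boundary_transform(c(-0.1, 0.5)), "\\[0, 1\\]")
})

test_that("beta regression recovers simulated coefficients", {
  set.seed(51)
  n <- 500
  age <- runif(n, 0, 16)
  mu <- plogis(-1 + 0.1 * age)
  y <- rbeta(n, mu * 30, (1 - mu) * 30)
  X <- cbind(`(Intercept)` = 1, age = age)
  fit <- fit_beta_regression(y, X)
  expect_true(fit$converged)
  expect_lt(abs(fit$coef[["(Intercept)"]] - (-1)), 3 * fit$se[["(Intercept)"]])
  expect_lt(abs(fit$coef[["age"]] - 0.1), 3 * fit$se[["age"]])
  expect_lt(abs(fit$phi - 30) / 30, 0.25)
  expect_true(all(fit$fitted > 0 & fit$fitted < 1))

  # constant response at 0.5: the logit-mean intercept collapses to 0
  f0 <- fit_beta_regression(rep(0.5, 20), matrix(1, 20, 1))
  expect_lt(abs(f0$coef[1]), 1e-6)

  expect_error(fit_beta_regression(y, cbind(1, age, age * 2)), "rank deficient")
  expect_error(fit_beta_regression(c(0, y[-1]), X), "strictly inside")
})

test_that("Breusch-Pagan statistic matches the explicit two-regression oracle", {
  x <- c(1, 2, 3, 4); y <- c(1, 2, 3, 10)
  # hand OLS: slope 2.8, intercept -3; squared residuals and auxiliary R^2
  e2 <- (y - (-3 + 2.8 * x))^2
  aux <- lm(e2 ~ x)
  r2 <- 1 - sum(resid(aux)^2) / sum((e2 - mean(e2))^2)
  bp <- breusch_pagan(y, cbind(1, x))
  expect_equal(bp$bp_stat, 4 * r2, tolerance = 1e-10)
  expect_equal(bp$bp_stat, 1.395, tolerance = 1e-3)
  expect_equal(bp$df, 1L)
  expect_equal(bp$p, 0.2375, tolerance = 1e-3)

  # zero residual variance
  bp0 <- breusch_pagan(2 * x + 1, cbind(1, x))
  expect_equal(bp0$bp_stat, 0)
  expect_equal(bp0$p, 1)
})

test_that("Breusch-Pagan agrees with the reference implementation", {
  set.seed(61)
  for (i in 1:50) {
    n <- sample(8:60, 1)
    x1 <- rnorm(n); x2 <- rnorm(n)
    y <- 1 + x1 - x2 + rnorm(n) * (1 + 0.4 * abs(x1))
    mine <- breusch_pagan(y, cbind(1, x1, x2))
    ref <- lmtest::bptest(y ~ x1 + x2)
    expect_equal(mine$bp_stat, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$p, unname(ref$p.value), tolerance = 1e-10)
    expect_equal(mine$df, unname(ref$parameter))
  }
})

test_that("Breusch-Pagan p-values are uniform under homoscedastic errors", {
  set.seed(71)
  n <- 200
  x <- rnorm(n)
  X <- cbind(1, x)
  ps <- replicate(1000, breusch_pagan(2 + x + rnorm(n), X)$p)
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("Holm adjustment follows the step-down rule and dominates Bonferroni", {
  holm_oracle <- function(p) {
    m <- length(p)
    o <- order(p)
    pmin(1, cummax((m - seq_len(m) + 1) * p[o]))[order(o)]
  }
  expect_equal(p.adjust(c(0.001, 0.02, 0.04), "holm"), c(0.003, 0.04, 0.04))
  set.seed(81)
  for (i in 1:20) {
    p <- runif(sample(3:50, 1))
    expect_equal(p.adjust(p, "holm"), holm_oracle(p), tolerance = 1e-12)
    expect_true(all(p.adjust(p, "holm") <= pmin(1, length(p) * p) + 1e-12))
  }
})

test_that("VMP screen separates drifting from stable sites", {
  fx <- small_fixture()
  mat <- fx$prep$methylated
  vm <- detect_vmps(mat)
  cls <- truth_classes(fx$sim$truth, mat)
  expect_equal(vm$site_key, rownames(mat$meth))
  tested <- !is.na(vm$p)
  expect_true(all(vm$p_holm[tested] >= vm$p[tested]))
  expect_true(all(vm$p_holm[tested] <= pmin(1, sum(tested) * vm$p[tested]) + 1e-12))
  # unadjusted heteroscedasticity evidence is stronger at true drift sites
  ht <- wilcox.test(vm$p[cls == "vmp" & tested], vm$p[cls == "stable" & tested],
                    alternative = "less")
  expect_lt(ht$p.value, 0.01)
  # family-wise error control: stable sites are almost never called
  expect_lte(mean(vm$is_vmp[cls == "stable"], na.rm = TRUE), 0.05)
})

test_that("entropy matches the normalized binary-entropy form exactly", {
  expect_equal(shannon_entropy(rep(0.5, 7)), 1.0)
  expect_equal(shannon_entropy(c(0, 1, 0, 1, 1)), 0.0)
  direct <- (0.25 * log(0.25) + 0.75 * log(0.75)) / log(0.5)
  expect_equal(shannon_entropy(0.25), direct, tolerance = 1e-12)
  expect_error(shannon_entropy(numeric()), "empty")
  expect_error(shannon_entropy(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("entropy is symmetric in MF vs 1-MF and maximal at one half", {
  set.seed(91)
  for (i in 1:10) {
    mf <- runif(20)
    expect_equal(shannon_entropy(mf), shannon_entropy(1 - mf), tolerance = 1e-12)
  }
  grid <- seq(0, 1, by = 0.01)
  vals <- vapply(grid, shannon_entropy, numeric(1))
  expect_equal(grid[which.max(vals)], 0.5)
  expect_true(all(vals >= 0 & vals <= 1))
})

test_that("per-sample entropy is deterministic over a fixed site set", {
  sheet <- make_samples(c("F", "F"), c(0L, 0L), 1:2)
  meth <- matrix(c(5L, 5L, 5L, 5L), 2, 2)
  cov <- matrix(10L, 2, 2)
  mat <- make_matrix(meth, cov, sheet)
  ent <- entropy_per_sample(mat, rownames(mat$meth))
  expect_equal(ent$entropy, c(1, 1))
  expect_equal(ent$n_sites, c(2L, 2L))
  expect_error(entropy_per_sample(mat, character()), "empty")
  expect_error(entropy_per_sample(mat, "chrX:1"), "not in matrix")
})

test_that("entropy ageing model detects a female-specific slope", {
  set.seed(103)
  sheet <- make_samples(rep(c("F", "M"), each = 9),
                        rep(rep(c(0L, 8L, 16L), each = 3), 2),
                        rep(1:3, 6))
  mu <- ifelse(sheet$sex == "F", plogis(-0.4 + 0.06 * sheet$age_days),
               plogis(-0.4))
  ent <- data.frame(sample_id = sheet$sample_id,
                    entropy = rbeta(18, mu * 400, (1 - mu) * 400),
                    n_sites = 100L)
  em <- entropy_age_model(ent, sheet)
  expect_lt(em$interaction_p, 0.05)
  ps <- em$per_sex
  expect_lt(ps$p[ps$sex == "F"], 0.05)
  expect_gt(ps$p[ps$sex == "M"], 0.05)
  expect_gt(ps$slope[ps$sex == "F"], 0)
})

test_that("a shared entropy-age relation rarely yields a spurious interaction", {
  set.seed(113)
  sheet <- make_samples(rep(c("F", "M"), each = 9),
                        rep(rep(c(0L, 8L, 16L), each = 3), 2),
                        rep(1:3, 6))
  mu <- plogis(-0.4 + 0.03 * sheet$age_days)
  hits <- 0L
  for (r in 1:20) {
    ent <- data.frame(sample_id = sheet$sample_id,
                      entropy = rbeta(18, mu * 150, (1 - mu) * 150),
                      n_sites = 100L)
    em <- entropy_age_model(ent, sheet)
    hits <- hits + (em$interaction_p < 0.05)
  }
  expect_lte(hits, 4L)  # ~alpha * 20 with binomial slack
})
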