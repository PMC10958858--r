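test_that("two-group deviance equals the grouped-binomial likelihood ratio", {
  # closed-form oracle: pooled vs per-group MLEs plugged into the likelihood
  lrt_oracle <- function(mA, cA, mB, cB) {
    ll <- function(m, c, p) sum(ifelse(m == 0, 0, m * log(p)) +
                                  ifelse(c - m == 0, 0, (c - m) * log(1 - p)))
    pA <- sum(mA) / sum(cA); pB <- sum(mB) / sum(cB)
    pp <- sum(mA + mB) / sum(cA + cB)
    2 * (ll(mA, cA, pA) + ll(mB, cB, pB) - ll(c(mA, mB), c(cA, cB), pp))
  }
  res <- dmp_test(c(2, 3), c(10, 10), c(8, 7), c(10, 10))
  expect_equal(res$delta, 0.5)
  expect_equal(res$deviance, lrt_oracle(c(2, 3), c(10, 10), c(8, 7), c(10, 10)),
               tolerance = 1e-10)
  expect_equal(res$deviance, 10.465, tolerance = 1e-4)
  expect_equal(res$p, 1.22e-3, tolerance = 0.01)

  # identical groups
  res0 <- dmp_test(c(5, 5), c(10, 10), c(5, 5), c(10, 10))
  expect_equal(res0$delta, 0)
  expect_equal(res0$deviance, 0)
  expect_equal(res0$p, 1)

  # maximal separation
  res1 <- dmp_test(c(0, 0), c(30, 30), c(30, 30), c(30, 30))
  expect_equal(res1$delta, 1)
  expect_lt(res1$p, 1e-10)
})

test_that("deviance matches a binomial glm on random instances", {
  set.seed(41)
  for (i in 1:30) {
    nA <- sample(2:4, 1); nB <- sample(2:4, 1)
    cA <- sample(5:20, nA, replace = TRUE)
    cB <- sample(5:20, nB, replace = TRUE)
    mA <- rbinom(nA, cA, runif(1, 0.05, 0.95))
    mB <- rbinom(nB, cB, runif(1, 0.05, 0.95))
    mine <- dmp_test(mA, cA, mB, cB)
    grp <- factor(c(rep("A", nA), rep("B", nB)))
    m <- c(mA, mB); cc <- c(cA, cB)
    g1 <- glm(cbind(m, cc - m) ~ grp, family = binomial)
    g0 <- glm(cbind(m, cc - m) ~ 1, family = binomial)
    expect_equal(mine$deviance, g0$deviance - g1$deviance, tolerance = 1e-8)
    # antisymmetry
    swap <- dmp_test(mB, cB, mA, cA)
    expect_equal(swap$delta, -mine$delta)
    expect_equal(swap$p, mine$p, tolerance = 1e-12)
  }
})

test_that("DMP status applies strict q and delta thresholds", {
  sheet <- make_samples(rep("F", 6), rep(c(0L, 16L), each = 3), rep(1:3, 2))
  # site 1: delta exactly 0.15 -> ns despite tiny p; site 2: delta 0.25 ->
  # hyper; site 3: null
  meth <- rbind(c(60, 60, 60, 105, 105, 105),
                c(60, 60, 60, 135, 135, 135),
                c(90, 90, 90, 90, 90, 90))
  cov <- matrix(300L, 3, 6)
  mat <- make_matrix(meth, cov, sheet)
  dmps <- call_dmps(mat, comparisons = data.frame(sex = "F", ageA = 0, ageB = 16))
  expect_equal(dmps$delta, c(0.15, 0.25, 0))
  expect_lt(dmps$q[1], 0.05)
  expect_equal(dmps$status, c("ns", "hyper", "ns"))

  expect_error(call_dmps(mat, comparisons = data.frame(sex = "M", ageA = 0, ageB = 16)),
               "unknown")
})

test_that("consistency classification requires the same direction twice", {
  mk <- function(site, cmp, status)
    data.frame(site_key = site, comparison = cmp, sex = "M",
               ageA = NA, ageB = NA, status = status,
               stringsAsFactors = FALSE)
  dmps <- rbind(mk("s1", "M_d0_vs_d8", "hyper"), mk("s1", "M_d8_vs_d16", "hyper"),
                mk("s2", "M_d0_vs_d8", "hyper"), mk("s2", "M_d8_vs_d16", "hypo"),
                mk("s3", "M_d0_vs_d8", "hypo"), mk("s3", "M_d8_vs_d16", "hypo"),
                mk("s4", "M_d0_vs_d8", "ns"), mk("s4", "M_d8_vs_d16", "hyper"))
  cl <- classify_consistent(dmps, "M", ages = c(0, 8, 16))
  expect_equal(cl$consistent_hyper, "s1")
  expect_equal(cl$consistent_hypo, "s3")
  expect_setequal(cl$other, c("s2", "s4"))
  expect_length(intersect(cl$consistent_hyper, cl$consistent_hypo), 0)
  expect_error(classify_consistent(dmps[dmps$comparison == "M_d0_vs_d8", ],
                                   "M", ages = c(0, 8, 16)), "missing")
})

test_that("weighted methylation is the pooled count ratio", {
  expect_equal(weighted_methylation(c(3, 7), c(10, 10)), 0.5)
  expect_equal(weighted_methylation(0, 10), 0)
  expect_true(is.na(weighted_methylation(c(0, 0), c(0, 0))))
})

test_that("gene-level calls need two DMPs and a 15% weighted difference", {
  sheet <- make_samples(rep("F", 6), rep(c(0L, 16L), each = 3), rep(1:3, 2))
  # gene A (2 sites, both strong DMPs, weighted delta 0.30), gene B (2 sites,
  # one DMP diluted by a flat site -> weighted delta ~0.1), gene C (1 DMP)
  meth <- rbind(c(30, 30, 30, 120, 120, 120),
                c(30, 30, 30, 120, 120, 120),
                c(30, 30, 30, 150, 150, 150),
                c(150, 150, 150, 90, 90, 90),
                c(30, 30, 30, 150, 150, 150))
  cov <- matrix(300L, 5, 6)
  mat <- make_matrix(meth, cov, sheet, pos = c(10L, 20L, 110L, 120L, 210L))
  genes <- data.frame(gene_id = c("gA", "gB", "gC"), chrom = "chr1",
                      start = c(5L, 105L, 205L), end = c(25L, 125L, 215L),
                      strand = "+")
  dmps <- call_dmps(mat, comparisons = data.frame(sex = "F", ageA = 0, ageB = 16))
  gdm <- gene_level_dm(dmps, genes, mat)
  expect_equal(gdm$status[gdm$gene_id == "gA"], "dm")
  expect_equal(gdm$n_dm_cpgs[gdm$gene_id == "gA"], 2L)
  expect_equal(gdm$weighted_delta[gdm$gene_id == "gA"], 0.3, tolerance = 1e-12)
  expect_equal(gdm$status[gdm$gene_id == "gB"], "ns")
  expect_equal(gdm$status[gdm$gene_id == "gC"], "ns")
})

test_that("null DMP rate on stable sites stays below the nominal level", {
  fx <- small_fixture()
  dmps <- call_dmps(fx$prep$methylated)
  cls <- truth_classes(fx$sim$truth, fx$prep$methylated)
  stable <- dmps$site_key %in% rownames(fx$prep$methylated$meth)[cls == "stable"]
  fpr <- mean(dmps$status[stable] != "ns")
  n <- sum(stable)
  expect_lte(fpr, 0.05 + 2 * sqrt(0.05 * 0.95 / n))
})
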