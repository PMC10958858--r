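stranded <- function(chrom, pos, strand, meth, unmeth) {
  data.frame(chrom = chrom, pos = pos, strand = strand,
             meth = meth, unmeth = unmeth, stringsAsFactors = FALSE)
}

test_that("strand merging pools CpG pairs and re-homes singletons", {
  s <- stranded("chr1", c(100L, 101L, 300L, 501L),
                c("+", "-", "+", "-"),
                c(3L, 2L, 1L, 0L), c(7L, 3L, 7L, 9L))
  m <- merge_strands(s)
  expect_equal(m$pos, c(100L, 300L, 500L))
  expect_equal(m$meth[m$pos == 100L], 5L)
  expect_equal(m$meth[m$pos == 100L] + m$unmeth[m$pos == 100L], 15L)
  expect_equal(m$meth[m$pos == 300L], 1L)
  expect_equal(m$unmeth[m$pos == 500L], 9L)
  expect_true(all(m$strand == "merged"))

  expect_error(merge_strands(m), "skip merging")
})

test_that("strand merging conserves total counts on random inputs", {
  set.seed(21)
  for (i in 1:20) {
    pos_plus <- sort(sample(seq(2L, 400L, 2L), 30))
    has_minus <- runif(30) < 0.6
    lone_minus <- sort(sample(seq(501L, 999L, 2L), 5))
    s <- rbind(
      stranded("chrZ", pos_plus, "+", rpois(30, 3), rpois(30, 9)),
      stranded("chrZ", pos_plus[has_minus] + 1L, "-",
               rpois(sum(has_minus), 3), rpois(sum(has_minus), 9)),
      stranded("chrZ", lone_minus, "-", rpois(5, 3), rpois(5, 9)))
    m <- merge_strands(s)
    expect_equal(sum(m$meth), sum(s$meth))
    expect_equal(sum(m$meth + m$unmeth), sum(s$meth + s$unmeth))
    expect_false(any(duplicated(m$pos)))
  }
})

test_that("conversion error is the pooled spike rate, floored when zero", {
  lam <- stranded("lambda", 1:10 * 10L, "merged", rep(5L, 10), rep(995L, 10))
  expect_equal(estimate_conversion_error(lam)$rate, 0.005)
  lam0 <- stranded("lambda", 1:10 * 10L, "merged", rep(0L, 10), rep(1000L, 10))
  expect_equal(estimate_conversion_error(lam0)$rate, 0.5 / 10000)
  expect_error(estimate_conversion_error(lam[0, ]), "zero total")
})

test_that("coverage filter enforces the floor and the upper percentile", {
  s <- stranded("chr1", 1:3 * 10L, "merged", c(1L, 2L, 2L), c(8L, 8L, 8L))
  # coverages 9, 10, 10: the floor removes the first, the percentile none
  out <- filter_by_coverage(s)
  expect_equal(out$pos, c(20L, 30L))

  # 100 sites at coverage 10 plus one at 10000: the outlier exceeds the
  # type-7 99th percentile and is removed
  s2 <- stranded("chr1", 1:101 * 10L, "merged",
                 rep(0L, 101), c(rep(10L, 100), 10000L))
  hi <- quantile(c(rep(10, 100), 10000), 0.99, type = 7, names = FALSE)
  out2 <- filter_by_coverage(s2)
  expect_false(10010L %in% out2$pos)
  expect_equal(nrow(out2), sum(c(rep(10, 100), 10000) <= hi))

  expect_error(filter_by_coverage(s, min_cov = 0), "min_cov")
})

test_that("median normalization scales counts half-up and preserves order", {
  sheet <- make_samples(c("F", "F"), c(0L, 0L), 1:2)
  meth <- matrix(c(5L, 2L, 1L, 6L), 2, 2)
  cov <- matrix(c(15L, 25L, 30L, 50L), 2, 2)  # medians 20 and 40
  mat <- make_matrix(meth, cov, sheet)
  nm <- normalize_coverage(mat)
  # sample 1 scaled by 2, sample 2 untouched
  expect_equal(unname(nm$meth[, 1]), c(10L, 4L))
  expect_equal(unname(nm$cov[, 1]), c(30L, 50L))
  expect_equal(nm$meth[, 2], mat$meth[, 2])
  expect_true(all(nm$meth <= nm$cov))

  eq <- make_matrix(meth, matrix(c(15L, 25L, 15L, 25L), 2, 2), sheet)
  expect_equal(normalize_coverage(eq)$cov, eq$cov)
})

test_that("binomial methylation calls match the exact tail probabilities", {
  sheet <- make_samples(c("F", "F"), c(0L, 0L), 1:2)
  meth <- matrix(c(0L, 3L, 20L, 1L), 2, 2)
  cov <- matrix(20L, 2, 2)
  mat <- make_matrix(meth, cov, sheet)
  calls <- call_methylated(mat, 0.005)
  tail_oracle <- function(k, n, p) sum(dbinom(k:n, n, p))
  expect_equal(calls$p[1, 1], 1.0)
  expect_equal(calls$p[2, 1], tail_oracle(3, 20, 0.005), tolerance = 1e-12)
  expect_lt(abs(calls$p[2, 1] - 1.3e-4) / 1.3e-4, 0.05)
  expect_equal(calls$p[1, 2], 0.005^20, tolerance = 1e-12)
  expect_true(calls$methylated[1, 2])
  expect_true(calls$methylated_in_any[["chr1:10"]])
  expect_true(all(calls$q >= calls$p))
})

test_that("BH adjustment matches the brute-force step-up oracle", {
  bh_oracle <- function(p) {
    m <- length(p)
    o <- order(p)
    q <- p[o] * m / seq_len(m)
    q <- rev(cummin(rev(q)))
    pmin(1, q)[order(o)]
  }
  set.seed(31)
  for (i in 1:20) {
    p <- runif(sample(5:60, 1))^sample(1:3, 1)
    expect_equal(p.adjust(p, "BH"), bh_oracle(p), tolerance = 1e-12)
  }
  # monotone after sorting
  p <- runif(100)
  q <- p.adjust(p, "BH")
  expect_true(all(diff(q[order(p)]) >= -1e-15))
})

test_that("preprocessing keeps nearly all truly methylated sites and few null sites", {
  fx <- small_fixture()
  cls <- truth_classes(fx$sim$truth, fx$prep$matrix)
  flagged <- fx$prep$calls$methylated_in_any
  # >= 99% of stable sites (mu >= 0.2) are recognized as methylated
  expect_gte(mean(flagged[cls == "stable"]), 0.99)
  # conversion error recovered from the spike
  expect_lt(abs(fx$prep$conversion$rate - 0.005), 0.002)
  # sites methylated in >= 1 sample are exactly the downstream matrix rows
  expect_equal(rownames(fx$prep$methylated$meth), names(which(flagged)))
})
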