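xlogy <- function(x, y) ifelse(x == 0, 0, x * log(y))

binom_loglik <- function(meth, cov, p) {
  # grouped binomial log-likelihood, constants dropped (they cancel in LRTs)
  sum(xlogy(meth, p) + xlogy(cov - meth, 1 - p))
}

#' Per-CpG two-group logistic-regression test
#'
#' Likelihood-ratio test of a binomial logistic regression of methylated
#' counts on the group indicator, with replicates as independent binomial
#' observations. Because the only covariate is the group, the MLEs are the
#' pooled within-group proportions and the deviance has closed form:
#' `2 * (l(p_A, p_B) - l(p_pooled))`, referred to chi-square with 1 df. The
#' effect size `delta` is the pooled-fraction difference `B - A`.
#'
#' Vectorized over sites: pass matrices (sites x replicates) to test many
#' CpGs at once.
#'
#' @param methA,covA Methylated counts and coverages of group A (vector =
#'   one site, or sites x replicates matrix).
#' @param methB,covB Same for group B.
#' @return Data frame with `delta`, `deviance`, `p` (one row per site).
#' @export
dmp_test <- function(methA, covA, methB, covB) {
  as_mat <- function(x) if (is.matrix(x)) x else matrix(x, nrow = 1L)
  methA <- as_mat(methA); covA <- as_mat(covA)
  methB <- as_mat(methB); covB <- as_mat(covB)
  if (ncol(methA) < 2L || ncol(methB) < 2L) stop("need >= 2 samples per group")
  if (any(covA <= 0) || any(covB <= 0)) stop("all coverages must be positive")
  mA <- rowSums(methA); cA <- rowSums(covA)
  mB <- rowSums(methB); cB <- rowSums(covB)
  if (any(cA == 0) || any(cB == 0)) stop("group with zero total coverage")
  pA <- mA / cA
  pB <- mB / cB
  pp <- (mA + mB) / (cA + cB)
  ll <- function(m, c, p) xlogy(m, p) + xlogy(c - m, 1 - p)
  dev <- 2 * (ll(mA, cA, pA) + ll(mB, cB, pB) - ll(mA, cA, pp) - ll(mB, cB, pp))
  dev <- pmax(dev, 0)
  data.frame(delta = pB - pA, deviance = dev,
             p = stats::pchisq(dev, df = 1, lower.tail = FALSE))
}

#' All pairwise age comparisons within each sex
#'
#' @param ages Vector of distinct ages (default taken from a sheet).
#' @param sexes Sexes to compare within.
#' @return Data frame `sex, ageA, ageB` with `ageA < ageB`, all pairs.
#' @export
age_comparisons <- function(ages, sexes = c("F", "M")) {
  ages <- sort(unique(ages))
  pairs <- utils::combn(ages, 2)
  do.call(rbind, lapply(sexes, function(s) {
    data.frame(sex = s, ageA = pairs[1, ], ageB = pairs[2, ],
               stringsAsFactors = FALSE)
  }))
}

comparison_label <- function(sex, ageA, ageB) {
  sprintf("%s_d%d_vs_d%d", sex, ageA, ageB)
}

#' Call differentially methylated positions
#'
#' Runs [dmp_test()] per site for every requested within-sex age comparison,
#' BH-adjusts p-values within each comparison, and classifies each site:
#' `hyper` if `q < q_max` and `delta > min_delta`, `hypo` if `q < q_max` and
#' `delta < -min_delta` (strict inequalities), else `ns`.
#'
#' @param mat `meth_matrix` restricted to methylated sites.
#' @param comparisons Data frame `sex, ageA, ageB`; default all age pairs in
#'   both sexes.
#' @param q_max q-value threshold (default 0.05).
#' @param min_delta Minimum methylation difference (default 0.15; the call
#'   requires `|delta|` strictly greater).
#' @return Data frame of class `dmp_result`: `site_key, comparison, sex,
#'   ageA, ageB, delta, deviance, p, q, status`.
#' @export
call_dmps <- function(mat, comparisons = NULL, q_max = 0.05, min_delta = 0.15) {
  sheet <- mat$samples
  if (is.null(comparisons)) {
    comparisons <- age_comparisons(sheet$age_days, unique(sheet$sex))
  }
  bad <- !(comparisons$sex %in% sheet$sex) |
    !(comparisons$ageA %in% sheet$age_days) |
    !(comparisons$ageB %in% sheet$age_days)
  if (any(bad)) {
    stop("comparison refers to unknown sex or age: ",
         comparison_label(comparisons$sex[bad][1],
                          comparisons$ageA[bad][1], comparisons$ageB[bad][1]))
  }
  res <- lapply(seq_len(nrow(comparisons)), function(i) {
    cmp <- comparisons[i, ]
    a <- which(sheet$sex == cmp$sex & sheet$age_days == cmp$ageA)
    b <- which(sheet$sex == cmp$sex & sheet$age_days == cmp$ageB)
    if (length(a) < 2L || length(b) < 2L) {
      stop("comparison ", comparison_label(cmp$sex, cmp$ageA, cmp$ageB),
           " needs >= 2 replicates per side")
    }
    tst <- dmp_test(mat$meth[, a, drop = FALSE], mat$cov[, a, drop = FALSE],
                    mat$meth[, b, drop = FALSE], mat$cov[, b, drop = FALSE])
    tst$q <- stats::p.adjust(tst$p, method = "BH")
    data.frame(site_key = rownames(mat$meth),
               comparison = comparison_label(cmp$sex, cmp$ageA, cmp$ageB),
               sex = cmp$sex, ageA = cmp$ageA, ageB = cmp$ageB,
               tst, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$status <- ifelse(out$q < q_max & out$delta > min_delta, "hyper",
                       ifelse(out$q < q_max & out$delta < -min_delta, "hypo", "ns"))
  rownames(out) <- NULL
  class(out) <- c("dmp_result", class(out))
  out
}

#' Sites significant in at least one comparison
#'
#' @param dmps [call_dmps()] output.
#' @return Character vector of site keys with status `hyper` or `hypo` in
#'   any comparison — the "age-significant" CpG set used for entropy and the
#'   clock.
#' @export
dmp_union_sites <- function(dmps) {
  sort(unique(dmps$site_key[dmps$status != "ns"]))
}

#' Consistent direction across successive comparisons
#'
#' Partitions one sex's sites by direction consistency over the two
#' successive comparisons (youngest vs middle, middle vs oldest):
#' `consistent_hyper` = significantly hyper in both, `consistent_hypo` =
#' significantly hypo in both; the two sets are disjoint by construction.
#'
#' @param dmps [call_dmps()] output containing both successive comparisons
#'   for `sex`.
#' @param sex Sex to classify.
#' @param ages The three ordered ages (default from the results).
#' @return List with `consistent_hyper`, `consistent_hypo`, `other` (site
#'   key vectors).
#' @export
classify_consistent <- function(dmps, sex, ages = NULL) {
  d <- dmps[dmps$sex == sex, , drop = FALSE]
  if (is.null(ages)) ages <- sort(unique(c(d$ageA, d$ageB)))
  if (length(ages) < 3L) stop("need three timepoints for consistency classification")
  lab1 <- comparison_label(sex, ages[1], ages[2])
  lab2 <- comparison_label(sex, ages[2], ages[3])
  c1 <- d[d$comparison == lab1, , drop = FALSE]
  c2 <- d[d$comparison == lab2, , drop = FALSE]
  if (nrow(c1) == 0L || nrow(c2) == 0L) {
    stop("missing successive comparison for sex ", sex)
  }
  s2 <- c2$status[match(c1$site_key, c2$site_key)]
  hyper <- c1$site_key[c1$status == "hyper" & !is.na(s2) & s2 == "hyper"]
  hypo <- c1$site_key[c1$status == "hypo" & !is.na(s2) & s2 == "hypo"]
  all_sites <- unique(c(c1$site_key, c2$site_key))
  list(consistent_hyper = hyper, consistent_hypo = hypo,
       other = setdiff(all_sites, c(hyper, hypo)))
}

#' Weighted methylation level of a region
#'
#' Total methylated cytosines within the region divided by the region's
#' total coverage — a coverage-weighted regional methylation summary. With
#' zero total coverage the level is undefined and `NA` is returned.
#'
#' @param meth,cov Count vectors/matrices over the region's CpGs (and the
#'   relevant samples).
#' @return A proportion, or `NA` when total coverage is 0.
#' @export
weighted_methylation <- function(meth, cov) {
  tot <- sum(as.numeric(cov))
  if (tot == 0) return(NA_real_)
  sum(as.numeric(meth)) / tot
}

assign_sites_to_genes <- function(sites, genes) {
  # CpGs overlapping several genes are counted in each
  lapply(seq_len(nrow(genes)), function(g) {
    which(sites$chrom == genes$chrom[g] &
            sites$pos >= genes$start[g] & sites$pos <= genes$end[g])
  })
}

#' Gene-level differential methylation
#'
#' A gene is differentially methylated for a comparison when it contains at
#' least two significant DMPs and the weighted methylation difference across
#' the entire feature (all its analysed CpGs, each group's replicates
#' pooled) is at least `min_delta` in absolute value.
#'
#' @param dmps [call_dmps()] output.
#' @param genes Gene feature data frame (`gene_id, chrom, start, end,
#'   strand`).
#' @param mat The `meth_matrix` the DMPs were called on.
#' @param min_delta Weighted-difference threshold (default 0.15).
#' @param min_dm_cpgs Minimum significant CpGs in the feature (default 2).
#' @return Data frame `gene_id, comparison, n_cpgs, n_dm_cpgs,
#'   weighted_meth_A, weighted_meth_B, weighted_delta, status`.
#' @export
gene_level_dm <- function(dmps, genes, mat, min_delta = 0.15, min_dm_cpgs = 2) {
  sheet <- mat$samples
  gene_sites <- assign_sites_to_genes(mat$sites, genes)
  keys <- rownames(mat$meth)
  comps <- unique(dmps[, c("comparison", "sex", "ageA", "ageB")])
  rows <- list()
  for (ci in seq_len(nrow(comps))) {
    cmp <- comps[ci, ]
    a <- which(sheet$sex == cmp$sex & sheet$age_days == cmp$ageA)
    b <- which(sheet$sex == cmp$sex & sheet$age_days == cmp$ageB)
    d <- dmps[dmps$comparison == cmp$comparison, , drop = FALSE]
    sig <- d$site_key[d$status != "ns"]
    for (g in seq_len(nrow(genes))) {
      idx <- gene_sites[[g]]
      if (length(idx) == 0L) next
      wmA <- weighted_methylation(mat$meth[idx, a], mat$cov[idx, a])
      wmB <- weighted_methylation(mat$meth[idx, b], mat$cov[idx, b])
      n_dm <- sum(keys[idx] %in% sig)
      wd <- wmB - wmA
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = genes$gene_id[g], comparison = cmp$comparison,
        n_cpgs = length(idx), n_dm_cpgs = n_dm,
        weighted_meth_A = wmA, weighted_meth_B = wmB, weighted_delta = wd,
        status = if (!is.na(wd) && n_dm >= min_dm_cpgs && abs(wd) >= min_delta)
          "dm" else "ns",
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fixed-effects summary of weighted methylation by sex and age
#'
#' Inspection table: per sex x age group, the weighted methylation level
#' over all analysed CpGs (replicates pooled), with a per-group CpG count.
#'
#' @param mat A `meth_matrix` (typically the methylated-site matrix).
#' @return Data frame `sex, age_days, n_samples, weighted_methylation`.
#' @export
weighted_methylation_summary <- function(mat) {
  sheet <- mat$samples
  groups <- unique(sheet[, c("sex", "age_days")])
  groups <- groups[order(groups$sex, groups$age_days), ]
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    idx <- which(sheet$sex == groups$sex[i] & sheet$age_days == groups$age_days[i])
    data.frame(sex = groups$sex[i], age_days = groups$age_days[i],
               n_samples = length(idx),
               weighted_methylation =
                 weighted_methylation(mat$meth[, idx], mat$cov[, idx]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
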