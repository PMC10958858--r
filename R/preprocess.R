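#' Pool top- and bottom-strand cytosines into single CpGs
#'
#' Destranding: a plus-strand C at position `p` and a minus-strand C at
#' `p + 1` belong to one CpG; their counts are summed and reported at the
#' plus-strand position `p`. Unpaired sites pass through re-labelled
#' `merged` at their plus-strand-equivalent coordinate (a minus-strand
#' singleton at `p` is reported at `p - 1`). Total methylated and total
#' coverage are conserved exactly.
#'
#' @param sites One sample's site data frame with strands `+`/`-`.
#' @return Merged site data frame, sorted and unique, strand `"merged"`.
#' @export
merge_strands <- function(sites) {
  if (any(sites$strand == "merged")) {
    stop("input already strand-collapsed ('merged'); skip merging")
  }
  if (!all(sites$strand %in% c("+", "-"))) stop("strands must be '+' or '-'")
  plus <- sites[sites$strand == "+", , drop = FALSE]
  minus <- sites[sites$strand == "-", , drop = FALSE]
  # minus-strand C at p pairs with plus-strand C at p - 1
  minus_home <- minus$pos - 1L
  pk <- site_key(plus$chrom, plus$pos)
  mk <- site_key(minus$chrom, minus_home)
  idx <- match(mk, pk)
  paired <- !is.na(idx)

  out_meth <- plus$meth
  out_unmeth <- plus$unmeth
  out_meth[idx[paired]] <- out_meth[idx[paired]] + minus$meth[paired]
  out_unmeth[idx[paired]] <- out_unmeth[idx[paired]] + minus$unmeth[paired]

  merged <- data.frame(chrom = c(plus$chrom, minus$chrom[!paired]),
                       pos = c(plus$pos, minus_home[!paired]),
                       strand = "merged",
                       meth = c(out_meth, minus$meth[!paired]),
                       unmeth = c(out_unmeth, minus$unmeth[!paired]),
                       stringsAsFactors = FALSE)
  if (anyDuplicated(site_key(merged$chrom, merged$pos))) {
    stop("duplicate merged CpG positions; input may mix collapsed and stranded sites")
  }
  merged[order(merged$chrom, merged$pos, method = "radix"), , drop = FALSE] |>
    (\(d) { rownames(d) <- NULL; d })()
}

#' Estimate the bisulfite non-conversion error from the lambda spike
#'
#' Any apparent methylation on the unmethylated spike genome is conversion
#' failure; the rate is total methylated over total coverage across all spike
#' CpGs (pooled over samples if several are supplied). A zero estimate is
#' floored at half a pseudo-count (`0.5 / total coverage`) so the binomial
#' null is non-degenerate.
#'
#' @param lambda_sites Site data frame(s) from the spike chromosome.
#' @return List of class `conversion_error` with `rate` and `total_coverage`.
#' @export
estimate_conversion_error <- function(lambda_sites) {
  if (is.data.frame(lambda_sites)) lambda_sites <- list(lambda_sites)
  meth <- sum(vapply(lambda_sites, function(s) sum(as.numeric(s$meth)), numeric(1)))
  covg <- meth + sum(vapply(lambda_sites, function(s) sum(as.numeric(s$unmeth)), numeric(1)))
  if (length(lambda_sites) == 0L || covg == 0) {
    stop("cannot estimate conversion error: zero total spike coverage")
  }
  rate <- meth / covg
  if (rate == 0) rate <- 0.5 / covg
  structure(list(rate = rate, total_coverage = covg), class = "conversion_error")
}

#' Per-sample coverage filter
#'
#' Removes sites with coverage below `min_cov` and sites whose coverage
#' strictly exceeds the sample's empirical `upper_percentile` of the
#' pre-filter coverage distribution (linear-interpolation percentile,
#' quantile type 7). Guards the per-CpG models against low-information sites
#' and collapsed repeats / PCR stacks.
#'
#' @param sites One sample's site data frame.
#' @param min_cov Minimum coverage retained (default 10).
#' @param upper_percentile Upper percentile cut (default 99).
#' @return Filtered site data frame.
#' @export
filter_by_coverage <- function(sites, min_cov = 10, upper_percentile = 99) {
  if (min_cov < 1) stop("min_cov must be >= 1")
  covg <- sites$meth + sites$unmeth
  hi <- stats::quantile(covg, upper_percentile / 100, type = 7, names = FALSE)
  keep <- covg >= min_cov & covg <= hi
  out <- sites[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

round_half_up <- function(x) floor(x + 0.5)

#' Median-based coverage normalization
#'
#' Scales each sample's counts by `f_s = max(medians) / median_s` (sample
#' median coverage), rounding half-up to integers, so sample coverage depths
#' are comparable. `meth <= cov` is preserved because both count components
#' are scaled by the same factor.
#'
#' @param mat A united `meth_matrix`.
#' @return The normalized `meth_matrix`.
#' @export
normalize_coverage <- function(mat) {
  meds <- apply(mat$cov, 2, function(x) stats::median(x[x > 0]))
  if (any(colSums(mat$cov) == 0)) stop("sample with all-zero coverage")
  f <- max(meds) / meds
  unmeth <- mat$cov - mat$meth
  new_meth <- round_half_up(sweep(mat$meth, 2, f, `*`))
  new_unmeth <- round_half_up(sweep(unmeth, 2, f, `*`))
  mat$meth <- new_meth
  mat$cov <- new_meth + new_unmeth
  storage.mode(mat$meth) <- "integer"
  storage.mode(mat$cov) <- "integer"
  mat
}

#' Call methylated CpGs by a binomial test against the conversion error
#'
#' For every site x sample cell, tests whether the methylated count exceeds
#' what bisulfite non-conversion alone would produce: one-sided upper-tail
#' exact binomial p = P(X >= meth | n = coverage, p0 = error rate). BH
#' adjustment is applied jointly across all tested cells; a cell is
#' methylated when `q < fdr`, and a site is `methylated_in_any` when any
#' sample's cell is. Downstream analyses use only those sites — in a sparse
#' insect methylome the overwhelming majority of CpGs carry no methylation.
#'
#' @param mat A united, filtered (optionally normalized) `meth_matrix`.
#' @param err A `conversion_error` object (or a bare rate in (0,1)).
#' @param fdr FDR threshold (default 0.05).
#' @return List of class `meth_callset` with matrices `p`, `q`,
#'   `methylated`, and vector `methylated_in_any` (named by site key).
#' @export
call_methylated <- function(mat, err, fdr = 0.05) {
  rate <- if (inherits(err, "conversion_error")) err$rate else err
  if (!(rate > 0 && rate < 1)) stop("conversion error rate must be in (0,1)")
  if (any(mat$cov == 0)) stop("coverage-0 cell in united matrix; unite with require_all")
  p <- stats::pbinom(mat$meth - 1L, mat$cov, rate, lower.tail = FALSE)
  q <- matrix(stats::p.adjust(p, method = "BH"), nrow(p), ncol(p),
              dimnames = dimnames(p))
  methylated <- q < fdr
  structure(list(p = p, q = q, methylated = methylated,
                 methylated_in_any = apply(methylated, 1, any),
                 fdr = fdr, rate = rate),
            class = "meth_callset")
}

#' Preprocess per-sample site lists into the analysis-ready matrix
#'
#' The full path from raw per-CpG counts to the methylated-CpG analysis set:
#' split off the spike chromosome and estimate the conversion error, filter
#' each sample by coverage, unite across samples (all-sample intersection),
#' median-normalize coverage, and run the binomial methylation caller.
#'
#' @param site_lists Per-sample site data frames (strand-collapsed), in
#'   sample sheet order.
#' @param samples Sample sheet data frame.
#' @param lambda_chrom Name of the spike chromosome (default `"lambda"`).
#' @param min_cov,upper_percentile Coverage filter, see
#'   [filter_by_coverage()].
#' @param fdr Methylation-call FDR, see [call_methylated()].
#' @param normalize Median-normalize coverage? Default `TRUE`.
#' @return List with `matrix` (all retained sites), `methylated` (the
#'   `meth_matrix` restricted to sites methylated in >= 1 sample), `calls`,
#'   `conversion`, and filtering `counts` (audit trail of sites in/out).
#' @export
preprocess_samples <- function(site_lists, samples, lambda_chrom = "lambda",
                               min_cov = 10, upper_percentile = 99,
                               fdr = 0.05, normalize = TRUE) {
  lam <- lapply(site_lists, function(s) s[s$chrom == lambda_chrom, , drop = FALSE])
  main <- lapply(site_lists, function(s) s[s$chrom != lambda_chrom, , drop = FALSE])
  conv <- estimate_conversion_error(lam)
  n_before <- vapply(main, nrow, integer(1))
  filtered <- lapply(main, filter_by_coverage, min_cov = min_cov,
                     upper_percentile = upper_percentile)
  n_after <- vapply(filtered, nrow, integer(1))
  mat <- unite(filtered, samples, require_all = TRUE)
  if (normalize) mat <- normalize_coverage(mat)
  calls <- call_methylated(mat, conv, fdr = fdr)
  meth_mat <- subset_sites(mat, names(which(calls$methylated_in_any)))
  list(matrix = mat, methylated = meth_mat, calls = calls, conversion = conv,
       counts = data.frame(sample_id = samples$sample_id,
                           sites_in = n_before, sites_kept = n_after),
       n_united = nrow(mat$sites),
       n_methylated = nrow(meth_mat$sites))
}
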