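#' Methylated-gene background
#'
#' A gene counts as methylated when its weighted methylation level —
#' `sum(meth)/sum(cov)` over the gene's CpGs per replicate, averaged across
#' the replicates of a sex x age group — strictly exceeds `threshold`
#' (default 0.05, the spike-derived cutoff) in at least one group. Genes
#' with no covered CpGs in the matrix are excluded with a warning.
#'
#' @param mat A united `meth_matrix`.
#' @param genes Gene feature data frame.
#' @param threshold Weighted-methylation cutoff (strict `>`).
#' @return Character vector of methylated gene ids.
#' @export
methylated_background <- function(mat, genes, threshold = 0.05) {
  sheet <- mat$samples
  groups <- unique(sheet[, c("sex", "age_days")])
  gene_sites <- assign_sites_to_genes(mat$sites, genes)
  covered <- lengths(gene_sites) > 0L
  if (any(!covered)) {
    warning(sum(!covered), " gene(s) with no covered CpGs excluded from background")
  }
  keep <- vapply(which(covered), function(g) {
    idx <- gene_sites[[g]]
    for (i in seq_len(nrow(groups))) {
      cols <- which(sheet$sex == groups$sex[i] & sheet$age_days == groups$age_days[i])
      wm <- vapply(cols, function(s)
        weighted_methylation(mat$meth[idx, s], mat$cov[idx, s]), numeric(1))
      if (mean(wm, na.rm = TRUE) > threshold) return(TRUE)
    }
    FALSE
  }, logical(1))
  genes$gene_id[which(covered)[keep]]
}

#' Genes overlapped by a set of CpG sites
#'
#' @param site_keys Character `chrom:pos` keys.
#' @param genes Gene feature data frame.
#' @return Character vector of gene ids containing >= 1 of the sites.
#' @export
genes_of_sites <- function(site_keys, genes) {
  if (length(site_keys) == 0L) return(character())
  parts <- do.call(rbind, strsplit(site_keys, ":", fixed = TRUE))
  sites <- data.frame(chrom = parts[, 1L], pos = as.integer(parts[, 2L]),
                      stringsAsFactors = FALSE)
  hit <- lengths(assign_sites_to_genes(sites, genes)) > 0L
  genes$gene_id[hit]
}

#' Hypergeometric GO-term over-representation
#'
#' For each term annotating at least one universe gene, tests whether the
#' study set contains more term-annotated genes than expected under
#' hypergeometric sampling from the universe: `p = P(X >= k)` for
#' `X ~ Hypergeometric(N, K, n)`, BH-adjusted across terms. The universe is
#' the background restricted to genes with at least one GO annotation —
#' unannotated genes carry no information for the model.
#'
#' @param study Character vector of study gene ids; must be a subset of
#'   `background`.
#' @param background Character vector of background gene ids.
#' @param go Named list mapping gene id to character vector of terms.
#' @param q_max Significance threshold on the BH-adjusted p (default 0.05).
#' @return Data frame `term, k, K, n, N, p, q, significant`, ordered by p.
#' @export
hypergeometric_enrichment <- function(study, background, go, q_max = 0.05) {
  study <- unique(study)
  background <- unique(background)
  stray <- setdiff(study, background)
  if (length(stray) > 0L) {
    stop("study genes outside the background: ", paste(stray, collapse = ", "))
  }
  universe <- intersect(background, names(go)[lengths(go) > 0L])
  study_u <- intersect(study, universe)
  N <- length(universe)
  n <- length(study_u)
  term_genes <- split(rep(universe, lengths(go[universe])), unlist(go[universe]))
  terms <- names(term_genes)
  K <- lengths(term_genes)
  k <- vapply(term_genes, function(g) sum(g %in% study_u), integer(1))
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  out <- data.frame(term = terms, k = k, K = K, n = n, N = N, p = p,
                    row.names = NULL, stringsAsFactors = FALSE)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$q < q_max
  out[order(out$p, out$term, method = "radix"), , drop = FALSE] |>
    (\(d) { rownames(d) <- NULL; d })()
}
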