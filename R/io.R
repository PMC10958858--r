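#' Read a Bismark coverage file
#'
#' Parses the 6-column Bismark coverage dialect
#' (`chrom, start, end, %methylation, count_methylated, count_unmethylated`).
#' Coverage files are strand-collapsed by convention, so every site is
#' returned with strand `"merged"`. The percentage column is ignored in
#' favour of the raw counts. Coordinates are 1-based; `start` is taken as the
#' position (files with `start == end` are the norm).
#'
#' @param path Path to a tab-separated coverage file.
#' @return A data frame of CpG sites with columns `chrom`, `pos`, `strand`,
#'   `meth`, `unmeth`. Zero rows for an empty file.
#' @export
read_coverage_file <- function(path) {
  if (!file.exists(path)) stop("coverage file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(empty_sites())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != 6L)
  if (length(bad) > 0L) {
    stop(sprintf("malformed coverage line %d: expected 6 tab-separated columns, got %d",
                 bad[1L], nf[bad[1L]]))
  }
  m <- matrix(unlist(fields), ncol = 6L, byrow = TRUE)
  pos <- parse_int_col(m[, 2L], "position", path_hint = "coverage")
  meth <- parse_int_col(m[, 5L], "methylated count", path_hint = "coverage")
  unmeth <- parse_int_col(m[, 6L], "unmethylated count", path_hint = "coverage")
  if (any(pos < 1L)) stop("malformed coverage line ", which(pos < 1L)[1L], ": position < 1")
  if (any(meth < 0L) || any(unmeth < 0L)) {
    stop("malformed coverage line ",
         which(meth < 0L | unmeth < 0L)[1L], ": negative count")
  }
  data.frame(chrom = m[, 1L], pos = pos, strand = "merged",
             meth = meth, unmeth = unmeth, stringsAsFactors = FALSE)
}

empty_sites <- function() {
  data.frame(chrom = character(), pos = integer(), strand = character(),
             meth = integer(), unmeth = integer(), stringsAsFactors = FALSE)
}

parse_int_col <- function(x, what, path_hint = "") {
  suppressWarnings(v <- as.numeric(x))
  bad <- which(is.na(v) | v != floor(v))
  if (length(bad) > 0L) {
    stop(sprintf("parse error at line %d: non-integer %s '%s'",
                 bad[1L], what, x[bad[1L]]))
  }
  as.integer(v)
}

#' Write a Bismark coverage file
#'
#' Inverse of [read_coverage_file()]: counts round-trip exactly. The
#' percentage column is recomputed from the counts (blank when coverage is 0).
#'
#' @param sites Data frame of CpG sites (`chrom`, `pos`, `meth`, `unmeth`).
#' @param path Output path.
#' @export
write_coverage_file <- function(sites, path) {
  cov <- sites$meth + sites$unmeth
  pct <- ifelse(cov > 0, 100 * sites$meth / cov, 0)
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%d",
                   sites$chrom, sites$pos, sites$pos,
                   format(pct, trim = TRUE, scientific = FALSE),
                   sites$meth, sites$unmeth)
  writeLines(lines, path)
  invisible(path)
}

#' Read a Bismark cytosine report
#'
#' Parses the 7-column per-cytosine report
#' (`chrom, pos, strand, count_methylated, count_unmethylated, context,
#' trinucleotide`), keeping only rows whose context matches
#' `context_filter`. Strand is preserved as read; use [merge_strands()] to
#' destrand.
#'
#' @param path Path to the report.
#' @param context_filter Context to retain (default `"CpG"`).
#' @return Data frame of CpG sites as in [read_coverage_file()], with strand
#'   `"+"` or `"-"`.
#' @export
read_cytosine_report <- function(path, context_filter = "CpG") {
  if (!file.exists(path)) stop("cytosine report not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(empty_sites())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != 7L)
  if (length(bad) > 0L) {
    stop(sprintf("malformed report line %d: expected 7 columns, got %d",
                 bad[1L], nf[bad[1L]]))
  }
  m <- matrix(unlist(fields), ncol = 7L, byrow = TRUE)
  strand <- m[, 3L]
  bad_strand <- which(!strand %in% c("+", "-"))
  if (length(bad_strand) > 0L) {
    stop(sprintf("parse error at line %d: unknown strand symbol '%s'",
                 bad_strand[1L], strand[bad_strand[1L]]))
  }
  keep <- m[, 6L] == context_filter
  m <- m[keep, , drop = FALSE]
  if (nrow(m) == 0L) return(empty_sites())
  data.frame(chrom = m[, 1L],
             pos = parse_int_col(m[, 2L], "position"),
             strand = m[, 3L],
             meth = parse_int_col(m[, 4L], "methylated count"),
             unmeth = parse_int_col(m[, 5L], "unmethylated count"),
             stringsAsFactors = FALSE)
}

#' Read a sample sheet
#'
#' Tab-separated with header columns `sample_id`, `sex`, `age_days`,
#' `replicate`, `path`. Sample ids must be unique; sex must be `F` or `M`.
#'
#' @param path Path to the sheet.
#' @return Data frame of sample records.
#' @export
read_sample_sheet <- function(path) {
  sheet <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("sample_id", "sex", "age_days", "replicate", "path")
  missing <- setdiff(required, names(sheet))
  if (length(missing) > 0L) {
    stop("sample sheet missing columns: ", paste(missing, collapse = ", "))
  }
  validate_samples(sheet)
  sheet
}

validate_samples <- function(samples) {
  if (anyDuplicated(samples$sample_id)) {
    stop("duplicated sample_id in sample sheet: ",
         samples$sample_id[duplicated(samples$sample_id)][1L])
  }
  if (!all(samples$sex %in% c("F", "M"))) stop("sex must be 'F' or 'M'")
  if (any(samples$age_days < 0)) stop("age_days must be non-negative")
  invisible(samples)
}

site_key <- function(chrom, pos) paste(chrom, pos, sep = ":")

#' Unite per-sample CpG site lists into a methylation matrix
#'
#' Merges one site list per sample into a single sites x samples count
#' matrix, the common currency of all downstream statistics. With
#' `require_all = TRUE` (the default; the per-CpG models need every library
#' observed) only sites present in every sample are kept; otherwise the union
#' is kept with coverage 0 where a sample lacks the site. Rows are sorted by
#' (chrom, pos) using C-locale string order, so the ordering is deterministic
#' for any input order.
#'
#' @param site_lists List of site data frames, one per sample, in sample
#'   sheet order.
#' @param samples Sample sheet data frame.
#' @param require_all Keep only sites observed in all samples?
#' @return An object of class `meth_matrix`: a list with `sites` (data frame
#'   `chrom`, `pos`), `samples`, and integer matrices `meth` and `cov`
#'   (dimnames: site key x sample_id).
#' @export
unite <- function(site_lists, samples, require_all = TRUE) {
  validate_samples(samples)
  if (length(site_lists) != nrow(samples)) {
    stop("need exactly one site list per sample")
  }
  keys <- vector("list", length(site_lists))
  for (i in seq_along(site_lists)) {
    k <- site_key(site_lists[[i]]$chrom, site_lists[[i]]$pos)
    dup <- which(duplicated(k))
    if (length(dup) > 0L) {
      stop(sprintf("duplicate site %s within sample %s",
                   k[dup[1L]], samples$sample_id[i]))
    }
    keys[[i]] <- k
  }
  if (require_all) {
    all_keys <- Reduce(intersect, keys)
  } else {
    all_keys <- unique(unlist(keys))
  }
  # reconstruct chrom/pos from the surviving keys of the first occurrence
  lookup <- do.call(rbind, lapply(site_lists, function(s) {
    data.frame(chrom = s$chrom, pos = s$pos, stringsAsFactors = FALSE)
  }))
  lookup <- lookup[!duplicated(site_key(lookup$chrom, lookup$pos)), , drop = FALSE]
  lookup <- lookup[match(all_keys, site_key(lookup$chrom, lookup$pos)), , drop = FALSE]
  ord <- order(lookup$chrom, lookup$pos, method = "radix")
  sites <- lookup[ord, , drop = FALSE]
  rownames(sites) <- NULL
  skeys <- site_key(sites$chrom, sites$pos)

  n_sites <- nrow(sites)
  n_samp <- nrow(samples)
  meth <- matrix(0L, n_sites, n_samp, dimnames = list(skeys, samples$sample_id))
  cov <- matrix(0L, n_sites, n_samp, dimnames = list(skeys, samples$sample_id))
  for (i in seq_along(site_lists)) {
    s <- site_lists[[i]]
    idx <- match(site_key(s$chrom, s$pos), skeys)
    keep <- !is.na(idx)
    meth[idx[keep], i] <- s$meth[keep]
    cov[idx[keep], i] <- s$meth[keep] + s$unmeth[keep]
  }
  structure(list(sites = sites, samples = samples, meth = meth, cov = cov),
            class = "meth_matrix")
}

#' @exportS3Method base::print
print.meth_matrix <- function(x, ...) {
  cat(sprintf("meth_matrix: %d sites x %d samples\n", nrow(x$sites), nrow(x$samples)))
  invisible(x)
}

#' Subset a methylation matrix by site keys
#'
#' @param mat A `meth_matrix`.
#' @param keys Character vector of `chrom:pos` keys to keep (order preserved
#'   from the matrix, not from `keys`).
#' @return A `meth_matrix` restricted to those sites.
#' @export
subset_sites <- function(mat, keys) {
  keep <- rownames(mat$meth) %in% keys
  structure(list(sites = mat$sites[keep, , drop = FALSE],
                 samples = mat$samples,
                 meth = mat$meth[keep, , drop = FALSE],
                 cov = mat$cov[keep, , drop = FALSE]),
            class = "meth_matrix")
}

#' Methylation fractions of a matrix
#'
#' @param mat A `meth_matrix` with all coverages positive.
#' @return Numeric sites x samples matrix of `meth / cov`.
#' @export
meth_fractions <- function(mat) {
  if (any(mat$cov == 0)) stop("methylation fraction undefined at coverage 0")
  mat$meth / mat$cov
}

#' Write / read a united matrix as TSV
#'
#' Long-free wide layout: `chrom`, `pos`, then `meth.<sample>` and
#' `cov.<sample>` per sample. Sample metadata travels in the sample sheet.
#'
#' @param mat A `meth_matrix`.
#' @param path Output path.
#' @export
write_matrix_tsv <- function(mat, path) {
  out <- cbind(mat$sites,
               as.data.frame(mat$meth) |> stats::setNames(paste0("meth.", colnames(mat$meth))),
               as.data.frame(mat$cov) |> stats::setNames(paste0("cov.", colnames(mat$cov))))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @param samples Sample sheet data frame matching the stored columns.
#' @export
read_matrix_tsv <- function(path, samples) {
  validate_samples(samples)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  sites <- tab[, c("chrom", "pos")]
  skeys <- site_key(sites$chrom, sites$pos)
  meth <- as.matrix(tab[, paste0("meth.", samples$sample_id), drop = FALSE])
  cov <- as.matrix(tab[, paste0("cov.", samples$sample_id), drop = FALSE])
  dimnames(meth) <- dimnames(cov) <- list(skeys, samples$sample_id)
  structure(list(sites = sites, samples = samples,
                 meth = meth, cov = cov),
            class = "meth_matrix")
}

#' Read gene annotation and GO map
#'
#' Gene features come from a GFF3 file (records of type `gene`; the `ID`
#' attribute is the gene id) or from a 1-based inclusive BED-like TSV with
#' header `gene_id, chrom, start, end, strand`. The GO map is a 2-column TSV
#' (`gene_id`, `go_id`), aggregated to one set of terms per gene.
#'
#' @param gff_path Gene annotation path (`.gff3`/`.gff` or TSV).
#' @param go_path GO map TSV path.
#' @return List with `genes` (data frame `gene_id`, `chrom`, `start`, `end`,
#'   `strand`) and `go` (named list: gene id -> character vector of terms).
#' @export
read_annotations <- function(gff_path, go_path) {
  genes <- if (grepl("\\.gff3?$", gff_path, ignore.case = TRUE)) {
    read_gff_genes(gff_path)
  } else {
    g <- utils::read.delim(gff_path, stringsAsFactors = FALSE)
    need <- c("gene_id", "chrom", "start", "end", "strand")
    if (!all(need %in% names(g))) {
      stop("gene TSV must have columns: ", paste(need, collapse = ", "))
    }
    g[, need]
  }
  if (any(is.na(genes$gene_id)) || any(!nzchar(genes$gene_id))) {
    stop("gene record with missing gene identifier")
  }
  if (any(genes$start > genes$end)) {
    stop("gene with start > end: ", genes$gene_id[which(genes$start > genes$end)[1L]])
  }
  go_tab <- utils::read.delim(go_path, header = FALSE, stringsAsFactors = FALSE,
                              col.names = c("gene_id", "go_id"))
  if (any(!nzchar(go_tab$go_id))) stop("empty GO term identifier in GO map")
  go <- split(go_tab$go_id, go_tab$gene_id)
  go <- lapply(go, unique)
  list(genes = genes, go = go)
}

read_gff_genes <- function(path) {
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    gr <- as.data.frame(rtracklayer::import(path))
    gr <- gr[gr$type == "gene", , drop = FALSE]
    if (is.null(gr$ID)) stop("GFF3 gene records lack an ID attribute")
    data.frame(gene_id = as.character(gr$ID),
               chrom = as.character(gr$seqnames),
               start = gr$start,
               end = gr$end,
               strand = as.character(gr$strand),
               stringsAsFactors = FALSE)
  } else {
    # minimal fallback for environments without rtracklayer
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
    f <- strsplit(lines, "\t", fixed = TRUE)
    f <- f[vapply(f, function(x) length(x) == 9L && x[3L] == "gene", logical(1))]
    if (length(f) == 0L) {
      return(data.frame(gene_id = character(), chrom = character(),
                        start = integer(), end = integer(),
                        strand = character(), stringsAsFactors = FALSE))
    }
    ids <- vapply(f, function(x) {
      m <- regmatches(x[9L], regexpr("ID=[^;]+", x[9L]))
      if (length(m) == 0L) stop("GFF3 gene record lacks an ID attribute")
      sub("^ID=", "", m)
    }, character(1))
    data.frame(gene_id = ids,
               chrom = vapply(f, `[`, character(1), 1L),
               start = as.integer(vapply(f, `[`, character(1), 4L)),
               end = as.integer(vapply(f, `[`, character(1), 5L)),
               strand = vapply(f, `[`, character(1), 7L),
               stringsAsFactors = FALSE)
  }
}
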