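#' Genes overlapping consensus regions
#'
#' Any-overlap (at least 1 bp, closed-interval arithmetic) between regions
#' and gene intervals: a gene starting at `end + 1` does not overlap.
#' Unsorted gene tables are sorted internally.
#'
#' @param regions data.frame with `chrom`, `start_bp`, `end_bp` (a
#'   `consensus_regions` object fits).
#' @param genes data.frame with `chrom`, `start`, `end`, `gene_id`.
#' @return data.frame pairing each region with each overlapping gene
#'   (`chrom`, `start_bp`, `end_bp`, `gene_id`); the deduplicated gene list
#'   is attached as attribute `gene_list`.
#' @export
genes_in_regions <- function(regions, genes) {
  for (col in c("chrom", "start", "end", "gene_id"))
    assert_that(col %in% names(genes), "genes lacks column '%s'", col)
  genes <- genes[order(factor(genes$chrom, unique(genes$chrom)), genes$start), ,
                 drop = FALSE]
  out <- list()
  for (chrom in unique(regions$chrom)) {
    rr <- regions[regions$chrom == chrom, , drop = FALSE]
    gg <- genes[genes$chrom == chrom, , drop = FALSE]
    if (nrow(rr) == 0L || nrow(gg) == 0L) next
    hits <- IRanges::findOverlaps(as_iranges(rr$start_bp, rr$end_bp),
                                  as_iranges(gg$start, gg$end))
    if (length(hits) == 0L) next
    out[[length(out) + 1L]] <- data.frame(
      chrom = chrom,
      start_bp = rr$start_bp[S4Vectors::queryHits(hits)],
      end_bp = rr$end_bp[S4Vectors::queryHits(hits)],
      gene_id = gg$gene_id[S4Vectors::subjectHits(hits)],
      stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), start_bp = integer(), end_bp = integer(),
               gene_id = character(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "gene_list") <- unique(res$gene_id)
  res
}

#' Hypergeometric gene-set enrichment (Fisher and EASE)
#'
#' For each gene set, tests over-representation of `gene_list` against
#' `background_genes` with the one-sided Fisher exact test: with `k` list
#' genes in the set, `K` background genes in the set, a list of size `n`
#' and a background of size `N`, `fisher_p = P(X >= k)` for
#' `X ~ Hypergeometric(K, N - K, n)`.  The EASE score is the same tail
#' probability with one success removed (`P(X >= k - 1)`), defined as 1
#' when `k <= 1` — a conservative variant that penalizes categories
#' supported by a single gene.  Rows with `ease_p` at or below
#' `ease_threshold` (default 0.1) are flagged enriched.
#'
#' @param gene_list character vector of genes of interest (must be a subset
#'   of the background).
#' @param background_genes character vector, the annotation universe.
#' @param gene_sets data.frame with `set_id`, `gene_id`.
#' @param ease_threshold flagging threshold on the EASE score.
#' @param p_adjust apply Benjamini-Hochberg to `fisher_p` and `ease_p`
#'   (off by default; raw EASE scores are the conventional report).
#' @return data.frame: `set_id`, `k`, `K`, `n`, `N`, `fisher_p`, `ease_p`,
#'   `enriched` (and `fisher_fdr`, `ease_fdr` when `p_adjust`).
#' @export
enrichment <- function(gene_list, background_genes, gene_sets,
                       ease_threshold = 0.1, p_adjust = FALSE) {
  background_genes <- unique(background_genes)
  gene_list <- unique(gene_list)
  assert_that(length(background_genes) > 0, "background gene list is empty")
  assert_that(all(gene_list %in% background_genes),
              "gene_list must be a subset of background_genes")
  for (col in c("set_id", "gene_id"))
    assert_that(col %in% names(gene_sets), "gene_sets lacks column '%s'", col)
  N <- length(background_genes)
  n <- length(gene_list)
  sets <- split(unique(gene_sets[c("set_id", "gene_id")])$gene_id,
                unique(gene_sets[c("set_id", "gene_id")])$set_id)
  rows <- lapply(names(sets), function(id) {
    members <- intersect(sets[[id]], background_genes)
    K <- length(members)
    k <- length(intersect(members, gene_list))
    # P(X >= k) with X ~ Hypergeom(K successes, N-K failures, n draws)
    fisher_p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    ease_p <- if (k <= 1) 1 else stats::phyper(k - 2, K, N - K, n, lower.tail = FALSE)
    data.frame(set_id = id, k = k, K = K, n = n, N = N,
               fisher_p = fisher_p, ease_p = ease_p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (p_adjust) {
    out$fisher_fdr <- stats::p.adjust(out$fisher_p, "BH")
    out$ease_fdr <- stats::p.adjust(out$ease_p, "BH")
  }
  out$enriched <- out$ease_p <= ease_threshold
  rownames(out) <- NULL
  out
}
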