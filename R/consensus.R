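#' Group consensus ROH regions
#'
#' Computes, at base-pair resolution, the maximal genomic intervals covered
#' by a ROH in at least `min_support` members of a group.  Support is the
#' number of group members with a ROH covering every bp of the interval
#' (the minimum per-bp coverage within it).  Group members without any
#' segment contribute zero coverage (with a warning).
#'
#' @param segments a `roh_segments` data.frame ([call_roh()]); segments of
#'   one sample must not overlap.
#' @param group_ids sample ids forming the group.
#' @param min_support integer, or `"all"` for the full group size.
#' @return data.frame of class `consensus_regions`: `chrom`, `start_bp`,
#'   `end_bp`, `support`, `breed_specific` (all `FALSE` here).
#' @export
consensus_regions <- function(segments, group_ids, min_support = "all") {
  if (identical(min_support, "all")) min_support <- length(group_ids)
  min_support <- as.integer(min_support)
  assert_that(min_support >= 1, "min_support must be >= 1")
  absent <- setdiff(group_ids, unique(segments$sample_id))
  if (length(absent))
    warning(sprintf("group sample(s) without any ROH: %s",
                    paste(absent, collapse = ", ")))
  seg <- segments[segments$sample_id %in% group_ids, , drop = FALSE]
  out <- list()
  for (chrom in unique(seg$chrom)) {
    sc <- seg[seg$chrom == chrom, , drop = FALSE]
    # one reduced range set per sample guarantees 0/1 coverage per member
    per_sample <- lapply(split(sc, sc$sample_id), function(d)
      IRanges::reduce(as_iranges(d$start_bp, d$end_bp)))
    w <- max(sc$end_bp) + 1L
    cov <- Reduce(`+`, lapply(per_sample, IRanges::coverage, width = w))
    sl <- IRanges::slice(cov, lower = min_support)
    if (length(sl) == 0L) next
    out[[length(out) + 1L]] <- data.frame(
      chrom = chrom,
      start_bp = IRanges::start(sl), end_bp = IRanges::end(sl),
      support = as.integer(IRanges::viewMins(sl)),
      breed_specific = FALSE, stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), start_bp = integer(), end_bp = integer(),
               support = integer(), breed_specific = logical(),
               stringsAsFactors = FALSE)
  res <- res[order(factor(res$chrom, unique(segments$chrom)), res$start_bp), ,
             drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("consensus_regions", "data.frame")
  res
}

#' Restrict consensus regions to breed-specific ones
#'
#' Removes from each consensus region every base covered by a ROH in at
#' least `max_support_excluded` members of the excluded comparison group
#' (crossbreeds).  With the whole-genome rule any single crossbreed ROH
#' removes the overlapped bases (`max_support_excluded = 1`); the chip rule
#' uses 5.  Fragments shorter than `min_fragment_bp` are dropped; survivors
#' are flagged `breed_specific`.  With `drop_whole_region = TRUE` a region
#' overlapping excluded-group support is removed entirely instead of being
#' fragmented.
#'
#' @param consensus output of [consensus_regions()].
#' @param excluded_segments `roh_segments` of the excluded group.
#' @param max_support_excluded excluded-member support at which a base is
#'   removed.
#' @param min_fragment_bp minimum surviving fragment length (default 1000,
#'   avoiding sliver artifacts after subtraction).
#' @param drop_whole_region remove whole regions instead of fragments.
#' @return a `consensus_regions` data.frame with `breed_specific = TRUE`.
#' @export
breed_specific_filter <- function(consensus, excluded_segments,
                                  max_support_excluded = 1,
                                  min_fragment_bp = 1000,
                                  drop_whole_region = FALSE) {
  assert_that(max_support_excluded >= 1, "max_support_excluded must be >= 1")
  out <- list()
  for (chrom in unique(consensus$chrom)) {
    cc <- consensus[consensus$chrom == chrom, , drop = FALSE]
    ec <- excluded_segments[excluded_segments$chrom == chrom, , drop = FALSE]
    bad <- if (nrow(ec)) {
      per_sample <- lapply(split(ec, ec$sample_id), function(d)
        IRanges::reduce(as_iranges(d$start_bp, d$end_bp)))
      w <- max(ec$end_bp) + 1L
      cov <- Reduce(`+`, lapply(per_sample, IRanges::coverage, width = w))
      sl <- IRanges::slice(cov, lower = max_support_excluded)
      as_iranges(IRanges::start(sl), IRanges::end(sl))
    } else IRanges::IRanges()
    for (r in seq_len(nrow(cc))) {
      reg <- as_iranges(cc$start_bp[r], cc$end_bp[r])
      hit <- IRanges::intersect(reg, bad)
      keep <- if (drop_whole_region && length(hit) > 0) IRanges::IRanges()
              else IRanges::setdiff(reg, bad)
      keep <- keep[IRanges::width(keep) >= min_fragment_bp]
      if (length(keep) == 0L) next
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom, start_bp = IRanges::start(keep),
        end_bp = IRanges::end(keep), support = cc$support[r],
        breed_specific = TRUE, stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    consensus[0, , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("consensus_regions", "data.frame")
  res
}

#' Per-chromosome consensus coverage table
#'
#' Sums consensus-region length per chromosome (kb) and expresses it as a
#' percentage of chromosome length.  Chromosomes of the genome spec with no
#' regions are reported with zeros, so that "no consensus regions on this
#' chromosome" is visible in the table.
#'
#' @param regions a `consensus_regions` data.frame.
#' @param genome a [genome_spec()].
#' @return data.frame: `chrom`, `total_consensus_kb`, `coverage_pct`.
#' @export
coverage_table <- function(regions, genome) {
  chroms <- autosomes(genome)
  stray <- setdiff(unique(regions$chrom), names(genome$chrom_lengths))
  assert_that(length(stray) == 0, "region chromosome(s) absent from genome spec: %s",
              paste(stray, collapse = ", "))
  kb <- vapply(chroms, function(ch) {
    rr <- regions[regions$chrom == ch, , drop = FALSE]
    sum(rr$end_bp - rr$start_bp + 1) / 1000
  }, numeric(1))
  data.frame(chrom = chroms,
             total_consensus_kb = unname(kb),
             coverage_pct = unname(100 * kb * 1000 / genome$chrom_lengths[chroms]),
             stringsAsFactors = FALSE)
}
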