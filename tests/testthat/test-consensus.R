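seg_row <- function(id, chrom, start, end) {
  data.frame(sample_id = id, chrom = chrom, start_bp = start, end_bp = end,
             n_snps = 10L, n_het = 0L, n_missing = 0L,
             length_kb = (end - start + 1) / 1000, stringsAsFactors = FALSE)
}

test_that("consensus of identical and disjoint segments", {
  segs <- rbind(seg_row("a", "1", 100, 500), seg_row("b", "1", 100, 500))
  got <- consensus_regions(segs, c("a", "b"), 2)
  expect_equal(got$start_bp, 100L)
  expect_equal(got$end_bp, 500L)
  expect_equal(got$support, 2L)
  disjoint <- rbind(seg_row("a", "1", 100, 200), seg_row("b", "1", 300, 400))
  expect_equal(nrow(consensus_regions(disjoint, c("a", "b"), 2)), 0L)
  expect_warning(consensus_regions(segs, c("a", "b", "c"), 2), "c")
})

test_that("consensus equals the per-base counting oracle on random sets", {
  set.seed(99)
  for (rep in 1:25) {
    ids <- letters[1:5]
    rows <- list()
    for (id in ids) {
      n <- sample(0:4, 1)
      if (n == 0) next
      starts <- sort(sample.int(1800, n))
      for (s in starts) {
        e <- min(s + sample.int(300, 1), 2000)
        rows[[length(rows) + 1L]] <- seg_row(id, "1", s, e)
      }
    }
    if (length(rows) == 0) next
    segs <- do.call(rbind, rows)
    # per-sample segments must be non-overlapping: reduce by construction
    segs <- do.call(rbind, lapply(split(segs, segs$sample_id), function(d) {
      r <- IRanges::reduce(IRanges::IRanges(d$start_bp, d$end_bp))
      seg_row(d$sample_id[1], "1", IRanges::start(r), IRanges::end(r))
    }))
    ms <- sample(1:5, 1)
    got <- suppressWarnings(consensus_regions(segs, ids, ms))
    want <- support_oracle(segs, ids, ms, 2000)
    expect_equal(got$start_bp, want$start_bp)
    expect_equal(got$end_bp, want$end_bp)
    expect_equal(got$support, want$support)
  }
})

test_that("breed-specific filter removes, fragments, and flags regions", {
  cons <- consensus_regions(rbind(seg_row("a", "1", 1000, 9000),
                                  seg_row("b", "1", 1000, 9000)), c("a", "b"), 2)
  # no crossbreed overlap: unchanged, flagged specific
  none <- breed_specific_filter(cons, seg_row("x", "2", 1, 100), 1, 1)
  expect_equal(none$start_bp, 1000L)
  expect_true(all(none$breed_specific))
  # fully covered by one crossbreed ROH under the WGS rule: removed
  gone <- breed_specific_filter(cons, seg_row("x", "1", 500, 9500), 1, 1)
  expect_equal(nrow(gone), 0L)
  # partial overlap splits into two fragments
  frag <- breed_specific_filter(cons, seg_row("x", "1", 3000, 4000), 1, 1)
  expect_equal(frag$start_bp, c(1000L, 4001L))
  expect_equal(frag$end_bp, c(2999L, 9000L))
  # short fragments are dropped
  frag2 <- breed_specific_filter(cons, seg_row("x", "1", 3000, 8500), 1,
                                 min_fragment_bp = 1000)
  expect_equal(frag2$start_bp, 1000L)
  # threshold above the excluded support leaves the region intact
  kept <- breed_specific_filter(cons, seg_row("x", "1", 3000, 4000), 2, 1)
  expect_equal(nrow(kept), 1L)
  # whole-region mode removes instead of fragmenting
  whole <- breed_specific_filter(cons, seg_row("x", "1", 3000, 4000), 1, 1,
                                 drop_whole_region = TRUE)
  expect_equal(nrow(whole), 0L)
})

test_that("breed-specific subtraction equals a per-base oracle", {
  set.seed(77)
  for (rep in 1:15) {
    ids <- c("a", "b", "c")
    segs <- do.call(rbind, lapply(ids, function(id) {
      s <- sort(sample.int(1500, 2))
      rbind(seg_row(id, "1", s[1], s[1] + 200),
            seg_row(id, "1", max(s[1] + 300, s[2] + 250), s[2] + 500))
    }))
    cons <- suppressWarnings(consensus_regions(segs, ids, 2))
    ex <- do.call(rbind, lapply(c("x", "y"), function(id) {
      s <- sample.int(1800, 1)
      seg_row(id, "1", s, s + sample.int(400, 1))
    }))
    got <- breed_specific_filter(cons, ex, 1, min_fragment_bp = 1)
    # oracle: recompute surviving bases explicitly
    bad <- logical(2500)
    for (r in seq_len(nrow(ex))) bad[ex$start_bp[r]:ex$end_bp[r]] <- TRUE
    keep <- logical(2500)
    for (r in seq_len(nrow(cons)))
      keep[cons$start_bp[r]:cons$end_bp[r]] <- TRUE
    keep <- keep & !bad
    rl <- rle(keep)
    ends <- cumsum(rl$lengths); starts <- ends - rl$lengths + 1L
    expect_equal(got$start_bp, starts[rl$values])
    expect_equal(got$end_bp, ends[rl$values])
  }
})

test_that("coverage table arithmetic and zero reporting", {
  genome <- genome_spec(c("1" = 3e6, "2" = 3e6, "X" = 1e6),
                        excluded_chroms = "X")
  regions <- data.frame(chrom = "1",
                        start_bp = c(1001, 100001), end_bp = c(11000, 120000),
                        support = 2L, breed_specific = TRUE)
  tab <- coverage_table(regions, genome)
  expect_equal(tab$chrom, c("1", "2"))
  expect_equal(tab$total_consensus_kb, c(30, 0))
  expect_equal(tab$coverage_pct, c(1, 0))
  whole <- data.frame(chrom = "2", start_bp = 1, end_bp = 3e6)
  expect_equal(coverage_table(whole, genome)$coverage_pct, c(0, 100))
  expect_error(coverage_table(data.frame(chrom = "7", start_bp = 1, end_bp = 2),
                              genome), "7")
})

test_that("F_ROH arithmetic on the captured autosome", {
  genome <- genome_spec(c("1" = 2265395079))
  expect_equal(froh(seg_row("a", "1", 1, 10)[0, ], genome,
                    sample_ids = "a")$froh, 0)
  all_of_it <- seg_row("a", "1", 1, 2265395079)
  expect_equal(froh(all_of_it, genome)$froh, 1.0)
  # forced arithmetic on the published denominator
  f <- froh(seg_row("a", "1", 1000, 1000 + 453079016 - 1), genome)
  expect_equal(f$sum_roh_bp, 453079016)
  expect_equal(f$froh, 0.2, tolerance = 1e-9)
  # excluded chromosomes do not count
  fx <- froh(rbind(seg_row("a", "1", 1, 1e6), seg_row("a", "X", 1, 1e6)),
             genome_spec(c("1" = 2265395079, "X" = 1e8)))
  expect_equal(fx$sum_roh_bp, 1e6)
  # overlapping segments violate the caller contract
  expect_error(froh(rbind(seg_row("a", "1", 100, 500),
                          seg_row("a", "1", 400, 900)), genome),
               "overlapping")
})

test_that("F_ROH is additive over chromosomes and breed means average members", {
  genome <- genome_spec(c("1" = 1e6, "2" = 1e6), autosomal_captured_bp = 2e6)
  segs <- rbind(seg_row("a", "1", 1, 2e5), seg_row("a", "2", 1, 3e5),
                seg_row("b", "1", 1, 1e5))
  f <- froh(segs, genome)
  expect_equal(f$froh[f$sample_id == "a"], 0.25)
  md <- data.frame(sample_id = c("a", "b"), breed = "M")
  expect_equal(froh_breed_means(f, md)$mean_froh, (0.25 + 0.05) / 2)
})

test_that("gene overlap uses closed-interval any-overlap semantics", {
  regions <- data.frame(chrom = "1", start_bp = 1000L, end_bp = 2000L)
  genes <- data.frame(chrom = "1",
                      start = c(1200L, 2001L, 900L, 1990L),
                      end = c(1300L, 2500L, 999L, 2600L),
                      gene_id = c("inside", "abutting", "before", "spanning"))
  hits <- genes_in_regions(regions, genes)
  expect_setequal(hits$gene_id, c("inside", "spanning"))
  expect_setequal(attr(hits, "gene_list"), c("inside", "spanning"))
})

test_that("gene overlap equals the quadratic all-pairs oracle", {
  set.seed(55)
  for (rep in 1:10) {
    regions <- data.frame(chrom = sample(c("1", "2"), 6, TRUE),
                          start_bp = sample.int(5000, 6))
    regions$end_bp <- regions$start_bp + sample.int(800, 6)
    genes <- data.frame(chrom = sample(c("1", "2"), 15, TRUE),
                        start = sample.int(5500, 15), gene_id = sprintf("g%02d", 1:15))
    genes$end <- genes$start + sample.int(400, 15)
    got <- genes_in_regions(regions, genes)
    want <- 0L
    for (r in seq_len(nrow(regions))) for (g in seq_len(nrow(genes))) {
      if (regions$chrom[r] == genes$chrom[g] &&
          regions$start_bp[r] <= genes$end[g] &&
          genes$start[g] <= regions$end_bp[r]) {
        want <- want + 1L
        expect_true(any(got$gene_id == genes$gene_id[g] &
                          got$start_bp == regions$start_bp[r]))
      }
    }
    expect_equal(nrow(got), want)
  }
})

test_that("enrichment matches direct hypergeometric summation", {
  bg <- sprintf("g%03d", 1:100)
  sets <- data.frame(set_id = "S", gene_id = bg[1:20])
  gl <- c(bg[1:5], bg[50:54])          # k = 5, n = 10, K = 20, N = 100
  tab <- enrichment(gl, bg, sets)
  direct <- sum(vapply(5:10, function(i)
    choose(20, i) * choose(80, 10 - i) / choose(100, 10), numeric(1)))
  expect_equal(tab$fisher_p, direct, tolerance = 1e-12)
  ease_direct <- sum(vapply(4:10, function(i)
    choose(20, i) * choose(80, 10 - i) / choose(100, 10), numeric(1)))
  expect_equal(tab$ease_p, ease_direct, tolerance = 1e-12)
})

test_that("enrichment edge cases and the EASE-vs-Fisher inequality", {
  bg <- sprintf("g%03d", 1:60)
  sets <- data.frame(set_id = c("empty", "all")[c(1, rep(2, 60))],
                     gene_id = c("g999", bg))
  tab <- enrichment(bg[1:10], bg, sets)
  expect_equal(tab$fisher_p[tab$set_id == "empty"], 1)  # k = 0
  expect_equal(tab$ease_p[tab$set_id == "empty"], 1)
  expect_equal(tab$fisher_p[tab$set_id == "all"], 1)    # k = K = n covers all
  expect_error(enrichment("g001", character(0), sets), "background")
  expect_error(enrichment("zzz", bg, sets), "subset")
  set.seed(66)
  for (rep in 1:50) {
    N <- sample(20:200, 1)
    bgr <- sprintf("r%03d", seq_len(N))
    K <- sample.int(N, 1)
    n <- sample.int(N, 1)
    tab <- enrichment(sample(bgr, n), bgr,
                      data.frame(set_id = "S", gene_id = sample(bgr, K)))
    expect_gte(tab$ease_p, tab$fisher_p)
  }
})
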