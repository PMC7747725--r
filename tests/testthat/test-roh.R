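# explicit window-by-window enumeration, independent of both callers
enumerate_hit_rates <- function(g, w, het_max, miss_max) {
  m <- length(g)
  vapply(seq_len(m), function(i) {
    starts <- intersect(seq_len(max(m - w + 1, 0)), (i - w + 1):i)
    rates <- vapply(starts, function(s) {
      win <- g[s:(s + w - 1)]
      sum(win == 1L, na.rm = TRUE) <= het_max && sum(is.na(win)) <= miss_max
    }, logical(1))
    mean(rates)
  }, numeric(1))
}

test_that("hit rates on homogeneous inputs", {
  p <- roh_params()
  all_hom <- snp_hit_rates(rep(0L, 100), p)
  expect_true(all(all_hom$flag))
  expect_true(all(all_hom$hit_rate == 1))
  all_het <- snp_hit_rates(rep(1L, 100), p)
  expect_false(any(all_het$flag))
  expect_true(all(all_het$hit_rate == 0))
})

test_that("hit rates with a het cluster equal brute-force window enumeration", {
  g <- rep(0L, 50)
  g[11:14] <- 1L   # 4 hets in a row, one more than the window allowance
  p <- roh_params(window_snps = 20, window_het = 3, window_missing = 5,
                  hit_rate_threshold = 0.05)
  got <- snp_hit_rates(g, p)
  want <- enumerate_hit_rates(g, 20, 3, 5)
  expect_equal(got$hit_rate, want)
  expect_equal(got$flag, want >= 0.05)
})

test_that("hit rates match enumeration on random vectors and parameters", {
  set.seed(101)
  for (rep in 1:25) {
    m <- sample(5:120, 1)
    g <- sample(c(0L, 1L, 2L, NA), m, TRUE, prob = c(0.5, 0.2, 0.2, 0.1))
    w <- sample(2:25, 1)
    p <- roh_params(window_snps = w, window_het = sample(0:(w - 1), 1),
                    window_missing = sample(0:4, 1),
                    hit_rate_threshold = runif(1, 0.01, 1))
    got <- snp_hit_rates(g, p)
    if (m < w) {
      pass <- sum(g == 1L, na.rm = TRUE) <= p$window_het &&
        sum(is.na(g)) <= p$window_missing
      expect_equal(got$flag, rep(pass, m))
    } else {
      want <- enumerate_hit_rates(g, w, p$window_het, p$window_missing)
      expect_equal(got$hit_rate, want)
      expect_equal(got$flag, want >= p$hit_rate_threshold)
    }
  }
})

test_that("segment thresholds: SNP count, span, density at the WGS boundary", {
  p <- roh_params_preset("wgs")
  # 20 flagged SNPs spanning exactly 2.4 kb: density 0.12 kb/SNP, kept
  pos <- as.integer(seq(1000, 1000 + 2399, length.out = 20))
  seg <- segments_from_flags(rep(TRUE, 20), pos, rep(0L, 20), p)
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$n_snps, 20L)
  expect_equal(seg$length_kb, 2.4)
  # 19 flagged SNPs: below min_snps
  expect_equal(nrow(segments_from_flags(rep(TRUE, 19), pos[1:19],
                                        rep(0L, 19), p)), 0L)
  # same 20 SNPs spread over 3 kb: density 0.15 > 0.12, dropped
  pos2 <- as.integer(seq(1000, 4000, length.out = 20))
  expect_equal(nrow(segments_from_flags(rep(TRUE, 20), pos2,
                                        rep(0L, 20), p)), 0L)
})

test_that("runs split at gaps above max_gap_kb and pieces are re-tested", {
  p <- roh_params(min_snps = 5, min_length_kb = 0.1,
                  density_kb_per_snp = 50, max_gap_kb = 100)
  pos <- c(seq(1000, 9000, by = 2000), seq(200000, 208000, by = 2000))
  stopifnot(diff(pos)[5] > 100000)
  seg <- segments_from_flags(rep(TRUE, 10), as.integer(pos), rep(0L, 10), p)
  expect_equal(nrow(seg), 2L)
  expect_equal(seg$start_bp, c(1000L, 200000L))
  # with min_snps 6, both 5-SNP pieces fail although the joined run has 10
  p6 <- roh_params(min_snps = 6, min_length_kb = 0.1,
                   density_kb_per_snp = 50, max_gap_kb = 100)
  expect_equal(nrow(segments_from_flags(rep(TRUE, 10), as.integer(pos),
                                        rep(0L, 10), p6)), 0L)
})

test_that("call_roh finds whole-chromosome homozygosity and skips het samples", {
  g <- rbind(rep(0L, 60), rep(1L, 60))
  x <- make_gm(g, pos = seq_len(60) * 100L)
  p <- roh_params(min_length_kb = 1, density_kb_per_snp = 1)
  seg <- call_roh(x, p)
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$sample_id, "s01")
  expect_equal(seg$start_bp, 100L)
  expect_equal(seg$end_bp, 6000L)
  expect_equal(seg$n_snps, 60L)
})

test_that("caller agrees exactly with the brute-force oracle", {
  set.seed(202)
  for (i in 1:60) {
    x <- random_instance()
    p <- random_roh_params()
    got <- plain_df(suppressWarnings(call_roh(x, p)))
    want <- plain_df(brute_force_roh(x, p))
    expect_identical(got, want)
  }
})

test_that("oracle refuses large inputs and handles degenerate ones", {
  big <- make_gm(matrix(0L, 1, 10001), pos = seq_len(10001) * 10L)
  expect_error(brute_force_roh(big), "10,000")
  one <- make_gm(matrix(0L, 1, 1))
  expect_equal(nrow(brute_force_roh(one)), 0L)   # single SNP, window 20
})

test_that("tightening min_snps or min_length_kb only removes segments", {
  set.seed(303)
  for (i in 1:20) {
    x <- random_instance(150)
    base <- random_roh_params()
    loose <- suppressWarnings(call_roh(x, base))
    strict_params <- base
    strict_params$min_snps <- base$min_snps + sample(1:5, 1)
    strict_params$min_length_kb <- base$min_length_kb * runif(1, 1, 3)
    strict <- suppressWarnings(call_roh(x, strict_params))
    key <- function(d) paste(d$sample_id, d$chrom, d$start_bp, d$end_bp)
    expect_true(all(key(strict) %in% key(loose)))
  }
})

test_that("segments of one sample never overlap on a chromosome", {
  set.seed(404)
  for (i in 1:15) {
    x <- random_instance(150)
    seg <- suppressWarnings(call_roh(x, random_roh_params()))
    for (d in split(seg, paste(seg$sample_id, seg$chrom))) {
      d <- d[order(d$start_bp), ]
      if (nrow(d) > 1)
        expect_true(all(d$start_bp[-1] > d$end_bp[-nrow(d)]))
    }
  }
})

test_that("window larger than run minimum triggers a warning", {
  x <- make_gm(matrix(0L, 1, 30))
  expect_warning(call_roh(x, roh_params(window_snps = 25, min_snps = 20,
                                        window_het = 3)),
                 "window")
})
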