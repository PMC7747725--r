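# shared fixture builders; everything is generated in code at test time

# quick genotype_matrix from a genotype matrix/vector (samples x sites)
make_gm <- function(geno, pos = NULL, chrom = "1", group = NULL,
                    phenotype = NULL, impact = NULL, depth = NULL,
                    alt = "C") {
  geno <- rbind(geno)
  n <- ncol(geno)
  if (is.null(pos)) pos <- seq_len(n) * 100L
  sites <- data.frame(chrom = rep_len(chrom, n), pos = pos,
                      ref = "A", alt = rep_len(alt, n),
                      stringsAsFactors = FALSE)
  if (!is.null(impact)) sites$impact <- rep_len(impact, n)
  ns <- nrow(geno)
  samples <- data.frame(
    sample_id = sprintf("s%02d", seq_len(ns)), breed = "b",
    group = if (is.null(group)) rep("case", ns) else rep_len(group, ns),
    phenotype = if (is.null(phenotype)) rep("unknown", ns) else rep_len(phenotype, ns),
    stringsAsFactors = FALSE)
  genotype_matrix(sites, samples, geno, depth)
}

# random small instance for oracle-equivalence checks
random_instance <- function(n_max = 200) {
  n <- sample(5:n_max, 1)
  ns <- sample(1:3, 1)
  geno <- matrix(sample(c(0L, 1L, 2L, NA), ns * n, TRUE,
                        prob = c(0.4, 0.25, 0.25, 0.1)), ns, n)
  make_gm(geno, pos = sort(sample.int(n * 300L, n)))
}

random_roh_params <- function() {
  w <- sample(2:25, 1)
  roh_params(window_snps = w, window_het = sample(0:(w - 1), 1),
             window_missing = sample(0:5, 1),
             hit_rate_threshold = runif(1, 0.01, 1),
             min_snps = sample(2:25, 1),
             min_length_kb = runif(1, 0.1, 5),
             density_kb_per_snp = runif(1, 0.05, 50),
             max_gap_kb = runif(1, 1, 20),
             truncated_window = sample(c(TRUE, FALSE), 1))
}

# strip class/attributes for data.frame comparison
plain_df <- function(x) {
  x <- as.data.frame(x)
  attr(x, "params") <- NULL
  rownames(x) <- NULL
  x
}

# a small, fast simulation shared by several test files
desk_sim <- function(seed = 5, ...) {
  args <- utils::modifyList(
    list(seed = seed, chrom_length_bp = 2e6,
         tract_length_range = c(5e4, 2e5),
         n_consensus_tracts = 3, n_planted_tracts = 1),
    list(...))
  simulate_cohort(do.call(sim_config, args))
}

# per-bp support counting oracle over an explicit position array
support_oracle <- function(segments, ids, min_support, max_pos) {
  cov <- integer(max_pos)
  for (id in ids) {
    d <- segments[segments$sample_id == id, , drop = FALSE]
    covered <- logical(max_pos)
    for (r in seq_len(nrow(d))) covered[d$start_bp[r]:d$end_bp[r]] <- TRUE
    cov <- cov + covered
  }
  ok <- cov >= min_support
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  data.frame(start_bp = starts[keep], end_bp = ends[keep],
             support = vapply(keep, function(k) min(cov[starts[k]:ends[k]]),
                              integer(1)))
}
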