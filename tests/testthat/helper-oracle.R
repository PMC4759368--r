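# Brute-force all-pairs interval oracles used to validate the overlap-based
# partitions, plus small fixture builders shared across tests.

oracle_overlaps_any <- function(s, other) {
  vapply(seq_len(nrow(s)), function(i) {
    any(s$chrom[i] == other$chrom &
          s$start[i] < other$end & s$end[i] > other$start)
  }, logical(1))
}

# Per-site 2-way region labels, computed by exhaustive comparison.
oracle_regions2 <- function(A, B) {
  list(a = ifelse(oracle_overlaps_any(A, B), "ab", "a_only"),
       b = ifelse(oracle_overlaps_any(B, A), "ab", "b_only"))
}

# Per-site 3-way region labels.
oracle_regions3 <- function(A, B, C) {
  lab <- function(a, b, c) {
    tag <- paste0(ifelse(a, "a", ""), ifelse(b, "b", ""), ifelse(c, "c", ""))
    ifelse(nchar(tag) == 1, paste0(tag, "_only"), tag)
  }
  list(a = lab(TRUE, oracle_overlaps_any(A, B), oracle_overlaps_any(A, C)),
       b = lab(oracle_overlaps_any(B, A), TRUE, oracle_overlaps_any(B, C)),
       c = lab(oracle_overlaps_any(C, A), oracle_overlaps_any(C, B), TRUE))
}

# Random non-degenerate interval set on two chromosomes of 1 Mb.
random_interval_set <- function(n, max_width = 800) {
  chrom <- sample(c("chr1", "chr2"), n, replace = TRUE)
  start <- sample.int(1e6 - max_width, n, replace = TRUE) - 1
  width <- sample.int(max_width, n, replace = TRUE)
  sort_df <- data.frame(chrom = chrom, start = start, end = start + width,
                        raw_maxd = sample.int(50, n, replace = TRUE),
                        stringsAsFactors = FALSE)
  sort_df[order(sort_df$chrom, sort_df$start), ]
}

random_hotspot_set <- function(n, condition, total_reads = 1e7) {
  hotspot_set(random_interval_set(n), sample_id = paste0(condition, "_s"),
              condition = condition, total_reads = total_reads)
}

# Small, quick study design reused by several tests.
small_spec <- function(...) {
  truth_spec(conditions = c("B34", "B39d1", "OIMd1"),
             n_shared = 40,
             n_unique = c(B34 = 5, B39d1 = 5, OIMd1 = 10),
             n_planted_genes = 4, n_planted_sites = 6,
             planted_max_offset = 30000,
             total_reads = 1e6, ...)
}

small_fixture <- function(seed = 1, tracks = FALSE, ...) {
  make_fixture(spec = small_spec(), seed = seed, n_chroms = 1,
               chrom_length = 2e6, n_genes = 50, tracks = tracks, ...)
}
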