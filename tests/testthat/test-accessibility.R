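test_that("normalize_maxd scales to 10 million reads and is linear", {
  expect_equal(normalize_maxd(12, 1e7), 12)
  expect_equal(normalize_maxd(12, 5e6), 24)
  expect_equal(normalize_maxd(0, 123), 0)
  expect_error(normalize_maxd(3, 0), "total_reads")
  x <- sample.int(100, 20)
  expect_equal(normalize_maxd(3 * x, 2e6), 3 * normalize_maxd(x, 2e6))
})

test_that("maxd_difference_test matches exact binomial tails", {
  expect_equal(maxd_difference_test(15, 1e7, 15, 1e7)$p_value, 1)
  expect_equal(maxd_difference_test(30, 1e7, 0, 1e7)$p_value, 2 * 0.5^30)
  expect_equal(maxd_difference_test(0, 1e7, 0, 1e7)$p_value, 1)
  expect_false(maxd_difference_test(0, 1e7, 0, 1e7)$significant)
  # depth offsets: counts proportional to depths are unremarkable
  p <- maxd_difference_test(20, 2e7, 10, 1e7)$p_value
  expect_gt(p, 0.5)
  expect_error(maxd_difference_test(1, 0, 1, 1), "depths")
})

test_that("replicate concordance takes unions of cross-replicate overlaps", {
  mk <- function(df, id, cond = "c") {
    hotspot_set(df, sample_id = id, condition = cond, total_reads = 1e7)
  }
  a <- data.frame(chrom = "chr1", start = c(0, 200), end = c(100, 300),
                  raw_maxd = c(10, 20))
  # identical replicates reproduce the intervals
  rc <- replicate_concordant(mk(a, "r1"), mk(a, "r2"))
  expect_equal(rc$sites[, c("start", "end")], a[, c("start", "end")],
               ignore_attr = TRUE)
  expect_equal(rc$sites$norm_maxd, c(10, 20))
  # disjoint replicates yield nothing
  b <- data.frame(chrom = "chr1", start = 5000, end = 5100, raw_maxd = 5)
  expect_equal(nrow(replicate_concordant(mk(a, "r1"), mk(b, "r2"))$sites), 0)
  # partial overlap unions the pair
  c1 <- data.frame(chrom = "chr1", start = 0, end = 100, raw_maxd = 8)
  c2 <- data.frame(chrom = "chr1", start = 50, end = 150, raw_maxd = 12)
  rc2 <- replicate_concordant(mk(c1, "r1"), mk(c2, "r2"))
  expect_equal(rc2$sites$start, 0)
  expect_equal(rc2$sites$end, 150)
  expect_equal(rc2$sites$norm_maxd, 10)
  expect_error(replicate_concordant(mk(a, "r1", "x"), mk(a, "r2", "y")),
               "different conditions")
})

test_that("replicate concordance is commutative", {
  withr::with_seed(42, {
    for (i in 1:5) {
      r1 <- random_hotspot_set(80, "c")
      r2 <- random_hotspot_set(80, "c")
      ab <- replicate_concordant(r1, r2)
      ba <- replicate_concordant(r2, r1)
      expect_equal(ab$sites[, c("chrom", "start", "end", "norm_maxd")],
                   ba$sites[, c("chrom", "start", "end", "norm_maxd")])
    }
  })
})

test_that("compare_two partitions unique and common sites correctly", {
  mk <- function(df, cond) {
    hotspot_set(df, sample_id = cond, condition = cond, total_reads = 1e7)
  }
  a <- mk(data.frame(chrom = "chr1", start = c(0, 200), end = c(100, 300),
                     raw_maxd = c(10, 10)), "A")
  b <- mk(data.frame(chrom = "chr1", start = 50, end = 150, raw_maxd = 10),
          "B")
  cmp <- compare_two(a, b)
  expect_equal(sum(cmp$sites$status == "unique_a"), 1)
  expect_equal(sum(cmp$sites$status == "unique_b"), 0)
  common <- cmp$sites[grepl("common", cmp$sites$status), ]
  expect_equal(nrow(common), 1)
  expect_equal(common$start, 0)
  expect_equal(common$end, 150)
  expect_equal(unname(cmp$venn$counts),
               unname(c(a_only = 1L, b_only = 0L, ab = 2L)))

  # identical sets: no uniques
  cmp2 <- compare_two(a, a)
  expect_equal(sum(grepl("unique", cmp2$sites$status)), 0)

  # disjoint sets: all unique
  d <- mk(data.frame(chrom = "chr2", start = 0, end = 50, raw_maxd = 4), "B")
  cmp3 <- compare_two(a, d)
  expect_setequal(cmp3$sites$status, c("unique_a", "unique_b"))
})

test_that("compare_two flags depth-adjusted MaxD changes", {
  mk <- function(raw, cond, reads) {
    hotspot_set(data.frame(chrom = "chr1", start = 0, end = 100,
                           raw_maxd = raw),
                sample_id = cond, condition = cond, total_reads = reads)
  }
  # 60 vs 5 tags at equal depth: clearly modified
  cmp <- compare_two(mk(60, "A", 1e7), mk(5, "B", 1e7))
  expect_equal(cmp$sites$status, "common_modified")
  expect_equal(cmp$sites$delta_norm_maxd, -55)
  # same counts, same depth: unchanged
  cmp2 <- compare_two(mk(30, "A", 1e7), mk(30, "B", 1e7))
  expect_equal(cmp2$sites$status, "common_unchanged")
})

test_that("two- and three-way partitions match the brute-force oracle", {
  withr::with_seed(7, {
    for (i in 1:6) {
      A <- random_hotspot_set(120, "A")
      B <- random_hotspot_set(120, "B")
      C <- random_hotspot_set(120, "C")
      cmp <- compare_two(A, B)
      or2 <- oracle_regions2(A$sites, B$sites)
      mem <- cmp$venn$membership
      expect_equal(as.character(mem$region[mem$set == "a"]), or2$a)
      expect_equal(as.character(mem$region[mem$set == "b"]), or2$b)
      cmp3 <- compare_three(A, B, C)
      or3 <- oracle_regions3(A$sites, B$sites, C$sites)
      mem3 <- cmp3$venn$membership
      expect_equal(as.character(mem3$region[mem3$set == "a"]), or3$a)
      expect_equal(as.character(mem3$region[mem3$set == "b"]), or3$b)
      expect_equal(as.character(mem3$region[mem3$set == "c"]), or3$c)
    }
  })
})

test_that("compare_three handles the degenerate identity and disjoint cases", {
  mk <- function(df, cond) {
    hotspot_set(df, sample_id = cond, condition = cond, total_reads = 1e7)
  }
  a <- data.frame(chrom = "chr1", start = c(0, 500), end = c(100, 600),
                  raw_maxd = 5)
  same <- compare_three(mk(a, "A"), mk(a, "B"), mk(a, "C"))
  expect_equal(unname(same$venn$counts["abc"]), 6L)
  expect_equal(sum(same$venn$counts), 6L)
  b <- transform(a, start = start + 1e4, end = end + 1e4)
  c_ <- transform(a, start = start + 2e4, end = end + 2e4)
  dis <- compare_three(mk(a, "A"), mk(b, "B"), mk(c_, "C"))
  expect_equal(unname(dis$venn$counts[c("a_only", "b_only", "c_only")]),
               c(2L, 2L, 2L))
  expect_equal(nrow(dis$unique$A), 2)
})

test_that("top_changed_sites ranks TSS-proximal sites by |delta|", {
  g <- make_genome(1, 1e6, 10, seed = 5)
  tss <- gene_tss(g)
  diff <- data.frame(
    chrom = "chr1",
    start = c(tss[[1]] - 50, tss[[2]] - 50, tss[[3]] + 2000),
    end = c(tss[[1]] + 50, tss[[2]] + 50, tss[[3]] + 2100),
    delta_norm_maxd = c(5, -20, 100))
  out <- top_changed_sites(diff, g, n = 1500, tss_flank = 1000)
  # the site 2 kb past its TSS is excluded despite the largest |delta|
  expect_equal(nrow(out), 2)
  expect_equal(out$delta_norm_maxd, c(-20, 5))
  # ties broken by position
  diff2 <- data.frame(chrom = "chr1",
                      start = c(tss[[2]] - 50, tss[[1]] - 50),
                      end = c(tss[[2]] + 50, tss[[1]] + 50),
                      delta_norm_maxd = c(7, 7))
  out2 <- top_changed_sites(diff2, g)
  expect_equal(out2$start, sort(out2$start))
  expect_equal(nrow(top_changed_sites(diff, g, n = 1)), 1)
})

test_that("motif windows are centred, fixed-width and clipped at bounds", {
  g <- make_genome(1, 1e6, 0, seed = 1)
  sites <- data.frame(site_id = c("s1", "s2"), chrom = "chr1",
                      start = c(1000, 0), end = c(1100, 120),
                      peak = c(1050, 50))
  win <- export_motif_windows(sites, g, width = 200)
  expect_equal(win$start, c(950, 0))
  expect_equal(win$end, c(1150, 150))
  expect_equal(win$clipped, c(FALSE, TRUE))
  expect_error(export_motif_windows(sites, g, width = 201), "even")
  bad <- transform(sites, chrom = "chrX")
  expect_error(export_motif_windows(bad, g), "unknown chromosome")
  # midpoint fallback when no peak is recorded
  win2 <- export_motif_windows(sites[, 1:4], g, width = 100)
  expect_equal(win2$start[1], interval_mid0(1000, 1100) - 50)
})

test_that("the exact test keeps its nominal type-I error on Poisson pairs", {
  withr::with_seed(99, {
    n <- 2000
    a <- stats::rpois(n, 20)
    b <- stats::rpois(n, 20)
    rej <- mean(maxd_difference_test(a, 1e7, b, 1e7)$p_value < 0.05)
    se <- sqrt(0.05 * 0.95 / n)
    expect_lte(rej, 0.05 + 3 * se)
  })
})
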