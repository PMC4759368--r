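# Hand-built two-gene genome used to exercise every branch of the priority
# classifier: gene A (+) with two exons, gene B (-) downstream on the same
# chromosome.
toy_genome <- function() {
  genes <- data.frame(gene_id = c("GA", "GB"), chrom = "chr1",
                      strand = c("+", "-"),
                      tx_start = c(20000, 80000), tx_end = c(30000, 90000))
  exons <- data.frame(gene_id = c("GA", "GA", "GB"),
                      start = c(20000, 28000, 80000),
                      end = c(21000, 30000, 90000))
  structure(list(chroms = c(chr1 = 2e5), genes = genes, exons = exons),
            class = "dhs_genome")
}

test_that("classification follows the promoter > exon > intron priority", {
  g <- toy_genome()
  # within +/- 2.5 kb of GA's TSS (20000)
  expect_equal(classify_site(data.frame(chrom = "chr1", start = 19900,
                                        end = 20100), g)$category, "promoter")
  # promoter window edge: [TSS-2500, TSS+2500) is half-open, so a site
  # ending exactly at TSS-2500 does not touch it
  expect_equal(classify_site(data.frame(chrom = "chr1", start = 17500,
                                        end = 17600), g)$category, "promoter")
  expect_equal(classify_site(data.frame(chrom = "chr1", start = 17400,
                                        end = 17500), g)$category,
               "distal_upstream")
  # inside GA's second exon but outside any promoter window
  expect_equal(classify_site(data.frame(chrom = "chr1", start = 28100,
                                        end = 28200), g)$category, "exon")
  # gene body, between exons
  expect_equal(classify_site(data.frame(chrom = "chr1", start = 25000,
                                        end = 25100), g)$category, "intron")
  # a site touching both an exon of GA and GB's promoter window is promoter
  span <- data.frame(chrom = "chr1", start = 29000, end = 88000)
  expect_equal(classify_site(span, g)$category, "promoter")
  # intergenic, 10 kb 5' of GA's TSS
  up <- classify_site(data.frame(chrom = "chr1", start = 9950,
                                 end = 10050), g)
  expect_equal(up$category, "distal_upstream")
  expect_equal(up$nearest_gene_id, "GA")
  # signed distance runs TSS -> site midpoint (floor((s + e - 1) / 2))
  expect_equal(up$distance_to_tss, 9999 - 20000)
  # 3' of GB (minus strand): low coordinates are downstream of its TSS
  down <- classify_site(data.frame(chrom = "chr1", start = 60000,
                                   end = 60100), g)
  expect_equal(down$category, "downstream")
  expect_equal(down$nearest_gene_id, "GB")
  expect_error(classify_site(data.frame(chrom = "chr1", start = 0, end = 10),
                             make_genome(1, 1e5, 0, seed = 1)),
               "empty gene annotation")
})

test_that("annotation is an exact partition with coherent fractions", {
  g <- make_genome(2, 1e6, 40, seed = 11)
  withr::with_seed(3, {
    sites <- random_interval_set(300)
  })
  ann <- annotate_all(sites, g)
  expect_equal(sum(ann$counts), 300)
  expect_equal(sum(ann$fractions), 1, tolerance = 1e-9)
  expect_false(anyNA(ann$sites$category))
  expect_false(anyNA(ann$sites$nearest_gene_id))
  # empty input: zero counts, zero fractions, no failure
  empty <- annotate_all(sites[0, ], g)
  expect_equal(sum(empty$counts), 0)
  expect_equal(sum(empty$fractions), 0)
})

test_that("promoter priority wins on every constructed overlap pattern", {
  g <- toy_genome()
  tss <- 20000
  offsets <- c(-2600, -2500, -2499, -100, 0, 2499, 2500)
  for (off in offsets) {
    site <- data.frame(chrom = "chr1", start = tss + off,
                       end = tss + off + 100)
    cat <- classify_site(site, g)$category
    hits_prom <- (tss + off) < tss + 2500 && (tss + off + 100) > tss - 2500
    if (hits_prom) expect_equal(cat, "promoter")
    else expect_true(cat != "promoter")
  }
})

test_that("annotation of jittered peak calls recovers the planted categories", {
  fx <- small_fixture(seed = 3)
  truth <- fx$truth$conditions$OIMd1
  sim_sites <- fx$hotspots$OIMd1[[1]]$sites
  ann <- annotate_all(sim_sites, fx$genome,
                      promoter_halfwidth = fx$spec$promoter_halfwidth)
  # jitter is +/-10 bp on sites hundreds of bp wide: categories should agree
  # for nearly all sites
  agree <- mean(ann$sites$category ==
                  truth$true_category[match(ann$sites$site_id,
                                            truth$site_id)])
  expect_gte(agree, 0.9)
})

test_that("aggregation profiles obey symmetry, zero and closed-form cases", {
  genes <- data.frame(gene_id = "G1", chrom = "chr1", strand = "+",
                      tx_start = 5000, tx_end = 8000)
  g <- structure(list(chroms = c(chr1 = 2e4), genes = genes,
                      exons = data.frame(gene_id = "G1", start = 5000,
                                         end = 8000)),
                 class = "dhs_genome")
  # symmetric tags about the TSS give a symmetric profile
  track <- data.frame(chrom = "chr1", start = c(4900, 5099),
                      end = c(4901, 5100), count = c(6, 6))
  prof <- aggregation_profile(track, g, flank = 1000, bin = 100,
                              total_reads = 1e7)
  expect_equal(prof$density, rev(prof$density))
  # zero track
  empty <- aggregation_profile(track[0, ], g, flank = 1000, bin = 100,
                               total_reads = 1e7)
  expect_true(all(empty$density == 0))
  # uniform density d per bp: every bin = d * bin * 1e7 / total_reads
  uni <- data.frame(chrom = "chr1", start = 0, end = 2e4, count = 3)
  prof_u <- aggregation_profile(uni, g, flank = 1000, bin = 50,
                                total_reads = 5e6)
  expect_equal(prof_u$density, rep(3 * 50 * 1e7 / 5e6, 40))
  # linearity: profile of a track sum equals the sum of profiles
  both <- rbind(track, uni)
  p_both <- aggregation_profile(both, g, flank = 1000, bin = 100,
                                total_reads = 1e7)
  p_sep <- aggregation_profile(track, g, flank = 1000, bin = 100,
                               total_reads = 1e7)$density +
    aggregation_profile(uni, g, flank = 1000, bin = 100,
                        total_reads = 1e7)$density
  expect_equal(p_both$density, p_sep)
  # minus-strand genes read 5' to 3': a tag 250 bp downstream of the TSS
  # lands in the same positive-offset bin on either strand
  g_minus <- g
  g_minus$genes$strand <- "-"            # TSS becomes tx_end - 1 = 7999
  tag_plus <- data.frame(chrom = "chr1", start = 5250, end = 5251, count = 10)
  tag_minus <- data.frame(chrom = "chr1", start = 7749, end = 7750,
                          count = 10)
  p_plus <- aggregation_profile(tag_plus, g, flank = 1000, bin = 100,
                                total_reads = 1e7)
  p_minus <- aggregation_profile(tag_minus, g_minus, flank = 1000, bin = 100,
                                 total_reads = 1e7)
  expect_equal(p_minus$density, p_plus$density)
  expect_gt(p_plus$density[p_plus$offset == 200], 0)
  expect_error(aggregation_profile(track, g, flank = 1000, bin = 33,
                                   total_reads = 1e7), "divide")
})

test_that("maxd_distribution builds per-category ECDFs", {
  df <- data.frame(category = c("promoter", "promoter", "exon"),
                   norm_maxd = c(10, 30, 5))
  d <- maxd_distribution(df)
  expect_equal(d$promoter$n, 2)
  expect_equal(d$promoter$ecdf(9.99), 0)
  expect_equal(d$promoter$ecdf(10), 0.5)   # right-continuous step
  expect_equal(d$promoter$ecdf(30), 1)
  expect_equal(d$exon$ecdf(Inf), 1)
  expect_true("intron" %in% attr(d, "empty_categories"))
  # shifting all values shifts the support
  df2 <- transform(df, norm_maxd = norm_maxd + 7)
  d2 <- maxd_distribution(df2)
  expect_equal(d2$promoter$values, d$promoter$values + 7)
})
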