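test_that("define_enhancers removes exactly the promoter sites", {
  df <- data.frame(site_id = sprintf("s%d", 1:10),
                   category = c(rep("promoter", 3), rep("intron", 4),
                                rep("distal_upstream", 3)))
  enh <- define_enhancers(df)
  expect_equal(nrow(enh), 7)
  expect_false(any(enh$category == "promoter"))
  # complement identity
  expect_setequal(c(enh$site_id, df$site_id[df$category == "promoter"]),
                  df$site_id)
  all_prom <- df[df$category == "promoter", ]
  expect_equal(nrow(define_enhancers(all_prom)), 0)
})

test_that("enhancer-gene links respect the inclusive distance bound", {
  genes <- data.frame(gene_id = c("G1", "G2", "G3"), chrom = "chr1",
                      strand = "+",
                      tx_start = c(100000, 150999, 151000),
                      tx_end = c(110000, 160000, 161001))
  g <- structure(list(chroms = c(chr1 = 1e6), genes = genes,
                      exons = data.frame(gene_id = "G1", start = 100000,
                                         end = 110000)),
                 class = "dhs_genome")
  # enhancer [100500, 101000): G1's TSS 500 bp away, G2's TSS exactly 50 kb
  # from end-1, G3's TSS at 50,001 bp
  enh <- data.frame(site_id = "e1", chrom = "chr1", start = 100500,
                    end = 101000, category = "intron",
                    delta_norm_maxd = -8.2)
  lk <- link_enhancers_to_genes(enh, g, max_dist = 50000)
  expect_setequal(lk$gene_id, c("G1", "G2"))
  expect_equal(lk$distance[lk$gene_id == "G2"], 50000)
  expect_equal(lk$intensity, c(-8.2, -8.2))
  # TSS inside the site has distance 0
  inside <- data.frame(site_id = "e2", chrom = "chr1", start = 99000,
                       end = 100500, category = "intron", intensity = 1)
  lk2 <- link_enhancers_to_genes(inside, g)
  expect_equal(lk2$distance[lk2$gene_id == "G1"], 0)
  expect_equal(nrow(link_enhancers_to_genes(enh[0, ], g)), 0)
})

test_that("link counts grow monotonically with the pairing distance", {
  g <- make_genome(1, 1e6, 30, seed = 13)
  withr::with_seed(5, {
    enh <- random_interval_set(40)
  })
  enh$intensity <- 1
  n_prev <- -1
  for (d in c(0, 1000, 10000, 50000, 2e5)) {
    n <- nrow(link_enhancers_to_genes(enh, g, max_dist = d))
    expect_gte(n, n_prev)
    n_prev <- n
  }
})

test_that("gene intensity collapses to the strongest signed link", {
  links <- data.frame(site_id = c("a", "b", "c"), gene_id = c("G1", "G1", "G2"),
                      intensity = c(5, -9, -8.2))
  tab <- gene_intensity_table(links)
  expect_equal(tab$intensity[tab$gene_id == "G1"], -9)
  expect_equal(tab$n_links[tab$gene_id == "G1"], 2)
  expect_equal(tab$intensity[tab$gene_id == "G2"], -8.2)
  tab_sum <- gene_intensity_table(links, mode = "sum")
  expect_equal(tab_sum$intensity[tab_sum$gene_id == "G1"], -4)
  expect_equal(nrow(gene_intensity_table(links[0, ])), 0)
})

test_that("hypergeometric enrichment matches exact tail probabilities", {
  bg <- sprintf("g%02d", 1:20)
  # set of 5, query of 5, overlap 4: p = 76/15504
  res <- enrich_gene_sets(bg[1:5], bg, list(s1 = bg[2:6]))
  expect_equal(res$p_value, 76 / 15504)
  expect_equal(res$overlap, 4)
  # a set equal to the background is never enriched
  res2 <- enrich_gene_sets(bg[1:5], bg, list(all = bg))
  expect_equal(res2$p_value, 1)
  # BH across sets, ordered by p
  res3 <- enrich_gene_sets(bg[1:5], bg,
                           list(hit = bg[1:5], miss = bg[16:20]))
  expect_equal(res3$set_name[1], "hit")
  expect_true(all(diff(res3$p_value) >= 0))
  expect_equal(res3$bh_fdr, stats::p.adjust(res3$p_value, "BH"))
  expect_error(enrich_gene_sets(c("zz"), bg, list(s = bg[1:2])), "subset")
  expect_error(enrich_gene_sets(bg[1], character(), list(s = bg[1])),
               "background")
})

test_that("expression overlay keeps unmatched genes and is idempotent", {
  tab <- data.frame(gene_id = c("G1", "G2"), intensity = c(3, -2),
                    n_links = c(1L, 1L))
  ratios <- data.frame(gene_id = "G1", log2fc = 1.5)
  ov <- overlay_expression(tab, ratios)
  expect_equal(ov$log2_ratio, c(1.5, NA))
  expect_equal(ov$in_expression, c(TRUE, FALSE))
  ov2 <- overlay_expression(ov[, c("gene_id", "intensity", "n_links")],
                            ratios)
  expect_equal(ov2$log2_ratio, ov$log2_ratio)
  expect_error(overlay_expression(tab, data.frame(gene_id = "X", v = 1)),
               "namespace")
})

test_that("enrichment p-values are uniform under a random-query null", {
  withr::with_seed(17, {
    bg <- sprintf("g%05d", 1:10000)
    collection <- list(big = bg[1:5000])
    pvals <- replicate(400, {
      q <- sample(bg, 1000)
      enrich_gene_sets(q, bg, collection)$p_value
    })
    # ties are inherent to the discrete hypergeometric null
    ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
    expect_gt(ks$p.value, 0.01)
  })
})
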