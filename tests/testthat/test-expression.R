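mk_expr <- function(values, conditions, times, reps) {
  samples <- data.frame(
    sample_id = sprintf("%s_t%g_r%d", conditions, times, reps),
    condition = conditions, time = times, replicate = reps)
  expr_matrix(values, samples)
}

test_that("replicate_average takes per-group arithmetic means", {
  v <- matrix(c(2, 2, 2, 1, 2, 3), nrow = 1,
              dimnames = list("g1", NULL))
  em <- mk_expr(v, rep(c("A", "B"), each = 3), rep(0, 6), rep(1:3, 2))
  m <- replicate_average(em)
  expect_equal(unname(m$values["g1", ]), c(2, 2))
  # single replicate passes through
  v2 <- matrix(c(5, 7), nrow = 1, dimnames = list("g1", NULL))
  em2 <- mk_expr(v2, c("A", "B"), c(0, 0), c(1, 1))
  expect_equal(unname(replicate_average(em2)$values["g1", ]), c(5, 7))
  # a missing value names the gene and sample
  v3 <- v
  v3[1, 2] <- NA
  em3 <- em
  em3$values[1, 2] <- NA
  expect_error(replicate_average(em3), "g1")
})

test_that("relative_log2_ratio matches the closed form and its invariant", {
  m <- matrix(c(2, 4, 6), nrow = 1, dimnames = list("g1", c("t0", "t1", "t2")))
  r <- relative_log2_ratio(m)
  expect_equal(unname(r[1, ]), c(-1, 0, log2(1.5)))
  expect_equal(unname(round(r[1, 3], 5)), 0.58496)
  # constant gene
  expect_equal(unname(relative_log2_ratio(matrix(2, 1, 3,
    dimnames = list("g", NULL)))[1, ]), rep(0, 3))
  # scale invariance
  expect_equal(relative_log2_ratio(10 * m), relative_log2_ratio(m))
  # per-gene mean of pre-log ratios is exactly one
  withr::with_seed(2, {
    mm <- matrix(stats::rlnorm(60, 5, 1), nrow = 10,
                 dimnames = list(sprintf("g%d", 1:10), NULL))
  })
  rr <- relative_log2_ratio(mm)
  expect_equal(rowMeans(2^rr), rep(1, 10), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(relative_log2_ratio(matrix(c(0, 1), 1)), "undefined")
  # control-referenced mode
  rc <- relative_log2_ratio(m, ref = "control", control = "t0")
  expect_equal(unname(rc[1, ]), c(0, 1, log2(3)))
})

test_that("select_top_genes applies the fold threshold and ranking", {
  m <- matrix(c(0, 0, 0,  2.4, 0, 0,  1, -3, 0, 2.33, 0, 0), nrow = 4,
              byrow = TRUE,
              dimnames = list(c("flat", "up", "down", "edge"), NULL))
  sel <- select_top_genes(m, fold_threshold = 5, n = 10)
  expect_setequal(sel, c("up", "down", "edge"))
  expect_equal(sel[1], "down")                 # |-3| ranks first
  expect_false("flat" %in% select_top_genes(m, fold_threshold = 2, n = 10))
  # raising the threshold never adds genes
  for (f in c(2, 5, 8, 12)) {
    expect_true(all(select_top_genes(m, f, 10) %in%
                      select_top_genes(m, 2, 10)))
  }
  expect_equal(length(select_top_genes(m, 5, 2)), 2)
  # ties broken by gene id
  m2 <- matrix(c(3, 3), nrow = 2, dimnames = list(c("b", "a"), NULL))
  expect_equal(select_top_genes(m2, 2, 2), c("a", "b"))
})

test_that("cluster_genes recovers planted structure deterministically", {
  withr::with_seed(4, {
    blob1 <- matrix(stats::rnorm(50, mean = 3, sd = 0.2), nrow = 10)
    blob2 <- matrix(stats::rnorm(50, mean = -3, sd = 0.2), nrow = 10)
  })
  m <- rbind(blob1, blob2)
  rownames(m) <- sprintf("g%02d", 1:20)
  cl <- cluster_genes(m, k = 2)
  expect_equal(length(unique(cl[1:10])), 1)
  expect_equal(length(unique(cl[11:20])), 1)
  expect_true(cl[1] != cl[20])
  # permutation invariance up to label swap
  perm <- sample(1:20)
  cl_p <- cluster_genes(m[perm, ], k = 2)
  expect_equal(unname(cl_p[rownames(m)] == cl_p[["g01"]]),
               unname(cl == cl[["g01"]]))
  # duplicated rows co-cluster; k = n gives singletons
  m3 <- rbind(m, g21 = m[1, ])
  cl3 <- cluster_genes(m3, k = 3)
  expect_equal(cl3[["g21"]], cl3[["g01"]])
  expect_equal(sort(unname(cluster_genes(m, k = 20))), 1:20)
  expect_error(cluster_genes(m, k = 21), "exceeds")
})
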