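test_that("UPGMA clustering reproduces hand-computed merges", {
  # two identical samples merge first at height 0
  d0 <- matrix(c(0, 0, 5, 0, 0, 5, 5, 5, 0), nrow = 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  cl0 <- upgma_cluster(d0)
  expect_equal(cl0$merge_heights[1], 0)
  expect_equal(sort(cl0$hclust$labels[-cl0$hclust$merge[1, ]]), c("a", "b"))

  # 4-leaf toy: {A,B} at 2, {C,D} at 2, cross distances 6
  d <- matrix(6, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  diag(d) <- 0
  d["A", "B"] <- d["B", "A"] <- 2
  d["C", "D"] <- d["D", "C"] <- 2
  cl <- upgma_cluster(d)
  expect_equal(cl$merge_heights, c(2, 2, 6))
  first_two <- sapply(1:2, function(k)
    paste(sort(cl$hclust$labels[-cl$hclust$merge[k, ]]), collapse = ""))
  expect_setequal(first_two, c("AB", "CD"))

  expect_error(upgma_cluster(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("UPGMA merge heights equal brute-force average pairwise distances", {
  set.seed(13)
  for (r in 1:5) {
    n <- 8
    x <- matrix(stats::rnorm(n * 3), nrow = n,
                dimnames = list(paste0("s", 1:n), NULL))
    d <- as.matrix(stats::dist(x))
    cl <- upgma_cluster(d)
    hc <- cl$hclust
    lab <- hc$labels
    for (k in seq_along(hc$height)) {
      side <- function(v) if (v < 0) -v else hclust_members(hc, v)
      m1 <- lab[side(hc$merge[k, 1])]
      m2 <- lab[side(hc$merge[k, 2])]
      expect_equal(hc$height[k], mean(d[m1, m2, drop = FALSE]),
                   tolerance = 1e-10)
    }
    # cophenetic distances form an ultrametric
    coph <- as.matrix(stats::cophenetic(hc))
    for (i in 1:n) for (j in 1:n) for (k in 1:n) {
      expect_lte(coph[i, j], max(coph[i, k], coph[k, j]) + 1e-12)
    }
    # merge heights are non-decreasing
    expect_true(all(diff(cl$merge_heights) >= -1e-12))
  }
})

test_that("dendrogram sorting places the tighter subtree first", {
  # {E,F} at 1, {A,B} at 2, {C,D} at 4; (EF,CD) at 8; root at 10
  d <- matrix(10, 6, 6, dimnames = list(LETTERS[1:6], LETTERS[1:6]))
  diag(d) <- 0
  d["A", "B"] <- d["B", "A"] <- 2
  d["C", "D"] <- d["D", "C"] <- 4
  d["E", "F"] <- d["F", "E"] <- 1
  for (i in c("C", "D")) for (j in c("E", "F"))
    d[i, j] <- d[j, i] <- 8
  cl <- sort_dendrogram(upgma_cluster(d))
  expect_equal(cl$leaf_order, c("E", "F", "C", "D", "A", "B"))

  # sorting is idempotent and never changes topology or heights
  cl2 <- sort_dendrogram(cl)
  expect_equal(cl2$leaf_order, cl$leaf_order)
  expect_equal(cl2$hclust$merge, cl$hclust$merge)
  expect_equal(cl2$merge_heights, cl$merge_heights)

  # mirror-imaged input (reversed label order) sorts to the same leaf order
  rev_idx <- rev(seq_len(nrow(d)))
  cl_rev <- sort_dendrogram(upgma_cluster(d[rev_idx, rev_idx]))
  expect_equal(cl_rev$leaf_order, cl$leaf_order)
})

test_that("tag adjacency counts nests with neighbouring sleeves", {
  # near-noise-free simulation: each nest's two sleeves cluster together
  cfg <- simulation_config(n_bees = 8, seed = 61, sigma_individual = 0.6,
                           sigma_drift = 0.01, sigma_noise = 0.01)
  sim <- simulate_dataset(cfg)
  tb <- sim$peak_table
  ids <- tb$sample_meta$sample_id[tb$sample_meta$source %in%
                                    c("mark1", "mark2")]
  clr <- clr_transform(quantile_normalize(tb$areas[ids, ]))
  cl <- sort_dendrogram(upgma_cluster(as.matrix(stats::dist(clr))))
  expect_equal(tag_adjacency(cl, tb$sample_meta), 8)

  # single-nest dataset: the only possible order is adjacent
  meta1 <- data.frame(sample_id = c("A_m1", "A_m2"), nest_id = "A",
                      source = c("mark1", "mark2"))
  d1 <- matrix(c(0, 3, 3, 0), 2,
               dimnames = list(meta1$sample_id, meta1$sample_id))
  expect_equal(tag_adjacency(upgma_cluster(d1), meta1), 1)

  # random-permutation baseline: two fixed tags among 2n leaves are adjacent
  # with probability 2/(2n), so the expected count is about 1 for n = 25
  set.seed(71)
  ids <- c(outer(sprintf("N%02d", 1:25), c("_m1", "_m2"), paste0))
  meta <- data.frame(sample_id = ids, nest_id = substr(ids, 1, 3),
                     source = rep(c("mark1", "mark2"), each = 25))
  counts <- replicate(2000, {
    fake <- structure(list(leaf_order = sample(ids)), class = "upgma_clust")
    tag_adjacency(fake, meta)
  })
  expect_lt(abs(mean(counts) - 25 * 2 / 50), 0.15)
})

test_that("heatmap rendering writes the image and a faithful leaf-order TSV", {
  dir <- withr::local_tempdir()
  sim <- simulate_dataset(simulation_config(n_bees = 4, seed = 81))
  tb <- sim$peak_table
  ids <- tb$sample_meta$sample_id[tb$sample_meta$source %in%
                                    c("mark1", "mark2")]
  clr <- clr_transform(quantile_normalize(tb$areas[ids, ]))
  col_cl <- sort_dendrogram(upgma_cluster(as.matrix(stats::dist(clr))))
  row_cl <- sort_dendrogram(upgma_cluster(as.matrix(stats::dist(t(clr)))))
  out <- render_heatmap(t(clr), row_cl, col_cl,
                        file.path(dir, "hm.png"))
  expect_true(file.exists(out$image))
  lo <- utils::read.delim(out$leaf_orders, colClasses = "character")
  expect_equal(lo$row[seq_along(row_cl$leaf_order)], row_cl$leaf_order)
  expect_equal(lo$column[lo$column != ""], col_cl$leaf_order)

  # deterministic TSV bytes on re-render
  out2 <- render_heatmap(t(clr), row_cl, col_cl,
                         file.path(dir, "hm2.png"))
  expect_identical(readLines(out$leaf_orders), readLines(out2$leaf_orders))

  # 2x2 matrix renders without error
  m2 <- matrix(c(1, 2, 3, 4), 2,
               dimnames = list(c("r1", "r2"), c("c1", "c2")))
  cl2 <- upgma_cluster(as.matrix(stats::dist(m2)))
  cl2c <- upgma_cluster(as.matrix(stats::dist(t(m2))))
  expect_no_error(render_heatmap(m2, cl2, cl2c, file.path(dir, "small.png")))

  expect_error(render_heatmap(m2, cl2, cl2c,
                              file.path(dir, "nope", "x.png")),
               "unwritable")
})
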