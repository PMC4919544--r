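# clustering and gene-set intersections

test_that("kmeans_clusters partitions separable point masses perfectly", {
  proto <- matrix(rnorm(6 * 80, 0, 3), 6, 80)
  x <- proto[rep(1:6, each = 10), ]
  rownames(x) <- sprintf("g%03d", 1:60)
  ca <- kmeans_clusters(x, k = 6, seed = 2, n_init = 5)
  expect_equal(ca$withinss, 0, tolerance = 1e-8)
  expect_equal(length(unique(ca$assignment)), 6L)
  # all members of a point mass share a label
  for (b in 1:6) {
    expect_equal(length(unique(ca$assignment[(b - 1) * 10 + 1:10])), 1L)
  }
  # labels renumbered by size: equal sizes here, so all sizes 10
  expect_equal(unname(tabulate(ca$assignment, 6)), rep(10L, 6))
})

test_that("kmeans_clusters recovers planted Gaussian clusters (ARI >= 0.9)", {
  set.seed(67)
  k <- 6; W <- 80; per <- 40; sigma <- 0.5
  cent <- matrix(rnorm(k * W, 0, 3), k, W)
  x <- cent[rep(1:k, each = per), ] +
    matrix(rnorm(k * per * W, 0, sigma), k * per, W)
  rownames(x) <- sprintf("g%03d", seq_len(k * per))
  truth_lab <- rep(1:k, each = per)
  ca <- kmeans_clusters(x, k = 6, seed = 3, n_init = 20)
  expect_gte(adjusted_rand_index(ca$assignment, truth_lab), 0.9)
  # determinism
  ca2 <- kmeans_clusters(x, k = 6, seed = 3, n_init = 20)
  expect_identical(ca$assignment, ca2$assignment)
  expect_identical(ca$centroids, ca2$centroids)
})

test_that("kmeans_clusters applies the mask policy and guards k", {
  set.seed(71)
  vals <- matrix(rnorm(10 * 80), 10, 80,
                 dimnames = list(sprintf("g%02d", 1:10), NULL))
  mask <- matrix(FALSE, 10, 80, dimnames = dimnames(vals))
  mask[1, 1:50] <- TRUE    # > 50% masked -> dropped
  mask[2, 1:10] <- TRUE    # imputed
  m <- tss_matrix(vals, mask, window_spec())
  ca <- kmeans_clusters(m, k = 3, seed = 1, n_init = 3)
  expect_equal(ca$dropped, "g01")
  expect_equal(length(ca$assignment), 9L)
  expect_error(kmeans_clusters(m, k = 20, seed = 1), "usable genes")
})

test_that("hypergeom_p equals exhaustive enumeration for all N <= 12", {
  # closed-form sweep over every consistent configuration
  for (N in 1:12) for (K in 0:N) for (n in 0:N) {
    for (k in max(0, n + K - N):min(K, n)) {
      enum <- 0
      for (j in k:min(K, n)) {
        enum <- enum + choose(K, j) * choose(N - K, n - j)
      }
      expect_equal(hypergeom_p(N, K, n, k), enum / choose(N, n),
                   tolerance = 1e-12)
    }
  }
  # literal draw-enumeration oracle for one configuration
  draws <- combn(12, 4)
  annotated <- 1:5
  overlap3 <- mean(apply(draws, 2, function(d) sum(d %in% annotated) >= 3))
  expect_equal(hypergeom_p(12, 5, 4, 3), overlap3, tolerance = 1e-12)
  expect_equal(hypergeom_p(100, 10, 5, 0), 1.0)
  expect_equal(hypergeom_p(10, 4, 10, 4), 1.0)   # n = N forces full overlap
  expect_error(hypergeom_p(10, 11, 5, 2), "inconsistent")
  expect_error(hypergeom_p(10, 4, 5, 5), "inconsistent")
})

test_that("rate_class_table computes one test per cluster x class", {
  set.seed(73)
  x <- matrix(rnorm(60 * 80), 60, 80,
              dimnames = list(toy_ann$gene_id[rep(1:50, length.out = 60)], NULL))
  rownames(x) <- sprintf("gene%04d", 1:60)
  ann <- data.frame(gene_id = rownames(x), chrom = "chrS",
                    start = seq(0, by = 3000, length.out = 60),
                    end = seq(1000, by = 3000, length.out = 60),
                    strand = "+",
                    rate_class = sample(c("<1", "1-3.9", "4-15.9", "16-50", ">50"),
                                        60, TRUE), stringsAsFactors = FALSE)
  ca <- kmeans_clusters(x, k = 4, seed = 5, n_init = 3)
  tab <- rate_class_table(ca, ann)
  expect_equal(nrow(tab), 4L * 5L)
  # partition conservation: overlaps in a cluster row sum to cluster size
  for (cl in 1:4) {
    expect_equal(sum(tab$overlap[tab$cluster == cl]),
                 tab$cluster_size[tab$cluster == cl][1])
  }
  # every p is a valid upper-tail hypergeometric probability
  expect_true(all(tab$p > 0 & tab$p <= 1))
  # a cluster equal to one class has its smallest p in that class
  ann2 <- ann
  ann2$rate_class <- "<1"
  genes_c1 <- names(ca$assignment)[ca$assignment == 1]
  ann2$rate_class[ann2$gene_id %in% genes_c1] <- ">50"
  tab2 <- rate_class_table(ca, ann2)
  row1 <- tab2[tab2$cluster == 1, ]
  expect_equal(row1$rate_class[which.min(row1$p)], ">50")
})

test_that("venn_sets produces a true partition with exact set algebra", {
  sets <- list(A = c("g1", "g2", "g3"), B = c("g2", "g3", "g4"))
  v <- venn_sets(sets)
  expect_setequal(v$common, c("g2", "g3"))
  expect_setequal(v$unique$A, "g1")
  expect_setequal(v$unique$B, "g4")
  # identical tables
  v_same <- venn_sets(list(A = c("x", "y"), B = c("x", "y")))
  expect_setequal(v_same$common, c("x", "y"))
  expect_equal(lengths(v_same$unique), c(A = 0L, B = 0L))
  # disjoint sets
  v_dis <- venn_sets(list(A = "x", B = "y"))
  expect_equal(length(v_dis$common), 0L)
  expect_error(venn_sets(sets, universe = c("g1", "g2", "g3")), "universe")
})

test_that("4-way venn regions match a brute-force membership enumeration", {
  set.seed(79)
  universe <- sprintf("g%03d", 1:200)
  sets <- lapply(setNames(1:4, c("w", "x", "y", "z")),
                 function(i) sample(universe, 60))
  v <- venn_sets(sets, universe = universe)
  # regions are pairwise disjoint and union to the union of the sets
  all_region_genes <- unlist(v$regions, use.names = FALSE)
  expect_false(anyDuplicated(all_region_genes) > 0)
  expect_setequal(all_region_genes, unique(unlist(sets)))
  # brute-force pattern of every gene
  for (gname in sample(all_region_genes, 25)) {
    pattern <- paste(names(sets)[vapply(sets, function(s) gname %in% s,
                                        logical(1))], collapse = "&")
    expect_true(gname %in% v$regions[[pattern]])
  }
})
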