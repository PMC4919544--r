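# generators: determinism, planted ground truth, degenerate inputs

test_that("make_toy_genome handles the empty case and rejects infeasible input", {
  g <- make_toy_genome(0, 1e4, seed = 3)
  expect_equal(nrow(g$annotation), 0L)
  expect_equal(unname(g$chrom_sizes), 10000L)
  expect_error(make_toy_genome(100, 5e4, min_gap = 2000, seed = 1),
               "cannot place")
})

test_that("make_toy_genome is deterministic and respects min_gap", {
  a <- make_toy_genome(50, 3e5, min_gap = 2000, seed = 1)
  b <- make_toy_genome(50, 3e5, min_gap = 2000, seed = 1)
  expect_identical(a, b)
  ann <- a$annotation
  # exhaustive pairwise gap check
  for (i in seq_len(nrow(ann) - 1)) {
    for (j in (i + 1):nrow(ann)) {
      gap <- max(ann$start[i], ann$start[j]) - min(ann$end[i], ann$end[j])
      expect_gte(gap, 2000)
    }
  }
  expect_setequal(unique(ann$strand), c("+", "-"))
  expect_true(all(ann$rate_class %in% c("<1", "1-3.9", "4-15.9", "16-50", ">50")))
  expect_false(anyDuplicated(ann$gene_id) > 0)
})

test_that("simulate_mnase_fragments: null delta gives equal expectations", {
  tr <- synthetic_truth(toy_ann)   # delta all zero
  wt <- simulate_mnase_fragments(toy_ann, tr, toy_sizes, 4e4, "WT", seed = 2)
  mu <- simulate_mnase_fragments(toy_ann, tr, toy_sizes, 4e4, "mutant", seed = 3)
  cwt <- rpm_normalize(extend_and_pile(wt, toy_sizes, 148))
  cmu <- rpm_normalize(extend_and_pile(mu, toy_sizes, 148))
  d <- difference_track(cmu, cwt)
  v <- unlist(d$values)
  # mean |delta| small relative to the mean WT signal
  expect_lt(mean(abs(v)), 0.25 * mean(unlist(cwt$values)))
  expect_error(simulate_mnase_fragments(toy_ann, tr, toy_sizes, 0, "WT"),
               "n_fragments")
})

test_that("simulate_mnase_fragments recovers a planted 2x occupancy gain", {
  delta <- matrix(0, nrow(toy_ann), toy_spec$n_windows)
  gain_w <- which(toy_mid >= -140 & toy_mid < 300)
  gain_genes <- c(5L, 20L, 40L)
  delta[gain_genes, gain_w] <- 1
  tr <- synthetic_truth(toy_ann, occupancy_delta = delta)
  wt <- simulate_mnase_fragments(toy_ann, tr, toy_sizes, 1e5, "WT", seed = 4)
  mu <- simulate_mnase_fragments(toy_ann, tr, toy_sizes, 1e5, "mutant", seed = 5)
  mwt <- tss_window_matrix(rpm_normalize(extend_and_pile(wt, toy_sizes, 148)),
                           toy_ann, toy_spec)
  mmu <- tss_window_matrix(rpm_normalize(extend_and_pile(mu, toy_sizes, 148)),
                           toy_ann, toy_spec)
  ids <- toy_ann$gene_id[gain_genes]
  ratio <- mean_profile(mmu, ids) / mean_profile(mwt, ids)
  plus1 <- toy_mid >= 0 & toy_mid < 150
  expect_equal(mean(ratio[plus1]), 2, tolerance = 0.1)
  # determinism
  wt2 <- simulate_mnase_fragments(toy_ann, tr, toy_sizes, 1e5, "WT", seed = 4)
  expect_identical(wt, wt2)
})

test_that("simulate_spikein_chip labels partition reads and is deterministic", {
  tr <- synthetic_truth(toy_ann, scaling_factor = 2, orthologous_fraction = 0.08)
  sp <- simulate_spikein_chip(toy_ann, tr, toy_sizes, 2e4, 2e4, seed = 6)
  for (lib in sp) {
    expect_true(all(lib$species %in% c("target", "reference", "orthologous")))
    expect_equal(sum(lib$species == "target") + sum(lib$species == "reference") +
                   sum(lib$species == "orthologous"), nrow(lib))
  }
  expect_equal(mean(sp$chip$species == "orthologous"), 0.08, tolerance = 0.25)
  sp2 <- simulate_spikein_chip(toy_ann, tr, toy_sizes, 2e4, 2e4, seed = 6)
  expect_identical(sp, sp2)
})

test_that("identity spike-in configuration gives calibration factor ~ 1", {
  tr <- synthetic_truth(toy_ann, scaling_factor = 1, orthologous_fraction = 0,
                        mixing_ratio = 1)
  sp <- simulate_spikein_chip(toy_ann, tr, toy_sizes, 5e4, 5e4, seed = 7)
  f <- calibration_factor(partition_species(sp$chip, sp$input))
  expect_equal(f, 1, tolerance = 0.05)
})

test_that("simulate_rite_reads: no duplicates when dup_rate = 0, f = 0.5 symmetry", {
  tr <- synthetic_truth(toy_ann)   # f = 0.5 everywhere
  rr <- simulate_rite_reads(toy_ann, tr, toy_sizes, 2e4, dup_rate = 0, seed = 8)
  expect_equal(rr$truth$n_duplicates, 0L)
  expect_false(any(rr$truth$reads$is_duplicate))
  # genome-wide Flag:V5 ratio within a generous binomial band
  n_flag <- sum(rr$alignments$tag == "Flag")
  expect_equal(n_flag / nrow(rr$alignments), 0.5, tolerance = 0.02)
  # raw read layout: 6 random + 4 fixed + insert
  expect_true(all(substr(rr$fastq$sequence, 7, 10) == "CTGA"))
  expect_true(all(nchar(rr$fastq$sequence) == 50))
  expect_error(simulate_rite_reads(toy_ann, tr, toy_sizes, 100,
                                   fixed_barcode = "CTG"), "fixed_barcode")
  rr2 <- simulate_rite_reads(toy_ann, tr, toy_sizes, 2e4, dup_rate = 0, seed = 8)
  expect_identical(rr, rr2)
})

test_that("simulate_rite_reads recovers planted promoter/body new fractions", {
  tr <- synthetic_truth(toy_ann, promoter_new_fraction = 0.8,
                        body_new_fraction = 0.2)
  rr <- simulate_rite_reads(toy_ann, tr, toy_sizes, 1e5, dup_rate = 0, seed = 9)
  aln <- rr$alignments
  wtc <- window_tag_counts(aln[aln$tag == "Flag", ], aln[aln$tag == "V5", ],
                           toy_ann, toy_sizes, toy_spec)
  pf <- mean_profile(wtc$flag)
  pv <- mean_profile(wtc$v5)
  prom <- toy_mid >= -300 & toy_mid < 0
  body <- toy_mid >= 0
  expect_equal(sum(pf[prom]) / sum(pv[prom]), 4, tolerance = 0.15)
  expect_equal(sum(pf[body]) / sum(pv[body]), 0.25, tolerance = 0.15)
})

test_that("simulate_stranded_counts: determinism, errors, planted means", {
  de <- data.frame(gene_id = toy_ann$gene_id[1:5], strand_class = "sense",
                   log2fc = 2)
  tr <- synthetic_truth(toy_ann, de_table = de)
  a <- simulate_stranded_counts(toy_ann, tr, 3, 0.05, seed = 10)
  b <- simulate_stranded_counts(toy_ann, tr, 3, 0.05, seed = 10)
  expect_identical(a, b)
  expect_error(simulate_stranded_counts(toy_ann, tr, 3, dispersion = 0),
               "dispersion")
  expect_error(simulate_stranded_counts(toy_ann, tr, 1, 0.05), "n_replicates")
  expect_identical(dim(a$sense$wt), c(nrow(toy_ann), 3L))
  # planted genes boosted ~4x in the mutant, others not
  r <- rowMeans(a$sense$mut) / pmax(rowMeans(a$sense$wt), 1)
  expect_gt(min(r[1:5]), 2)
  expect_lt(mean(r[-(1:5)]), 1.5)
})

test_that("disjointness of planted DE sets is enforced", {
  de <- data.frame(gene_id = rep(toy_ann$gene_id[1], 2),
                   strand_class = "sense", log2fc = c(1, -1))
  expect_error(synthetic_truth(toy_ann, de_table = de), "disjoint")
})
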