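# spike-in calibration: species tallies, the factor formula, track scaling,
# fold enrichment with zero substitution, bidirectional Poisson q

test_that("partition_species tallies labels and excludes orthologous reads", {
  mk <- function(sp) data.frame(chrom = "c", start = seq_along(sp), strand = "+",
                                mapq = 60, species = sp, stringsAsFactors = FALSE)
  chip <- mk(rep(c("target", "reference", "orthologous"), c(100, 50, 10)))
  input <- mk(rep(c("target", "reference"), c(80, 40)))
  cc <- partition_species(chip, input)
  expect_equal(cc$chip_sc, 100)
  expect_equal(cc$chip_cg, 50)
  expect_equal(cc$input_sc, 80)
  expect_equal(cc$input_cg, 40)
  # zero reference reads -> factor undefined
  expect_error(partition_species(mk(rep("target", 5)), input), "positive")
  expect_error(partition_species(mk(c("target", NA)), input), "species")
  expect_error(partition_species(mk(c("target", "mouse")), input), "unknown species")
})

test_that("species tallies match a brute-force groupby on random records", {
  set.seed(13)
  sp_chip <- sample(c("target", "reference", "orthologous"), 1e4, TRUE,
                    prob = c(0.6, 0.3, 0.1))
  sp_in <- sample(c("target", "reference", "orthologous"), 1e4, TRUE,
                  prob = c(0.5, 0.4, 0.1))
  mk <- function(sp) data.frame(chrom = "c", start = 1, strand = "+", mapq = 60,
                                species = sp, stringsAsFactors = FALSE)
  cc <- partition_species(mk(sp_chip), mk(sp_in))
  expect_equal(cc$chip_sc, as.numeric(table(sp_chip)[["target"]]))
  expect_equal(cc$chip_cg, as.numeric(table(sp_chip)[["reference"]]))
  expect_equal(cc$input_sc, as.numeric(table(sp_in)[["target"]]))
  expect_equal(cc$input_cg, as.numeric(table(sp_in)[["reference"]]))
})

test_that("calibration_factor implements (Input_Cg x ChIP_Sc)/(Input_Sc x ChIP_Cg)", {
  expect_equal(calibration_factor(calibration_counts(5, 5, 5, 5)), 1.0)
  cc <- calibration_counts(chip_sc = 8e6, chip_cg = 1e6,
                           input_sc = 8e6, input_cg = 2e6)
  expect_equal(calibration_factor(cc), 2.0)
  # swapping ChIP and input roles inverts the factor
  swapped <- calibration_counts(chip_sc = 8e6, chip_cg = 2e6,
                                input_sc = 8e6, input_cg = 1e6)
  expect_equal(calibration_factor(swapped), 1 / 2.0)
  # scale invariance
  for (c_ in c(2, 10, 1000)) {
    scaled <- calibration_counts(8e6 * c_, 1e6 * c_, 8e6 * c_, 2e6 * c_)
    expect_equal(calibration_factor(scaled), 2.0)
  }
  expect_error(calibration_counts(0, 1, 1, 1), "positive")
})

test_that("calibrate_track scales rpm tracks and guards preconditions", {
  sizes <- c(chrT = 10L)
  tr <- coverage_track(list(chrT = 1:10 / 2), sizes, normalization = "rpm",
                       total_reads = 10)
  expect_equal(calibrate_track(tr, 1)$values$chrT, tr$values$chrT)
  out <- calibrate_track(tr, 2)
  expect_equal(out$values$chrT, 1:10)
  expect_equal(out$normalization, "calibrated")
  expect_error(calibrate_track(tr, 0), "factor")
  raw <- coverage_track(list(chrT = 1:10 / 2), sizes, total_reads = 10)
  expect_error(calibrate_track(raw, 2), "rpm")
})

test_that("fold_enrichment applies the zero->1 substitution", {
  sizes <- c(chrT = 4L)
  mk <- function(v) coverage_track(list(chrT = v), sizes, total_reads = 1)
  same <- mk(c(2, 3, 4, 5))
  expect_equal(fold_enrichment(same, same)$values$chrT, rep(1, 4))
  chip <- mk(c(0, 10, 0, 3))
  ctrl <- mk(c(5, 0, 0, 3))
  expect_equal(fold_enrichment(chip, ctrl)$values$chrT, c(1 / 5, 10, 1, 1))
  # element-wise oracle on random bins
  set.seed(17)
  a <- round(runif(1000) * 4); b <- round(runif(1000) * 4)
  sizes2 <- c(chrT = 1000L)
  got <- fold_enrichment(coverage_track(list(chrT = a), sizes2, total_reads = 1),
                         coverage_track(list(chrT = b), sizes2, total_reads = 1))
  oracle <- ifelse(a == 0, 1, a) / ifelse(b == 0, 1, b)
  expect_identical(got$values$chrT, oracle)
})

test_that("bidirectional_q matches an exact Poisson oracle with hand BH", {
  obs <- c(30, 5, 1, 8, 0)
  lam <- c(5, 5, 5, 8, 4)
  got <- bidirectional_q(obs, lam)
  # independent oracle: tail sums of the Poisson pmf, then step-up BH by hand
  sf <- function(k, l) sum(exp(-l) * l^(k:150) / factorial(k:150))
  cdf <- function(k, l) sum(exp(-l) * l^(0:k) / factorial(0:k))
  p_enr <- mapply(sf, obs, lam)
  p_dep <- mapply(cdf, obs, lam)
  expect_equal(got$p_enriched, p_enr, tolerance = 1e-10)
  expect_equal(got$p_depleted, p_dep, tolerance = 1e-10)
  hand_bh <- function(p) {
    n <- length(p); o <- order(p, decreasing = TRUE)
    ro <- order(o)
    pmin(1, cummin(p[o] * n / (n:1)))[ro]
  }
  expect_equal(got$q_enriched, hand_bh(p_enr), tolerance = 1e-12)
  expect_equal(got$q_depleted, hand_bh(p_dep), tolerance = 1e-12)
  expect_equal(got$direction[1], "enriched")   # obs 30 vs lambda 5
  expect_equal(got$direction[3], "depleted")   # obs 1 vs lambda 5
  # reversing roles: enrichment of chip-vs-control mirrors depletion
  expect_error(bidirectional_q(c(-1, 2), c(1, 1)), "negative")
  expect_error(bidirectional_q(c(1, 2), c(1, 0)), "positive")
})

test_that("null bins (obs = lambda) report the enriched tie direction", {
  got <- bidirectional_q(rep(5, 10), rep(5, 10))
  expect_true(all(got$direction == "enriched"))
  expect_true(all(got$q_enriched > 0.5))
})

test_that("end-to-end spike-in calibration recovers the true global scaling", {
  trA <- synthetic_truth(toy_ann, scaling_factor = 1)
  trB <- synthetic_truth(toy_ann, scaling_factor = 2)
  spA <- simulate_spikein_chip(toy_ann, trA, toy_sizes, 8e4, 8e4, seed = 31)
  spB <- simulate_spikein_chip(toy_ann, trB, toy_sizes, 8e4, 8e4, seed = 32)
  pile <- function(x) {
    rpm_normalize(extend_and_pile(x$chip[x$chip$species == "target", ],
                                  toy_sizes, 200, bin_size = 50))
  }
  ta <- pile(spA); tb <- pile(spB)
  fa <- calibration_factor(partition_species(spA$chip, spA$input))
  fb <- calibration_factor(partition_species(spB$chip, spB$input))
  ca <- calibrate_track(ta, fa); cb <- calibrate_track(tb, fb)
  va <- unlist(ca$values); vb <- unlist(cb$values)
  hi <- unlist(ta$values) > quantile(unlist(ta$values), 0.5)
  expect_equal(median(vb[hi] / va[hi]), 2, tolerance = 0.05)
  # rpm alone masks the change
  expect_equal(median(unlist(tb$values)[hi] / unlist(ta$values)[hi]), 1,
               tolerance = 0.1)
})
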