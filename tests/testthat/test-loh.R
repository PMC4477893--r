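test_that("expected BAF under monoallelic loss follows the mixture algebra", {
  expect_equal(expected_baf_under_loh(0), c(lower = 0.5, upper = 0.5))
  expect_equal(expected_baf_under_loh(1), c(lower = 0, upper = 1))
  e <- expected_baf_under_loh(0.65)
  expect_equal(unname(e["lower"]), 0.2593, tolerance = 1e-3)
  expect_equal(unname(e["upper"]), 0.7407, tolerance = 1e-3)
  expect_error(expected_baf_under_loh(1.5), "purity")
  # components sum to 1 and are monotone in purity
  ts <- seq(0, 1, by = 0.05)
  bands <- vapply(ts, expected_baf_under_loh, numeric(2))
  expect_equal(colSums(bands), rep(1, length(ts)))
  expect_true(all(diff(bands["lower", ]) <= 0))
  expect_true(all(diff(bands["upper", ]) >= 0))
})

test_that("purity estimation inverts the expected BAF exactly", {
  for (t in seq(0, 1, by = 0.05)) {
    b <- expected_baf_under_loh(t)[["lower"]]
    expect_equal(estimate_purity_from_baf(rep(b, 25)), t,
                 tolerance = 1e-12)
  }
  expect_equal(estimate_purity_from_baf(rep(0.5, 30)), 0)
  expect_error(estimate_purity_from_baf(rep(0.3, 10)), "at least 20")
  expect_error(estimate_purity_from_baf(rep(0.7, 30)), "\\[0, 0.5\\]")
})

test_that("purity is recovered from a simulated LOH arm", {
  arms14 <- default_arms()
  arms14 <- arms14[arms14$arm %in% c("14p", "14q"), ]
  sim <- simulate_loh_genome(purity = 0.65, n_snps_per_arm = 2000,
                             depth_mean = 45, loh_arm = "14q",
                             arms = arms14, seed = 21)
  summ <- arm_summaries(sim)
  est <- summ$purity_estimate[summ$arm == "14q"]
  expect_true(summ$loh_call[summ$arm == "14q"])
  expect_lt(abs(est - 0.65), 0.05)
})

test_that("arm summaries call exactly the simulated LOH arm", {
  sim <- simulate_loh_genome(purity = 0.65, n_snps_per_arm = 300, seed = 3)
  summ <- arm_summaries(sim)
  expect_identical(summ$arm[summ$loh_call %in% TRUE], "14q")
  # normalised depth ratio of the lost arm ~ (2 - t) / 2
  expect_lt(abs(summ$depth_ratio[summ$arm == "14q"] - 0.675), 0.05)
  expect_true(all(abs(summ$depth_ratio[summ$arm != "14q"] - 1) < 0.1))
  # purity-aware cutoff mode agrees here
  summ2 <- arm_summaries(sim, purity = 0.65)
  expect_identical(summ2$arm[summ2$loh_call %in% TRUE], "14q")

  null <- simulate_loh_genome(purity = 0, n_snps_per_arm = 300, seed = 4)
  nsum <- arm_summaries(null)
  expect_false(any(nsum$loh_call, na.rm = TRUE))
  expect_true(all(nsum$median_folded_baf > 0.4))
})

test_that("folding makes summaries invariant to allele swaps", {
  sim <- simulate_loh_genome(purity = 0.6, n_snps_per_arm = 200, seed = 5)
  swapped <- sim
  flip <- seq(1, nrow(sim), by = 2)
  swapped$tumour_alt[flip] <- sim$tumour_depth[flip] - sim$tumour_alt[flip]
  swapped$control_alt[flip] <- sim$control_depth[flip] -
    sim$control_alt[flip]
  a <- arm_summaries(sim)
  b <- arm_summaries(swapped)
  expect_equal(a$median_folded_baf, b$median_folded_baf, tolerance = 1e-12)
  expect_identical(a$loh_call, b$loh_call)
})

test_that("arm bookkeeping: assignment, empty arms, input validation", {
  arms <- default_arms()
  snps <- data.frame(chrom = c("chr1", "chr1", "chr9"),
                     pos = c(5e7, 1.5e8, 1),
                     tumour_alt = 10L, tumour_depth = 20L,
                     control_alt = 10L, control_depth = 20L)
  got <- assign_arms(snps, arms)
  expect_identical(got$arm, c("1p", "1q", "9p"))
  summ <- arm_summaries(transform(got[1, ], arm = "1p"))
  expect_identical(summ$n_snps, 1L)
  shallow <- transform(got, tumour_depth = 5L, tumour_alt = 2L)
  esumm <- arm_summaries(shallow)
  expect_true(all(esumm$n_snps == 0L))
  expect_true(all(is.na(esumm$loh_call)))
  bad <- transform(got, tumour_alt = 100L)
  expect_error(arm_summaries(bad), "exceed")
})
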