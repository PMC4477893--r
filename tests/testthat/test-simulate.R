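test_that("generators are fully deterministic given a seed", {
  expect_identical(simulate_variant_table(seed = 9),
                   simulate_variant_table(seed = 9))
  expect_identical(simulate_loh_genome(n_snps_per_arm = 50, seed = 9),
                   simulate_loh_genome(n_snps_per_arm = 50, seed = 9))
  expect_identical(simulate_screen_panel(seed = 9),
                   simulate_screen_panel(seed = 9))
  expect_identical(simulate_methylation(n_background = 50, seed = 9),
                   simulate_methylation(n_background = 50, seed = 9))
  expect_identical(simulate_zf_protein(seed = 9),
                   simulate_zf_protein(seed = 9))
  # and differ across seeds
  expect_false(identical(simulate_screen_panel(seed = 9),
                         simulate_screen_panel(seed = 10)))
})

test_that("variant generator encodes the stated allele model", {
  v <- simulate_variant_table(n_founder = 500, n_subclonal = 200,
                              n_germline_het = 200, purity = 0.6, seed = 2)
  expect_identical(table(v$truth)[["founder"]], 500L)
  validate_variants(v[names(v) != "truth"])
  somatic <- v$truth != "germline"
  expect_true(all(v$control_alt_count[somatic] == 0))
  expect_true(all(v$known_snp_id[somatic] == ""))
  expect_true(all(v$known_snp_id[!somatic] != ""))

  # purity 1, deep coverage: founder fractions concentrate at 1/2
  deep <- simulate_variant_table(n_founder = 200, n_subclonal = 0,
                                 n_germline_het = 0, purity = 1,
                                 depth_mean = 1000, seed = 3)
  frac <- (deep$tumour_alt_fwd + deep$tumour_alt_rev) / deep$tumour_depth
  expect_lt(max(abs(frac - 0.5)), 0.08)
  expect_lt(abs(mean(frac) - 0.5), 0.005)

  none <- simulate_variant_table(n_founder = 0, n_subclonal = 5,
                                 n_germline_het = 5, seed = 4)
  expect_false("founder" %in% none$truth)

  nb <- simulate_variant_table(n_founder = 50, depth_model =
                                 "negative-binomial", seed = 5)
  expect_gt(var(nb$tumour_depth), var(v$tumour_depth))
})

test_that("screen generator honours MAFs and enrichment flags", {
  zero <- simulate_screen_panel(mafs = rep(0, 10), seed = 6)
  expect_true(all(zero$carriers == 0))
  enr <- simulate_screen_panel(enriched = 1, seed = 7)
  expect_true(enr$truth_enriched[1])
  expect_false(any(enr$truth_enriched[-1]))
  expect_error(simulate_screen_panel(mafs = c(0.6)), "mafs")
})

test_that("LOH generator scales depth and BAF on the lost arm only", {
  sim <- simulate_loh_genome(purity = 0.65, n_snps_per_arm = 400, seed = 8)
  truth <- attr(sim, "truth")
  expect_identical(truth$loh_arm, "14q")
  on_loh <- sim$arm == "14q"
  baf <- sim$tumour_alt / sim$tumour_depth
  expect_lt(median(pmin(baf[on_loh], 1 - baf[on_loh])), 0.32)
  expect_gt(median(pmin(baf[!on_loh], 1 - baf[!on_loh])), 0.4)
  expect_lt(mean(sim$tumour_depth[on_loh]),
            0.75 * mean(sim$tumour_depth[!on_loh]))
})

test_that("planted zinc fingers include the published motifs", {
  prot <- simulate_zf_protein(n_fingers = 4, seed = 10)
  expect_identical(prot$fingers$motif_seq[1:2],
                   unique(znf407_zinc_fingers()$motif_seq))
  found <- scan_c2h2(prot$sequence)
  expect_identical(found$start, prot$fingers$start)
  ann <- map_variants_to_fingers(prot$sequence, prot$variants[, 1:3])
  expect_true(all(ann$in_finger))
  expect_identical(ann$offset_in_motif, prot$variants$offset_in_motif)
})
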