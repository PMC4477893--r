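test_that("founder threshold reproduces the published boundaries", {
  p <- founder_params(purity = 0.6, inclusion = 0.95)
  expect_identical(founder_threshold(13, p), 1L)
  expect_identical(founder_threshold(14, p), 2L)
  expect_identical(founder_threshold(28, p), 5L)
  expect_identical(founder_threshold(33, p), 6L)
  expect_identical(founder_threshold(37, p), 7L)
  # derived boundaries (brute-force oracle): 4 is first reached at n = 24
  expect_identical(founder_threshold(24, p), 4L)
  expect_identical(founder_threshold(24, p), oracle_threshold(24, 0.3))
  # fallback floor at tiny coverage: no k >= 1 reaches 95% tail mass
  expect_identical(founder_threshold(1, p), 1L)
  expect_identical(founder_threshold(5, p), 1L)
})

test_that("founder model parameters are validated", {
  expect_error(founder_params(purity = 0), "purity")
  expect_error(founder_params(purity = 1.2), "purity")
  expect_error(founder_params(inclusion = 1), "inclusion")
  expect_error(founder_params(inclusion = 0), "inclusion")
  expect_error(founder_params(het_factor = 0), "het_factor")
  expect_error(founder_threshold(0), "coverage")
  expect_error(founder_threshold(2.5), "coverage")
  # hemizygous mode: factor 1 doubles the success probability
  hemi <- founder_params(purity = 0.6, het_factor = 1)
  expect_gte(founder_threshold(40, hemi), founder_threshold(40))
})

test_that("threshold table covers a range with the published jumps", {
  tab <- build_threshold_table(10, 40)
  expect_identical(tab$n, 10:40)
  expect_identical(tab$k[tab$n == 13], 1L)
  expect_identical(tab$k[tab$n == 14], 2L)
  expect_identical(tab$k[tab$n == 28], 5L)
  expect_true(all(diff(tab$k) >= 0))
  one <- build_threshold_table(5, 5)
  expect_identical(one$n, 5L)
  expect_identical(one$k, 1L)
  expect_error(build_threshold_table(10, 9), "n_min")
})

test_that("thresholds are monotone and honour the inclusion guarantee", {
  p <- founder_params()
  k <- founder_threshold(1:500, p)
  expect_true(all(diff(k) >= 0))
  for (n in which(k > 1)) {
    tail_k <- pbinom(k[n] - 1, n, p$q, lower.tail = FALSE)
    tail_k1 <- pbinom(k[n], n, p$q, lower.tail = FALSE)
    expect_gte(tail_k, p$inclusion)
    expect_lt(tail_k1, p$inclusion)
  }
})

test_that("classification matches the threshold and rejects bad input", {
  expect_true(classify_founder(14, 53))   # KIT driver read support
  expect_identical(founder_threshold(53), 11L)
  expect_true(classify_founder(8, 37))    # boundary: k(37) = 7
  expect_false(classify_founder(6, 37))
  expect_false(classify_founder(0, 50))
  expect_error(classify_founder(10, 5), "exceeds coverage")
  expect_error(classify_founder(-1, 5), "alt_count")
})

test_that("SNV founder counting handles fixtures, empty and weak rows", {
  cand <- founder_candidates()
  n <- count_founder_snvs(cand)
  expect_identical(as.integer(n), 12L)
  expect_true(all(attr(n, "pass")))  # the frameshift deletion passes too
  expect_identical(as.integer(count_founder_snvs(cand[0, ])), 0L)
  weak <- data.frame(gene = "X", alt_count = 1, coverage = 100,
                     variant_class = "SNV")
  expect_identical(as.integer(count_founder_snvs(weak)), 0L)
  bad <- data.frame(gene = "BAD1", alt_count = 10, coverage = 5,
                    variant_class = "SNV")
  expect_error(count_founder_snvs(bad), "BAD1")
})

test_that("designed sensitivity holds for direct binomial draws", {
  # alt ~ Binomial(n, 0.3) with n uniform in 20..60: the designed 95%
  # inclusion must hold up to Monte-Carlo error
  withr::with_seed(7, {
    n <- sample(20:60, 10000, replace = TRUE)
    alt <- rbinom(10000, n, 0.3)
    sens <- mean(classify_founder(pmax(alt, 0), n))
    expect_gte(sens, 0.945)
  })
})
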