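test_that("reference-anchor normalisation is linear, clipped and scale-free", {
  expect_equal(normalize_probe(100, 100, 1000), 0)
  expect_equal(normalize_probe(1000, 100, 1000), 1)
  expect_equal(normalize_probe(550, 100, 1000), 0.5)
  expect_equal(normalize_probe(c(0, 5000), 100, 1000), c(0, 1))  # clipping
  expect_error(normalize_probe(5, 10, 10), "ref_high > ref_low")
  expect_error(normalize_probe(-1, 0, 10), "non-negative")
  # invariant under common positive rescaling, monotone in the raw value
  raw <- seq(0, 2000, by = 50)
  a <- normalize_probe(raw, 100, 1000)
  b <- normalize_probe(raw * 3.7, 370, 3700)
  expect_equal(a, b, tolerance = 1e-12)
  expect_true(all(diff(a) >= 0))
  # beta-transform alternative stays in [0, 1)
  bv <- beta_from_intensities(c(0, 500, 5000), c(500, 500, 0))
  expect_true(all(bv >= 0 & bv < 1))
  expect_lt(bv[1], bv[2])
})

test_that("matrix normalisation uses per-probe anchors", {
  m <- matrix(c(100, 1000, 20, 40), nrow = 2, byrow = TRUE,
              dimnames = list(c("p1", "p2"), c("s1", "s2")))
  ref <- data.frame(probe_id = c("p1", "p2"), ref_low = c(100, 20),
                    ref_high = c(1000, 60))
  norm <- normalize_matrix(m, ref)
  expect_equal(norm["p1", ], c(s1 = 0, s2 = 1))
  expect_equal(norm["p2", ], c(s1 = 0, s2 = 0.5))
  expect_error(normalize_matrix(m, ref[1, ]), "p2")
})

test_that("variance filter retains exactly the planted variable probes", {
  m <- matrix(0.3, nrow = 3, ncol = 4,
              dimnames = list(paste0("p", 1:3), paste0("s", 1:4)))
  m[2, ] <- c(0, 1, 0, 1)     # variance 1/3 > 0.1
  expect_identical(variance_filter(m), "p2")
  two <- matrix(c(0, 1), 1, 2, dimnames = list("p1", c("a", "b")))
  expect_identical(variance_filter(two), "p1")  # var({0,1}) = 0.5
  expect_error(variance_filter(m[, 1, drop = FALSE]), "fewer than 2")

  sim <- simulate_methylation(group_means = c(0.9, 0.1),
                              n_informative = 300, n_background = 9700,
                              seed = 31)
  keep <- variance_filter(sim$matrix, threshold = 0.1)
  expect_setequal(keep, sim$truth$informative_probes)

  flat <- simulate_methylation(n_informative = 0, n_background = 1000,
                               seed = 32)
  expect_length(variance_filter(flat$matrix, threshold = 0.1), 0)
})

test_that("correlation-distance clustering behaves on edge cases", {
  base <- matrix(runif(40), nrow = 10)
  m <- cbind(base[, 1], base[, 1], base[, 2], 1 - base[, 2])
  colnames(m) <- c("a", "a2", "b", "negb")
  rownames(m) <- paste0("p", 1:10)
  cl <- cluster_samples(m)
  d <- as.matrix(cl$dist)
  expect_equal(d["a", "a2"], 0, tolerance = 1e-12)
  expect_equal(d["b", "negb"], 2, tolerance = 1e-12)
  expect_true(all(abs(d - t(d)) < 1e-12))
  expect_true(all(diff(cl$hclust$height) >= -1e-12))
  # the identical pair merges first
  first <- sort(abs(cl$hclust$merge[1, ]))
  expect_identical(colnames(m)[first], c("a", "a2"))

  degenerate <- m
  degenerate[, 2] <- 0.5
  expect_error(cluster_samples(degenerate), "a2")
})

test_that("two-group structure is recovered and is order-invariant", {
  sim <- simulate_methylation(seed = 33)
  cl <- cluster_samples(sim$matrix)
  labels <- cut_clusters(cl, 2)
  expect_equal(adjusted_rand_index(labels, sim$truth$groups), 1)
  # sample permutation changes nothing but leaf order
  perm <- sample(ncol(sim$matrix))
  cl2 <- cluster_samples(sim$matrix[, perm])
  labels2 <- cut_clusters(cl2, 2)
  expect_equal(adjusted_rand_index(labels2[colnames(sim$matrix)], labels), 1)
})

test_that("dendrograms export to Newick with all sample leaves", {
  sim <- simulate_methylation(group_sizes = c(4, 4), n_informative = 50,
                              n_background = 100, seed = 34)
  cl <- cluster_samples(sim$matrix)
  path <- withr::local_tempfile(fileext = ".nwk")
  write_dendrogram_newick(cl, path)
  tree <- ape::read.tree(path)
  expect_setequal(tree$tip.label, colnames(sim$matrix))
})
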