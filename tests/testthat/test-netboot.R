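test_that("bootstrap resampling hits its depth exactly", {
  m <- matrix(c(100, 0, 50, 50), 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  out <- bootstrap_subsample(m, 10000, seed = 4)
  expect_true(all(colSums(out) == 10000))
  ## a single-genus sample stays single-genus
  expect_equal(out["g1", "s1"], 10000)
  ## 50/50 within the binomial 3-sigma band
  expect_lt(abs(out["g1", "s2"] - 5000), 3 * sqrt(2500))
  ## determinism
  expect_identical(out, bootstrap_subsample(m, 10000, seed = 4))
  expect_false(identical(out, bootstrap_subsample(m, 10000, seed = 5)))
  m0 <- m; m0[, 2] <- 0
  expect_error(bootstrap_subsample(m0, 100), "empty sample")
})

test_that("gower-krzanowski decomposition matches the line example", {
  ## points {0,1} and {10,11}: T = 101, W = 1, B = 100
  x <- c(0, 1, 10, 11)
  d <- as.matrix(dist(x))
  dec <- group_distance_decomposition(d, c("g1", "g1", "g2", "g2"))
  expect_equal(dec$T, 101)
  expect_equal(dec$W, 1)
  expect_equal(dec$B, 100)
  ## equals the classical between-group sum of squares on coordinates
  expect_equal(dec$B, 2 * (0.5 - 5.5)^2 + 2 * (10.5 - 5.5)^2)
  ## identical points and single-group edge cases
  dec0 <- group_distance_decomposition(matrix(0, 3, 3), rep("g", 3))
  expect_equal(c(dec0$T, dec0$W, dec0$B), c(0, 0, 0))
  d2 <- as.matrix(dist(c(1, 4, 9)))
  dec1 <- group_distance_decomposition(d2, rep("g", 3))
  expect_equal(dec1$B, 0)
  expect_equal(dec1$T, dec1$W)
})

test_that("T = W + B and euclidean B matches centroid sums of squares", {
  set.seed(10)
  for (rep in 1:25) {
    n <- sample(6:12, 1)
    d <- rand_distance(n, rep)
    g <- sample(c("a", "b", "c"), n, replace = TRUE)
    if (length(unique(g)) < 2) g[1:2] <- c("a", "b")
    dec <- group_distance_decomposition(d, g)
    expect_equal(dec$T, dec$W + dec$B, tolerance = 1e-9)
    expect_true(all(c(dec$T, dec$W) >= -1e-12))
  }
  ## euclidean case: B equals the between-group SS of the coordinates
  set.seed(77)
  x <- matrix(rnorm(20 * 3), 20)
  g <- rep(c("a", "b"), each = 10)
  dec <- group_distance_decomposition(as.matrix(dist(x)), g)
  centroids <- apply(x, 2, tapply, g, mean)
  grand <- colMeans(x)
  ssb <- sum(10 * (centroids["a", ] - grand)^2 +
               10 * (centroids["b", ] - grand)^2)
  expect_equal(dec$B, ssb, tolerance = 1e-9)
})

test_that("bootstrap networks separate groups when effects are large", {
  md <- generate_metadata(2)   # 16 samples
  p <- simulation_params(
    n_taxa = 25, library_sizes = 200000L,
    landuse_log_effects = effect_pattern(25, 2.5, seed = 3),
    dirichlet_concentration = 300, seed = 41)
  prof <- generate_profiles(md, p)
  boot <- bootstrap_networks(prof$counts,
                             bootstrap_config(n_iter = 15, n_reads = 5000,
                                              seed = 6),
                             metadata = md)
  expect_equal(nrow(boot$summary), 15L)
  expect_gte(sum(boot$summary$mean_between > boot$summary$mean_within), 14)
  ## submatrix covers all samples in every iteration
  expect_true(all(vapply(boot$matrices, function(m)
    all(dim(m) == c(16L, 16L)), logical(1))))
  ## decomposition identity holds on the bootstrap summaries
  expect_equal(boot$summary$T, boot$summary$W + boot$summary$B,
               tolerance = 1e-9)
  ## determinism contract
  boot2 <- bootstrap_networks(prof$counts,
                              bootstrap_config(n_iter = 2, n_reads = 5000,
                                               seed = 6),
                              metadata = md)
  expect_equal(boot$summary[1:2, ], boot2$summary[1:2, ])
})

test_that("zero-variance resamples give all-zero sample distances", {
  m <- matrix(c(50, 50, 50), 1,
              dimnames = list("g1", paste0("s", 1:3)))
  boot <- bootstrap_networks(m, bootstrap_config(n_iter = 1,
                                                 n_reads = 100, seed = 2))
  expect_true(all(boot$matrices[[1]] == 0))
})
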