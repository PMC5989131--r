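test_that("shannon and evenness match closed forms", {
  r <- shannon_evenness(rep(25, 4))
  expect_equal(r$H, log(4))
  expect_equal(r$E, 1)
  expect_equal(r$S, 4L)
  r1 <- shannon_evenness(c(0, 17, 0))
  expect_equal(r1$H, 0)
  expect_equal(r1$E, 1)
  r2 <- shannon_evenness(c(0.5, 0.25, 0.25))
  expect_equal(r2$H, 1.5 * log(2), tolerance = 1e-12)  # = 1.0397 nats
  expect_equal(r2$E, exp(r2$H) / 3)
  expect_equal(round(r2$H, 4), 1.0397)
  expect_equal(round(r2$E, 4), 0.9428)
  expect_error(shannon_evenness(c(0, 0)), "positive")
  ## E = 1 iff uniform over support
  expect_lt(shannon_evenness(c(4, 1, 1))$E, 1)
})

test_that("rarefaction endpoints and expectations are exact", {
  counts <- c(sp1 = 50, sp2 = 50)
  ## depth = total reads recovers observed richness for every seed
  for (s in 1:5) {
    rc <- rarefaction_curve(counts, depths = 100, reps = 3, seed = s)
    expect_equal(rc$mean_taxa, 2)
  }
  expect_equal(rarefaction_curve(counts, depths = 1, reps = 20,
                                 seed = 1)$mean_taxa, 1)
  ## Monte-Carlo mean vs the hypergeometric expectation (vegan::rarefy)
  counts2 <- c(a = 30, b = 15, c = 5)
  rc <- rarefaction_curve(counts2, depths = c(2, 10, 25), reps = 400,
                          seed = 42)
  expected <- as.numeric(vegan::rarefy(counts2, sample = c(2, 10, 25)))
  expect_true(all(abs(rc$mean_taxa - expected) < 3 * rc$sd_taxa /
                    sqrt(400) + 1e-9))
  ## means non-decreasing in depth
  expect_true(all(diff(rc$mean_taxa) >= 0))
  expect_error(rarefaction_curve(counts, depths = 101), "exceeds")
})

test_that("per-feature permutation t tests flag shifts, not nulls", {
  set.seed(8)
  m <- matrix(rnorm(10 * 12, 10), 10,
              dimnames = list(paste0("f", 1:10), paste0("s", 1:12)))
  groups <- rep(c("A", "B"), each = 6)
  ## null: no feature flagged
  res0 <- per_feature_group_test(m, groups, n_perm = 499, seed = 2)
  expect_false(any(res0$significant))
  expect_true(all(res0$p > 0 & res0$p <= 1))
  ## a 10-fold shift on one feature with tight noise is flagged
  m2 <- m
  m2["f3", groups == "B"] <- m2["f3", groups == "B"] * 10
  res1 <- per_feature_group_test(m2, groups, n_perm = 499, seed = 2)
  expect_true(res1$significant[res1$feature == "f3"])
  expect_false(any(res1$significant[res1$feature != "f3"]))
  expect_error(per_feature_group_test(m, rep(c("A", "B"), c(1, 11))),
               "at least 2")
})

test_that("permutation p agrees with exhaustive label splits at n=3+3", {
  set.seed(5)
  x <- c(1.2, 1.9, 1.4, 3.1, 3.4, 2.8)
  m <- matrix(x, 1, dimnames = list("f", paste0("s", 1:6)))
  groups <- rep(c("A", "B"), each = 3)
  welch <- function(a, b) (mean(a) - mean(b)) /
    sqrt(var(a) / 3 + var(b) / 3)
  t_obs <- abs(welch(x[1:3], x[4:6]))
  sets <- combn(6, 3)
  exact <- mean(apply(sets, 2, function(ix)
    abs(welch(x[ix], x[-ix])) >= t_obs - 1e-12))
  res <- per_feature_group_test(m, groups, n_perm = 1999, seed = 3)
  expect_lt(abs(res$p - exact), 3 * sqrt(exact * (1 - exact) / 1999))
})

test_that("permutation p-values are super-uniform under the null", {
  set.seed(31)
  groups <- rep(c("A", "B"), each = 5)
  pvals <- replicate(200, {
    m <- matrix(rnorm(10), 1)
    colnames(m) <- paste0("s", 1:10)
    per_feature_group_test(m, groups, n_perm = 99,
                           seed = sample.int(1e6, 1))$p
  })
  expect_lt(mean(pvals <= 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / 200))
  expect_lt(mean(pvals <= 0.2), 0.2 + 3 * sqrt(0.2 * 0.8 / 200))
})

test_that("mann-whitney matches enumeration and wilcox.test", {
  mw <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 1 / 3)   # 2 of 6 assignments as extreme
  ## identical multisets sit at the null mean
  expect_equal(mann_whitney(c(5, 6, 7), c(5, 6, 7))$U, 4.5)
  ## agreement with wilcox.test where both are exact (no ties)
  set.seed(6)
  for (rep in 1:10) {
    a <- round(rnorm(5), 3); b <- round(rnorm(6) + 0.5, 3)
    expect_equal(mann_whitney(a, b)$p,
                 wilcox.test(a, b, exact = TRUE)$p.value,
                 tolerance = 1e-10)
  }
  ## large-sample normal path is close to wilcox.test's corrected normal
  a <- rnorm(15); b <- rnorm(20) + 0.3
  expect_equal(mann_whitney(a, b)$p,
               wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value,
               tolerance = 1e-6)
  expect_error(mann_whitney(numeric(0), 1), "non-empty")
})

test_that("p decreases monotonically with shift size at n = 3 per group", {
  shifts <- c(0.5, 2, 8)
  set.seed(12)
  base_a <- rnorm(3, 10, 0.5); base_b <- rnorm(3, 10, 0.5)
  ps <- vapply(shifts, function(s) mann_whitney(base_a, base_b + s)$p,
               numeric(1))
  expect_true(all(diff(ps) <= 0))
})

test_that("kendall correlations match closed forms", {
  res <- kendall_rain_correlation(data.frame(v = c(1, 3, 2)), c(1, 2, 3))
  expect_equal(res$tau, 1 / 3)   # 2 concordant, 1 discordant of 3 pairs
  res2 <- kendall_rain_correlation(data.frame(v = c(2, 5, 9, 11)),
                                   c(1, 2, 3, 4))
  expect_equal(res2$tau, 1)
  ## generator round trip
  er <- generate_env_rain(1000, c(x = 0.5, y = -0.4), seed = 9)
  res3 <- kendall_rain_correlation(er$env, er$rain)
  expect_lt(abs(res3$tau[res3$variable == "x"] - 0.5), 0.1)
  expect_lt(abs(res3$tau[res3$variable == "y"] + 0.4), 0.1)
  expect_true(all(res3$p < 0.05))
  expect_error(kendall_rain_correlation(data.frame(v = 1:4), 1:5),
               "lengths differ")
})
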