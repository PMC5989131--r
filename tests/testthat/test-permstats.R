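test_that("one-factor permanova reduces to classical anova", {
  d <- as.matrix(dist(c(0, 1, 2, 3)))
  rownames(d) <- colnames(d) <- paste0("u", 1:4)
  md <- data.frame(sample_id = paste0("u", 1:4), grp = c("A", "A", "B", "B"))
  res <- permanova(d, md, "grp", exhaustive = TRUE, pool = FALSE)
  expect_equal(res$pseudo_F[1], 8)      # SSB=4, SSW=1 -> (4/1)/(1/2)
  expect_equal(res$p[1], 1 / 3)         # 8 of 24 relabelings reach F >= 8
  ## random univariate data: pseudo-F equals aov's F exactly
  set.seed(21)
  y <- rnorm(12)
  g <- rep(c("A", "B", "C"), each = 4)
  d2 <- as.matrix(dist(y))
  rownames(d2) <- colnames(d2) <- paste0("u", 1:12)
  md2 <- data.frame(sample_id = paste0("u", 1:12), grp = g)
  res2 <- permanova(d2, md2, "grp", n_perm = 99, pool = FALSE, seed = 2)
  f_aov <- summary(aov(y ~ g))[[1]]$`F value`[1]
  expect_equal(res2$pseudo_F[1], f_aov, tolerance = 1e-10)
})

test_that("permanova sums of squares partition the total exactly", {
  md <- generate_metadata(3)
  p <- simulation_params(n_taxa = 20, library_sizes = 2000L, seed = 17)
  prof <- generate_profiles(md, p)
  d <- community_distance(prof$counts, "braycurtis")
  res <- permanova(d, md, c("land_use", "timing", "rain_event"),
                   random = "rain_event", n_perm = 49, pool = FALSE,
                   seed = 1)
  expect_equal(sum(res$SS), attr(res, "SS_total"), tolerance = 1e-9)
  expect_equal(sum(res$df), nrow(md) - 1)
  ## EMS denominators of the mixed model
  expect_equal(res$denominator[res$term == "land_use"],
               "land_use:rain_event")
  expect_equal(res$denominator[res$term == "timing"],
               "timing:rain_event")
  expect_equal(res$denominator[res$term == "rain_event"], "residual")
  expect_equal(res$denominator[res$term == "land_use:timing"],
               "land_use:timing:rain_event")
  expect_true(all(res$p[!is.na(res$p)] > 0 & res$p[!is.na(res$p)] <= 1))
})

test_that("permanova agrees with vegan::adonis2 on a fixed one-way design", {
  set.seed(33)
  m <- matrix(rpois(30 * 12, 8), 30,
              dimnames = list(paste0("t", 1:30), paste0("s", 1:12)))
  md <- data.frame(sample_id = paste0("s", 1:12),
                   grp = rep(c("A", "B", "C"), each = 4))
  d <- community_distance(m, "braycurtis")
  res <- permanova(d, md, "grp", n_perm = 199, pool = FALSE, seed = 5)
  ref <- vegan::adonis2(as.dist(d) ~ grp, data = md, permutations = 199)
  expect_equal(res$pseudo_F[1], ref$F[1], tolerance = 1e-8)
  expect_equal(res$SS[1], ref$SumOfSqs[1], tolerance = 1e-8)
})

test_that("pooling removes weak interactions and flags them", {
  md <- generate_metadata(3)
  p <- simulation_params(
    n_taxa = 25, library_sizes = 50000L,
    landuse_log_effects = effect_pattern(25, 2, seed = 2),
    dirichlet_concentration = 300, seed = 23)
  prof <- generate_profiles(md, p)
  d <- community_distance(transform_counts(
    normalize_to_smallest(prof$counts), "sqrt"), "braycurtis")
  res <- permanova(d, md, c("land_use", "timing", "rain_event"),
                   random = "rain_event", n_perm = 199,
                   pool_threshold = 0.25, seed = 7)
  pooled <- res$term[res$pooled]
  ## null interactions pool; the strong land-use effect never does
  expect_false("land_use" %in% pooled)
  expect_true(all(grepl(":", pooled)))
  expect_true(res$p[res$term == "land_use"] <= 0.05)
  ## with pooling disabled the table keeps every term testable
  res0 <- permanova(d, md, c("land_use", "timing", "rain_event"),
                    random = "rain_event", n_perm = 49, pool = FALSE,
                    seed = 7)
  expect_false(any(res0$pooled))
})

test_that("null-group permanova p-values stay large on identical groups", {
  set.seed(55)
  m <- matrix(rpois(20 * 8, 6), 20,
              dimnames = list(paste0("t", 1:20), paste0("s", 1:8)))
  md <- data.frame(sample_id = paste0("s", 1:8),
                   grp = rep(c("A", "B"), 4))
  d <- community_distance(m, "braycurtis")
  res <- permanova(d, md, "grp", n_perm = 199, pool = FALSE, seed = 3)
  expect_gte(res$p[1], 0.3)
  ## design validation
  md_bad <- md; md_bad$grp <- c(rep("A", 5), rep("B", 3))
  expect_error(permanova(d, md_bad, "grp"), "unbalanced")
  md_one <- md; md_one$grp <- "A"
  expect_error(permanova(d, md_one, "grp"), "2 levels")
})

test_that("permdisp matches the univariate levene-style computation", {
  y <- c(1, 2, 3, 10, 20, 30)
  g <- rep(c("a", "b"), each = 3)
  d <- as.matrix(dist(y))
  rownames(d) <- colnames(d) <- paste0("s", 1:6)
  res <- permdisp(d, g, n_perm = 199, seed = 1)
  dist_manual <- abs(y - ave(y, g))
  expect_equal(unname(res$group_means),
               unname(tapply(dist_manual, g, mean)), tolerance = 1e-9)
  f_manual <- summary(aov(dist_manual ~ g))[[1]]$`F value`[1]
  expect_equal(res$F, f_manual, tolerance = 1e-9)
  ## mirror-image groups: equal dispersion, large p
  y2 <- c(-1, 0, 1, 99, 100, 101)
  d2 <- as.matrix(dist(y2)); rownames(d2) <- colnames(d2) <- paste0("s", 1:6)
  res2 <- permdisp(d2, g, n_perm = 199, seed = 2)
  expect_lt(res2$F, 1e-9)
  expect_gte(res2$p, 0.9)
  expect_error(permdisp(d, c("a", rep("b", 5))), "at least 2")
})

test_that("permdisp detects a tenfold scale difference", {
  set.seed(9)
  hits <- vapply(1:10, function(s) {
    x <- rbind(matrix(rnorm(10 * 3, sd = 1), 10),
               matrix(rnorm(10 * 3, sd = 10), 10))
    d <- as.matrix(dist(x))
    rownames(d) <- colnames(d) <- paste0("s", 1:20)
    permdisp(d, rep(c("a", "b"), each = 10), n_perm = 199,
             seed = s)$p <= 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("simper decomposes bray-curtis contributions", {
  m <- matrix(c(1, 2, 3, 3, 2, 1), 3,
              dimnames = list(paste0("t", 1:3), c("s1", "s2")))
  res <- simper(m, c("A", "B"))
  expect_equal(attr(res, "mean_dissimilarity"), 1 / 3)
  expect_equal(sort(res$contribution), sort(c(2 / 12, 0, 2 / 12)))
  expect_equal(res$cumulative_pct[nrow(res)], 100)
  ## identical samples across groups: all contributions zero
  m2 <- m[, c(1, 1, 1, 1)]; colnames(m2) <- paste0("s", 1:4)
  res2 <- simper(m2, c("A", "A", "B", "B"))
  expect_true(all(res2$contribution == 0))
})

test_that("simper totals equal mean between-group dissimilarity (vegan)", {
  set.seed(14)
  m <- matrix(rpois(15 * 10, 5), 15,
              dimnames = list(paste0("t", 1:15), paste0("s", 1:10)))
  g <- rep(c("A", "B"), each = 5)
  res <- simper(m, g)
  d <- community_distance(m, "braycurtis")
  between <- d[1:5, 6:10]
  expect_equal(attr(res, "mean_dissimilarity"), mean(between),
               tolerance = 1e-12)
  ref <- vegan::simper(t(m), g, permutations = 0)
  ref_avg <- unname(ref$A_B$average[match(res$feature, ref$A_B$species)])
  expect_equal(res$contribution, ref_avg, tolerance = 1e-10)
})

test_that("relate finds monotone association and calibrates under the null", {
  d1 <- rand_distance(8, 3)
  d2 <- sqrt(d1)     # monotone transform -> rho = 1
  res <- relate(d1, d2, n_perm = 199, seed = 1)
  expect_equal(res$rho, 1)
  expect_lte(res$p, 0.05)
  ## exhaustive agreement at n = 4: 4! = 24 permutations
  d3 <- rand_distance(4, 6)
  d4 <- rand_distance(4, 7)
  ut <- upper.tri(d3)
  rho_obs <- cor(d3[ut], d4[ut], method = "spearman")
  perms <- sednet:::all_perms(4)
  exact <- mean(apply(perms, 1, function(pi)
    cor(d3[ut], d4[pi, pi][ut], method = "spearman") >= rho_obs - 1e-12))
  res2 <- relate(d3, d4, n_perm = 1999, seed = 9)
  expect_lt(abs(res2$p - exact), 0.05)
  ## agreement with vegan's mantel on the statistic
  mt <- vegan::mantel(as.dist(d3), as.dist(d4), method = "spearman",
                      permutations = 0)
  expect_equal(res2$rho, unname(mt$statistic), tolerance = 1e-10)
  expect_error(relate(d3, rand_distance(5, 1)), "same samples")
})
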