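mk <- function(v, nr) matrix(v, nr, dimnames = list(
  paste0("t", seq_len(nr)), paste0("s", seq_len(length(v) / nr))))

test_that("normalization to the smallest library equalizes totals", {
  m <- mk(c(10, 90, 40, 160), 2)    # totals 100, 200
  out <- normalize_to_smallest(m)
  expect_equal(unname(colSums(out)), c(100, 100))
  expect_equal(out[, 2], m[, 2] / 2)
  ## already equal totals: identity
  m2 <- mk(c(1, 2, 2, 1), 2)
  expect_equal(normalize_to_smallest(m2), m2, ignore_attr = TRUE)
  ## totals (30, 90, 60) -> factors (1, 1/3, 1/2)
  m3 <- mk(c(30, 0, 90, 0, 60, 0), 2)
  expect_equal(unname(colSums(normalize_to_smallest(m3))), rep(30, 3))
  ## proportions within a column are untouched
  p_before <- m[, 2] / sum(m[, 2])
  p_after <- out[, 2] / sum(out[, 2])
  expect_equal(p_before, p_after)
  m4 <- mk(c(1, 1, 0, 0), 2)
  expect_error(normalize_to_smallest(m4), "empty sample.*s2")
})

test_that("transforms act element-wise", {
  m <- mk(c(9, 0, 2, 5), 2)
  expect_equal(transform_counts(m, "sqrt")[1, 1], 3)
  expect_equal(transform_counts(m, "sqrt")[2, 1], 0)
  expect_equal(unname(transform_counts(m, "presence")[, 2]), c(1, 1))
  expect_equal(transform_counts(mk(c(0, 2, 5, 0), 2), "presence")[1, 1], 0)
})

test_that("distances match their closed forms and vegan", {
  m <- mk(c(1, 2, 3, 3, 2, 1), 3)
  d <- community_distance(m, "braycurtis")
  expect_equal(d["s1", "s2"], 1 / 3)   # (2 + 0 + 2) / 12
  ## jaccard: A = {t1,t2}, B = {t2,t3} -> 1 - 1/3
  mj <- mk(c(1, 1, 0, 0, 1, 1), 3)
  expect_equal(community_distance(mj, "jaccard")["s1", "s2"], 2 / 3)
  ## identical and disjoint columns
  expect_equal(community_distance(mk(c(1, 2, 1, 2), 2))["s1", "s2"], 0)
  expect_equal(community_distance(mk(c(1, 0, 0, 2), 2))["s1", "s2"], 1)
  ## agreement with vegan on random data
  set.seed(3)
  mr <- matrix(rpois(60, 5), 6, dimnames = list(paste0("t", 1:6),
                                                paste0("s", 1:10)))
  expect_equal(as.matrix(community_distance(mr, "braycurtis")),
               as.matrix(vegan::vegdist(t(mr), "bray")),
               tolerance = 1e-12)
  ## both-zero pair: distance 0 with warning
  mz <- mk(c(1, 0, 0, 0, 0, 0), 2)
  expect_warning(dz <- community_distance(mz, "braycurtis"), "no positive")
  expect_equal(dz["s2", "s3"], 0)
  expect_error(community_distance(mk(c(1, 2), 2)), "2 samples")
})

test_that("bray-curtis is a [0,1] semimetric, zero iff columns equal", {
  set.seed(9)
  m <- matrix(rpois(80, 3), 8, dimnames = list(paste0("t", 1:8),
                                               paste0("s", 1:10)))
  m[, 2] <- m[, 1]
  d <- community_distance(m, "braycurtis")
  expect_true(all(d >= 0 & d <= 1))
  expect_equal(unname(d), unname(t(d)))
  expect_equal(d["s1", "s2"], 0)
  off <- d[upper.tri(d)][-1]
  expect_true(all(off[off != d["s1", "s2"]] > 0))
})

test_that("binary bray-curtis maps to jaccard by the Sorensen formula", {
  set.seed(4)
  m <- matrix(rbinom(120, 1, 0.4), 12,
              dimnames = list(paste0("t", 1:12), paste0("s", 1:10)))
  m[1, ] <- 1   # avoid all-zero pairs
  bs <- community_distance(transform_counts(m, "presence"), "braycurtis")
  jac <- community_distance(m, "jaccard")
  expect_equal(jac, 2 * bs / (1 + bs), tolerance = 1e-12)
})

test_that("prevalence filter uses the ceiling rule", {
  m <- matrix(0, 3, 48, dimnames = list(c("keep24", "drop23", "all"),
                                        paste0("s", 1:48)))
  m["keep24", 1:24] <- 1
  m["drop23", 1:23] <- 1
  m["all", ] <- 1
  out <- prevalence_filter(m, 0.5)
  expect_setequal(rownames(out), c("keep24", "all"))
  ## smallest positive fraction retains anything present at least once
  expect_equal(nrow(prevalence_filter(m, 1e-9)), 3L)
  expect_warning(prevalence_filter(m[2, , drop = FALSE] * 0, 0.5),
                 "removed every")
})

test_that("average-linkage clustering is ultrametric and isolates outliers", {
  m <- rbind(a = c(10, 0, 0, 10), b = c(10, 0, 0, 10),
             c = c(0, 10, 10, 0))
  colnames(m) <- paste0("s", 1:4)
  hc <- hierarchical_cluster(m)
  expect_equal(hc$height[1], 0)          # identical rows merge first
  expect_equal(sort(-hc$merge[1, ]), which(rownames(m) %in% c("a", "b")))
  expect_true(all(diff(hc$height) >= 0)) # monotone merge heights
  set.seed(2)
  mr <- matrix(rpois(50, 4), 10)
  colnames(mr) <- paste0("s", 1:5)
  rownames(mr) <- paste0("t", 1:10)
  expect_true(all(diff(hierarchical_cluster(mr)$height) >= -1e-12))
  expect_error(hierarchical_cluster(m[1, , drop = FALSE]), "2 rows")
})
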