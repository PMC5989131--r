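test_that("sequence complexity matches closed forms", {
  expect_equal(sequence_complexity("AAAAAAAA"), 0)
  expect_equal(sequence_complexity("ACGTACGT"), 1)
  ## entropy of (1/2, 1/2, 0, 0) = log 2, normalized by log 4
  expect_equal(sequence_complexity("AACC"), 0.5)
  expect_equal(sequence_complexity(c("AAAA", "ACGT")), c(0, 1))
  expect_error(sequence_complexity(""), "non-empty")
})

test_that("lca_assign applies score floor, top-percent band and LCA", {
  tree <- tiny_tree()
  bp <- binning_params()
  ## GenA (50) and GenB (48) both inside the 10% band -> FamF
  expect_equal(lca_assign(c(6, 7), c(50, 48), bp, tree), 5L)
  ## single surviving hit is its own LCA
  expect_equal(lca_assign(8, 50, bp, tree), 8L)
  ## all hits below the floor -> no-hits node
  expect_equal(lca_assign(c(6, 7), c(34, 20), bp, tree), NO_HITS_ID)
  ## out-of-band low hit ignored: 40 < 0.9 * 50
  expect_equal(lca_assign(c(8, 10), c(50, 40), bp, tree), 8L)
  ## boundary tie retained: 45 == 0.9 * 50 -> LCA(SpA1, SpB1) = FamF
  expect_equal(lca_assign(c(8, 10), c(50, 45), bp, tree), 5L)
  expect_error(lca_assign(99, 50, bp, tree), "unknown")
})

test_that("LCA is order-invariant and matches the brute-force oracle", {
  tree <- tiny_tree()
  bp <- binning_params(min_score = 0, top_percent = 100)
  ## brute force: deepest node whose ancestor set contains all hits
  brute_lca <- function(ids) {
    common <- Reduce(intersect, lapply(ids, function(i) tree$paths[[i]]))
    common[which.max(tree$depth[common])]
  }
  set.seed(11)
  for (rep in 1:50) {
    k <- sample(1:6, 1)
    ids <- sample(2:10, k, replace = TRUE)
    sc <- runif(k, 40, 100)
    got <- lca_assign(ids, sc, bp, tree)
    expect_equal(got, brute_lca(unique(ids)))
    perm <- sample(k)
    expect_equal(lca_assign(ids[perm], sc[perm], bp, tree), got)
  }
})

test_that("widening the retained hit set only coarsens assignments", {
  ## retaining more hits (wider top-percent band, lower score floor with a
  ## fixed best hit) can only move the LCA towards the root, never deeper
  tree <- tiny_tree()
  depth_of <- function(id) if (id < 0) 0L else tree$depth[id]
  set.seed(13)
  for (rep in 1:40) {
    k <- sample(1:5, 1)
    ids <- sample(6:10, k, replace = TRUE)
    sc <- runif(k, 40, 100)   # all above both floors: band is the variable
    base <- lca_assign(ids, sc, binning_params(min_score = 30,
                                               top_percent = 10), tree)
    wider_band <- lca_assign(ids, sc, binning_params(min_score = 30,
                                                     top_percent = 60),
                             tree)
    lower_floor <- lca_assign(ids, sc, binning_params(min_score = 0,
                                                      top_percent = 10),
                              tree)
    expect_lte(depth_of(wider_band), depth_of(base))
    ## ... and the coarser call is an ancestor of the finer one
    expect_true(wider_band %in% tree$paths[[base]])
    expect_equal(lower_floor, base)
  }
})

test_that("min-support moves reads up and conserves totals", {
  tree <- tiny_tree()
  ## GenA = 24 under threshold 25, FamF holds 10 of its own -> 34 at FamF
  v <- c(`6` = 24, `5` = 10)
  out <- apply_min_support(v, 25L, tree)
  expect_equal(unname(out["5"]), 34)
  expect_false("6" %in% names(out))
  ## min_support = 1 leaves assignments unchanged
  v2 <- c(`8` = 3, `6` = 1, `10` = 2)
  expect_equal(sort(apply_min_support(v2, 1L, tree)),
               sort(v2[v2 > 0]))
  ## conservation on random inputs, including cascades to the root
  set.seed(5)
  for (rep in 1:20) {
    ids <- sample(2:10, sample(3:8, 1))
    v3 <- stats::setNames(sample(1:40, length(ids), replace = TRUE), ids)
    out3 <- apply_min_support(v3, 25L, tree)
    expect_equal(sum(out3), sum(v3))
    ## every retained non-root node meets the threshold
    expect_true(all(out3[names(out3) != "1"] >= 25))
  }
})

test_that("rank projection aggregates below-rank reads and audits the rest", {
  tree <- tiny_tree()
  asn <- data.frame(
    sample_id = c("a", "a", "a", "a", "b", "b"),
    node_id = c(8L, 9L, 10L, 5L, 8L, NO_HITS_ID),
    count = c(2, 3, 4, 7, 1, 5))
  m <- profile_at_rank(asn, "genus", tree)
  expect_equal(m["GenA", "a"], 5)   # SpA1 + SpA2
  expect_equal(m["GenB", "a"], 4)
  ## family-level assignment sits above genus -> audit row only
  expect_equal(m["(above genus)", "a"], 7)
  expect_equal(m["(no hits)", "b"], 5)
  expect_setequal(attr(m, "audit_rows"), c("(above genus)", "(no hits)"))
  ## species projection then genus projection equals direct genus counts
  ms <- profile_at_rank(asn[asn$node_id > 5, ], "species", tree)
  expect_equal(sum(ms), sum(asn$count[asn$node_id > 5]))
  expect_error(profile_at_rank(asn, "kingdom", tree), "unknown rank")
})

test_that("zero-noise simulation round-trips through binning exactly", {
  sm <- small_sim(decoy_rate = 0, nohit_rate = 0, lowcomplexity_rate = 0)
  asn <- assign_reads(sm$sim$hits, sm$sim$taxonomy,
                      binning_params(min_support = 1), reads = sm$sim$reads)
  for (rk in c("species", "genus")) {
    prof <- drop_audit_rows(profile_at_rank(asn, rk, sm$sim$taxonomy,
                                            sm$md))
    truth <- sm$sim$truth
    if (rk == "genus") {
      sp <- tax_nodes_at_rank(sm$sim$taxonomy, "species")
      gen <- vapply(sp, tax_ancestor_at_rank, integer(1),
                    tree = sm$sim$taxonomy, rank = "genus")
      truth <- rowsum(truth, sm$sim$taxonomy$name[gen])
    }
    expect_equal(prof[rownames(truth), colnames(truth)],
                 unclass(truth), ignore_attr = TRUE)
  }
})

test_that("decoys within the band coarsen but never misplace reads", {
  sm <- small_sim(n_taxa = 10, lib = 600, decoy_rate = 0.5, nohit_rate = 0,
                  lowcomplexity_rate = 0, seed = 19)
  asn <- assign_reads(sm$sim$hits, sm$sim$taxonomy,
                      binning_params(min_support = 1),
                      reads = sm$sim$reads)
  truth <- sm$sim$reads$true_taxon[match(asn$read_id, sm$sim$reads$read_id)]
  tree <- sm$sim$taxonomy
  ok <- vapply(seq_len(nrow(asn)), function(i)
    asn$node_id[i] %in% tree$paths[[truth[i]]], logical(1))
  expect_true(all(ok))   # assignment always an ancestor of the true taxon
})
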