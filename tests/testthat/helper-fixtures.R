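## Shared fixtures, built in code.

## Ten-node hand-built taxonomy:
##   root(1) > P(2) > C(3) > O(4) > FamF(5) > GenA(6), GenB(7)
##   GenA > SpA1(8), SpA2(9); GenB > SpB1(10)
tiny_tree <- function() {
  tax_tree(data.frame(
    node_id  = 1:10,
    parent_id = c(1, 1, 2, 3, 4, 5, 5, 6, 6, 7),
    rank = c("root", "phylum", "class", "order", "family",
             "genus", "genus", "species", "species", "species"),
    name = c("root", "P", "C", "O", "FamF", "GenA", "GenB",
             "SpA1", "SpA2", "SpB1")))
}

## random additive (tree) metric with its true splits
## splits are returned as canonical member strings (the side not holding
## the first label), with their branch-length weights
rand_tree_metric <- function(n, seed) {
  set.seed(seed)
  phy <- ape::unroot(ape::rtree(n, rooted = TRUE,
                                br = function(k) runif(k, 0.2, 1)))
  d <- ape::cophenetic.phylo(phy)
  labs <- sort(rownames(d))
  d <- d[labs, labs]
  list(d = d, phy = phy, splits = tree_splits(phy, labs))
}

## enumerate the bipartitions (with weights) of an unrooted ape tree
tree_splits <- function(phy, labs) {
  n_tip <- length(phy$tip.label)
  below <- vector("list", n_tip + phy$Nnode)
  for (i in seq_len(n_tip)) below[[i]] <- phy$tip.label[i]
  ## postorder: children accumulated before their parents
  for (e in ape::postorder(phy)) {
    par <- phy$edge[e, 1]; chd <- phy$edge[e, 2]
    below[[par]] <- c(below[[par]], below[[chd]])
  }
  out <- lapply(seq_len(nrow(phy$edge)), function(e) {
    side <- below[[phy$edge[e, 2]]]
    list(members = canonical_split(side, labs),
         weight = phy$edge.length[e])
  })
  keys <- vapply(out, `[[`, character(1), "members")
  w <- vapply(out, `[[`, numeric(1), "weight")
  stats::setNames(w, keys)
}

## canonical key for a bipartition: the side not holding labs[1], sorted
canonical_split <- function(members, labs) {
  if (labs[1] %in% members) members <- setdiff(labs, members)
  paste(sort(members), collapse = "|")
}

## canonical split keys + weights of a circular_splits object
css_split_keys <- function(css) {
  labs <- sort(css$ordering)
  mem <- split_members(css)
  keys <- vapply(mem, canonical_split, character(1), labs = labs)
  stats::setNames(css$splits$weight, keys)
}

## random valid distance matrix (metric not required)
rand_distance <- function(n, seed) {
  set.seed(seed)
  x <- matrix(runif(n * 4), n)
  d <- as.matrix(dist(x))
  dimnames(d) <- list(paste0("s", seq_len(n)), paste0("s", seq_len(n)))
  d
}

## small simulated dataset shared across tests
small_sim <- function(n_reps = 1L, n_taxa = 12L, lib = 400L, seed = 7L,
                      ...) {
  md <- generate_metadata(n_reps)
  p <- simulation_params(n_taxa = n_taxa, library_sizes = lib,
                         seed = seed, ...)
  list(md = md, params = p,
       sim = generate_profiles_and_hits(md, p))
}
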