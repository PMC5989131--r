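#' @import data.table
#' @importFrom stats rmultinom runif rnorm rgamma qgamma pnorm rbinom
#' @importFrom utils combn head tail write.table read.table packageVersion
NULL

#' Reserved node ids for reads outside the taxonomy
#'
#' Reads whose hits all fall below the score threshold are assigned to the
#' "no hits" node; reads diverted by the sequence-complexity filter go to
#' "unassigned".  Both live outside the rooted tree.
#' @format integer constants.
#' @export
NO_HITS_ID <- -1L

#' @rdname NO_HITS_ID
#' @export
UNASSIGNED_ID <- -2L

#' Ranks used by the simulated taxonomies, root first
#' @export
TAX_RANKS <- c("root", "phylum", "class", "order", "family", "genus",
               "species")

#' Construct a taxonomy tree from a node table
#'
#' The tree is rooted and rank-labelled: every non-root node has exactly one
#' parent, and ranks are monotone from the root down.  Ancestor paths are
#' precomputed because the LCA and rank-projection operations are called per
#' read.
#'
#' @param nodes data.frame with columns `node_id`, `parent_id`, `rank`,
#'   `name`.  The root has `parent_id == node_id`.
#' @return an object of class `tax_tree`.
#' @export
tax_tree <- function(nodes) {
  stopifnot(is.data.frame(nodes),
            all(c("node_id", "parent_id", "rank", "name") %in% names(nodes)))
  nodes <- as.data.frame(nodes)
  ids <- as.integer(nodes$node_id)
  if (anyDuplicated(ids)) stop("duplicate node ids in taxonomy")
  if (any(ids <= 0)) stop("taxonomy node ids must be positive integers")
  root <- ids[nodes$parent_id == nodes$node_id]
  if (length(root) != 1L) stop("taxonomy must have exactly one root")
  parent <- integer(max(ids))
  parent[ids] <- as.integer(nodes$parent_id)
  rank <- character(max(ids))
  rank[ids] <- as.character(nodes$rank)
  name <- character(max(ids))
  name[ids] <- as.character(nodes$name)
  if (!all(nodes$parent_id %in% c(ids))) stop("parent ids missing from tree")

  ## root-first ancestor paths; also detects cycles
  paths <- vector("list", max(ids))
  depth <- integer(max(ids))
  for (id in ids) {
    p <- id
    chain <- id
    while (p != root) {
      p <- parent[p]
      if (p %in% chain) stop("taxonomy contains a cycle at node ", id)
      chain <- c(p, chain)
    }
    paths[[id]] <- chain
    depth[id] <- length(chain)
  }
  structure(list(nodes = nodes, root = root, parent = parent, rank = rank,
                 name = name, paths = paths, depth = depth, ids = ids),
            class = "tax_tree")
}

#' @export
print.tax_tree <- function(x, ...) {
  cat("tax_tree:", length(x$ids), "nodes, root =", x$root, "\n")
  cat("ranks:", paste(unique(x$rank[x$ids]), collapse = ", "), "\n")
  invisible(x)
}

#' Lowest common ancestor of a set of taxonomy nodes
#'
#' @param tree a [tax_tree()].
#' @param ids integer node ids (must exist in the tree).
#' @return the node id of the deepest node ancestral to all of `ids`.
#' @export
tax_lca <- function(tree, ids) {
  ids <- unique(as.integer(ids))
  bad <- ids[ids > length(tree$parent) | ids < 1L]
  if (length(bad) || any(vapply(ids, function(i) is.null(tree$paths[[i]]),
                                logical(1)))) {
    stop("unknown taxon id(s): ", paste(ids[!ids %in% tree$ids],
                                        collapse = ", "))
  }
  if (length(ids) == 1L) return(ids)
  common <- Reduce(intersect, tree$paths[ids])
  common[length(common)]
}

#' Simulate a rank-stratified taxonomy
#'
#' Builds a random taxonomy with the full phylum-to-species rank ladder and
#' exactly `n_species` species leaves.  Every species has an ancestor at
#' every rank, so rank projection is total.
#'
#' @param n_species number of species leaves (>= 2).
#' @param seed integer seed.
#' @return a [tax_tree()].
#' @export
simulate_taxonomy <- function(n_species, seed = 1L) {
  stopifnot(n_species >= 2)
  with_seed(seed, {
    n <- c(species = n_species)
    shrink <- c(genus = 2.5, family = 2.2, order = 2, class = 2, phylum = 2)
    lower <- n_species
    for (r in names(shrink)) {
      lower <- max(2L, as.integer(ceiling(lower / shrink[[r]])))
      n[r] <- lower
    }
    level_order <- c("phylum", "class", "order", "family", "genus", "species")
    next_id <- 1L
    root_id <- next_id
    rows <- list(data.frame(node_id = root_id, parent_id = root_id,
                            rank = "root", name = "root"))
    parent_ids <- root_id
    for (r in level_order) {
      k <- n[[r]]
      ids <- next_id + seq_len(k)
      next_id <- next_id + k
      np <- length(parent_ids)
      ## surjective parent assignment: round-robin then shuffle
      assign <- parent_ids[((seq_len(k) - 1L) %% np) + 1L]
      assign <- sample(assign)
      rows[[length(rows) + 1L]] <- data.frame(
        node_id = ids, parent_id = assign, rank = r,
        name = sprintf("%s%03d", substr(r, 1, 1), seq_len(k)))
      parent_ids <- ids
    }
    tax_tree(do.call(rbind, rows))
  })
}

#' Species leaves of a taxonomy
#' @param tree a [tax_tree()].
#' @param rank rank whose nodes to return (default `"species"`).
#' @return integer node ids.
#' @export
tax_nodes_at_rank <- function(tree, rank) {
  if (!rank %in% tree$rank[tree$ids]) stop("rank not present in tree: ", rank)
  tree$ids[tree$rank[tree$ids] == rank]
}

#' Ancestor of a node at a given rank
#'
#' @return the ancestor's node id, or `NA` if the node sits above `rank`.
#' @param tree a [tax_tree()]; `id` node id; `rank` target rank.
#' @param id node id.
#' @param rank target rank.
#' @export
tax_ancestor_at_rank <- function(tree, id, rank) {
  path <- tree$paths[[id]]
  if (is.null(path)) stop("unknown taxon id: ", id)
  hit <- path[tree$rank[path] == rank]
  if (length(hit)) hit[1] else NA_integer_
}

#' Read / write a taxonomy table (TSV: node_id, parent_id, rank, name)
#' @param path file path.
#' @export
read_taxonomy <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  tax_tree(df)
}

#' @rdname read_taxonomy
#' @param tree a [tax_tree()].
#' @export
write_taxonomy <- function(tree, path) {
  utils::write.table(tree$nodes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
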