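## MEGAN-style taxonomic binning: complexity filter, score-thresholded LCA,
## minimum-support reassignment, rank projection.

#' Binning parameters
#'
#' Defaults are the thresholds used for species-level mapping of the
#' sediment metagenomes: minimum bit score 35, top-percent band 10, minimum
#' support 25 reads, minimum sequence complexity 0.44.
#'
#' @param min_score minimum bit score a hit must reach to be considered.
#' @param top_percent retain hits scoring at least
#'   `(1 - top_percent/100) * best`.
#' @param min_support minimum reads a node must accumulate to keep them.
#' @param min_complexity reads below this normalized sequence entropy are
#'   diverted to the unassigned bin before LCA.
#' @return list of class `binning_params`.
#' @export
binning_params <- function(min_score = 35, top_percent = 10,
                           min_support = 25L, min_complexity = 0.44) {
  stopifnot(min_score >= 0, top_percent >= 0, top_percent <= 100,
            min_support >= 1, min_complexity >= 0, min_complexity <= 1)
  structure(list(min_score = min_score, top_percent = top_percent,
                 min_support = as.integer(min_support),
                 min_complexity = min_complexity),
            class = "binning_params")
}

#' Normalized mononucleotide sequence complexity
#'
#' Shannon entropy of the base composition divided by log(4), so a
#' homopolymer scores 0 and a uniform composition scores 1.  Vectorized
#' over sequences.
#'
#' @param x character vector of nucleotide sequences.
#' @return numeric vector in `[0, 1]`.
#' @export
sequence_complexity <- function(x) {
  if (length(x) == 0L) return(numeric(0))
  if (any(is.na(x)) || any(nchar(x) == 0L))
    stop("sequences must be non-empty")
  total <- nchar(x)
  ## count per letter via vectorized deletion; covers the IUPAC alphabet
  alph <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
            "B", "D", "H", "V", "N")
  h <- numeric(length(x))
  for (ch in alph) {
    cnt <- total - nchar(gsub(ch, "", x, fixed = TRUE))
    p <- cnt / total
    nz <- p > 0
    h[nz] <- h[nz] - p[nz] * log(p[nz])
  }
  h / log(4)
}

#' LCA assignment for a single read's hit list
#'
#' Hits below `min_score` are discarded; among survivors only hits within
#' the top-percent band of the best score are retained (ties at the
#' boundary kept); the read is assigned to the lowest common ancestor of
#' the retained taxa.  A read with no surviving hit goes to the no-hits
#' node.
#'
#' @param taxon_ids,bit_scores parallel vectors describing the hits.
#' @param params a [binning_params()].
#' @param tree a [tax_tree()].
#' @return a node id (possibly [NO_HITS_ID]).
#' @export
lca_assign <- function(taxon_ids, bit_scores, params, tree) {
  stopifnot(length(taxon_ids) == length(bit_scores))
  if (any(!is.finite(bit_scores))) stop("bit scores must be finite")
  keep <- bit_scores >= params$min_score
  if (!any(keep)) return(NO_HITS_ID)
  taxon_ids <- taxon_ids[keep]
  bit_scores <- bit_scores[keep]
  best <- max(bit_scores)
  band <- bit_scores >= (1 - params$top_percent / 100) * best
  tax_lca(tree, taxon_ids[band])
}

#' Batch LCA assignment over a hit table
#'
#' @param hits data.frame with `read_id`, `taxon_id`, `bit_score`.
#' @param tree a [tax_tree()].
#' @param params a [binning_params()].
#' @param reads optional data.frame with `read_id`, `sample_id` and either
#'   `complexity` or `sequence`; reads listed here but absent from `hits`,
#'   or failing the complexity filter, are binned accordingly.  When NULL,
#'   every read in `hits` is treated as passing the filter.
#' @return data.frame `read_id`, `sample_id` (if known), `node_id`.
#' @export
assign_reads <- function(hits, tree, params = binning_params(),
                         reads = NULL) {
  stopifnot(all(c("read_id", "taxon_id", "bit_score") %in% names(hits)))
  if (!all(hits$taxon_id %in% tree$ids))
    stop("unknown taxon id(s) in hit table: ",
         paste(head(setdiff(hits$taxon_id, tree$ids)), collapse = ", "))
  dt <- data.table::as.data.table(hits)
  unassigned_ids <- character(0)
  if (!is.null(reads)) {
    cx <- reads$complexity
    if (is.null(cx)) cx <- sequence_complexity(reads$sequence)
    unassigned_ids <- reads$read_id[cx < params$min_complexity]
    dt <- dt[!dt$read_id %in% unassigned_ids, ]
  }
  ## score floor then top-percent band within read
  dt <- dt[dt$bit_score >= params$min_score, ]
  assigned <- NULL
  if (nrow(dt)) {
    frac <- 1 - params$top_percent / 100
    bit_score <- taxon_id <- read_id <- NULL  # data.table NSE
    dt[, `:=`(best = max(bit_score)), by = read_id]
    dt <- dt[bit_score >= frac * dt$best, ]
    per_read <- dt[, list(taxa = list(unique(taxon_id))), by = read_id]
    nt <- lengths(per_read$taxa)
    node <- integer(nrow(per_read))
    single <- nt == 1L
    node[single] <- vapply(per_read$taxa[single], `[`, integer(1), 1L)
    for (i in which(!single))
      node[i] <- tax_lca(tree, per_read$taxa[[i]])
    assigned <- data.frame(read_id = per_read$read_id, node_id = node,
                           stringsAsFactors = FALSE)
  }
  out <- assigned
  if (!is.null(reads)) {
    known <- if (is.null(out)) character(0) else out$read_id
    nohit_ids <- setdiff(reads$read_id, c(known, unassigned_ids))
    out <- rbind(out,
                 data.frame(read_id = nohit_ids,
                            node_id = rep(NO_HITS_ID, length(nohit_ids)),
                            stringsAsFactors = FALSE),
                 data.frame(read_id = unassigned_ids,
                            node_id = rep(UNASSIGNED_ID,
                                          length(unassigned_ids)),
                            stringsAsFactors = FALSE))
    out$sample_id <- reads$sample_id[match(out$read_id, reads$read_id)]
    out <- out[order(match(out$read_id, reads$read_id)), ]
    rownames(out) <- NULL
  } else {
    ## reads present in hits but with no hit above the floor
    nohit_ids <- setdiff(unique(hits$read_id), out$read_id)
    if (length(nohit_ids))
      out <- rbind(out, data.frame(read_id = nohit_ids,
                                   node_id = rep(NO_HITS_ID,
                                                 length(nohit_ids)),
                                   stringsAsFactors = FALSE))
    rownames(out) <- NULL
  }
  out
}

#' Minimum-support reassignment
#'
#' Processing nodes leaves upward, any taxonomy node holding fewer than
#' `min_support` reads passes them to its parent; the walk repeats until
#' every retained node meets the threshold or reads reach the root.  The
#' no-hits and unassigned bins are exempt.  Total counts are conserved.
#'
#' @param counts named numeric vector (names = node ids) of read counts.
#' @param min_support threshold.
#' @param tree a [tax_tree()].
#' @return adjusted named vector (zero-count nodes dropped).
#' @export
apply_min_support <- function(counts, min_support, tree) {
  if (any(counts < 0)) stop("counts must be non-negative")
  acc <- counts
  ## move the deepest under-threshold node up, repeat to fixpoint; moving
  ## deepest-first guarantees each node is finalized only after all its
  ## descendants have contributed
  repeat {
    ids <- as.integer(names(acc))
    low <- ids[!(ids %in% c(NO_HITS_ID, UNASSIGNED_ID)) &
                 acc > 0 & acc < min_support & ids != tree$root]
    if (!length(low)) break
    id <- low[which.max(tree$depth[low])]
    p <- as.character(tree$parent[id])
    acc[p] <- if (p %in% names(acc) && !is.na(acc[p]))
      acc[p] + acc[as.character(id)] else acc[as.character(id)]
    acc[as.character(id)] <- 0
  }
  acc[acc > 0]
}

#' Project per-sample node assignments onto one taxonomic rank
#'
#' Reads assigned at or below `rank` count toward their ancestor at that
#' rank; reads assigned above it, no-hits reads and unassigned reads are
#' reported in separate audit rows (`"(above rank)"`, `"(no hits)"`,
#' `"(unassigned)"`), recorded in the matrix attribute `audit_rows`.
#'
#' @param assignments data.frame with `sample_id`, `node_id` and optionally
#'   `count` (default 1 per row).
#' @param rank target rank.
#' @param tree a [tax_tree()].
#' @param metadata optional metadata fixing the sample column order.
#' @return numeric matrix, taxa x samples, attribute `audit_rows`.
#' @export
profile_at_rank <- function(assignments, rank, tree, metadata = NULL) {
  if (!rank %in% tree$rank[tree$ids]) stop("unknown rank: ", rank)
  cnt <- assignments$count
  if (is.null(cnt)) cnt <- rep(1, nrow(assignments))
  node <- as.integer(assignments$node_id)
  label <- character(length(node))
  special <- node %in% c(NO_HITS_ID, UNASSIGNED_ID)
  label[node == NO_HITS_ID] <- "(no hits)"
  label[node == UNASSIGNED_ID] <- "(unassigned)"
  if (any(!special)) {
    anc <- vapply(node[!special], tax_ancestor_at_rank, integer(1),
                  tree = tree, rank = rank)
    lab <- ifelse(is.na(anc), paste0("(above ", rank, ")"),
                  tree$name[pmax(anc, 1L)])
    label[!special] <- lab
  }
  samples <- if (!is.null(metadata)) metadata$sample_id else
    unique(assignments$sample_id)
  agg <- tapply(cnt, list(label, factor(assignments$sample_id,
                                        levels = samples)), sum,
                default = 0)
  m <- as.matrix(agg)
  audit <- intersect(c(paste0("(above ", rank, ")"), "(no hits)",
                       "(unassigned)"), rownames(m))
  m <- m[c(setdiff(sort(rownames(m)), audit), audit), , drop = FALSE]
  attr(m, "audit_rows") <- audit
  attr(m, "level") <- rank
  m
}

#' Drop audit rows from a rank profile
#' @param m matrix from [profile_at_rank()].
#' @export
drop_audit_rows <- function(m) {
  audit <- attr(m, "audit_rows")
  if (is.null(audit) || !length(audit)) return(m)
  out <- m[setdiff(rownames(m), audit), , drop = FALSE]
  attr(out, "level") <- attr(m, "level")
  attr(out, "audit_rows") <- character(0)
  out
}
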