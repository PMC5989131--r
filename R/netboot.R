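## Bootstrap network reproducibility: resample reads with replacement from
## each sample's genus-level annotations, rebuild the neighbor-net splits
## graph, take the shortest-path submatrix over the sample nodes, and
## decompose it into within- and between-group summary distances.

#' Bootstrap configuration
#'
#' @param n_iter bootstrap iterations (the study used 100).
#' @param n_reads reads drawn with replacement per sample and iteration.
#'   The study's value was six million per data set; the desk-scale default
#'   is 10,000.
#' @param grouping name of the metadata factor used for the within/between
#'   decomposition.
#' @param seed integer seed; iteration `b` uses substream `seed + b`.
#' @export
bootstrap_config <- function(n_iter = 100L, n_reads = 10000L,
                             grouping = "land_use", seed = 1L) {
  stopifnot(n_iter >= 1, n_reads >= 1)
  structure(list(n_iter = as.integer(n_iter), n_reads = as.integer(n_reads),
                 grouping = grouping, seed = as.integer(seed)),
            class = "bootstrap_config")
}

#' Resample reads with replacement within each sample
#'
#' Each sample's column is replaced by a multinomial draw of `n_reads`
#' reads with probabilities equal to its observed proportions, so every
#' resampled column totals exactly `n_reads` (this is the depth adjustment
#' applied before every bootstrap network).
#'
#' @param m taxa x samples count matrix; every column total must be > 0.
#' @param n_reads resampling depth.
#' @param seed integer seed.
#' @export
bootstrap_subsample <- function(m, n_reads, seed = 1L) {
  check_count_matrix(m)
  tot <- colSums(m)
  if (any(tot == 0))
    stop("empty sample(s): ", paste(colnames(m)[tot == 0], collapse = ", "))
  with_seed(seed, {
    out <- m
    for (j in seq_len(ncol(m)))
      out[, j] <- rmultinom(1, n_reads, m[, j] / tot[j])
    out
  })
}

#' Gower-Krzanowski within/between decomposition of a distance matrix
#'
#' Total summary distance `T = (1/n) sum_{i<j} d_ij^2`, within-group
#' `W = sum_g (1/n_g) sum_{i<j in g} d_ij^2`, between-group `B = T - W`
#' (the analysis-of-distance identity; for Euclidean distances these are
#' the classical MANOVA sums of squares).  Mean raw within- and
#' between-group pairwise distances are reported alongside.
#'
#' @param d distance matrix (or `dist`) with sample ids.
#' @param groups group labels aligned with the rows of `d`.
#' @return list `T`, `W`, `B`, `W_g` (per group), `mean_within`,
#'   `mean_between`.
#' @export
group_distance_decomposition <- function(d, groups) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  if (length(groups) != n) stop("groups must match the distance matrix")
  groups <- as.character(groups)
  ut <- upper.tri(dm)
  d2 <- dm^2
  Tstat <- sum(d2[ut]) / n
  lev <- unique(groups)
  W_g <- vapply(lev, function(g) {
    idx <- which(groups == g)
    if (length(idx) < 2) return(0)
    sub <- d2[idx, idx]
    sum(sub[upper.tri(sub)]) / length(idx)
  }, numeric(1))
  names(W_g) <- lev
  same <- outer(groups, groups, `==`)
  within_vals <- dm[ut & same]
  between_vals <- dm[ut & !same]
  list(T = Tstat, W = sum(W_g), B = Tstat - sum(W_g), W_g = W_g,
       mean_within = if (length(within_vals)) mean(within_vals) else NA_real_,
       mean_between = if (length(between_vals)) mean(between_vals)
                      else NA_real_)
}

#' Bootstrap splits networks and their sample-node distance submatrices
#'
#' Per iteration: resample every sample to a common depth, compute
#' Bray-Curtis distances, build the neighbor-net splits graph, and extract
#' the shortest-path submatrix over the sample nodes.  When `metadata` is
#' given, each submatrix is decomposed into within/between summary
#' distances for the configured grouping factor.
#'
#' @param m genus-level count matrix (taxa x samples).
#' @param cfg a [bootstrap_config()].
#' @param metadata optional sample metadata with the grouping column.
#' @param keep_matrices return the per-iteration submatrices (default
#'   TRUE; set FALSE to save memory on long runs).
#' @return list with `summary` (data.frame: iteration, n_nodes, n_splits,
#'   T, W, B, mean_within, mean_between, per-group W columns) and
#'   `matrices` (list of sample-node distance matrices).
#' @export
bootstrap_networks <- function(m, cfg = bootstrap_config(),
                               metadata = NULL, keep_matrices = TRUE) {
  check_count_matrix(m)
  groups <- NULL
  if (!is.null(metadata)) {
    groups <- metadata[[cfg$grouping]][match(colnames(m),
                                             metadata$sample_id)]
    if (anyNA(groups)) stop("metadata does not cover all samples")
  }
  rows <- vector("list", cfg$n_iter)
  mats <- if (keep_matrices) vector("list", cfg$n_iter) else NULL
  for (b in seq_len(cfg$n_iter)) {
    res <- tryCatch({
      mb <- bootstrap_subsample(m, cfg$n_reads,
                                seed = substream_seed(cfg$seed, b))
      db <- community_distance(mb, "braycurtis")
      css <- neighbor_net(db)
      g <- build_splits_graph(css)
      sub <- sample_node_distances(g)
      sub <- sub[colnames(m), colnames(m)]
      list(g = g, sub = sub)
    }, error = function(e)
      stop("bootstrap iteration ", b, ": ", conditionMessage(e)))
    row <- data.frame(iteration = b, n_nodes = res$g$n_nodes,
                      n_splits = nrow(res$g$css$splits))
    if (!is.null(groups)) {
      dec <- group_distance_decomposition(res$sub, groups)
      row <- cbind(row, data.frame(T = dec$T, W = dec$W, B = dec$B,
                                   mean_within = dec$mean_within,
                                   mean_between = dec$mean_between))
      wg <- as.data.frame(as.list(dec$W_g))
      names(wg) <- paste0("W_", names(dec$W_g))
      row <- cbind(row, wg)
    }
    rows[[b]] <- row
    if (keep_matrices) mats[[b]] <- res$sub
  }
  list(summary = do.call(rbind, rows), matrices = mats)
}
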