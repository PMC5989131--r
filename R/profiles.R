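## Count-matrix operations: normalization to the smallest library,
## square-root / presence transforms, Bray-Curtis and Jaccard distances,
## prevalence filtering, hierarchical clustering.

#' @importFrom vegan vegdist
#' @importFrom stats hclust as.dist cophenetic
NULL

check_count_matrix <- function(m) {
  if (!is.matrix(m)) stop("expected a matrix")
  if (any(m < 0)) stop("count matrix has negative entries")
  if (is.null(colnames(m))) stop("count matrix must have sample columns")
  invisible(m)
}

#' Scale every sample to the smallest library size
#'
#' Each column is multiplied by `min(colSums) / colSum`, so all column
#' totals equal the smallest afterwards while within-sample proportions are
#' preserved exactly.  No re-rounding to integers is done; see
#' [subsample_counts()] for the seeded subsampling alternative.
#'
#' @param m taxa x samples count matrix.
#' @return rescaled matrix.
#' @export
normalize_to_smallest <- function(m) {
  check_count_matrix(m)
  tot <- colSums(m)
  if (any(tot == 0))
    stop("empty sample(s): ", paste(colnames(m)[tot == 0], collapse = ", "))
  out <- sweep(m, 2, min(tot) / tot, `*`)
  attr(out, "level") <- attr(m, "level")
  out
}

#' Seeded random subsampling to a common depth
#'
#' Draws `depth` reads without replacement from each sample (hypergeometric
#' thinning); the stochastic counterpart of [normalize_to_smallest()].
#'
#' @param m integer count matrix.
#' @param depth target depth (default the smallest column total).
#' @param seed integer seed.
#' @export
subsample_counts <- function(m, depth = min(colSums(m)), seed = 1L) {
  check_count_matrix(m)
  if (any(colSums(m) < depth)) stop("depth exceeds a sample's total")
  with_seed(seed, {
    out <- m
    for (j in seq_len(ncol(m))) {
      pool <- rep(seq_len(nrow(m)), m[, j])
      take <- sample(pool, depth)
      out[, j] <- tabulate(take, nbins = nrow(m))
    }
    out
  })
}

#' Transform a count matrix
#'
#' @param m count matrix.
#' @param method `"sqrt"` (element-wise square root, the abundance
#'   transform used before Bray-Curtis) or `"presence"` (0/1).
#' @export
transform_counts <- function(m, method = c("sqrt", "presence")) {
  method <- match.arg(method)
  check_count_matrix(m)
  out <- switch(method, sqrt = sqrt(m), presence = (m > 0) * 1)
  attr(out, "level") <- attr(m, "level")
  out
}

#' Between-sample community distance
#'
#' Bray-Curtis `sum |x - y| / sum (x + y)` on abundances, or Jaccard
#' `1 - |A n B| / |A u B|` on presence/absence.  A pair of all-zero samples
#' is defined to have distance 0 (with a warning) so downstream network
#' construction always receives a valid matrix.
#'
#' @param m taxa x samples matrix.
#' @param method `"braycurtis"` or `"jaccard"`.
#' @return a symmetric `dist`-convertible matrix with zero diagonal.
#' @export
community_distance <- function(m, method = c("braycurtis", "jaccard")) {
  method <- match.arg(method)
  check_count_matrix(m)
  if (ncol(m) < 2) stop("need at least 2 samples")
  x <- t(m)
  d <- switch(method,
              braycurtis = suppressWarnings(vegan::vegdist(x, "bray")),
              jaccard = suppressWarnings(
                vegan::vegdist(x, "jaccard", binary = TRUE)))
  dm <- as.matrix(d)
  if (any(is.na(dm))) {
    warning("sample pair(s) with no positive entries; distance set to 0")
    dm[is.na(dm)] <- 0
  }
  diag(dm) <- 0
  dm
}

#' Filter features by prevalence
#'
#' Retains rows with positive entries in at least
#' `ceiling(min_frac * n_samples)` samples (the >= 50%-of-samples rule used
#' before hierarchical clustering).
#'
#' @param m count matrix.
#' @param min_frac minimum fraction of samples, in (0, 1].
#' @export
prevalence_filter <- function(m, min_frac = 0.5) {
  check_count_matrix(m)
  if (min_frac <= 0 || min_frac > 1) stop("min_frac must be in (0, 1]")
  need <- ceiling(min_frac * ncol(m))
  keep <- rowSums(m > 0) >= need
  if (!any(keep)) warning("prevalence filter removed every feature")
  out <- m[keep, , drop = FALSE]
  attr(out, "level") <- attr(m, "level")
  out
}

#' Average-linkage hierarchical clustering of feature profiles
#'
#' Clusters matrix rows on Bray-Curtis distances between their profiles
#' (ecology convention; linkage configurable).  Row order is the
#' deterministic tie-break.
#'
#' @param m feature x sample matrix with >= 2 rows.
#' @param linkage linkage method passed to [stats::hclust()].
#' @return an `hclust` object.
#' @export
hierarchical_cluster <- function(m, linkage = "average") {
  check_count_matrix(m)
  if (nrow(m) < 2) stop("need at least 2 rows to cluster")
  d <- suppressWarnings(vegan::vegdist(m, "bray"))
  d[is.na(d)] <- 0
  stats::hclust(d, method = linkage)
}
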