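## Diversity estimation and the univariate test battery: rarefaction,
## Shannon entropy and Buzas-Gibson evenness, permutation t tests with
## Bonferroni correction, Mann-Whitney U, Kendall tau rain correlations.

#' @importFrom stats sd var pt pnorm cor cor.test qnorm quantile
NULL

#' Rarefaction curve for one sample
#'
#' For each depth, draws that many reads without replacement from the
#' sample's read-level taxon assignments and counts distinct taxa, averaged
#' over `reps` draws.
#'
#' @param assignments either a vector of per-read taxon labels or a named
#'   count vector (expanded internally).
#' @param depths increasing subsample sizes (each <= total reads).
#' @param reps number of random draws per depth.
#' @param seed integer seed.
#' @return data.frame `depth`, `mean_taxa`, `sd_taxa`.
#' @export
rarefaction_curve <- function(assignments, depths, reps = 10L, seed = 1L) {
  if (!is.null(names(assignments)) && is.numeric(assignments))
    assignments <- rep(names(assignments), assignments)
  n <- length(assignments)
  if (any(depths > n)) stop("depth exceeds total reads (", n, ")")
  if (any(depths < 1) || reps < 1) stop("depths and reps must be positive")
  with_seed(seed, {
    res <- vapply(depths, function(k) {
      draws <- vapply(seq_len(reps), function(r)
        length(unique(sample(assignments, k))), numeric(1))
      c(mean(draws), stats::sd(draws))
    }, numeric(2))
  })
  data.frame(depth = depths, mean_taxa = res[1, ],
             sd_taxa = ifelse(is.na(res[2, ]), 0, res[2, ]))
}

#' Shannon diversity and Buzas-Gibson evenness
#'
#' `H = -sum p log p` in nats over the positive entries of the normalized
#' profile, `S` the number of positive entries, and evenness `E = exp(H) /
#' S` (1 for a perfectly even community).
#'
#' @param profile non-negative abundance vector.
#' @param base logarithm base (default e, i.e. entropy in nats).
#' @return list with `S`, `H`, `E`.
#' @export
shannon_evenness <- function(profile, base = exp(1)) {
  if (any(profile < 0)) stop("profile must be non-negative")
  pos <- profile[profile > 0]
  if (!length(pos)) stop("profile has no positive entries")
  p <- pos / sum(pos)
  H <- -sum(p * log(p, base = base))
  S <- length(pos)
  list(S = S, H = H, E = base^H / S)
}

#' Per-feature two-group permutation t tests with Bonferroni correction
#'
#' For every matrix row, a Welch t statistic between the two groups; the
#' permutation p-value counts label shuffles whose |t| reaches the observed
#' one, with the +1 correction.  A feature is flagged significant when its
#' p-value clears the Bonferroni-adjusted level `alpha / n_features`.
#'
#' @param m feature x sample matrix.
#' @param groups two-level factor/character vector along columns.
#' @param n_perm number of label permutations (default 999).
#' @param alpha familywise level before Bonferroni division.
#' @param seed integer seed.
#' @return data.frame `feature`, `t`, `p`, `significant`.
#' @export
per_feature_group_test <- function(m, groups, n_perm = 999L, alpha = 0.05,
                                   seed = 1L) {
  groups <- as.character(groups)
  lev <- unique(groups)
  if (length(lev) != 2L) stop("groups must have exactly two levels")
  n1 <- sum(groups == lev[1]); n2 <- sum(groups == lev[2])
  if (n1 < 2 || n2 < 2) stop("each group needs at least 2 samples")
  welch_t <- function(idx1) {
    a <- m[, idx1, drop = FALSE]
    b <- m[, -idx1, drop = FALSE]
    (rowMeans(a) - rowMeans(b)) /
      sqrt(apply(a, 1, stats::var) / ncol(a) +
             apply(b, 1, stats::var) / ncol(b))
  }
  idx1 <- which(groups == lev[1])
  t_obs <- welch_t(idx1)
  t_obs[!is.finite(t_obs)] <- 0
  count <- rep(0L, nrow(m))
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      perm <- sample(ncol(m))
      t_b <- welch_t(perm[seq_len(n1)])
      t_b[!is.finite(t_b)] <- 0
      count <- count + (abs(t_b) >= abs(t_obs) - 1e-12)
    }
  })
  p <- (1 + count) / (n_perm + 1)
  data.frame(feature = rownames(m) %||% seq_len(nrow(m)),
             t = t_obs, p = p,
             significant = p <= alpha / nrow(m),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Mann-Whitney U test
#'
#' U from rank sums with midrank ties; the two-sided p-value is exact by
#' enumeration of all group assignments when `n_a + n_b <= max_exact`,
#' otherwise a normal approximation with tie correction and continuity
#' correction is used.  "Two-sided" is measured as distance of U from its
#' null mean `n_a n_b / 2`.
#'
#' @param a,b numeric samples.
#' @param max_exact total size up to which the exact enumeration runs.
#' @return list with `U` (for sample `a`), `p`, and `method`.
#' @export
mann_whitney <- function(a, b, max_exact = 12L) {
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (n1 + n2 <= max_exact) {
    sets <- utils::combn(n1 + n2, n1)
    Us <- apply(sets, 2, function(ix) sum(r[ix]) - n1 * (n1 + 1) / 2)
    p <- mean(abs(Us - mu) >= abs(U - mu) - 1e-12)
    method <- "exact enumeration"
  } else {
    n <- n1 + n2
    ties <- table(pooled)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (abs(U - mu) - 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-max(z, 0)))
    method <- "normal approximation"
  }
  list(U = U, p = p, method = method)
}

#' Kendall tau-b correlations of environmental variables with rain
#'
#' @param env data.frame of environmental variables (rows = time points).
#' @param rain numeric rain series aligned with `env` rows.
#' @return data.frame `variable`, `tau`, `p` (exact null when sample size
#'   permits and there are no ties, otherwise normal approximation, as in
#'   [stats::cor.test()]).
#' @export
kendall_rain_correlation <- function(env, rain) {
  if (nrow(env) != length(rain)) stop("env and rain lengths differ")
  if (length(rain) < 3) stop("need at least 3 time points")
  res <- lapply(names(env), function(v) {
    ct <- suppressWarnings(stats::cor.test(env[[v]], rain,
                                           method = "kendall"))
    data.frame(variable = v, tau = unname(ct$estimate),
               p = ct$p.value, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
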