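## Permutational multivariate statistics: mixed-model PERMANOVA with
## expected-mean-square denominators, reduced-model residual permutation
## and term pooling; PERMDISP; SIMPER; RELATE.

#' @importFrom stats model.matrix contr.sum setNames
NULL

## Gower-centered inner-product matrix of a distance matrix
gower_center <- function(dm) {
  n <- nrow(dm)
  A <- -0.5 * dm^2
  H <- diag(n) - matrix(1 / n, n, n)
  H %*% A %*% H
}

## projection matrix onto the centered contrast space of a term
term_projection <- function(data, term_factors) {
  X <- matrix(1, nrow(data), 1)
  for (f in term_factors) {
    fac <- factor(data[[f]])
    C <- stats::contr.sum(nlevels(fac))[as.integer(fac), , drop = FALSE]
    X <- do.call(cbind, lapply(seq_len(ncol(C)), function(j) X * C[, j]))
  }
  X %*% solve(crossprod(X)) %*% t(X)
}

all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Mixed-model PERMANOVA on a distance matrix
#'
#' Partitions the Gower-centered squared-distance matrix over all main
#' effects and interactions of the supplied crossed, balanced factors.
#' Pseudo-F denominators follow the expected mean squares of the mixed
#' model: a term not containing the random factor is tested against its
#' interaction with the random factor (when that interaction is in the
#' model), while the random main effect and all interactions are tested
#' against the residual.  P-values come from permutation of reduced-model
#' residuals (Freedman-Lane): for each tested term, the fitted part of the
#' model without that term is kept fixed and the residuals are permuted.
#'
#' When `pool = TRUE`, non-significant interactions with p above
#' `pool_threshold` are pooled into the residual, highest order first, and
#' the remaining statistics recomputed (once per interaction order);
#' pooled terms are flagged.
#'
#' @param d distance matrix (or `dist`) over the samples of `data`.
#' @param data sample metadata (rows aligned with `d`).
#' @param factors character vector of factor column names (crossed,
#'   balanced design).
#' @param random name of the random factor(s), if any.
#' @param n_perm permutations (default 9999).
#' @param pool pool non-significant interactions (default TRUE).
#' @param pool_threshold pooling threshold on p (default 0.25).
#' @param seed integer seed.
#' @param exhaustive enumerate all `n!` sample permutations instead of
#'   sampling (only for small n); p then counts `F* >= F` over the full
#'   enumeration, identity included.
#' @param test_terms optional character vector restricting which terms get
#'   permutation p-values (all by default).
#' @return data.frame with one row per term plus a residual row: `term`,
#'   `df`, `SS`, `MS`, `pseudo_F`, `p`, `denominator`, `pooled`.
#' @export
permanova <- function(d, data, factors, random = character(0),
                      n_perm = 9999L, pool = TRUE, pool_threshold = 0.25,
                      seed = 1L, exhaustive = FALSE, test_terms = NULL) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  if (nrow(data) != n) stop("metadata rows must match the distance matrix")
  for (f in factors) {
    lv <- table(data[[f]])
    if (length(lv) < 2) stop("factor ", f, " needs at least 2 levels")
  }
  cells <- table(do.call(interaction, data[factors]))
  if (length(unique(cells[cells > 0])) != 1L)
    stop("unbalanced design is not supported")

  ## full factorial term list, ordered by interaction order
  terms <- unlist(lapply(seq_along(factors), function(k)
    utils::combn(factors, k, simplify = FALSE)), recursive = FALSE)
  term_name <- vapply(terms, paste, character(1), collapse = ":")
  df_term <- vapply(terms, function(tf)
    prod(vapply(tf, function(f) length(unique(data[[f]])) - 1L,
                numeric(1))), numeric(1))
  H <- lapply(terms, term_projection, data = data)
  names(H) <- term_name

  denominator_of <- function(tf, active) {
    rnd <- intersect(random, factors)
    if (length(rnd) && !any(rnd %in% tf)) {
      cand <- vapply(active, function(u)
        setequal(terms[[u]], c(tf, rnd)), logical(1))
      if (any(cand)) return(active[which(cand)[1]])
    }
    0L  # residual
  }

  G <- gower_center(dm)
  SS <- vapply(H, function(h) sum(h * G), numeric(1))
  SS_total <- sum(diag(G))

  perm_set <- NULL
  if (exhaustive) {
    if (n > 8) stop("exhaustive permutation only supported for n <= 8")
    perm_set <- all_perms(n)
  }

  fit <- function(active, pooled) {
    SS_res <- SS_total - sum(SS[active])
    df_res <- n - 1 - sum(df_term[active])
    MS <- SS[active] / df_term[active]
    ## a saturated design (one replicate per cell) has no residual; terms
    ## whose denominator is the residual cannot be tested there
    MS_res <- if (df_res > 0) SS_res / df_res else NA_real_
    den_idx <- vapply(active, function(u)
      denominator_of(terms[[u]], active), integer(1))
    Fval <- vapply(seq_along(active), function(k) {
      den <- den_idx[k]
      MS[k] / if (den == 0L) MS_res else SS[den] / df_term[den]
    }, numeric(1))
    names(Fval) <- term_name[active]

    Q_full <- diag(n) - matrix(1 / n, n, n) - Reduce(`+`, H[active])
    pvals <- rep(NA_real_, length(active))
    for (k in seq_along(active)) {
      tn <- term_name[active[k]]
      if (!is.null(test_terms) && !tn %in% test_terms) next
      if (den_idx[k] == 0L && df_res == 0) next   # untestable: saturated
      u <- active[k]
      others <- setdiff(active, u)
      H_red <- matrix(1 / n, n, n)
      if (length(others)) H_red <- H_red + Reduce(`+`, H[others])
      Q_red <- diag(n) - H_red
      den <- den_idx[k]
      H_num <- H[[u]]
      f_obs <- Fval[k]
      ## the permuted statistic is computed on the permuted reduced-model
      ## residuals alone: with a non-residual (interaction) denominator,
      ## adding the reduced-model fit back would re-inject the observed
      ## denominator variation on top of the permuted one and inflate the
      ## test's size
      f_perm <- function(pi) {
        Mp <- Q_red[pi, , drop = FALSE]
        Gp <- Mp %*% G %*% t(Mp)
        ss_num <- sum(H_num * Gp)
        ss_den <- if (den == 0L) {
          sum(Q_full * Gp) / df_res
        } else sum(H[[den]] * Gp) / df_term[den]
        (ss_num / df_term[u]) / ss_den
      }
      if (exhaustive) {
        fs <- apply(perm_set, 1, f_perm)
        pvals[k] <- mean(fs >= f_obs - 1e-12)
      } else {
        cnt <- 0L
        with_seed(substream_seed(seed, 1000L + u), {
          for (b in seq_len(n_perm)) {
            if (f_perm(sample.int(n)) >= f_obs - 1e-12) cnt <- cnt + 1L
          }
        })
        pvals[k] <- (1 + cnt) / (n_perm + 1)
      }
    }
    den_name <- rep("residual", length(den_idx))
    den_name[den_idx > 0L] <- term_name[den_idx[den_idx > 0L]]
    list(table = data.frame(term = term_name[active], df = df_term[active],
                            SS = unname(SS[active]), MS = unname(MS),
                            pseudo_F = unname(Fval), p = pvals,
                            denominator = den_name,
                            pooled = FALSE, stringsAsFactors = FALSE),
         SS_res = SS_res, df_res = df_res)
  }

  active <- seq_along(terms)
  pooled_terms <- character(0)
  res <- fit(active, pooled_terms)
  if (pool && length(factors) > 1) {
    for (ord in rev(seq(2, length(factors)))) {
      cand <- active[vapply(active, function(u)
        length(terms[[u]]) == ord, logical(1))]
      tab <- res$table
      drop <- cand[term_name[cand] %in%
                     tab$term[!is.na(tab$p) & tab$p > pool_threshold]]
      if (length(drop)) {
        pooled_terms <- c(pooled_terms, term_name[drop])
        active <- setdiff(active, drop)
        res <- fit(active, pooled_terms)
      }
    }
  }
  tab <- res$table
  if (length(pooled_terms)) {
    tab <- rbind(tab, data.frame(term = pooled_terms,
                                 df = df_term[match(pooled_terms,
                                                    term_name)],
                                 SS = unname(SS[pooled_terms]),
                                 MS = NA_real_, pseudo_F = NA_real_,
                                 p = NA_real_, denominator = "pooled",
                                 pooled = TRUE, stringsAsFactors = FALSE))
  }
  tab <- rbind(tab, data.frame(term = "Residual", df = res$df_res,
                               SS = res$SS_res,
                               MS = res$SS_res / res$df_res,
                               pseudo_F = NA_real_, p = NA_real_,
                               denominator = NA_character_, pooled = FALSE,
                               stringsAsFactors = FALSE))
  tab <- tab[order(match(tab$term, c(term_name, "Residual"))), ]
  rownames(tab) <- NULL
  attr(tab, "SS_total") <- SS_total
  tab
}

#' PERMDISP: homogeneity of multivariate dispersions
#'
#' Samples are embedded by principal coordinates (with Anderson's
#' negative-eigenvalue correction), each sample's distance to its group
#' centroid is computed, and the one-way ANOVA F on those distances is
#' tested by permuting group labels.
#'
#' @param d distance matrix (or `dist`).
#' @param groups group labels.
#' @param n_perm permutations (default 9999).
#' @param seed integer seed.
#' @param type `"centroid"` (default) or `"median"`.
#' @return list `F`, `p`, `group_means` (mean distance-to-centroid per
#'   group), `distances`.
#' @export
permdisp <- function(d, groups, n_perm = 9999L, seed = 1L,
                     type = c("centroid", "median")) {
  type <- match.arg(type)
  groups <- factor(groups)
  if (any(table(groups) < 2)) stop("every group needs at least 2 members")
  bd <- vegan::betadisper(stats::as.dist(as.matrix(d)), groups, type = type)
  pt <- with_seed(seed,
                  vegan::permutest(bd, permutations = n_perm))
  list(F = unname(pt$tab$F[1]), p = unname(pt$tab$`Pr(>F)`[1]),
       group_means = tapply(bd$distances, groups, mean),
       distances = bd$distances)
}

#' SIMPER: per-feature contributions to between-group Bray-Curtis
#' dissimilarity
#'
#' For every between-group sample pair the per-feature Bray-Curtis term
#' `|x_ij - x_ik| / sum_i (x_ij + x_ik)` is computed and averaged over
#' pairs; features are ranked by mean contribution.  Contributions sum to
#' the average between-group dissimilarity.
#'
#' @param m feature x sample matrix (transform beforehand if desired, e.g.
#'   square root, to match the distance analysis).
#' @param groups two-level labels along columns.
#' @return data.frame `feature`, `contribution`, `contribution_pct`,
#'   `cumulative_pct`, sorted by decreasing contribution; attribute
#'   `mean_dissimilarity`.
#' @export
simper <- function(m, groups) {
  check_count_matrix(m)
  groups <- as.character(groups)
  lev <- unique(groups)
  if (length(lev) != 2L) stop("groups must have exactly two levels")
  ja <- which(groups == lev[1]); jb <- which(groups == lev[2])
  if (!length(ja) || !length(jb)) stop("both groups must be non-empty")
  contrib <- numeric(nrow(m))
  n_pairs <- 0L
  for (j in ja) for (k in jb) {
    denom <- sum(m[, j] + m[, k])
    if (denom > 0) contrib <- contrib + abs(m[, j] - m[, k]) / denom
    n_pairs <- n_pairs + 1L
  }
  contrib <- contrib / n_pairs
  total <- sum(contrib)
  ord <- order(-contrib)
  out <- data.frame(feature = (rownames(m) %||% seq_len(nrow(m)))[ord],
                    contribution = contrib[ord],
                    contribution_pct = if (total > 0)
                      100 * contrib[ord] / total else 0,
                    stringsAsFactors = FALSE)
  out$cumulative_pct <- cumsum(out$contribution_pct)
  attr(out, "mean_dissimilarity") <- total
  out
}

#' RELATE: rank correlation between two distance matrices
#'
#' Spearman correlation of the off-diagonal upper triangles, with
#' significance from a Mantel-type permutation of the sample identities of
#' the second matrix (one-sided, large rho; +1 correction).
#'
#' @param d1,d2 distance matrices over the same samples in the same order.
#' @param n_perm permutations (default 9999).
#' @param seed integer seed.
#' @return list `rho`, `p`.
#' @export
relate <- function(d1, d2, n_perm = 9999L, seed = 1L) {
  m1 <- as.matrix(d1); m2 <- as.matrix(d2)
  if (!all(dim(m1) == dim(m2)))
    stop("distance matrices must cover the same samples")
  if (!is.null(rownames(m1)) && !is.null(rownames(m2)) &&
      !identical(rownames(m1), rownames(m2)))
    stop("samples must be in the same order")
  ut <- upper.tri(m1)
  rho <- stats::cor(m1[ut], m2[ut], method = "spearman")
  cnt <- 0L
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      pi <- sample.int(nrow(m2))
      r <- stats::cor(m1[ut], m2[pi, pi][ut], method = "spearman")
      if (r >= rho - 1e-12) cnt <- cnt + 1L
    }
  })
  list(rho = rho, p = (1 + cnt) / (n_perm + 1))
}
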