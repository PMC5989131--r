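## Neighbor-net: agglomerative construction of a circular ordering from a
## distance matrix, followed by non-negative least-squares estimation of
## weights for the interval splits of that ordering.

## working-matrix reduction of a 3-chain (x - y - z) of active nodes to two
## new virtual nodes stored at indices x and z; the convex weights (2/3,
## 1/3) and the averaged new inter-node distance are the canonical
## published constants of the agglomeration
nn_reduce <- function(d, x, y, z) {
  u <- (2 / 3) * d[x, ] + d[y, ] / 3
  v <- (2 / 3) * d[z, ] + d[y, ] / 3
  uv <- (d[x, y] + d[x, z] + d[y, z]) / 3
  d[x, ] <- d[, x] <- u
  d[z, ] <- d[, z] <- v
  d[y, ] <- d[, y] <- 0
  d[x, z] <- d[z, x] <- uv
  d[x, x] <- d[z, z] <- 0
  d
}

#' Circular ordering by neighbor-net agglomeration
#'
#' Clusters hold one or two active nodes (the ends of a growing path of
#' taxa).  Cluster pairs are selected by the neighbor-joining adjusted
#' distance on cluster-average distances; the concrete node pair inside the
#' selected clusters minimizes the same criterion with the remaining
#' clusters averaged.  Joins that produce three or four active nodes in a
#' path are reduced back to two virtual end nodes with fixed convex weights
#' (2/3, 1/3).  The recursion bottoms out in a single path, read off as the
#' circular ordering.
#'
#' @param d symmetric distance matrix (or `dist`) over >= 3 samples.
#' @return integer vector: positions into the rows of `d` in circular
#'   order, with `attr(,"labels")` the sample ids when present.
#' @export
nnet_ordering <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3) stop("need at least 3 samples for a circular ordering")
  if (!isSymmetric(unname(d), tol = 1e-8)) stop("distance matrix must be symmetric")
  labels <- rownames(d)
  clusters <- as.list(seq_len(n))   # active node ids per cluster
  ords <- as.list(seq_len(n))       # original taxa in path order

  cluster_dist <- function() {
    k <- length(clusters)
    DM <- matrix(0, k, k)
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      DM[i, j] <- DM[j, i] <- mean(d[clusters[[i]], clusters[[j]]])
    }
    DM
  }

  while (length(clusters) > 1L) {
    k <- length(clusters)
    DM <- cluster_dist()
    if (k > 2L) {
      r <- rowSums(DM) / (k - 2)
      Q <- DM - outer(r, r, `+`)
      diag(Q) <- Inf
      ij <- arrayInd(which.min(Q), dim(Q))
      e1 <- min(ij); e2 <- max(ij)
    } else {
      e1 <- 1L; e2 <- 2L
    }
    c1 <- clusters[[e1]]; c2 <- clusters[[e2]]
    n1 <- length(c1); n2 <- length(c2)

    if (n1 == 1L && n2 == 1L) {
      clusters[[e1]] <- c(c1, c2)
      ords[[e1]] <- c(ords[[e1]], ords[[e2]])
      clusters[[e2]] <- NULL
      ords[[e2]] <- NULL
      next
    }

    ## node-level selection: endpoints of the two chosen clusters compete
    ## as singletons against the remaining clusters' averages
    others <- clusters[-c(e1, e2)]
    nodes <- c(c1, c2)
    m <- length(nodes) + length(others)
    rhat <- vapply(nodes, function(x) {
      s <- sum(d[x, setdiff(nodes, x)])
      if (length(others))
        s <- s + sum(vapply(others, function(cl) mean(d[x, cl]), numeric(1)))
      s
    }, numeric(1))
    if (m > 2) rhat <- rhat / (m - 2)
    score <- outer(seq_len(n1), seq_len(n2), function(a, b)
      d[cbind(c1[a], c2[b])] - rhat[a] - rhat[n1 + b])
    ab <- arrayInd(which.min(score), dim(score))
    pick1 <- ab[1]; pick2 <- ab[2]

    ## orient the two paths so they join end-to-start at the chosen nodes
    ord1 <- ords[[e1]]; ord2 <- ords[[e2]]
    if (n1 == 2L && pick1 == 1L) { ord1 <- rev(ord1); c1 <- rev(c1) }
    if (n2 == 2L && pick2 == 2L) { ord2 <- rev(ord2); c2 <- rev(c2) }
    near1 <- c1[length(c1)]; near2 <- c2[1]
    far1 <- if (n1 == 2L) c1[1] else NULL
    far2 <- if (n2 == 2L) c2[length(c2)] else NULL

    if (n1 == 2L && n2 == 2L) {
      d <- nn_reduce(d, far1, near1, near2)
      d <- nn_reduce(d, far1, near2, far2)
      newcl <- c(far1, far2)
    } else if (n1 == 2L) {
      d <- nn_reduce(d, far1, near1, near2)
      newcl <- c(far1, near2)
    } else {
      d <- nn_reduce(d, near1, near2, far2)
      newcl <- c(near1, far2)
    }
    clusters[[e1]] <- newcl
    ords[[e1]] <- c(ord1, ord2)
    clusters[[e2]] <- NULL
    ords[[e2]] <- NULL
  }
  ord <- ords[[1]]
  if (!is.null(labels)) attr(ord, "labels") <- labels[ord]
  ord
}

## cache of split design matrices, keyed by n
.design_cache <- new.env(parent = emptyenv())

#' Design (incidence) matrix of the interval splits of a circular ordering
#'
#' Splits are the `n(n-1)/2` intervals `[i..j]`, `2 <= i <= j <= n`, of
#' positions on the circle (none contains position 1, which enumerates each
#' split once).  Row order is pairs `(p, q)`, `p < q`, row-major.
#'
#' @param n number of taxa on the circle.
#' @return 0/1 matrix, `n(n-1)/2` pairs x `n(n-1)/2` splits; columns carry
#'   an `splits` attribute with the `(i, j)` intervals.
#' @export
split_design_matrix <- function(n) {
  key <- as.character(n)
  if (!is.null(.design_cache[[key]])) return(.design_cache[[key]])
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  splits <- do.call(rbind, lapply(2:n, function(i)
    cbind(i = i, j = i:n)))
  A <- matrix(0, nrow(pairs), nrow(splits))
  for (s in seq_len(nrow(splits))) {
    inside <- seq(splits[s, "i"], splits[s, "j"])
    A[, s] <- xor(pairs[, 1] %in% inside, pairs[, 2] %in% inside) * 1
  }
  attr(A, "splits") <- splits
  attr(A, "pairs") <- pairs
  .design_cache[[key]] <- A
  A
}

#' Non-negative split weights for a circular ordering
#'
#' Solves `min || d - A w ||^2` subject to `w >= 0` over the interval
#' splits of the ordering (A the split-metric incidence).  The
#' unconstrained solution is tried first; when it has negative entries the
#' problem is re-solved as a quadratic program with an active-set solver.
#' Splits with weight below `weight_floor` are dropped as numerical dust.
#'
#' @param d distance matrix (or `dist`).
#' @param ordering from [nnet_ordering()]; defaults to computing it.
#' @param weight_floor retention threshold for split weights.
#' @return object of class `circular_splits`: list with `ordering` (sample
#'   ids in circular order), `splits` (data.frame `i`, `j`, `weight`:
#'   positions into the ordering), `n`, `rss` and `fitted` (fitted distance
#'   matrix in original sample order).
#' @export
nnls_split_weights <- function(d, ordering = NULL, weight_floor = 1e-9) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (is.null(ordering)) ordering <- nnet_ordering(d)
  if (length(ordering) != n || !setequal(ordering, seq_len(n)))
    stop("ordering must be a permutation of all samples")
  ids <- rownames(d)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  A <- split_design_matrix(n)
  pairs <- attr(A, "pairs")
  dd <- d[ordering, ordering]
  y <- dd[cbind(pairs[, 1], pairs[, 2])]
  w <- tryCatch(solve(A, y), error = function(e) rep(-1, ncol(A)))
  if (any(w < -1e-10)) {
    Dmat <- crossprod(A)
    dvec <- crossprod(A, y)
    nc <- ncol(A)
    Amat <- matrix(1, 1, nc)
    Aind <- rbind(rep(1L, nc), seq_len(nc))
    sol <- quadprog::solve.QP.compact(Dmat, as.vector(dvec), Amat, Aind)
    w <- sol$solution
  }
  w[w < 0] <- 0
  fitted_pairs <- as.vector(A %*% w)
  rss <- sum((y - fitted_pairs)^2)
  fitted <- matrix(0, n, n, dimnames = list(ids[ordering], ids[ordering]))
  fitted[cbind(pairs[, 1], pairs[, 2])] <- fitted_pairs
  fitted <- fitted + t(fitted)
  fitted <- fitted[ids, ids]
  sp <- attr(A, "splits")
  keep <- w >= weight_floor
  structure(list(ordering = ids[ordering],
                 ordering_index = as.integer(ordering),
                 splits = data.frame(i = sp[keep, "i"], j = sp[keep, "j"],
                                     weight = w[keep]),
                 n = n, rss = rss, fitted = fitted),
            class = "circular_splits")
}

#' @export
print.circular_splits <- function(x, ...) {
  cat("circular_splits:", x$n, "taxa,", nrow(x$splits),
      "splits, rss =", format(x$rss, digits = 4), "\n")
  invisible(x)
}

#' Neighbor-net split system from a distance matrix
#'
#' Convenience wrapper: [nnet_ordering()] then [nnls_split_weights()].
#'
#' @inheritParams nnls_split_weights
#' @export
neighbor_net <- function(d, weight_floor = 1e-9) {
  d <- as.matrix(d)
  nnls_split_weights(d, nnet_ordering(d), weight_floor)
}

#' Distances implied by a circular split system
#'
#' `d(a, b)` = sum of weights of the splits separating `a` and `b`.
#'
#' @param css a `circular_splits` object.
#' @return symmetric matrix in circular-ordering sample order.
#' @export
split_metric_distances <- function(css) {
  n <- css$n
  dm <- matrix(0, n, n, dimnames = list(css$ordering, css$ordering))
  for (s in seq_len(nrow(css$splits))) {
    inside <- seq(css$splits$i[s], css$splits$j[s])
    v <- seq_len(n) %in% inside
    sep <- outer(v, v, xor)
    dm <- dm + sep * css$splits$weight[s]
  }
  dm
}

#' Membership (sample ids) of one side of each split
#' @param css a `circular_splits` object.
#' @return list of character vectors, one per split (the interval side).
#' @export
split_members <- function(css) {
  lapply(seq_len(nrow(css$splits)), function(s)
    css$ordering[seq(css$splits$i[s], css$splits$j[s])])
}
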