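## Realization of a circular split system as a splits graph.
##
## Each split is drawn as a chord of a disk whose boundary carries the taxa
## in circular order; the splits graph is the planar dual of the chord
## arrangement: nodes are the regions, and two regions separated by a
## chord segment are joined by an edge weighted with that split's weight.
## A straight path between two regions crosses exactly the chords
## separating them, once each, so weighted shortest paths in the dual equal
## the split metric by construction.  Chord crossings are decided
## combinatorially from the cyclic endpoint order; only the order of
## crossings along a chord uses floating-point geometry, with a
## deterministic angular stagger that keeps chords in general position.

#' Build the splits graph of a circular split system
#'
#' @param css a `circular_splits` object from [nnls_split_weights()].
#' @return object of class `splits_graph`: list with `n_nodes`, `edges`
#'   (data.frame `from`, `to`, `split`, `weight`), `taxon_node` (named
#'   integer: the graph node carrying each sample) and `css`.
#' @export
build_splits_graph <- function(css) {
  stopifnot(inherits(css, "circular_splits"))
  n <- css$n
  sp <- css$splits
  m <- nrow(sp)
  if (m && (any(sp$i < 2) || any(sp$j > n) || any(sp$i > sp$j)))
    stop("malformed split intervals")
  taxa_angle <- 2 * pi * (seq_len(n) - 1) / n

  if (m == 0L) {
    tn <- rep(1L, n); names(tn) <- css$ordering
    return(structure(list(n_nodes = 1L,
                          edges = data.frame(from = integer(0),
                                             to = integer(0),
                                             split = integer(0),
                                             weight = numeric(0)),
                          taxon_node = tn, css = css),
                     class = "splits_graph"))
  }

  ## chord endpoints: split [i..j] leaves the boundary in the gaps before
  ## taxon i and after taxon j; within a gap, endpoints are ordered by
  ## decreasing circular distance to their partner gap so that nested
  ## (compatible) splits nest rather than cross
  gapA <- sp$i - 1L
  gapB <- sp$j
  ep_gap <- c(gapA, gapB)                # endpoint 1 then endpoint 2
  ep_partner <- c(gapB, gapA)
  ep_chord <- rep(seq_len(m), 2L)
  gap_width <- 2 * pi / n
  ep_angle <- numeric(2L * m)
  for (g in unique(ep_gap)) {
    idx <- which(ep_gap == g)
    dist_ccw <- ((ep_partner[idx] - g - 1L) %% n) + 1L
    ord <- idx[order(-dist_ccw, ep_chord[idx])]
    k <- length(ord)
    base <- taxa_angle[g] + gap_width * seq_len(k) / (k + 1)
    stagger <- 0.2 * gap_width / (k + 1) *
      sin(9898.9 * ep_chord[ord] + 7.7 * g)
    ep_angle[ord] <- base + stagger
  }
  a1 <- ep_angle[seq_len(m)]
  a2 <- ep_angle[m + seq_len(m)]
  P1 <- cbind(cos(a1), sin(a1))
  P2 <- cbind(cos(a2), sin(a2))

  crosses <- function(c1, c2) {
    lo <- pmin(a1[c1], a2[c1]); hi <- pmax(a1[c1], a2[c1])
    b1 <- a1[c2]; b2 <- a2[c2]
    xor(lo < b1 & b1 < hi, lo < b2 & b2 < hi)
  }
  side_of <- function(chord, xy) {
    v <- P2[chord, ] - P1[chord, ]
    sign(v[1] * (xy[2] - P1[chord, 2]) - v[2] * (xy[1] - P1[chord, 1]))
  }
  intersect_params <- function(ca, cb) {
    ## returns c(t along ca, s along cb)
    r <- P2[ca, ] - P1[ca, ]
    s <- P2[cb, ] - P1[cb, ]
    denom <- r[1] * s[2] - r[2] * s[1]
    q <- P1[cb, ] - P1[ca, ]
    t <- (q[1] * s[2] - q[2] * s[1]) / denom
    u <- (q[1] * r[2] - q[2] * r[1]) / denom
    c(t, u)
  }
  point_on <- function(chord, t) P1[chord, ] + t * (P2[chord, ] - P1[chord, ])

  ## dual-graph state
  n_regions <- 1L
  e_from <- integer(0); e_to <- integer(0)
  e_chord <- integer(0); e_lo <- numeric(0); e_hi <- numeric(0)
  edges_of_chord <- vector("list", m)
  arcs <- data.frame(lo = 0, hi = 2 * pi, region = 1L)

  arc_at <- function(angle) {
    hit <- which(arcs$lo <= angle & angle < arcs$hi)
    if (length(hit) != 1L) stop("boundary arc lookup failed")
    hit
  }
  arc_mid_xy <- function(k) {
    a <- (arcs$lo[k] + arcs$hi[k]) / 2
    c(cos(a), sin(a))
  }

  for (c_new in seq_len(m)) {
    ## crossings with previously inserted chords
    prev <- seq_len(c_new - 1L)
    xing <- prev[crosses(c_new, prev)]
    tu <- if (length(xing))
      vapply(xing, function(d) intersect_params(c_new, d), numeric(2))
    else matrix(numeric(0), 2, 0)
    ordx <- order(tu[1, ])
    xing <- xing[ordx]
    tpar <- tu[1, ordx]
    spar <- tu[2, ordx]

    ## walk the chord from endpoint 1, recording traversed regions and the
    ## dual edges crossed
    start_arc <- arc_at(a1[c_new])
    path <- arc_at(a1[c_new])
    path <- arcs$region[path]
    crossed_edge <- integer(length(xing))
    for (k in seq_along(xing)) {
      dd <- xing[k]
      cand <- edges_of_chord[[dd]]
      hit <- cand[e_lo[cand] < spar[k] & spar[k] < e_hi[cand]]
      if (length(hit) != 1L) stop("splits-graph walk lost a crossing")
      cur <- path[length(path)]
      if (e_from[hit] == cur) nxt <- e_to[hit]
      else if (e_to[hit] == cur) nxt <- e_from[hit]
      else stop("splits-graph walk left its region")
      crossed_edge[k] <- hit
      path <- c(path, nxt)
    }
    if (anyDuplicated(path)) stop("chord re-entered a region")

    ## split every traversed region: old id keeps the negative side, a new
    ## id takes the positive side of the chord
    plus_id <- integer(0)
    plus_id[path] <- n_regions + seq_along(path)
    n_regions <- n_regions + length(path)

    ## boundary arcs: cut at the two chord endpoints, then reassign arcs of
    ## traversed regions by the side of their midpoint
    for (ang in c(a1[c_new], a2[c_new])) {
      k <- arc_at(ang)
      arcs <- rbind(arcs,
                    data.frame(lo = ang, hi = arcs$hi[k],
                               region = arcs$region[k]))
      arcs$hi[k] <- ang
    }
    for (k in which(arcs$region %in% path)) {
      if (side_of(c_new, arc_mid_xy(k)) > 0)
        arcs$region[k] <- plus_id[arcs$region[k]]
    }

    ## existing edges incident to traversed regions
    touched <- which(e_from %in% path | e_to %in% path)
    touched <- setdiff(touched, crossed_edge)
    for (e in touched) {
      mid <- point_on(e_chord[e], (e_lo[e] + e_hi[e]) / 2)
      if (side_of(c_new, mid) > 0) {
        if (e_from[e] %in% path) e_from[e] <- plus_id[e_from[e]]
        if (e_to[e] %in% path) e_to[e] <- plus_id[e_to[e]]
      }
    }
    ## crossed edges split in two at the crossing point
    for (k in seq_along(crossed_edge)) {
      e <- crossed_edge[k]
      dd <- e_chord[e]
      lo <- e_lo[e]; hi <- e_hi[e]
      r1 <- e_from[e]; r2 <- e_to[e]     # both in path, still old ids
      mid_lo <- point_on(dd, (lo + spar[k]) / 2)
      lo_plus <- side_of(c_new, mid_lo) > 0
      ## sub-edge [lo, s]
      e_from[e] <- if (lo_plus) plus_id[r1] else r1
      e_to[e] <- if (lo_plus) plus_id[r2] else r2
      e_hi[e] <- spar[k]
      ## sub-edge [s, hi]
      e_from <- c(e_from, if (lo_plus) r1 else plus_id[r1])
      e_to <- c(e_to, if (lo_plus) r2 else plus_id[r2])
      e_chord <- c(e_chord, dd)
      e_lo <- c(e_lo, spar[k]); e_hi <- c(e_hi, hi)
      edges_of_chord[[dd]] <- c(edges_of_chord[[dd]], length(e_from))
    }
    ## new band of edges along the inserted chord
    bounds <- c(0, tpar, 1)
    for (k in seq_along(path)) {
      e_from <- c(e_from, path[k])
      e_to <- c(e_to, plus_id[path[k]])
      e_chord <- c(e_chord, c_new)
      e_lo <- c(e_lo, bounds[k]); e_hi <- c(e_hi, bounds[k + 1])
    }
    edges_of_chord[[c_new]] <-
      length(e_from) - length(path) + seq_along(path)
  }

  expected <- 1L + m + sum(vapply(seq_len(m), function(cc)
    sum(crosses(cc, seq_len(m)[-cc])), numeric(1))) / 2
  if (n_regions != expected)
    stop("splits-graph region count inconsistent with crossings")

  taxon_node <- vapply(taxa_angle, function(a) arcs$region[arc_at(a)],
                       integer(1))
  names(taxon_node) <- css$ordering
  structure(list(n_nodes = n_regions,
                 edges = data.frame(from = e_from, to = e_to,
                                    split = e_chord,
                                    weight = sp$weight[e_chord]),
                 taxon_node = taxon_node, css = css),
            class = "splits_graph")
}

#' @export
print.splits_graph <- function(x, ...) {
  cat("splits_graph:", x$n_nodes, "nodes,", nrow(x$edges), "edges,",
      nrow(x$css$splits), "splits\n")
  invisible(x)
}

#' Convert a splits graph to igraph
#' @param g a `splits_graph`.
#' @return an `igraph` graph with edge attributes `weight` and `split`.
#' @export
splits_graph_igraph <- function(g) {
  ig <- igraph::make_empty_graph(n = g$n_nodes, directed = FALSE)
  if (nrow(g$edges))
    ig <- igraph::add_edges(ig, rbind(g$edges$from, g$edges$to),
                            weight = g$edges$weight, split = g$edges$split)
  ig
}

#' Shortest-path distances between the sample nodes of a splits graph
#'
#' Edge weights are used as lengths by default; `weighted = FALSE` gives
#' hop counts instead.
#'
#' @param g a `splits_graph`.
#' @param weighted use split weights as edge lengths.
#' @return symmetric matrix over samples, in circular-ordering order.
#' @export
sample_node_distances <- function(g, weighted = TRUE) {
  ig <- splits_graph_igraph(g)
  w <- if (weighted) igraph::E(ig)$weight else NA
  nodes <- unique(g$taxon_node)   # several samples may share one node
  dm0 <- igraph::distances(ig, v = nodes, to = nodes, weights = w)
  idx <- match(g$taxon_node, nodes)
  dm <- dm0[idx, idx, drop = FALSE]
  dimnames(dm) <- list(names(g$taxon_node), names(g$taxon_node))
  dm
}
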