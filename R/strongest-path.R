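#' Dual edge weight
#'
#' Transforms an edge confidence into its dual-graph weight
#' `W(e) = -(log D + log P(e))` (natural logarithm). For confidences and
#' damping in (0, 1] the dual weight is a nonnegative real, so maximizing
#' the penalized confidence product is equivalent to a nonnegative-weight
#' shortest-path search on the reweighted graph.
#'
#' @param p edge confidence, in (0, 1].
#' @param d penalty factor D, in (0, 1]; D < 1 penalizes long paths by a
#'   constant factor per edge.
#' @return nonnegative numeric, `-(log(d) + log(p))`. Vectorized over `p`.
#' @examples
#' dualWeight(1, 0.95)   # -log(0.95)
#' dualWeight(0.5, 0.95)
#' @export
dualWeight <- function(p, d) {
  if (!is.numeric(p) || any(p <= 0 | p > 1))
    spInputError("confidence p must lie in (0, 1]")
  if (!is.numeric(d) || length(d) != 1L || d <= 0 || d > 1)
    spInputError("penalty factor d must lie in (0, 1]")
  -(log(d) + log(p))
}

# Build the dual graph with super-source sigma (= n+1) and super-sink tau
# (= n+2), run the forward (sigma -> v) and backward (v -> tau) Dijkstra
# passes, and return everything the path/subnetwork extractors need.
# Super edges carry weight exactly 0 so the D penalty is charged only for
# real edges.
dualDistances <- function(net, sources, targets, d) {
  if (length(sources) == 0L || length(targets) == 0L)
    spInputError("source and target sets must be non-empty")
  if (length(intersect(sources, targets)))
    spInputError("source and target sets must be disjoint")
  if (!is.numeric(d) || length(d) != 1L || d <= 0 || d > 1)
    spInputError("penalty factor d must lie in (0, 1]")
  n <- length(net@labels)
  e <- net@edges
  if (nrow(e)) {
    w <- dualWeight(e$p, d)
    if (net@directed) {
      arcFrom <- e$from; arcTo <- e$to; arcW <- w; arcP <- e$p
      arcEdge <- seq_len(nrow(e))
    } else {
      arcFrom <- c(e$from, e$to); arcTo <- c(e$to, e$from)
      arcW <- c(w, w); arcP <- c(e$p, e$p)
      arcEdge <- c(seq_len(nrow(e)), seq_len(nrow(e)))
    }
  } else {
    arcFrom <- arcTo <- arcEdge <- integer(); arcW <- arcP <- numeric()
  }
  sigma <- n + 1L; tau <- n + 2L
  arcFrom <- c(arcFrom, rep(sigma, length(sources)), targets)
  arcTo <- c(arcTo, sources, rep(tau, length(targets)))
  arcW <- c(arcW, rep(0, length(sources) + length(targets)))
  arcP <- c(arcP, rep(NA_real_, length(sources) + length(targets)))
  arcEdge <- c(arcEdge, rep(NA_integer_, length(sources) + length(targets)))

  g <- igraph::make_empty_graph(n = n + 2L, directed = TRUE)
  g <- igraph::add_edges(g, rbind(arcFrom, arcTo))
  a <- as.numeric(igraph::distances(g, v = sigma, mode = "out",
                                    weights = arcW, algorithm = "dijkstra"))
  b <- as.numeric(igraph::distances(g, v = tau, mode = "in",
                                    weights = arcW, algorithm = "dijkstra"))
  list(n = n, sigma = sigma, tau = tau, a = a, b = b, wStar = a[tau],
       arcFrom = arcFrom, arcTo = arcTo, arcW = arcW, arcP = arcP,
       arcEdge = arcEdge)
}

noPathResult <- function(d) {
  new("PathResult", found = FALSE, nodes = character(), edgeCount = 0L,
      product = NA_real_, penalizedScore = NA_real_, dualLength = Inf,
      damping = d)
}

#' Strongest path between two protein sets
#'
#' Finds the source-to-target path maximizing the product of edge
#' confidences times `damping^(edge count)` — the most probable chain of
#' interactions, with a constant per-edge penalty favoring shorter chains
#' among near-equal products. Computed exactly as the shortest path from a
#' super-source to a super-sink in the dual graph whose edge weights are
#' `-(log damping + log P(e))`.
#'
#' Ties are resolved deterministically: among paths of equal dual length,
#' the one with fewer edges wins (automatic whenever `damping < 1`), then
#' the lexicographically smallest label sequence.
#'
#' @param net a [ConfidenceNetwork-class].
#' @param sources,targets disjoint non-empty node sets (labels or 1-based
#'   indices).
#' @param damping penalty factor D in (0, 1]; default 0.95.
#' @return a [PathResult-class]; when the sets are disconnected,
#'   a "no path" result with `pathFound()` `FALSE`.
#' @examples
#' tf <- tempfile()
#' writeLines(c("A\tB\t0.9", "B\tC\t0.9", "A\tC\t0.7"), tf)
#' net <- readNetwork(tf, directed = TRUE)
#' strongestPath(net, "A", "C")
#' @export
strongestPath <- function(net, sources, targets, damping = 0.95) {
  stopifnot(is(net, "ConfidenceNetwork"))
  src <- resolveNodeRefs(net, sources, "source")
  tgt <- resolveNodeRefs(net, targets, "target")
  dd <- dualDistances(net, src, tgt, damping)
  if (!is.finite(dd$wStar)) return(noPathResult(damping))
  walk <- optimalDualWalk(net, dd)
  nodes <- walk$nodes
  product <- prod(walk$p)
  edgeCount <- length(nodes) - 1L
  new("PathResult", found = TRUE, nodes = net@labels[nodes],
      edgeCount = edgeCount, product = product,
      penalizedScore = product * damping^edgeCount,
      dualLength = -(edgeCount * log(damping) + sum(log(walk$p))),
      damping = damping)
}

# Deterministic extraction of one optimal path from the dual distances:
# restrict to the shortest-path DAG (arcs with a(u) + W + b(v) <= w* +
# 1e-9), compute per-node minimum hop count h(v) to tau within the DAG by
# reverse BFS, then walk from sigma always stepping to a successor with
# h(u) = h(cur) - 1, breaking ties by smallest label. Stepwise greedy
# label choice yields the lexicographically smallest minimum-edge optimal
# path; h strictly decreases, so the walk is simple and terminates.
optimalDualWalk <- function(net, dd) {
  tol <- 1e-9
  onOpt <- dd$a[dd$arcFrom] + dd$arcW + dd$b[dd$arcTo] <= dd$wStar + tol
  oF <- dd$arcFrom[onOpt]; oT <- dd$arcTo[onOpt]; oP <- dd$arcP[onOpt]
  nTot <- dd$n + 2L
  revAdj <- vector("list", nTot)
  for (i in seq_along(oF)) revAdj[[oT[i]]] <- c(revAdj[[oT[i]]], oF[i])
  h <- bfsHopDistances(revAdj, dd$tau, nTot)
  fwdAdj <- vector("list", nTot)
  fwdP <- vector("list", nTot)
  for (i in seq_along(oF)) {
    fwdAdj[[oF[i]]] <- c(fwdAdj[[oF[i]]], oT[i])
    fwdP[[oF[i]]] <- c(fwdP[[oF[i]]], oP[i])
  }
  cur <- dd$sigma
  nodes <- integer(); pSeq <- numeric()
  while (cur != dd$tau) {
    succ <- fwdAdj[[cur]]
    ps <- fwdP[[cur]]
    ok <- !is.na(h[succ]) & h[succ] == h[cur] - 1L
    succ <- succ[ok]; ps <- ps[ok]
    if (length(succ) == 0L)
      spError("internal: dead end in shortest-path DAG", "spInternalError")
    if (any(succ == dd$tau)) {
      cur <- dd$tau
    } else {
      lab <- net@labels[succ]
      pick <- order(lab)[1L]
      if (cur != dd$sigma) pSeq <- c(pSeq, ps[pick])
      cur <- succ[pick]
      nodes <- c(nodes, cur)
    }
  }
  list(nodes = nodes, p = pSeq)
}

#' Epsilon-suboptimal strongest-path subnetwork
#'
#' Computes the node set `V_eps` of all nodes lying on some
#' source-to-target path whose dual length is within `epsilon` of the
#' optimum `w*`: a node `v` qualifies when `a(v) + b(v) <= w* + epsilon`,
#' where `a(v)` is its shortest dual distance from the source set (forward
#' Dijkstra pass from the super-source) and `b(v)` its shortest dual
#' distance to the target set (backward pass to the super-sink). In dense
#' mode (default) the retained edges are the full induced subgraph on
#' `V_eps`; in sparse mode only edges `(u, v)` with
#' `a(u) + W(u, v) + b(v) <= w* + epsilon` — edges that themselves lie on
#' an eps-suboptimal path — are kept. Hop layers from the source set
#' (breadth-first search within the retained subnetwork) are attached for
#' layered layout.
#'
#' `epsilon` is expressed in dual-length (natural-log) units: admitting
#' paths up to `epsilon` above `w*` means admitting penalized confidence
#' products down to `exp(-epsilon)` times the optimum.
#'
#' @inheritParams strongestPath
#' @param epsilon nonnegative slack in dual-length units; `epsilon = 0`
#'   retains exactly the nodes on optimal paths.
#' @param sparse logical; see above. Default `FALSE` (dense).
#' @return an [EpsilonSubnetwork-class]; "no path" result when the sets
#'   are disconnected.
#' @examples
#' tf <- tempfile()
#' writeLines(c("A\tX\t0.9", "X\tB\t0.9", "A\tY\t0.8", "Y\tB\t0.8"), tf)
#' net <- readNetwork(tf, directed = TRUE)
#' nodeLabels(epsilonSubnetwork(net, "A", "B", epsilon = 0.3))
#' @export
epsilonSubnetwork <- function(net, sources, targets, damping = 0.95,
                              epsilon = 0, sparse = FALSE) {
  stopifnot(is(net, "ConfidenceNetwork"))
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon < 0)
    spInputError("epsilon must be a nonnegative number")
  src <- resolveNodeRefs(net, sources, "source")
  tgt <- resolveNodeRefs(net, targets, "target")
  dd <- dualDistances(net, src, tgt, damping)
  if (!is.finite(dd$wStar))
    return(new("EpsilonSubnetwork", found = FALSE, nodes = character(),
               a = numeric(), b = numeric(), wStar = Inf, epsilon = epsilon,
               sparse = isTRUE(sparse), layers = integer(),
               network = inducedSubgraph(net, integer())))
  slack <- 1e-9
  thr <- dd$wStar + epsilon + slack
  real <- seq_len(dd$n)
  member <- real[dd$a[real] + dd$b[real] <= thr]
  subnet <- inducedSubgraph(net, member)
  if (isTRUE(sparse) && nrow(subnet@edges)) {
    orig <- match(subnet@labels, net@labels)
    eF <- orig[subnet@edges$from]; eT <- orig[subnet@edges$to]
    w <- dualWeight(subnet@edges$p, damping)
    keep <- dd$a[eF] + w + dd$b[eT] <= thr
    if (!net@directed)
      keep <- keep | (dd$a[eT] + w + dd$b[eF] <= thr)
    subnet@edges <- subnet@edges[keep, , drop = FALSE]
    rownames(subnet@edges) <- NULL
  }
  al <- adjacencyList(subnet@labels, subnet@edges, subnet@directed)
  startIdx <- match(net@labels[intersect(src, member)], subnet@labels)
  layers <- bfsHopDistances(al$adj, startIdx, length(subnet@labels))
  names(layers) <- subnet@labels
  labs <- subnet@labels
  new("EpsilonSubnetwork", found = TRUE, nodes = labs,
      a = stats::setNames(dd$a[match(labs, net@labels)], labs),
      b = stats::setNames(dd$b[match(labs, net@labels)], labs),
      wStar = dd$wStar, epsilon = epsilon, sparse = isTRUE(sparse),
      layers = layers, network = subnet)
}
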