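#' Random confidence-weighted network
#'
#' Erdős–Rényi-style generator: each (ordered, if directed; unordered
#' otherwise) node pair carries an edge independently with probability
#' `density`, with confidence drawn uniformly from `weightRange`. Node
#' labels are `n000`, `n001`, ... so lexicographic tie-breaking downstream
#' is predictable. Fully deterministic under `seed`; the caller's global
#' random state is left untouched.
#'
#' @param nNodes number of nodes (>= 1).
#' @param density edge probability in [0, 1].
#' @param weightRange length-2 numeric within (0, 1]; confidences are
#'   uniform on this interval. Default `c(0.1, 1)`.
#' @param directed logical, default `FALSE`.
#' @param seed integer seed.
#' @return a [ConfidenceNetwork-class].
#' @export
randomNetwork <- function(nNodes, density, weightRange = c(0.1, 1),
                          directed = FALSE, seed) {
  if (!is.numeric(density) || density < 0 || density > 1)
    spInputError("density must lie in [0, 1]")
  if (!is.numeric(nNodes) || nNodes < 1)
    spInputError("nNodes must be >= 1")
  if (length(weightRange) != 2L || weightRange[1] <= 0 || weightRange[2] > 1 ||
      weightRange[1] > weightRange[2])
    spInputError("weightRange must be within (0, 1]")
  nNodes <- as.integer(nNodes)
  labels <- sprintf("n%03d", seq_len(nNodes) - 1L)
  if (directed) {
    pairs <- expand.grid(from = seq_len(nNodes), to = seq_len(nNodes))
    pairs <- pairs[pairs$from != pairs$to, , drop = FALSE]
  } else {
    pairs <- if (nNodes > 1L) {
      cmb <- utils::combn(nNodes, 2L)
      data.frame(from = cmb[1L, ], to = cmb[2L, ])
    } else data.frame(from = integer(), to = integer())
  }
  withLocalSeed(seed, {
    hit <- stats::runif(nrow(pairs)) < density
    p <- stats::runif(sum(hit), weightRange[1], weightRange[2])
    newConfidenceNetwork(labels, pairs$from[hit], pairs$to[hit], p, directed)
  })
}

#' Network with a planted high-confidence path
#'
#' Embeds a chain of `pathLength` edges at confidence `pHi` between a
#' designated source (`src`) and target (`tgt`), over fresh intermediate
#' nodes, inside Erdős–Rényi background noise whose confidences are
#' capped at `pLo < pHi`. Used to test that high-confidence chains are
#' recovered from noisy networks.
#'
#' @inheritParams randomNetwork
#' @param pathLength number of planted edges L (>= 1); uses L - 1
#'   intermediate nodes, so `nNodes >= L + 1` is required.
#' @param pHi planted edge confidence, in (0, 1].
#' @param pLo upper bound for noise confidences; must be `< pHi`. Noise
#'   weights are uniform on (0.05, pLo].
#' @return list with elements `network` (a
#'   [ConfidenceNetwork-class]) and `planted` (character vector, the
#'   ground-truth chain labels from source to target).
#' @export
plantedPathNetwork <- function(nNodes, density, pathLength = 3, pHi = 0.95,
                               pLo = 0.3, directed = FALSE, seed) {
  if (pHi <= pLo) spInputError("pHi must exceed pLo")
  if (pHi > 1 || pLo <= 0) spInputError("confidences must lie in (0, 1]")
  if (pathLength < 1) spInputError("pathLength must be >= 1")
  if (nNodes < pathLength + 1)
    spInputError("need at least pathLength + 1 nodes")
  nNodes <- as.integer(nNodes); pathLength <- as.integer(pathLength)
  nBg <- nNodes - (pathLength + 1L)
  mids <- if (pathLength > 1L) sprintf("mid%02d", seq_len(pathLength - 1L))
          else character()
  chain <- c("src", mids, "tgt")
  labels <- c(chain, if (nBg > 0L) sprintf("n%03d", seq_len(nBg) - 1L))
  chainIdx <- seq_len(pathLength + 1L)
  if (directed) {
    pairs <- expand.grid(from = seq_len(nNodes), to = seq_len(nNodes))
    pairs <- pairs[pairs$from != pairs$to, , drop = FALSE]
  } else {
    cmb <- utils::combn(nNodes, 2L)
    pairs <- data.frame(from = cmb[1L, ], to = cmb[2L, ])
  }
  # noise must not overwrite a planted edge (max-merge would keep pHi
  # anyway, but excluding them keeps the noise density honest)
  onChain <- paste(pmin(pairs$from, pairs$to), pmax(pairs$from, pairs$to)) %in%
    paste(pmin(chainIdx[-length(chainIdx)], chainIdx[-1L]),
          pmax(chainIdx[-length(chainIdx)], chainIdx[-1L]))
  pairs <- pairs[!onChain, , drop = FALSE]
  withLocalSeed(seed, {
    hit <- stats::runif(nrow(pairs)) < density
    pNoise <- stats::runif(sum(hit), min(0.05, pLo / 2), pLo)
    from <- c(chainIdx[-length(chainIdx)], pairs$from[hit])
    to <- c(chainIdx[-1L], pairs$to[hit])
    p <- c(rep(pHi, pathLength), pNoise)
    list(network = newConfidenceNetwork(labels, from, to, p, directed),
         planted = chain)
  })
}

#' Random signed regulatory network
#'
#' Directed Erdős–Rényi edge sampling; each edge is inhibitory (-1) with
#' probability `inhibitoryFraction`, activating (+1) otherwise.
#' Deterministic under `seed`.
#'
#' @inheritParams randomNetwork
#' @param inhibitoryFraction probability in [0, 1] that an edge is
#'   repressive.
#' @return a [SignedNetwork-class].
#' @export
randomSignedNetwork <- function(nNodes, density, inhibitoryFraction, seed) {
  if (!is.numeric(inhibitoryFraction) || inhibitoryFraction < 0 ||
      inhibitoryFraction > 1)
    spInputError("inhibitoryFraction must lie in [0, 1]")
  if (!is.numeric(density) || density < 0 || density > 1)
    spInputError("density must lie in [0, 1]")
  nNodes <- as.integer(nNodes)
  labels <- sprintf("n%03d", seq_len(nNodes) - 1L)
  pairs <- expand.grid(from = seq_len(nNodes), to = seq_len(nNodes))
  pairs <- pairs[pairs$from != pairs$to, , drop = FALSE]
  withLocalSeed(seed, {
    hit <- stats::runif(nrow(pairs)) < density
    sg <- ifelse(stats::runif(sum(hit)) < inhibitoryFraction, -1L, 1L)
    edges <- data.frame(from = as.integer(pairs$from[hit]),
                        to = as.integer(pairs$to[hit]), sign = sg)
    edges <- edges[order(edges$from, edges$to, edges$sign), , drop = FALSE]
    rownames(edges) <- NULL
    new("SignedNetwork", labels = labels, edges = edges)
  })
}

#' Brute-force strongest-path oracle
#'
#' Exhaustively enumerates all simple source-to-target paths by
#' depth-first search and scores each as `product * d^length`, returning
#' the maximum penalized score and every arg-max node sequence (paths
#' within 1e-9 of the optimal dual length). Intended as an independent
#' check of [strongestPath()] on small instances; refuses networks above
#' `maxNodes` unless the guard is raised explicitly. Partial paths whose
#' score already falls below the incumbent optimum are pruned — exact,
#' because extending a path only multiplies by factors at most 1.
#'
#' @param net a [ConfidenceNetwork-class].
#' @param sources,targets node sets (labels or indices), disjoint.
#' @param d penalty factor in (0, 1].
#' @param maxNodes guard on network size (default 12).
#' @return list with `score` (best penalized score; `NA` if no path),
#'   `dualLength`, and `paths` (list of label vectors, all optimal
#'   paths).
#' @export
bruteForceStrongest <- function(net, sources, targets, d = 0.95,
                                maxNodes = 12L) {
  stopifnot(is(net, "ConfidenceNetwork"))
  if (length(net@labels) > maxNodes)
    spInputError(sprintf(
      "network has %d nodes, above the exhaustive-enumeration guard (%d)",
      length(net@labels), maxNodes))
  src <- resolveNodeRefs(net, sources, "source")
  tgt <- resolveNodeRefs(net, targets, "target")
  if (length(intersect(src, tgt)))
    spInputError("source and target sets must be disjoint")
  n <- length(net@labels)
  al <- adjacencyList(net@labels, net@edges, net@directed)
  pOf <- net@edges$p
  tol <- 1e-9
  best <- Inf           # minimized dual length
  bestPaths <- list()
  isTgt <- logical(n); isTgt[tgt] <- TRUE
  visited <- logical(n)
  step <- -log(d)
  dfs <- function(v, dl, path) {
    # a path may legitimately pass through one target on its way to
    # another, so record and keep exploring
    if (isTgt[v]) {
      if (dl <= best + tol) {
        bestPaths <<- c(bestPaths, list(list(dl = dl, path = path)))
        best <<- min(best, dl)
      }
    }
    nb <- al$adj[[v]]; ei <- al$eidx[[v]]
    for (j in seq_along(nb)) {
      u <- nb[j]
      if (visited[u]) next
      ndl <- dl + step - log(pOf[ei[j]])
      if (ndl > best + tol) next
      visited[u] <<- TRUE
      dfs(u, ndl, c(path, u))
      visited[u] <<- FALSE
    }
  }
  for (s in src) {
    visited[] <- FALSE
    visited[s] <- TRUE
    dfs(s, 0, s)
  }
  if (!length(bestPaths))
    return(list(score = NA_real_, dualLength = Inf, paths = list()))
  dls <- vapply(bestPaths, `[[`, numeric(1), "dl")
  opt <- bestPaths[dls <= best + tol]
  keep <- !duplicated(vapply(opt, function(x)
    paste(x$path, collapse = "\r"), character(1)))
  list(score = exp(-best), dualLength = best,
       paths = lapply(opt[keep], function(x) net@labels[x$path]))
}
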