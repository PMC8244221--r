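# In-code fixture builders and independent oracles used across the suite.
# Oracles deliberately avoid the package's dual-graph machinery: exhaustive
# Floyd-Warshall relaxation, queue BFS, and DFS path enumeration.

# Build a ConfidenceNetwork from a label-based edge data.frame.
makeNet <- function(src, dst, p, directed = FALSE, labels = NULL) {
  labs <- if (is.null(labels)) unique(as.vector(rbind(src, dst))) else labels
  ppiPaths:::newConfidenceNetwork(labs, match(src, labs), match(dst, labs),
                                  p, directed)
}

writeNetFile <- function(src, dst, p, path = tempfile(fileext = ".tsv")) {
  writeLines(sprintf("%s\t%s\t%.10g", src, dst, p), path)
  path
}

# Exhaustive all-pairs dual-distance oracle (Floyd-Warshall), returning
# forward distances a(v) from the source set, backward distances b(v) to
# the target set, and the optimal dual length wStar.
fwDualOracle <- function(net, sources, targets, d) {
  labs <- nodeLabels(net)
  n <- length(labs)
  s <- match(sources, labs); t <- match(targets, labs)
  stopifnot(!anyNA(s), !anyNA(t))
  W <- matrix(Inf, n, n)
  diag(W) <- 0
  e <- edgeTable(net)
  if (nrow(e)) {
    i <- match(e$source, labs); j <- match(e$target, labs)
    w <- -(log(d) + log(e$p))
    for (k in seq_along(i)) {
      W[i[k], j[k]] <- min(W[i[k], j[k]], w[k])
      if (!isDirected(net)) W[j[k], i[k]] <- min(W[j[k], i[k]], w[k])
    }
  }
  for (k in seq_len(n)) W <- pmin(W, outer(W[, k], W[k, ], `+`))
  a <- apply(W[s, , drop = FALSE], 2L, min)
  b <- apply(W[, t, drop = FALSE], 1L, min)
  names(a) <- names(b) <- labs
  list(a = a, b = b, wStar = min(a[labs[t]]))
}

# Queue-based multi-source BFS hop distances over labels.
bfsOracle <- function(net, sources) {
  labs <- nodeLabels(net)
  n <- length(labs)
  e <- edgeTable(net)
  adj <- vector("list", n)
  if (nrow(e)) {
    i <- match(e$source, labs); j <- match(e$target, labs)
    for (k in seq_along(i)) {
      adj[[i[k]]] <- c(adj[[i[k]]], j[k])
      if (!isDirected(net)) adj[[j[k]]] <- c(adj[[j[k]]], i[k])
    }
  }
  dist <- rep(NA_integer_, n)
  q <- match(sources, labs)
  dist[q] <- 0L
  while (length(q)) {
    v <- q[1L]; q <- q[-1L]
    for (u in adj[[v]]) if (is.na(dist[u])) {
      dist[u] <- dist[v] + 1L
      q <- c(q, u)
    }
  }
  names(dist) <- labs
  dist
}

# Exhaustive hop-minimal signed path oracle: enumerate ALL simple s -> t
# paths by DFS, keep those of minimal length, expand parallel-edge sign
# combinations, return canonical "nodes|signs" strings.
signedOracle <- function(net, s, t) {
  labs <- nodeLabels(net)
  e <- edgeTable(net)
  n <- length(labs)
  adj <- vector("list", n)
  sgn <- list()
  if (nrow(e)) {
    i <- match(e$source, labs); j <- match(e$target, labs)
    for (k in seq_along(i)) {
      adj[[i[k]]] <- unique(c(adj[[i[k]]], j[k]))
      key <- paste(i[k], j[k])
      sgn[[key]] <- c(sgn[[key]], e$sign[k])
    }
  }
  si <- match(s, labs); ti <- match(t, labs)
  found <- list()
  visited <- logical(n)
  dfs <- function(v, path) {
    if (v == ti) { found[[length(found) + 1L]] <<- path; return() }
    for (u in adj[[v]]) if (!visited[u]) {
      visited[u] <<- TRUE
      dfs(u, c(path, u))
      visited[u] <<- FALSE
    }
  }
  visited[si] <- TRUE
  dfs(si, si)
  if (!length(found)) return(character())
  lens <- lengths(found)
  minimal <- found[lens == min(lens)]
  out <- character()
  for (pn in minimal) {
    combos <- list(integer())
    for (k in seq_len(length(pn) - 1L)) {
      ss <- sort(unique(sgn[[paste(pn[k], pn[k + 1L])]]))
      combos <- unlist(lapply(combos, function(pre)
        lapply(ss, function(x) c(pre, x))), recursive = FALSE)
    }
    for (sg in combos)
      out <- c(out, paste(paste(labs[pn], collapse = ","),
                          paste(sg, collapse = ","), sep = "|"))
  }
  sort(unique(out))
}

# Independently computed expansion candidate scores: total confidence of
# edges between each external node and the current set.
expansionScoreOracle <- function(net, current) {
  labs <- nodeLabels(net)
  e <- edgeTable(net)
  score <- setNames(numeric(length(labs)), labs)
  for (k in seq_len(nrow(e))) {
    a <- e$source[k]; b <- e$target[k]
    if (a %in% current && !(b %in% current)) score[b] <- score[b] + e$p[k]
    if (b %in% current && !(a %in% current)) score[a] <- score[a] + e$p[k]
  }
  score[score > 0]
}

# The deterministic random-instance grid shared by the sweep tests.
sweepInstance <- function(s) {
  list(n = 4L + (s %% 7L),
       density = c(0.2, 0.5, 0.8)[(s %% 3L) + 1L],
       directed = (s %% 2L) == 1L,
       d = c(1.0, 0.95, 0.8)[((s %/% 3L) %% 3L) + 1L])
}

sweepSetup <- function(s) {
  cfg <- sweepInstance(s)
  net <- randomNetwork(cfg$n, cfg$density, directed = cfg$directed, seed = s)
  labs <- nodeLabels(net)
  nA <- 1L + (s %% 2L)
  sources <- labs[seq_len(nA)]
  targets <- labs[c(cfg$n - 1L, cfg$n)]
  targets <- setdiff(targets, sources)
  c(cfg, list(net = net, sources = sources, targets = targets))
}
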