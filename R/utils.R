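# Condition constructors: spFormatError for malformed input files,
# spInputError for invalid arguments/parameters, spIOError for filesystem
# failures. All inherit from spError so callers can catch the family.
spError <- function(msg, class) {
  stop(structure(class = c(class, "spError", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

spFormatError <- function(msg) spError(msg, "spFormatError")
spInputError  <- function(msg) spError(msg, "spInputError")
spIOError     <- function(msg) spError(msg, "spIOError")

# Identifier normalization shared by annotation lookup and queries.
normalizeId <- function(x) tolower(trimws(x))

# Evaluate expr with a local RNG seed, restoring the caller's random state.
# Generators never leak into (or depend on) the global random stream.
withLocalSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    spInputError("seed must be a single integer")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Map user-supplied node references (labels or 1-based indices) onto
# internal indices of a network, with a clear error naming the misses.
resolveNodeRefs <- function(net, x, what = "node") {
  if (is.numeric(x)) {
    idx <- as.integer(x)
    if (any(is.na(idx)) || any(idx < 1L | idx > length(net@labels)))
      spInputError(sprintf("%s index out of range", what))
    return(unique(idx))
  }
  idx <- match(as.character(x), net@labels)
  if (anyNA(idx))
    spInputError(sprintf("unknown %s label(s): %s", what,
                         paste(unique(x[is.na(idx)]), collapse = ", ")))
  unique(idx)
}

# Directed adjacency list over edge rows; undirected networks contribute
# both orientations. Returns list(adj = neighbor index lists,
# eidx = parallel list of edge-row numbers).
adjacencyList <- function(labels, edges, directed) {
  n <- length(labels)
  from <- edges$from; to <- edges$to
  if (!directed) {
    eid <- c(seq_len(nrow(edges)), seq_len(nrow(edges)))
    src <- c(from, to); dst <- c(to, from)
  } else {
    eid <- seq_len(nrow(edges))
    src <- from; dst <- to
  }
  adj <- vector("list", n)
  eix <- vector("list", n)
  if (length(src)) {
    o <- order(src)
    src <- src[o]; dst <- dst[o]; eid <- eid[o]
    runs <- split(seq_along(src), src)
    for (k in names(runs)) {
      i <- as.integer(k)
      adj[[i]] <- dst[runs[[k]]]
      eix[[i]] <- eid[runs[[k]]]
    }
  }
  list(adj = adj, eidx = eix)
}

# Multi-source BFS hop distances over an adjacency list; NA_integer_ for
# unreachable nodes.
bfsHopDistances <- function(adj, starts, n) {
  dist <- rep(NA_integer_, n)
  dist[starts] <- 0L
  frontier <- starts
  d <- 0L
  while (length(frontier)) {
    d <- d + 1L
    nxt <- integer()
    for (v in frontier) {
      for (u in adj[[v]]) {
        if (is.na(dist[u])) {
          dist[u] <- d
          nxt <- c(nxt, u)
        }
      }
    }
    frontier <- nxt
  }
  dist
}

# Atomic text write: assemble in a sibling temp file, then rename.
atomicWriteLines <- function(lines, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) spIOError(sprintf("directory does not exist: %s", dir))
  tmp <- tempfile(tmpdir = dir, fileext = ".tmp")
  ok <- tryCatch({ writeLines(lines, tmp); TRUE }, error = function(e) FALSE)
  if (!ok || !file.rename(tmp, path)) {
    if (file.exists(tmp)) unlink(tmp)
    spIOError(sprintf("cannot write %s", path))
  }
  invisible(NULL)
}
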