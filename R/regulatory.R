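#' Read a signed regulatory network
#'
#' Parses a TRRUST-style tab-separated edge list: source gene, target
#' gene, mode of regulation. Modes are mapped case-insensitively:
#' `Activation` to +1, `Repression` to -1. Rows with mode `Unknown` are
#' dropped by default (their count is reported in a message); they can
#' instead be treated as activating (`unknownPolicy = "positive"`) or
#' expanded into both an activating and an inhibitory edge (`"both"`).
#' Any other mode string is a format error naming the offending line.
#' Extra columns (e.g. TRRUST's PubMed references) are ignored.
#' Parallel same-direction edges with conflicting signs are kept as two
#' distinct edges; duplicates of the same sign are collapsed.
#'
#' @param path file path (UTF-8, tab-separated, >= 3 columns, no header).
#' @param annotation optional [AnnotationTable-class]; endpoints must then
#'   resolve uniquely.
#' @param unknownPolicy `"drop"` (default), `"positive"`, or `"both"`.
#' @return a [SignedNetwork-class].
#' @export
readSignedNetwork <- function(path, annotation = NULL,
                              unknownPolicy = c("drop", "positive", "both")) {
  unknownPolicy <- match.arg(unknownPolicy)
  if (!file.exists(path)) spIOError(sprintf("file not found: %s", path))
  raw <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- nzchar(trimws(raw))
  lineno <- which(keep)
  if (!any(keep)) spFormatError("signed network file is empty")
  fields <- strsplit(raw[keep], "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    spFormatError(sprintf("signed network line %d has fewer than 3 columns",
                          lineno[short[1L]]))
  srcName <- trimws(vapply(fields, `[[`, character(1), 1L))
  dstName <- trimws(vapply(fields, `[[`, character(1), 2L))
  mode <- tolower(trimws(vapply(fields, `[[`, character(1), 3L)))
  known <- mode %in% c("activation", "repression", "unknown")
  if (any(!known))
    spFormatError(sprintf("unrecognized regulation mode '%s' at line %d",
                          mode[!known][1L], lineno[!known][1L]))
  unk <- mode == "unknown"
  if (any(unk) && unknownPolicy == "drop") {
    message(sprintf("dropped %d edge(s) with unknown regulation mode", sum(unk)))
    srcName <- srcName[!unk]; dstName <- dstName[!unk]; mode <- mode[!unk]
  }
  sign <- ifelse(mode == "repression", -1L, 1L)
  if (unknownPolicy == "both" && any(mode == "unknown")) {
    dup <- mode == "unknown"
    srcName <- c(srcName, srcName[dup])
    dstName <- c(dstName, dstName[dup])
    sign <- c(sign, rep(-1L, sum(dup)))
  }
  if (!is.null(annotation)) {
    stopifnot(is(annotation, "AnnotationTable"))
    uniq <- unique(c(srcName, dstName))
    idx <- lapply(uniq, function(nm) resolveId(annotation, nm))
    bad <- uniq[lengths(idx) != 1L]
    if (length(bad))
      spInputError(sprintf("endpoint(s) missing or ambiguous in annotation: %s",
                           paste(utils::head(bad, 5L), collapse = ", ")))
    map <- stats::setNames(vapply(idx, `[[`, integer(1), 1L), uniq)
    labels <- nodeLabels(annotation)
    from <- unname(map[srcName]); to <- unname(map[dstName])
  } else {
    labels <- unique(as.vector(rbind(srcName, dstName)))
    from <- match(srcName, labels); to <- match(dstName, labels)
  }
  loops <- from == to
  if (any(loops)) {
    message(sprintf("dropped %d self-loop edge(s)", sum(loops)))
    from <- from[!loops]; to <- to[!loops]; sign <- sign[!loops]
  }
  key <- !duplicated(paste(from, to, sign))
  edges <- data.frame(from = as.integer(from[key]), to = as.integer(to[key]),
                      sign = as.integer(sign[key]))
  edges <- edges[order(edges$from, edges$to, edges$sign), , drop = FALSE]
  rownames(edges) <- NULL
  new("SignedNetwork", labels = labels, edges = edges)
}

#' Classify a regulatory path by its sign product
#'
#' A path is activating when the product of its edge signs is +1 — i.e.
#' when it contains an even number of repressive links (two repressions
#' cancel) — and inhibitory when the product is -1.
#'
#' @param signs non-empty vector of +1/-1 edge signs along a path.
#' @return `"activating"` or `"inhibitory"`.
#' @examples
#' classifyPath(c(1, 1))    # activating
#' classifyPath(c(1, -1))   # inhibitory
#' classifyPath(c(-1, -1))  # activating (double repression)
#' @export
classifyPath <- function(signs) {
  if (length(signs) == 0L)
    spInputError("a zero-length path has no regulatory mode")
  if (!all(signs %in% c(-1, 1)))
    spInputError("signs must be +1 or -1")
  if (prod(signs) > 0) "activating" else "inhibitory"
}

#' Hop-minimal regulatory paths between source and target genes
#'
#' For each (source, target) pair independently, finds the minimum number
#' of links connecting them by breadth-first search on the signed
#' directed network, enumerates *all* paths of that minimal length via
#' the BFS predecessor DAG (distinct minimal paths can carry different
#' modes), classifies each by its edge-sign product, and returns those
#' matching the mode filter. Parallel conflicting-sign edges yield one
#' path per sign combination. Pairs with no connecting path are omitted
#' from the result and listed in its `noPath` attribute; a gene that is
#' both source and target yields no path to itself.
#'
#' @param net a [SignedNetwork-class].
#' @param sources,targets node sets (labels or 1-based indices); may
#'   overlap.
#' @param modeFilter `"both"` (default), `"activating"` or
#'   `"inhibitory"`.
#' @param maxPerPair cap on enumerated paths per pair (default 100); a
#'   warning reports pairs where the cap was hit.
#' @return data.frame with one row per path: `source`, `target`,
#'   `length`, `mode`, and list-columns `nodes` (label sequence) and
#'   `signs` (edge signs). Attribute `noPath`: data.frame of unconnected
#'   pairs.
#' @export
regulatoryPaths <- function(net, sources, targets,
                            modeFilter = c("both", "activating", "inhibitory"),
                            maxPerPair = 100L) {
  modeFilter <- match.arg(modeFilter)
  stopifnot(is(net, "SignedNetwork"))
  src <- resolveNodeRefs(net, sources, "source")
  tgt <- resolveNodeRefs(net, targets, "target")
  n <- length(net@labels)
  # unsigned adjacency for BFS; per (u,v) the set of available signs
  e <- unique(net@edges[, c("from", "to")])
  e$p <- rep(1, nrow(e))
  al <- adjacencyList(net@labels, e, directed = TRUE)
  signKey <- split(net@edges$sign, paste(net@edges$from, net@edges$to))

  rows <- list()
  noPath <- list()
  capped <- character()
  for (s in src) {
    dist <- bfsHopDistances(al$adj, s, n)
    for (t in tgt) {
      if (t == s) next
      if (is.na(dist[t])) {
        noPath[[length(noPath) + 1L]] <-
          data.frame(source = net@labels[s], target = net@labels[t])
        next
      }
      paths <- enumerateMinimalPaths(al$adj, dist, s, t, maxPerPair)
      if (attr(paths, "capped")) capped <- c(capped,
        sprintf("%s->%s", net@labels[s], net@labels[t]))
      for (pn in paths) {
        combos <- signCombinations(pn, signKey)
        for (sg in combos) {
          md <- classifyPath(sg)
          if (modeFilter != "both" && md != modeFilter) next
          rows[[length(rows) + 1L]] <- list(
            source = net@labels[s], target = net@labels[t],
            length = length(pn) - 1L, mode = md,
            nodes = net@labels[pn], signs = sg)
        }
      }
    }
  }
  if (length(capped))
    warning(sprintf("path cap (%d) hit for pair(s): %s", maxPerPair,
                    paste(capped, collapse = ", ")), call. = FALSE)
  out <- data.frame(
    source = vapply(rows, `[[`, character(1), "source"),
    target = vapply(rows, `[[`, character(1), "target"),
    length = vapply(rows, `[[`, integer(1), "length"),
    mode = vapply(rows, `[[`, character(1), "mode"))
  out$nodes <- lapply(rows, `[[`, "nodes")
  out$signs <- lapply(rows, `[[`, "signs")
  attr(out, "noPath") <- if (length(noPath)) do.call(rbind, noPath)
                         else data.frame(source = character(), target = character())
  out
}

# All hop-minimal s -> t node sequences: DFS forward over the BFS
# predecessor DAG (arcs u -> v with dist[v] == dist[u] + 1), up to cap.
enumerateMinimalPaths <- function(adj, dist, s, t, cap) {
  out <- list()
  cappedFlag <- FALSE
  recurse <- function(prefix, v) {
    if (length(out) >= cap) { cappedFlag <<- TRUE; return() }
    if (v == t) { out[[length(out) + 1L]] <<- c(prefix, v); return() }
    for (u in adj[[v]]) {
      if (!is.na(dist[u]) && dist[u] == dist[v] + 1L && dist[u] <= dist[t])
        recurse(c(prefix, v), u)
    }
  }
  recurse(integer(), s)
  attr(out, "capped") <- cappedFlag
  out
}

# Expand a node sequence into all per-edge sign assignments (cartesian
# product over parallel conflicting-sign edges).
signCombinations <- function(pathNodes, signKey) {
  per <- lapply(seq_len(length(pathNodes) - 1L), function(i)
    sort(signKey[[paste(pathNodes[i], pathNodes[i + 1L])]], decreasing = TRUE))
  combos <- list(integer())
  for (ss in per) {
    combos <- unlist(lapply(combos, function(pre)
      lapply(ss, function(x) c(pre, x))), recursive = FALSE)
  }
  combos
}
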