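#' Read a confidence-weighted network
#'
#' Parses the three-column network dialect: tab-separated rows of source
#' node, target node, confidence score in (0, 1]. When an annotation
#' table is supplied, endpoint names are resolved through it and must
#' resolve to exactly one node each (ambiguous aliases are an error here,
#' unlike in query lists); the network then spans all annotated nodes,
#' including annotated nodes without edges. Without a table, node names
#' are used verbatim and interned in order of first appearance.
#'
#' Duplicate edges (for undirected networks, (A,B) and (B,A) count as the
#' same edge) are merged keeping the maximum confidence; self-loops are
#' dropped with a message — they can never lie on a simple source-target
#' path. Scores outside (0, 1] after optional rescaling are a hard error;
#' `scoreDivisor` (e.g. 1000 for raw STRING dumps) rescales raw scores
#' before validation.
#'
#' @param path network file path (UTF-8, tab-separated, 3 columns, no
#'   header).
#' @param annotation optional [AnnotationTable-class].
#' @param directed logical; PPI networks are typically undirected,
#'   signaling networks directed. Default `FALSE`.
#' @param scoreDivisor positive number dividing raw scores before
#'   validation; default 1.
#' @return a [ConfidenceNetwork-class].
#' @examples
#' tf <- tempfile()
#' writeLines(c("A\tB\t0.9", "B\tC\t0.8"), tf)
#' readNetwork(tf)
#' @export
readNetwork <- function(path, annotation = NULL, directed = FALSE,
                        scoreDivisor = 1) {
  if (!file.exists(path)) spIOError(sprintf("file not found: %s", path))
  if (!is.numeric(scoreDivisor) || scoreDivisor <= 0)
    spInputError("scoreDivisor must be positive")
  raw <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- nzchar(trimws(raw))
  lineno <- which(keep)
  if (!any(keep))
    return(newConfidenceNetwork(character(), integer(), integer(),
                                numeric(), directed))
  fields <- strsplit(raw[keep], "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    spFormatError(sprintf("network file line %d has fewer than 3 columns",
                          lineno[short[1L]]))
  srcName <- trimws(vapply(fields, `[[`, character(1), 1L))
  dstName <- trimws(vapply(fields, `[[`, character(1), 2L))
  p <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3L)))
  bad <- which(is.na(p))
  if (length(bad))
    spFormatError(sprintf("non-numeric confidence at line %d", lineno[bad[1L]]))
  p <- p / scoreDivisor
  bad <- which(p <= 0 | p > 1)
  if (length(bad))
    spFormatError(sprintf(
      "confidence %.6g outside (0, 1] at line %d", p[bad[1L]], lineno[bad[1L]]))

  if (!is.null(annotation)) {
    stopifnot(is(annotation, "AnnotationTable"))
    uniq <- unique(c(srcName, dstName))
    idx <- lapply(uniq, function(nm) resolveId(annotation, nm))
    miss <- uniq[lengths(idx) == 0L]
    if (length(miss))
      spInputError(sprintf("network endpoint(s) not in annotation: %s",
                           paste(utils::head(miss, 5L), collapse = ", ")))
    ambi <- uniq[lengths(idx) > 1L]
    if (length(ambi))
      spInputError(sprintf("ambiguous network endpoint(s): %s",
                           paste(utils::head(ambi, 5L), collapse = ", ")))
    map <- stats::setNames(vapply(idx, `[[`, integer(1), 1L), uniq)
    labels <- nodeLabels(annotation)
    from <- unname(map[srcName]); to <- unname(map[dstName])
  } else {
    labels <- unique(as.vector(rbind(srcName, dstName)))
    from <- match(srcName, labels); to <- match(dstName, labels)
  }
  newConfidenceNetwork(labels, from, to, p, directed)
}

# Assemble a validated ConfidenceNetwork from parallel edge vectors:
# drops self-loops (with a message), canonicalizes undirected orientation,
# max-merges duplicates.
newConfidenceNetwork <- function(labels, from, to, p, directed) {
  loops <- from == to
  if (any(loops)) {
    message(sprintf("dropped %d self-loop edge(s)", sum(loops)))
    from <- from[!loops]; to <- to[!loops]; p <- p[!loops]
  }
  if (length(from) && !directed) {
    a <- pmin(from, to); b <- pmax(from, to)
    from <- a; to <- b
  }
  if (length(from)) {
    dt <- data.table::data.table(from = as.integer(from),
                                 to = as.integer(to), p = as.numeric(p))
    dt <- dt[, list(p = max(p)), by = c("from", "to")]
    data.table::setorder(dt, from, to)
    edges <- as.data.frame(dt)
  } else {
    edges <- data.frame(from = integer(), to = integer(), p = numeric())
  }
  new("ConfidenceNetwork", labels = as.character(labels), edges = edges,
      directed = isTRUE(directed))
}

#' Induced subgraph
#'
#' Restricts a network to a node subset, keeping exactly the edges with
#' both endpoints in the subset. Weights and labels are unchanged;
#' isolated members of the subset are retained as nodes. Idempotent.
#'
#' @param x a [ConfidenceNetwork-class].
#' @param nodes node labels or 1-based indices; unknown entries are an
#'   error.
#' @return a [ConfidenceNetwork-class] on the subset (label order follows
#'   the original network).
#' @name inducedSubgraph
#' @export
setMethod("inducedSubgraph", "ConfidenceNetwork", function(x, nodes) {
  idx <- sort(resolveNodeRefs(x, nodes))
  newIdx <- rep(NA_integer_, length(x@labels))
  newIdx[idx] <- seq_along(idx)
  e <- x@edges
  keep <- !is.na(newIdx[e$from]) & !is.na(newIdx[e$to])
  new("ConfidenceNetwork", labels = x@labels[idx],
      edges = data.frame(from = newIdx[e$from[keep]],
                         to = newIdx[e$to[keep]],
                         p = e$p[keep]),
      directed = x@directed)
})

#' Write a network to disk
#'
#' `"tsv"` writes the three-column input dialect (labels, confidence), so
#' writing and re-reading round-trips the node, edge and weight sets up to
#' edge order. `"sif"` writes Cytoscape Simple Interaction Format lines
#' `source pp target`, with the confidences in a sidecar tab-separated
#' edge-attribute table at `<path>.attrs.tsv`.
#'
#' @param net a [ConfidenceNetwork-class].
#' @param path output file path.
#' @param format `"tsv"` (default) or `"sif"`.
#' @return invisibly, the main output path.
#' @export
writeNetwork <- function(net, path, format = c("tsv", "sif")) {
  format <- match.arg(format)
  stopifnot(is(net, "ConfidenceNetwork"))
  e <- edgeTable(net)
  if (format == "tsv") {
    lines <- if (nrow(e))
      sprintf("%s\t%s\t%.15g", e$source, e$target, e$p)
    else character()
    atomicWriteLines(lines, path)
  } else {
    lines <- if (nrow(e)) sprintf("%s pp %s", e$source, e$target) else character()
    atomicWriteLines(lines, path)
    attrs <- c("source\tinteraction\ttarget\tconfidence",
               if (nrow(e))
                 sprintf("%s\tpp\t%s\t%.15g", e$source, e$target, e$p))
    atomicWriteLines(attrs, paste0(path, ".attrs.tsv"))
  }
  invisible(path)
}
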