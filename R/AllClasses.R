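#' @import methods
NULL

#' AnnotationTable: identifier-to-node lookup
#'
#' Maps any of a node's alternative identifiers (gene symbols, accession
#' numbers, ...) to its internal node index. Built from a tab-separated
#' annotation file in which each row describes one network node: the first
#' column is the canonical label and every additional column is a
#' comma-separated list of alternative identifiers. Matching is
#' whitespace-trimmed and case-insensitive.
#'
#' @slot labels character vector of canonical node labels; position defines
#'   the node index (1-based inside R, reported 0-based in files written for
#'   interoperability).
#' @slot altIds list with one element per node; each element is a list of
#'   character vectors, one per extra annotation column.
#' @slot lookup hashed environment mapping a normalized identifier to the
#'   integer vector of node indices carrying it (several nodes may share an
#'   alias).
#'
#' @seealso [readAnnotation()], [resolveId()]
#' @export
setClass("AnnotationTable",
  representation(labels = "character", altIds = "list", lookup = "environment"))

setValidity("AnnotationTable", function(object) {
  msg <- character()
  if (length(object@labels) == 0L)
    msg <- c(msg, "annotation table has no records")
  if (any(!nzchar(object@labels)))
    msg <- c(msg, "record with empty label")
  if (length(object@altIds) != length(object@labels))
    msg <- c(msg, "altIds length differs from labels length")
  if (length(msg)) msg else TRUE
})

#' ConfidenceNetwork: a confidence-weighted interaction network
#'
#' A directed or undirected graph whose edge weights are interaction
#' confidence scores in (0, 1], interpreted as the probability that the
#' interaction is real. Undirected edges are stored once (canonical
#' orientation, smaller index first) and traversed both ways. Duplicate
#' edges are merged keeping the maximum confidence and self-loops are
#' dropped at parse time, so a valid object has neither.
#'
#' @slot labels character vector of node labels; position defines the node
#'   index.
#' @slot edges data.frame with integer columns \code{from}, \code{to} and a
#'   numeric column \code{p} (confidence in (0, 1]).
#' @slot directed logical scalar.
#'
#' @seealso [readNetwork()], [strongestPath()], [inducedSubgraph()]
#' @export
setClass("ConfidenceNetwork",
  representation(labels = "character", edges = "data.frame",
                 directed = "logical"))

setValidity("ConfidenceNetwork", function(object) {
  msg <- character()
  n <- length(object@labels)
  e <- object@edges
  if (!all(c("from", "to", "p") %in% names(e)))
    return("edges must have columns from, to, p")
  if (anyDuplicated(object@labels))
    msg <- c(msg, "duplicated node labels")
  if (nrow(e)) {
    if (any(e$from < 1L | e$from > n | e$to < 1L | e$to > n))
      msg <- c(msg, "edge endpoint out of range")
    if (any(e$from == e$to))
      msg <- c(msg, "self-loop edge retained")
    if (any(e$p <= 0 | e$p > 1))
      msg <- c(msg, "confidence outside (0, 1]")
    key <- if (isTRUE(object@directed)) paste(e$from, e$to)
           else paste(pmin(e$from, e$to), pmax(e$from, e$to))
    if (anyDuplicated(key))
      msg <- c(msg, "duplicate edges present (should have been max-merged)")
  }
  if (length(msg)) msg else TRUE
})

#' SignedNetwork: a signed directed regulatory network
#'
#' A directed graph with edge signs +1 (activation) or -1 (repression),
#' typically a transcription-factor / target network in the TRRUST dialect.
#' Parallel same-direction edges with conflicting signs are kept as two
#' distinct edges.
#'
#' @slot labels character vector of node labels.
#' @slot edges data.frame with integer columns \code{from}, \code{to},
#'   \code{sign} (each sign exactly +1 or -1).
#'
#' @seealso [readSignedNetwork()], [regulatoryPaths()]
#' @export
setClass("SignedNetwork",
  representation(labels = "character", edges = "data.frame"))

setValidity("SignedNetwork", function(object) {
  msg <- character()
  n <- length(object@labels)
  e <- object@edges
  if (!all(c("from", "to", "sign") %in% names(e)))
    return("edges must have columns from, to, sign")
  if (nrow(e)) {
    if (any(e$from < 1L | e$from > n | e$to < 1L | e$to > n))
      msg <- c(msg, "edge endpoint out of range")
    if (!all(e$sign %in% c(-1L, 1L)))
      msg <- c(msg, "edge sign must be +1 or -1")
    if (anyDuplicated(paste(e$from, e$to, e$sign)))
      msg <- c(msg, "duplicate signed edge")
  }
  if (length(msg)) msg else TRUE
})

#' PathResult: one strongest path
#'
#' The result of a strongest-path query: the source-to-target path
#' maximizing the product of edge confidences times D^(edge count), found
#' as a shortest path in the dual graph. A query between disconnected sets
#' yields a "no path" result (\code{pathFound(x)} is \code{FALSE}) rather
#' than an error, so batch runs over several databases can continue.
#'
#' @slot found logical; FALSE for the "no path" result.
#' @slot nodes character vector of node labels along the path (super
#'   source/sink excluded); empty when no path exists.
#' @slot edgeCount integer number of edges.
#' @slot product numeric product of edge confidences P(e).
#' @slot penalizedScore numeric \code{product * damping^edgeCount}, the
#'   maximized objective.
#' @slot dualLength numeric total dual length, equal to
#'   \code{-log(penalizedScore)}.
#' @slot damping numeric penalty factor D used for the query.
#'
#' @seealso [strongestPath()]
#' @export
setClass("PathResult",
  representation(found = "logical", nodes = "character",
                 edgeCount = "integer", product = "numeric",
                 penalizedScore = "numeric", dualLength = "numeric",
                 damping = "numeric"))

setValidity("PathResult", function(object) {
  msg <- character()
  if (object@found) {
    if (length(object@nodes) < 1L)
      msg <- c(msg, "found path must have at least one node")
    if (object@edgeCount != length(object@nodes) - 1L)
      msg <- c(msg, "edgeCount must equal length(nodes) - 1")
    if (anyDuplicated(object@nodes))
      msg <- c(msg, "path must be simple")
    if (is.finite(object@dualLength) &&
        abs(object@dualLength + log(object@penalizedScore)) > 1e-9)
      msg <- c(msg, "dualLength inconsistent with penalizedScore")
  }
  if (length(msg)) msg else TRUE
})

#' EpsilonSubnetwork: nodes on epsilon-suboptimal strongest paths
#'
#' The node set V_eps of all nodes v with a(v) + b(v) <= w* + eps, where
#' a(v) is the shortest dual distance from the source set, b(v) the
#' shortest dual distance to the target set, and w* the optimal dual
#' length; together with the retained edge set (dense mode: induced
#' subgraph on V_eps; sparse mode: only edges that themselves lie on an
#' eps-suboptimal path) and BFS hop layers from the source set for layout.
#'
#' @slot found logical; FALSE when no source-to-target path exists.
#' @slot nodes character vector, the members of V_eps.
#' @slot a named numeric, forward dual distance per member of V_eps.
#' @slot b named numeric, backward dual distance per member of V_eps.
#' @slot wStar numeric optimal dual length.
#' @slot epsilon numeric threshold, in dual-length (natural log) units.
#' @slot sparse logical; TRUE when the sparse edge rule was applied.
#' @slot layers named integer, BFS hop distance from the source set within
#'   the retained subnetwork (NA for nodes unreachable in it).
#' @slot network ConfidenceNetwork over V_eps holding the retained edges.
#'
#' @seealso [epsilonSubnetwork()]
#' @export
setClass("EpsilonSubnetwork",
  representation(found = "logical", nodes = "character", a = "numeric",
                 b = "numeric", wStar = "numeric", epsilon = "numeric",
                 sparse = "logical", layers = "integer",
                 network = "ConfidenceNetwork"))

setValidity("EpsilonSubnetwork", function(object) {
  msg <- character()
  if (object@found) {
    slack <- 1e-9
    bad <- object@a[object@nodes] + object@b[object@nodes] >
      object@wStar + object@epsilon + slack
    if (any(bad))
      msg <- c(msg, "node violates a(v) + b(v) <= w* + epsilon")
    if (!setequal(nodeLabels(object@network), object@nodes))
      msg <- c(msg, "retained network nodes differ from V_eps")
  }
  if (length(msg)) msg else TRUE
})

#' ExpansionResult: greedy confidence-weighted network expansion
#'
#' Records each expansion round (which nodes were added and their total
#' interaction confidence with the then-current set) together with the
#' final node set and the induced network on it.
#'
#' @slot rounds list of data.frames with columns \code{label},
#'   \code{score}; one element per round.
#' @slot nodes character vector, the final node set (a superset of the
#'   input nodes present in the background network).
#' @slot network ConfidenceNetwork induced on \code{nodes}.
#' @slot shortfall logical; TRUE when fewer candidates than requested
#'   existed.
#'
#' @seealso [expandNetwork()]
#' @export
setClass("ExpansionResult",
  representation(rounds = "list", nodes = "character",
                 network = "ConfidenceNetwork", shortfall = "logical"))
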