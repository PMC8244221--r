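#' @rdname nNodes
#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))

#' @rdname nodeLabels
#' @export
setGeneric("nodeLabels", function(x) standardGeneric("nodeLabels"))

#' @rdname edgeTable
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))

#' @rdname isDirected
#' @export
setGeneric("isDirected", function(x) standardGeneric("isDirected"))

#' @rdname inducedSubgraph
#' @export
setGeneric("inducedSubgraph", function(x, nodes) standardGeneric("inducedSubgraph"))

#' @rdname pathFound
#' @export
setGeneric("pathFound", function(x) standardGeneric("pathFound"))

#' @rdname pathNodes
#' @export
setGeneric("pathNodes", function(x) standardGeneric("pathNodes"))

#' Number of nodes
#'
#' @param x an `AnnotationTable`, `ConfidenceNetwork` or `SignedNetwork`.
#' @return integer scalar.
#' @name nNodes
#' @aliases nNodes,ConfidenceNetwork-method nNodes,SignedNetwork-method
#'   nNodes,AnnotationTable-method
#' @export
setMethod("nNodes", "ConfidenceNetwork", function(x) length(x@labels))

#' @rdname nNodes
setMethod("nNodes", "SignedNetwork", function(x) length(x@labels))

#' @rdname nNodes
setMethod("nNodes", "AnnotationTable", function(x) length(x@labels))

#' Node labels
#'
#' @param x a network or result object.
#' @return character vector of labels; for path and subnetwork results,
#'   the labels of the nodes in the result.
#' @name nodeLabels
#' @export
setMethod("nodeLabels", "ConfidenceNetwork", function(x) x@labels)

#' @rdname nodeLabels
setMethod("nodeLabels", "SignedNetwork", function(x) x@labels)

#' @rdname nodeLabels
setMethod("nodeLabels", "AnnotationTable", function(x) x@labels)

#' @rdname nodeLabels
setMethod("nodeLabels", "PathResult", function(x) x@nodes)

#' @rdname nodeLabels
setMethod("nodeLabels", "EpsilonSubnetwork", function(x) x@nodes)

#' @rdname nodeLabels
setMethod("nodeLabels", "ExpansionResult", function(x) x@nodes)

#' Edge table with labels
#'
#' Returns the edge list as a data.frame with source/target labels rather
#' than internal indices.
#'
#' @param x a `ConfidenceNetwork`, `SignedNetwork`, `EpsilonSubnetwork` or
#'   `ExpansionResult`.
#' @return data.frame with columns `source`, `target`, and `p`
#'   (confidence) or `sign`.
#' @name edgeTable
#' @export
setMethod("edgeTable", "ConfidenceNetwork", function(x) {
  data.frame(source = x@labels[x@edges$from],
             target = x@labels[x@edges$to],
             p = x@edges$p)
})

#' @rdname edgeTable
setMethod("edgeTable", "SignedNetwork", function(x) {
  data.frame(source = x@labels[x@edges$from],
             target = x@labels[x@edges$to],
             sign = x@edges$sign)
})

#' @rdname edgeTable
setMethod("edgeTable", "EpsilonSubnetwork", function(x) edgeTable(x@network))

#' @rdname edgeTable
setMethod("edgeTable", "ExpansionResult", function(x) edgeTable(x@network))

#' Directedness flag
#'
#' @param x a `ConfidenceNetwork` or `SignedNetwork`.
#' @return logical scalar; signed regulatory networks are always directed.
#' @name isDirected
#' @export
setMethod("isDirected", "ConfidenceNetwork", function(x) x@directed)

#' @rdname isDirected
setMethod("isDirected", "SignedNetwork", function(x) TRUE)

#' Whether a source-to-target path exists
#'
#' @param x a `PathResult` or `EpsilonSubnetwork`.
#' @return logical scalar. The "no path" outcome is a first-class result,
#'   not an error.
#' @name pathFound
#' @export
setMethod("pathFound", "PathResult", function(x) x@found)

#' @rdname pathFound
setMethod("pathFound", "EpsilonSubnetwork", function(x) x@found)

#' Ordered node sequence of a path
#'
#' @param x a `PathResult`.
#' @return character vector of labels from source to target.
#' @name pathNodes
#' @export
setMethod("pathNodes", "PathResult", function(x) x@nodes)

setMethod("show", "ConfidenceNetwork", function(object) {
  cat(sprintf("ConfidenceNetwork: %d nodes, %d %s edges\n",
              nNodes(object), nrow(object@edges),
              if (object@directed) "directed" else "undirected"))
  if (nrow(object@edges))
    cat(sprintf("confidence range [%.3g, %.3g]\n",
                min(object@edges$p), max(object@edges$p)))
})

setMethod("show", "SignedNetwork", function(object) {
  cat(sprintf("SignedNetwork: %d nodes, %d directed signed edges (%d -, %d +)\n",
              nNodes(object), nrow(object@edges),
              sum(object@edges$sign < 0), sum(object@edges$sign > 0)))
})

setMethod("show", "AnnotationTable", function(object) {
  cat(sprintf("AnnotationTable: %d records, %d lookup keys\n",
              length(object@labels), length(ls(object@lookup))))
})

setMethod("show", "PathResult", function(object) {
  if (!object@found) {
    cat("PathResult: no path\n")
  } else {
    cat(sprintf("PathResult: %s\n", paste(object@nodes, collapse = " -> ")))
    cat(sprintf("  edges %d  product %.6g  penalized %.6g  dual length %.6g (D = %g)\n",
                object@edgeCount, object@product, object@penalizedScore,
                object@dualLength, object@damping))
  }
})

setMethod("show", "EpsilonSubnetwork", function(object) {
  if (!object@found) {
    cat("EpsilonSubnetwork: no path\n")
  } else {
    cat(sprintf("EpsilonSubnetwork (%s): |V_eps| = %d, %d edges, eps = %g, w* = %.6g\n",
                if (object@sparse) "sparse" else "dense",
                length(object@nodes), nrow(object@network@edges),
                object@epsilon, object@wStar))
  }
})

setMethod("show", "ExpansionResult", function(object) {
  cat(sprintf("ExpansionResult: %d nodes after %d round(s)%s\n",
              length(object@nodes), length(object@rounds),
              if (object@shortfall) " [candidate shortfall]" else ""))
})
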