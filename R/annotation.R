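#' Read a node annotation table
#'
#' Parses the tab-separated annotation dialect: one row per network node,
#' first column the canonical label (required, non-empty), every further
#' column a comma-separated list of alternative identifiers for the same
#' node. All identifiers, including the label, are entered into a lookup
#' index after trimming whitespace and case-folding, so queries match
#' regardless of case. An identifier shared by several nodes (e.g. an
#' alias common to paralogs) resolves to all of them.
#'
#' @param path path to the annotation file (UTF-8, tab-separated, no
#'   header).
#' @return an [AnnotationTable-class] object.
#' @examples
#' tf <- tempfile()
#' writeLines(c("TP53\tP04637,p53", "MDM2\tQ00987"), tf)
#' tab <- readAnnotation(tf)
#' resolveId(tab, "p53")
#' @export
readAnnotation <- function(path) {
  if (!file.exists(path)) spIOError(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- nzchar(trimws(lines))
  if (!any(keep)) spFormatError("annotation file is empty")
  lineno <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  labels <- vapply(fields, function(f) trimws(f[[1L]]), character(1))
  bad <- which(!nzchar(labels))
  if (length(bad))
    spFormatError(sprintf("empty label in annotation file at line %d",
                          lineno[bad[1L]]))
  altIds <- lapply(fields, function(f) {
    if (length(f) < 2L) return(list())
    lapply(f[-1L], function(col) {
      ids <- trimws(strsplit(col, ",", fixed = TRUE)[[1L]])
      ids[nzchar(ids)]
    })
  })
  lookup <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_along(labels)) {
    ids <- normalizeId(c(labels[i], unlist(altIds[[i]], use.names = FALSE)))
    for (id in unique(ids[nzchar(ids)])) {
      prev <- lookup[[id]]
      lookup[[id]] <- if (is.null(prev)) i else unique(c(prev, i))
    }
  }
  new("AnnotationTable", labels = labels, altIds = altIds, lookup = lookup)
}

#' Resolve one identifier to node indices
#'
#' Looks a single identifier up in an annotation table. The query is
#' whitespace-trimmed and case-folded before matching. An unknown
#' identifier is a legal empty result, not an error.
#'
#' @param table an [AnnotationTable-class].
#' @param query identifier string.
#' @return sorted integer vector of matching 1-based node indices (may be
#'   empty, may have several entries for a shared alias).
#' @export
resolveId <- function(table, query) {
  stopifnot(is(table, "AnnotationTable"))
  hit <- table@lookup[[normalizeId(query)]]
  if (is.null(hit)) integer() else sort(hit)
}

#' Resolve a list of identifiers
#'
#' Resolves each query with [resolveId()] and unions the results.
#' Unresolved queries are reported; with `onMissing = "warn"` they are
#' warned about and skipped, with `"error"` any miss aborts. An input
#' where *no* query resolves is always an error, regardless of policy —
#' an empty source or target set is never valid downstream.
#'
#' @param table an [AnnotationTable-class].
#' @param queries non-empty character vector of identifiers.
#' @param onMissing `"error"` (default) or `"warn"`.
#' @return list with elements `indices` (sorted unique integer vector) and
#'   `unresolved` (character vector of queries with no match).
#' @export
resolveIds <- function(table, queries, onMissing = c("error", "warn")) {
  onMissing <- match.arg(onMissing)
  if (length(queries) == 0L) spInputError("queries must be non-empty")
  hits <- lapply(queries, function(q) resolveId(table, q))
  unresolved <- as.character(queries[lengths(hits) == 0L])
  if (length(unresolved) == length(queries))
    spInputError(sprintf("none of the identifiers resolved: %s",
                         paste(unresolved, collapse = ", ")))
  if (length(unresolved)) {
    msg <- sprintf("unresolved identifier(s): %s",
                   paste(unresolved, collapse = ", "))
    if (onMissing == "error") spInputError(msg) else warning(msg, call. = FALSE)
  }
  list(indices = sort(unique(unlist(hits, use.names = FALSE))),
       unresolved = unresolved)
}
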