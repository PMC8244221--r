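#' Extract the interaction network among input proteins
#'
#' Returns the induced subgraph of the background network on the input
#' genes: the input proteins and every interaction among them. Input
#' genes absent from the background network are dropped with a warning
#' listing them; if none are present the call is an error. Isolated input
#' nodes are retained.
#'
#' @param net background [ConfidenceNetwork-class].
#' @param genes node labels (or 1-based indices).
#' @return a [ConfidenceNetwork-class].
#' @export
extractNetwork <- function(net, genes) {
  stopifnot(is(net, "ConfidenceNetwork"))
  if (is.numeric(genes)) {
    idx <- resolveNodeRefs(net, genes, "gene")
  } else {
    idx <- match(as.character(genes), net@labels)
    miss <- unique(as.character(genes)[is.na(idx)])
    if (length(miss) == length(unique(genes)))
      spInputError("none of the input genes are present in the background network")
    if (length(miss))
      warning(sprintf("gene(s) not in background network: %s",
                      paste(miss, collapse = ", ")), call. = FALSE)
    idx <- unique(idx[!is.na(idx)])
  }
  inducedSubgraph(net, idx)
}

#' Rank expansion candidates by total interaction confidence
#'
#' Scores every node outside the current set that has at least one edge
#' into it by the sum of confidences of its edges to current members
#' (for directed networks, incoming and outgoing edges both count, each
#' once). Candidate-candidate edges do not contribute. Ordered by score
#' descending, then label ascending, so the ranking is deterministic.
#'
#' @param net background [ConfidenceNetwork-class].
#' @param current non-empty node set (labels or indices).
#' @return data.frame with columns `label`, `score`, ordered as above;
#'   zero rows when no external node touches the set.
#' @export
rankCandidates <- function(net, current) {
  stopifnot(is(net, "ConfidenceNetwork"))
  cur <- resolveNodeRefs(net, current, "gene")
  if (length(cur) == 0L) spInputError("current set must be non-empty")
  inCur <- logical(length(net@labels))
  inCur[cur] <- TRUE
  e <- net@edges
  score <- numeric(length(net@labels))
  touchFrom <- !inCur[e$from] & inCur[e$to]   # candidate -> member
  touchTo <- inCur[e$from] & !inCur[e$to]     # member -> candidate
  if (any(touchFrom)) {
    s <- tapply(e$p[touchFrom], e$from[touchFrom], sum)
    score[as.integer(names(s))] <- score[as.integer(names(s))] + s
  }
  if (any(touchTo)) {
    s <- tapply(e$p[touchTo], e$to[touchTo], sum)
    score[as.integer(names(s))] <- score[as.integer(names(s))] + s
  }
  cand <- which(score > 0 & !inCur)
  out <- data.frame(label = net@labels[cand], score = score[cand])
  out <- out[order(-out$score, out$label), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Greedy confidence-weighted network expansion
#'
#' Starts from the induced network on the input genes and adds the `nAdd`
#' external proteins whose total interaction confidence with the current
#' set is highest. `"batch"` mode (default) ranks once and takes the top
#' `nAdd` in one shot; `"sequential"` mode adds one node at a time,
#' re-ranking after each addition so edges to freshly added nodes count —
#' the behavior of pressing an expand button repeatedly. When fewer than
#' `nAdd` candidates exist, all of them are added and the result carries a
#' shortfall flag.
#'
#' @param net background [ConfidenceNetwork-class].
#' @param genes input node set (labels or indices); resolved as in
#'   [extractNetwork()].
#' @param nAdd nonnegative integer, number of proteins to add.
#' @param mode `"batch"` or `"sequential"`.
#' @return an [ExpansionResult-class].
#' @examples
#' tf <- tempfile()
#' writeLines(c("C\tL1\t0.9", "C\tL2\t0.8", "C\tL3\t0.1"), tf)
#' net <- readNetwork(tf)
#' nodeLabels(expandNetwork(net, "C", 2))
#' @export
expandNetwork <- function(net, genes, nAdd, mode = c("batch", "sequential")) {
  mode <- match.arg(mode)
  if (!is.numeric(nAdd) || length(nAdd) != 1L || is.na(nAdd) || nAdd < 0)
    spInputError("nAdd must be a nonnegative integer")
  nAdd <- as.integer(nAdd)
  base <- extractNetwork(net, genes)
  cur <- net@labels[resolveNodeRefs(net, nodeLabels(base), "gene")]
  rounds <- list()
  shortfall <- FALSE
  if (nAdd > 0L) {
    if (mode == "batch") {
      rk <- rankCandidates(net, cur)
      take <- utils::head(rk, nAdd)
      shortfall <- nrow(rk) < nAdd
      if (nrow(take)) {
        rounds[[1L]] <- take
        cur <- c(cur, take$label)
      }
    } else {
      for (i in seq_len(nAdd)) {
        rk <- rankCandidates(net, cur)
        if (nrow(rk) == 0L) { shortfall <- TRUE; break }
        rounds[[length(rounds) + 1L]] <- rk[1L, , drop = FALSE]
        cur <- c(cur, rk$label[1L])
      }
    }
  }
  finalNet <- inducedSubgraph(net, cur)
  new("ExpansionResult", rounds = rounds, nodes = nodeLabels(finalNet),
      network = finalNet, shortfall = shortfall)
}

#' Per-round additions of an expansion
#'
#' @param x an [ExpansionResult-class].
#' @return list of data.frames (`label`, `score`), one per round.
#' @export
expansionRounds <- function(x) {
  stopifnot(is(x, "ExpansionResult"))
  x@rounds
}
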