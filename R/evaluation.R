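#' Intermediate genes of a strongest-path result
#'
#' The genes found "in the middle" of the strongest path(s): the result's
#' node set minus the source and target genes. These are the candidates a
#' pathway-reconstruction benchmark scores against the known pathway
#' members.
#'
#' @param result a [PathResult-class], [EpsilonSubnetwork-class], or a
#'   plain character vector of node labels.
#' @param sources,targets character vectors of source/target labels.
#' @return character vector of intermediate gene labels.
#' @export
intermediateGenes <- function(result, sources, targets) {
  nodes <- if (is.character(result)) result else nodeLabels(result)
  setdiff(nodes, c(as.character(sources), as.character(targets)))
}

#' Upper-tail hypergeometric enrichment p-value
#'
#' Probability of observing at least `k` pathway genes among `n` genes
#' drawn without replacement from a background of `N` genes of which `K`
#' belong to the pathway: `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`.
#' Computed via `phyper(k - 1, K, N - K, n, lower.tail = FALSE)`, which
#' works on log-gamma terms and is numerically stable for large counts.
#'
#' @param k overlap count (found genes also in the pathway).
#' @param n number of found genes (draws).
#' @param K pathway genes present in the background (successes).
#' @param N background network size (population).
#' @return probability in [0, 1]. Vectorized over `k`.
#' @examples
#' hypergeomPvalue(2, 3, 4, 10)  # exactly 1/3
#' @export
hypergeomPvalue <- function(k, n, K, N) {
  bad <- !is.numeric(k) || !is.numeric(n) || !is.numeric(K) || !is.numeric(N) ||
    any(k < 0) || n < 0 || K < 0 || N < 0 || any(k > n) || n > N || K > N ||
    any(k > K)
  if (bad) spInputError("inconsistent hypergeometric counts: need 0 <= k <= min(n, K), n <= N, K <= N")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values controlling the false discovery rate,
#' order-preserving with the input, clipped to 1 and monotone by
#' construction (delegates to `p.adjust(method = "BH")` after range
#' validation).
#'
#' @param pvalues numeric vector of raw p-values in [0, 1].
#' @return numeric vector of adjusted values, same order and length.
#' @examples
#' fdrAdjust(c(0.01, 0.02, 0.03))
#' @export
fdrAdjust <- function(pvalues) {
  if (!is.numeric(pvalues) || any(is.na(pvalues)) ||
      any(pvalues < 0 | pvalues > 1))
    spInputError("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Precision and recall against a pathway gene set
#'
#' Precision is the fraction of identified genes that belong to the
#' pathway; recall is the fraction of pathway genes that were retrieved.
#' With an empty `found` set precision is reported as 0 and flagged
#' (`attr(x, "emptyFound")`), since 0/0 has no natural value.
#'
#' @param found character vector of identified genes (duplicates
#'   ignored).
#' @param pathway non-empty character vector of pathway member genes.
#' @return named numeric `c(precision =, recall =)`; attribute `overlap`
#'   carries the intersection size.
#' @export
precisionRecall <- function(found, pathway) {
  pathway <- unique(as.character(pathway))
  if (length(pathway) == 0L) spInputError("pathway set must be non-empty")
  found <- unique(as.character(found))
  ov <- length(intersect(found, pathway))
  out <- c(precision = if (length(found)) ov / length(found) else 0,
           recall = ov / length(pathway))
  attr(out, "overlap") <- ov
  if (length(found) == 0L) attr(out, "emptyFound") <- TRUE
  out
}

#' Enrichment statistics for one or more pathways
#'
#' Benchmarks a set of identified intermediate genes against pathway
#' membership: counts, upper-tail hypergeometric p-value, BH-FDR across
#' the supplied pathways, precision and recall. The background is the
#' node label set of the network actually searched; it defines the
#' hypergeometric population, and both the found set and each pathway set
#' are intersected with it before counting. Source/target genes should be
#' removed from `found` beforehand (see [intermediateGenes()]); they are
#' also removed from the pathway sets here when supplied.
#'
#' @param found character vector of identified genes.
#' @param pathways named list of character vectors (one per pathway), or
#'   a single character vector.
#' @param background character vector of all node labels of the searched
#'   network.
#' @param exclude optional character vector (typically the sources and
#'   targets) removed from found, pathway and background sets before
#'   counting.
#' @return data.frame with one row per pathway: `pathway`, `found`,
#'   `overlap`, `pathwaySize`, `background`, `pValue`, `fdr`,
#'   `precision`, `recall`.
#' @export
enrichmentStats <- function(found, pathways, background, exclude = character()) {
  if (is.character(pathways)) pathways <- list(pathway = pathways)
  if (is.null(names(pathways)))
    names(pathways) <- paste0("pathway", seq_along(pathways))
  background <- setdiff(unique(as.character(background)), exclude)
  N <- length(background)
  found <- setdiff(intersect(unique(as.character(found)), background), exclude)
  n <- length(found)
  rows <- lapply(names(pathways), function(nm) {
    pw <- setdiff(intersect(unique(as.character(pathways[[nm]])), background),
                  exclude)
    K <- length(pw)
    k <- length(intersect(found, pw))
    pr <- if (K) precisionRecall(found, pw) else c(precision = NA_real_,
                                                   recall = NA_real_)
    data.frame(pathway = nm, found = n, overlap = k, pathwaySize = K,
               background = N,
               pValue = if (K) hypergeomPvalue(k, n, K, N) else NA_real_,
               precision = unname(pr["precision"]),
               recall = unname(pr["recall"]))
  })
  out <- do.call(rbind, rows)
  out$fdr <- NA_real_
  ok <- !is.na(out$pValue)
  out$fdr[ok] <- fdrAdjust(out$pValue[ok])
  out[, c("pathway", "found", "overlap", "pathwaySize", "background",
          "pValue", "fdr", "precision", "recall")]
}
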