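# Over-representation analysis: hypergeometric set tests with per-channel
# Benjamini-Hochberg control and gene-level channel indicators.

#' Hypergeometric upper-tail probability
#'
#' Probability of observing `x` or more query genes in a set of size `K`
#' when `n` genes are drawn without replacement from a universe of `M`:
#' `p = sum_{k=x}^{min(K,n)} C(K,k) C(M-K,n-k) / C(M,n)`, evaluated in
#' log space (`lchoose` + log-sum-exp) for stability at genomic sizes.
#'
#' @param x observed overlap, `0 <= x <= min(K, n)`.
#' @param K set size (annotated genes in the set).
#' @param M universe size (all annotated genes), `K <= M`.
#' @param n query size, `n <= M`.
#' @return upper-tail probability in (0, 1\].
#' @export
hypergeom_upper_tail <- function(x, K, M, n) {
  if (K > M || n > M || x < 0 || x > min(K, n)) {
    stop_config("invalid hypergeometric bounds: x=", x, " K=", K,
                " M=", M, " n=", n)
  }
  if (x == 0) return(1)
  k <- seq.int(x, min(K, n))
  lp <- lchoose(K, k) + lchoose(M - K, n - k) - lchoose(M, n)
  min(exp(logsumexp(lp)), 1)
}

#' Over-representation analysis of a query list against one channel
#'
#' Sets whose size (within the channel's annotation universe) falls
#' outside `[min_set_size, max_set_size]` are excluded before testing.
#' Each remaining set receives a hypergeometric upper-tail test with
#' `M = |annotation universe|` and `n = |query intersect annotation
#' universe|`; Benjamini-Hochberg adjustment is applied across the tested
#' sets of this channel only, and significance is declared at
#' `fdr < fdr_max`.
#'
#' @param query character vector of query genes.
#' @param collection a [geneset_collection()].
#' @param min_set_size,max_set_size tested set-size window (defaults 5
#'   and 2000).
#' @param fdr_max FDR significance threshold (default 0.05).
#' @return data.frame of class `enrichment_result`: set, set_size,
#'   overlap, p, fdr, significant; attributes `channel`, `universe_size`,
#'   `query_size`.
#' @export
enrich_collection <- function(query, collection, min_set_size = 5L,
                              max_set_size = 2000L, fdr_max = 0.05) {
  M_genes <- collection$annotation_universe
  q <- intersect(unique(trimws(query)), M_genes)
  empty <- data.frame(set = character(), set_size = integer(),
                      overlap = integer(), p = numeric(), fdr = numeric(),
                      significant = logical(), stringsAsFactors = FALSE)
  if (!length(q)) {
    warning("query has no overlap with the ", collection$channel,
            " annotation universe; empty result")
    return(structure(empty, channel = collection$channel,
                     universe_size = length(M_genes), query_size = 0L,
                     class = c("enrichment_result", "data.frame")))
  }
  sizes <- lengths(collection$sets)
  keep <- sizes >= min_set_size & sizes <= max_set_size
  sets <- collection$sets[keep]
  if (!length(sets)) {
    return(structure(empty, channel = collection$channel,
                     universe_size = length(M_genes), query_size = length(q),
                     class = c("enrichment_result", "data.frame")))
  }
  M <- length(M_genes)
  n <- length(q)
  overlap <- vapply(sets, function(s) length(intersect(s, q)), integer(1))
  K <- lengths(sets)
  p <- vapply(seq_along(sets),
              function(i) hypergeom_upper_tail(overlap[i], K[i], M, n),
              numeric(1))
  fdr <- bh_adjust(p)
  out <- data.frame(set = names(sets), set_size = K, overlap = overlap,
                    p = p, fdr = fdr, significant = fdr < fdr_max,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(out[order(out$p, out$set), , drop = FALSE],
            channel = collection$channel, universe_size = M,
            query_size = n,
            class = c("enrichment_result", "data.frame"))
}

#' Gene-level channel indicator from set-level enrichment
#'
#' A query gene scores 1 if it belongs to at least one significant set
#' of the channel (membership rule; significance itself is set-level).
#'
#' @param query character vector of query genes.
#' @param result an `enrichment_result` from [enrich_collection()]
#'   computed on this query and collection.
#' @param collection the [geneset_collection()] used.
#' @return named integer 0/1 vector over the query genes.
#' @export
channel_indicator <- function(query, result, collection) {
  query <- unique(trimws(query))
  sig_sets <- result$set[result$significant]
  members <- unique(unlist(collection$sets[sig_sets], use.names = FALSE))
  stats::setNames(as.integer(query %in% members), query)
}
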