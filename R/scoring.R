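# Five-channel gene scoring: aggregate the binary channel indicators into
# the 0-5 score, apply the score >= 2 risk rule, and produce the
# channel-correlation and membership-pattern diagnostics.

score_channels <- c("kegg", "bp", "ko", "glad4u", "geo")

#' Aggregate five channel indicators into the gene score table
#'
#' The score of a gene is the number of channels (pathway, biological
#' process, knockout phenotype, literature association, expression) in
#' which it was significant; genes meeting two or more criteria carry the
#' risk flag. The table is sorted by score descending, ties broken by
#' gene symbol.
#'
#' @param kegg,bp,ko,glad4u,geo named 0/1 vectors. Each must cover every
#'   universe gene (extra names are ignored after an intersection check).
#' @param universe character vector of universe genes (or a
#'   [gen_gene_universe()] result).
#' @param score_min risk-flag threshold (default 2).
#' @return data.frame of class `channel_scores`: gene, kegg, bp, ko,
#'   glad4u, geo, score, risk_flag.
#' @export
aggregate_scores <- function(kegg, bp, ko, glad4u, geo, universe,
                             score_min = 2L) {
  genes <- if (is.data.frame(universe)) universe$gene else universe
  chans <- list(kegg = kegg, bp = bp, ko = ko, glad4u = glad4u, geo = geo)
  mat <- matrix(0L, length(genes), length(chans),
                dimnames = list(genes, names(chans)))
  for (nm in names(chans)) {
    v <- chans[[nm]]
    if (is.null(names(v))) {
      stop_config("channel '", nm, "' indicator must be named by gene")
    }
    miss <- setdiff(genes, names(v))
    if (length(miss)) {
      stop_config("channel '", nm, "' is missing universe gene(s): ",
                  paste(utils::head(miss, 5), collapse = ", "),
                  if (length(miss) > 5) sprintf(" (+%d more)", length(miss) - 5))
    }
    mat[, nm] <- as.integer(v[genes] != 0)
  }
  out <- data.frame(gene = genes, mat, score = as.integer(rowSums(mat)),
                    row.names = NULL, stringsAsFactors = FALSE)
  out$risk_flag <- out$score >= score_min
  out <- out[order(-out$score, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("channel_scores", "data.frame"))
}

#' Select biological risk genes by score threshold
#'
#' @param table a `channel_scores` table from [aggregate_scores()].
#' @param score_min minimum score (default 2).
#' @return character vector (set) of risk-gene symbols.
#' @export
select_risk_genes <- function(table, score_min = 2L) {
  sort(unique(table$gene[table$score >= score_min]))
}

#' Pairwise correlation of the five channel indicators
#'
#' Pearson correlation between the binary indicator vectors over the full
#' universe (equivalently the phi coefficient). Channels with zero
#' variance yield NA rows/columns with a warning.
#'
#' @param table a `channel_scores` table.
#' @return symmetric 5 x 5 numeric matrix with unit diagonal.
#' @export
channel_correlation <- function(table) {
  if (nrow(table) < 2L) stop_config("need >= 2 genes for correlations")
  m <- as.matrix(table[score_channels])
  const <- apply(m, 2, function(x) stats::var(x) == 0)
  cc <- suppressWarnings(stats::cor(m))
  if (any(const)) {
    warning("constant channel(s): ",
            paste(score_channels[const], collapse = ", "),
            "; correlations set to NA")
    cc[const, ] <- NA_real_
    cc[, const] <- NA_real_
  }
  diag(cc) <- 1
  cc
}

#' Channel-exclusive and all-channel intersection counts
#'
#' `exclusive[ch]` counts genes whose only positive indicator is `ch`
#' (score exactly 1); `intersection` counts genes positive in all five
#' channels (score 5). These are the extreme cells of the five-way
#' membership-pattern partition.
#'
#' @param table a `channel_scores` table.
#' @return list with `exclusive` (named integer, one per channel) and
#'   `intersection` (integer).
#' @export
venn_counts <- function(table) {
  m <- as.matrix(table[score_channels])
  score <- rowSums(m)
  exclusive <- vapply(score_channels,
                      function(ch) sum(m[, ch] == 1L & score == 1),
                      numeric(1))
  list(exclusive = stats::setNames(as.integer(exclusive), score_channels),
       intersection = sum(score == length(score_channels)))
}
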