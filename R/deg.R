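# Differential-expression channel: per-sample median normalization, a
# fixed-prior moderated two-sample t statistic, Benjamini-Hochberg
# adjustment, up-regulated DEG calling and the union indicator across
# expression series.

#' Median-center an expression dataset
#'
#' If the data appear to be on the linear scale (maximum > 50), a
#' `log2(x + 1)` transform is applied first. Each sample column is then
#' shifted so its median equals the global (pre-centering) median. This
#' removes per-sample loading offsets while leaving within-sample rank
#' order, and hence two-group mean separation at fixed group sizes,
#' untouched.
#'
#' @param dataset an [expr_dataset()].
#' @return the normalized [expr_dataset()].
#' @export
normalize_expression <- function(dataset) {
  v <- dataset$values
  if (any(!is.finite(v))) {
    bad <- colnames(v)[colSums(!is.finite(v)) > 0][1]
    stop_format("non-finite expression values in sample '", bad, "'")
  }
  if (max(v) > 50) v <- log2(v + 1)
  if (any(!is.finite(v))) {
    bad <- colnames(v)[colSums(!is.finite(v)) > 0][1]
    stop_format("non-finite values after log2 transform in sample '", bad, "'")
  }
  target <- stats::median(v)
  med <- apply(v, 2, stats::median)
  v <- sweep(v, 2, med - target)
  expr_dataset(v, dataset$group, dataset$name)
}

#' Moderated two-sample t statistics with a fixed variance prior
#'
#' For each gene, with group sizes n1 (normal) and n2 (tumor), pooled
#' residual variance s^2 on d = n1 + n2 - 2 degrees of freedom, prior
#' variance s0^2 on d0 prior degrees of freedom, the shrunken variance is
#' `s~^2 = (d0 s0^2 + d s^2) / (d0 + d)` and
#' `t = logFC / (s~ sqrt(1/n1 + 1/n2))`, referred to a t distribution on
#' d0 + d degrees of freedom (two-sided). `d0 = 0` recovers the ordinary
#' pooled t exactly; large `d0` pins every gene to the prior variance.
#'
#' @param dataset an [expr_dataset()] (normalized).
#' @param prior_df d0 >= 0; default 4.
#' @param prior_var s0^2; default the median of the per-gene pooled
#'   variances.
#' @return data.frame: gene, logFC (tumor - normal, log2), t, df, p.
#' @export
moderated_t <- function(dataset, prior_df = 4, prior_var = NULL) {
  g <- dataset$group
  n1 <- sum(g == "normal")
  n2 <- sum(g == "tumor")
  if (n1 < 2L || n2 < 2L) {
    stop_config("need >= 2 samples per group, got ", n1, "/", n2)
  }
  if (prior_df < 0) stop_config("prior_df must be >= 0")
  v <- dataset$values
  norm_m <- rowMeans(v[, g == "normal", drop = FALSE])
  tum_m <- rowMeans(v[, g == "tumor", drop = FALSE])
  logfc <- tum_m - norm_m
  d <- n1 + n2 - 2L
  var1 <- apply(v[, g == "normal", drop = FALSE], 1, stats::var)
  var2 <- apply(v[, g == "tumor", drop = FALSE], 1, stats::var)
  s2 <- ((n1 - 1) * var1 + (n2 - 1) * var2) / d
  s0sq <- prior_var %||% stats::median(s2)
  stilde2 <- (prior_df * s0sq + d * s2) / (prior_df + d)
  se <- sqrt(stilde2 * (1 / n1 + 1 / n2))
  tstat <- logfc / se
  df_total <- prior_df + d
  p <- 2 * stats::pt(-abs(tstat), df = df_total)
  degenerate <- se == 0 & logfc != 0
  if (any(degenerate)) {
    warning(sum(degenerate), " gene(s) with zero shrunken variance and ",
            "nonzero logFC; p set to minimum representable")
    tstat[degenerate] <- sign(logfc[degenerate]) * Inf
    p[degenerate] <- .Machine$double.xmin
  }
  p[se == 0 & logfc == 0] <- 1
  tstat[se == 0 & logfc == 0] <- 0
  data.frame(gene = rownames(v), logFC = logfc, t = tstat,
             df = df_total, p = p, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Implements the step-up procedure directly: with p-values sorted
#' ascending, `adj[i] = min_{j >= i} (m p[j] / j)` capped at 1, returned
#' in the input order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric())
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop_config("p-values must lie in [0, 1] with no NAs")
  }
  m <- length(p)
  ord <- order(p)
  stepped <- p[ord] * m / seq_len(m)
  adj_sorted <- pmin(rev(cummin(rev(stepped))), 1)
  adj <- numeric(m)
  adj[ord] <- adj_sorted
  adj
}

#' Call up-regulated differentially expressed genes
#'
#' Strict thresholds on both axes: `adj_p < adj_p_max` and
#' `logFC > logfc_min` (ties at the cutoffs are excluded).
#' `absolute_logfc = TRUE` switches the fold-change rule to
#' `|logFC| > logfc_min` (both directions).
#'
#' @param result data.frame with columns gene, logFC, adj_p (e.g. from
#'   [run_deg()]).
#' @param adj_p_max adjusted-p cutoff (default 0.05).
#' @param logfc_min log2 fold-change cutoff (default 2).
#' @param absolute_logfc call both directions (default FALSE, up only).
#' @return character vector of DEG symbols.
#' @export
call_up_degs <- function(result, adj_p_max = 0.05, logfc_min = 2,
                         absolute_logfc = FALSE) {
  fc_ok <- if (absolute_logfc) abs(result$logFC) > logfc_min
           else result$logFC > logfc_min
  result$gene[result$adj_p < adj_p_max & fc_ok]
}

#' Normalize, test and adjust one expression dataset
#'
#' Convenience wrapper: [normalize_expression()] then [moderated_t()]
#' then [bh_adjust()], with the DEG flag attached.
#'
#' @inheritParams moderated_t
#' @inheritParams call_up_degs
#' @return data.frame: gene, logFC, t, df, p, adj_p, up_flag.
#' @export
run_deg <- function(dataset, prior_df = 4, prior_var = NULL,
                    adj_p_max = 0.05, logfc_min = 2,
                    absolute_logfc = FALSE) {
  res <- moderated_t(normalize_expression(dataset), prior_df, prior_var)
  res$adj_p <- bh_adjust(res$p)
  res$up_flag <- res$gene %in% call_up_degs(res, adj_p_max, logfc_min,
                                            absolute_logfc)
  res
}

#' Expression-channel indicator: union of up-DEG calls across datasets
#'
#' A universe gene scores 1 if it is called an up-regulated DEG in at
#' least one dataset.
#'
#' @param deg_sets list of character vectors (per-dataset up-DEG calls).
#' @param universe character vector of universe genes (or a
#'   [gen_gene_universe()] result).
#' @return named integer 0/1 vector over the universe.
#' @export
geo_channel_indicator <- function(deg_sets, universe) {
  if (!length(deg_sets)) stop_config("need at least one DEG set")
  genes <- if (is.data.frame(universe)) universe$gene else universe
  hits <- unique(unlist(deg_sets, use.names = FALSE))
  stats::setNames(as.integer(genes %in% hits), genes)
}
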