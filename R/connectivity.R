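# Connectivity-map style scoring: two-tailed signature from the reference
# profile, unweighted KS running-sum enrichment of the up/down sets in
# each compound's ranking, combined score for discordant tails, and
# percentile (tau) normalization to [-100, 100] against the touchstone
# background of compound scores.

#' Extract one compound/cell-line profile from a rank_profiles object
#'
#' @param profiles a `rank_profiles` object.
#' @param compound compound name.
#' @param cell_line cell-line label.
#' @return list(compound, cell_line, ranking) where `ranking` is a named
#'   integer permutation (rank 1 = most up-regulated).
#' @export
extract_profile <- function(profiles, compound, cell_line = "MCF7") {
  j <- which(profiles$compound == compound & profiles$cell_line == cell_line)
  if (length(j) != 1L) {
    stop_config("no unique profile for compound '", compound,
                "' in cell line '", cell_line, "'")
  }
  list(compound = compound, cell_line = cell_line,
       ranking = stats::setNames(profiles$ranks[, j], profiles$genes))
}

#' Build a two-tailed signature from a reference profile
#'
#' `up_set` holds the genes at ranks 1..q (most up-regulated under the
#' reference compound), `down_set` the genes at ranks N-q+1..N.
#'
#' @param reference a profile from [extract_profile()] (or any named
#'   integer ranking).
#' @param q signature tail size (default 150); requires N >= 2q.
#' @return list of class `signature`: up_set, down_set, q, reference
#'   compound/cell line.
#' @export
build_signature <- function(reference, q = 150L) {
  ranking <- if (is.list(reference)) reference$ranking else reference
  N <- length(ranking)
  if (N < 2L * q) {
    stop_config("profile has ", N, " genes but 2q = ", 2L * q,
                "; choose a smaller signature size q")
  }
  ord <- names(sort(ranking))
  structure(list(up_set = ord[seq_len(q)],
                 down_set = ord[seq.int(N - q + 1L, N)], q = as.integer(q),
                 compound = if (is.list(reference)) reference$compound else NA,
                 cell_line = if (is.list(reference)) reference$cell_line else NA),
            class = "signature")
}

#' Kolmogorov-Smirnov running-sum enrichment of a gene set in a ranking
#'
#' With r_1 < ... < r_n the sorted ranks of the set members in a profile
#' of length N, the statistic is `a = max_j (j/n - r_j/N)` (excess at the
#' top) and `b = max_j (r_j/N - (j-1)/n)` (excess at the bottom);
#' `es = a` if `a > b`, else `-b`. Positive values mean the set sits
#' toward the top (up-regulated end) of the ranking.
#'
#' @param gene_set character; nonempty subset of the profiled genes.
#' @param profile a profile from [extract_profile()] or a named integer
#'   ranking.
#' @return enrichment score in \[-1, 1\].
#' @export
ks_enrichment <- function(gene_set, profile) {
  ranking <- if (is.list(profile)) profile$ranking else profile
  gene_set <- unique(gene_set)
  if (!length(gene_set)) stop_config("empty gene set")
  miss <- setdiff(gene_set, names(ranking))
  if (length(miss)) {
    stop_config("gene set members absent from profile: ",
                paste(utils::head(miss, 5), collapse = ", "))
  }
  r <- sort(unname(ranking[gene_set]))
  n <- length(r)
  N <- length(ranking)
  j <- seq_len(n)
  a <- max(j / n - r / N)
  b <- max(r / N - (j - 1) / n)
  if (a > b) a else -b
}

#' Combine up- and down-tail enrichment scores
#'
#' `w = (es_up - es_down) / 2` when the two tails are discordant (the
#' compound moves the up set and the down set in opposite directions),
#' else 0. A zero score is treated as discordant with any nonzero score
#' so one-tailed signal is retained.
#'
#' @param es_up,es_down enrichment scores in \[-1, 1\].
#' @return combined score w in \[-1, 1\].
#' @export
combined_score <- function(es_up, es_down) {
  if (abs(es_up) > 1 || abs(es_down) > 1) {
    stop_config("enrichment scores must lie in [-1, 1]")
  }
  if (es_up == 0 && es_down == 0) return(0)
  if (sign(es_up) == sign(es_down) && es_up != 0 && es_down != 0) return(0)
  (es_up - es_down) / 2
}

#' Percentile (tau) normalization against a touchstone background
#'
#' `tau = sign(w) * 100 * #{b in background : |b| < |w|} / |background|`.
#'
#' @param w combined score.
#' @param background numeric vector of touchstone combined scores
#'   (typically all compounds of the analysis cell line, including the
#'   scored one).
#' @return tau in \[-100, 100\].
#' @export
tau_normalize <- function(w, background) {
  if (!length(background)) stop_config("empty touchstone background")
  sign(w) * 100 * sum(abs(background) < abs(w)) / length(background)
}

#' Score every compound of a cell line against a signature
#'
#' Computes es_up, es_down, w per compound in `cell_line`, then
#' normalizes each w against the touchstone background of all *other*
#' compounds' w values in that cell line (leave-one-out, so a compound
#' whose |w| tops the panel reaches |tau| = 100 under the strict
#' percentile), and applies the candidate rule (`w > 0` and tau beyond
#' the threshold).
#'
#' @param profiles a `rank_profiles` object.
#' @param signature a [build_signature()] result.
#' @param cell_line analysis cell line (default "MCF7").
#' @param tau_min candidate threshold on tau (default 80).
#' @param tau_ge use `tau >= tau_min` instead of strict `>` (default
#'   FALSE).
#' @return data.frame of class `connectivity_result`: compound,
#'   cell_line, es_up, es_down, w, tau, passes.
#' @export
connectivity_scores <- function(profiles, signature, cell_line = "MCF7",
                                tau_min = 80, tau_ge = FALSE) {
  idx <- which(profiles$cell_line == cell_line)
  if (!length(idx)) stop_config("no profiles in cell line '", cell_line, "'")
  res <- lapply(idx, function(j) {
    ranking <- stats::setNames(profiles$ranks[, j], profiles$genes)
    es_up <- ks_enrichment(signature$up_set, ranking)
    es_down <- ks_enrichment(signature$down_set, ranking)
    data.frame(compound = profiles$compound[j], cell_line = cell_line,
               es_up = es_up, es_down = es_down,
               w = combined_score(es_up, es_down),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$tau <- vapply(seq_len(nrow(out)), function(i) {
    tau_normalize(out$w[i], out$w[-i])
  }, numeric(1))
  tau_ok <- if (tau_ge) out$tau >= tau_min else out$tau > tau_min
  out$passes <- out$w > 0 & tau_ok
  rownames(out) <- NULL
  structure(out, class = c("connectivity_result", "data.frame"))
}

#' Rank compounds and apply the positivity and tau filters
#'
#' First keeps positively connected compounds (`w > 0`), then those with
#' tau beyond `threshold` (strict by default), sorted by tau descending
#' with ties broken by compound name.
#'
#' @param results a `connectivity_result` (needs columns compound, w,
#'   tau).
#' @param threshold tau cutoff (default 80).
#' @param ge use `tau >= threshold` (default FALSE, strict `>`).
#' @return the filtered, sorted candidate table; attribute
#'   `n_positive` records the count after the positivity filter alone.
#' @export
rank_and_filter <- function(results, threshold = 80, ge = FALSE) {
  pos <- results[results$w > 0, , drop = FALSE]
  keep <- if (ge) pos$tau >= threshold else pos$tau > threshold
  out <- pos[keep, , drop = FALSE]
  out <- out[order(-out$tau, out$compound), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, n_positive = nrow(pos),
            class = c("connectivity_result", "data.frame"))
}
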