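#' Load the bundled pancreatic-cancer case-study fixture
#'
#' The package ships a deterministic worked example from a published
#' pancreatic-cancer repurposing screen: the 13 candidate drugs that
#' cleared the connectivity-score cutoff against gemcitabine (with their
#' original indications, scores, target genes and evidence records) and
#' the 12 genes that attained the maximum five-channel score. It drives
#' the fixture mode of [run_pipeline()] and the worked examples in the
#' tests; gene and drug symbols here are real, unlike the synthetic
#' generators' `G####`/`DRUG####` namespaces.
#'
#' @return list of class `pc_fixture` with elements:
#'   \describe{
#'     \item{candidates}{data.frame, 13 rows: drug, original_indication,
#'       cmap_score, target, evidence_level, evidence_ids.}
#'     \item{score5_genes}{character(12), the maximum-score genes.}
#'     \item{registry}{[evidence_registry()] reconstructed from the
#'       evidence columns (trial rows for "Phase k" entries, publication
#'       rows for id-only entries).}
#'     \item{thresholds}{list(fdr = 0.05, logfc_min = 2, score_min = 2,
#'       tau_min = 80).}
#'   }
#' @export
pc_fixture <- function() {
  path <- system.file("extdata", "pc_candidates.tsv", package = "drugfunnel",
                      mustWork = TRUE)
  cand <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = c(cmap_score = "numeric"))
  if (nrow(cand) != 13L) {
    stop_format("case-study candidate table must have 13 rows, found ",
                nrow(cand))
  }
  if (any(cand$cmap_score <= -100 | cand$cmap_score > 100)) {
    stop_format("case-study scores must lie in (-100, 100]")
  }
  genes <- read_gene_list(system.file("extdata", "pc_score5_genes.txt",
                                      package = "drugfunnel", mustWork = TRUE))
  if (length(genes) != 12L) {
    stop_format("case-study top-score gene list must have 12 entries, found ",
                length(genes))
  }
  rows <- lapply(seq_len(nrow(cand)), function(i) {
    level <- trimws(cand$evidence_level[i])
    ids <- trimws(strsplit(cand$evidence_ids[i], ",")[[1]])
    ids <- ids[nzchar(ids)]
    if (grepl("^Phase [1-4]$", level)) {
      data.frame(drug = cand$drug[i], kind = "trial",
                 phase = as.integer(sub("Phase ", "", level)),
                 id = if (length(ids)) ids else "unregistered",
                 stringsAsFactors = FALSE)
    } else if (length(ids)) {
      data.frame(drug = cand$drug[i], kind = "publication",
                 phase = NA_integer_, id = ids, stringsAsFactors = FALSE)
    } else {
      NULL
    }
  })
  rows <- Filter(Negate(is.null), rows)
  registry <- evidence_registry(if (length(rows)) do.call(rbind, rows)
                                else empty_evidence())
  structure(list(candidates = cand, score5_genes = genes,
                 registry = registry,
                 thresholds = list(fdr = 0.05, logfc_min = 2,
                                   score_min = 2, tau_min = 80)),
            class = "pc_fixture")
}

#' @export
print.pc_fixture <- function(x, ...) {
  cat(sprintf("pc_fixture: %d candidate drugs (scores %.2f..%.2f), %d top-score genes\n",
              nrow(x$candidates), min(x$candidates$cmap_score),
              max(x$candidates$cmap_score), length(x$score5_genes)))
  invisible(x)
}
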