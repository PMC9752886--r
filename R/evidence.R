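# Evidence triage: classify each candidate drug by its strongest record
# (clinical-trial phase > preclinical publication > none) and assemble
# the final candidate report, summary counts and drug-target edge list.

#' Classify a drug's evidence level
#'
#' Trial records take precedence: the level is "Phase k" with k the
#' maximum recorded phase and the ids are all trial ids. Otherwise
#' publication records give "preclinical" with the literature ids;
#' otherwise "none".
#'
#' @param drug drug name.
#' @param registry an [evidence_registry()].
#' @return list(level, class, ids): `level` is one of "Phase 1".."Phase
#'   4", "preclinical", "none"; `class` collapses phases to "clinical".
#' @export
classify_evidence <- function(drug, registry) {
  registry <- evidence_registry(registry)
  rec <- registry[norm_drug(registry$drug) == norm_drug(drug), , drop = FALSE]
  trials <- rec[rec$kind == "trial", , drop = FALSE]
  pubs <- rec[rec$kind == "publication", , drop = FALSE]
  if (nrow(trials)) {
    list(level = sprintf("Phase %d", max(trials$phase)), class = "clinical",
         ids = trials$id)
  } else if (nrow(pubs)) {
    list(level = "preclinical", class = "preclinical", ids = pubs$id)
  } else {
    list(level = "none", class = "none", ids = character())
  }
}

#' Assemble the final candidate report, summary counts and edge list
#'
#' @param candidates data.frame with columns `drug` and `targets`
#'   (";"-joined), e.g. from [map_risk_to_drugs()].
#' @param results a `connectivity_result` restricted to the surviving
#'   candidates (needs compound, tau).
#' @param registry an [evidence_registry()].
#' @return list of class `candidate_report`:
#'   \describe{
#'     \item{report}{one row per candidate, sorted by tau descending:
#'       drug, tau, targets, evidence_level, evidence_class,
#'       evidence_ids (","-joined).}
#'     \item{summary}{named integer counts over clinical / preclinical /
#'       none.}
#'     \item{edges}{data.frame (target, drug, evidence_class), one row
#'       per drug-target link.}
#'   }
#' @export
build_candidate_report <- function(candidates, results, registry) {
  drugs <- results$compound
  miss <- setdiff(norm_drug(drugs), norm_drug(candidates$drug))
  if (length(miss)) {
    stop_config("candidate drug(s) missing from the drug-target table: ",
                paste(utils::head(drugs[norm_drug(drugs) %in% miss], 5),
                      collapse = ", "))
  }
  targets <- candidates$targets[match(norm_drug(drugs),
                                      norm_drug(candidates$drug))]
  ev <- lapply(drugs, classify_evidence, registry = registry)
  report <- data.frame(
    drug = drugs, tau = results$tau, targets = targets,
    evidence_level = vapply(ev, `[[`, character(1), "level"),
    evidence_class = vapply(ev, `[[`, character(1), "class"),
    evidence_ids = vapply(ev, function(e) paste(e$ids, collapse = ","),
                          character(1)),
    stringsAsFactors = FALSE)
  report <- report[order(-report$tau, report$drug), , drop = FALSE]
  rownames(report) <- NULL
  summary <- vapply(c("clinical", "preclinical", "none"),
                    function(cl) sum(report$evidence_class == cl), numeric(1))
  edges <- do.call(rbind, lapply(seq_len(nrow(report)), function(i) {
    tg <- strsplit(report$targets[i], ";", fixed = TRUE)[[1]]
    data.frame(target = tg, drug = report$drug[i],
               evidence_class = report$evidence_class[i],
               stringsAsFactors = FALSE)
  })) %||% data.frame(target = character(), drug = character(),
                      evidence_class = character(), stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  structure(list(report = report,
                 summary = stats::setNames(as.integer(summary),
                                           c("clinical", "preclinical", "none")),
                 edges = edges),
            class = "candidate_report")
}

#' @export
print.candidate_report <- function(x, ...) {
  cat(sprintf("candidate_report: %d drugs (clinical %d / preclinical %d / none %d)\n",
              nrow(x$report), x$summary[["clinical"]],
              x$summary[["preclinical"]], x$summary[["none"]]))
  if (nrow(x$report)) {
    print(utils::head(x$report[c("drug", "tau", "targets", "evidence_level")],
                      10))
  }
  invisible(x)
}
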