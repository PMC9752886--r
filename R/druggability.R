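# Druggability stage: status filtering of the drug-target map and the
# intersection of risk genes with recorded drug targets.

#' Filter a drug-target map by drug status
#'
#' @param map a [drug_target_map()].
#' @param allowed_statuses statuses to keep; default approved, clinical
#'   and experimental (withdrawn excluded).
#' @return the filtered [drug_target_map()].
#' @export
filter_drug_status <- function(map,
                               allowed_statuses = c("approved", "clinical",
                                                    "experimental")) {
  map <- drug_target_map(map)  # revalidates status tokens
  unknown <- setdiff(allowed_statuses, drug_statuses())
  if (length(unknown)) {
    stop_config("unknown status token(s) in allowed_statuses: ",
                paste(unknown, collapse = ", "))
  }
  drug_target_map(map[map$status %in% allowed_statuses, , drop = FALSE])
}

#' Intersect risk genes with drug targets
#'
#' Gene matching is by exact symbol; drug names are deduplicated
#' case-insensitively after whitespace normalization (no synonym
#' resolution). Each candidate drug appears once, with all of its
#' in-risk targets.
#'
#' @param risk_genes character vector of risk-gene symbols.
#' @param map a (typically status-filtered) [drug_target_map()].
#' @return list with `druggable_genes` (character, subset of
#'   `risk_genes`) and `candidate_drugs` (data.frame: drug, targets
#'   (";"-joined), n_targets; one row per distinct drug).
#' @export
map_risk_to_drugs <- function(risk_genes, map) {
  map <- drug_target_map(map)
  risk_genes <- unique(trimws(risk_genes))
  if (!length(risk_genes)) {
    warning("empty risk-gene set; no druggable genes or candidate drugs")
    return(list(druggable_genes = character(),
                candidate_drugs = empty_candidates()))
  }
  hit <- map[map$target %in% risk_genes, , drop = FALSE]
  druggable <- sort(intersect(risk_genes, hit$target))
  if (!nrow(hit)) {
    return(list(druggable_genes = character(),
                candidate_drugs = empty_candidates()))
  }
  key <- norm_drug(hit$drug)
  first_name <- tapply(hit$drug, key, `[`, 1L)
  targets <- tapply(hit$target, key,
                    function(x) paste(sort(unique(x)), collapse = ";"))
  n_targets <- tapply(hit$target, key, function(x) length(unique(x)))
  keys <- sort(names(targets))
  cand <- data.frame(drug = unname(first_name[keys]),
                     targets = unname(targets[keys]),
                     n_targets = as.integer(unname(n_targets[keys])),
                     stringsAsFactors = FALSE)
  cand <- cand[order(cand$drug), , drop = FALSE]
  rownames(cand) <- NULL
  list(druggable_genes = druggable, candidate_drugs = cand)
}

empty_candidates <- function() {
  data.frame(drug = character(), targets = character(),
             n_targets = integer(), stringsAsFactors = FALSE)
}
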