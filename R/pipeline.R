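# End-to-end orchestration: synthetic / fixture / user-file modes, stage
# sequencing with classed errors, artifact writing, MANIFEST hashing and
# the funnel summary.

#' Pipeline configuration
#'
#' Collects every stage threshold and path. All thresholds default to the
#' published analysis settings: FDR 0.05 for the annotation channels and
#' DEG adjustment, log2 fold-change cutoff 2 (up-regulated only), risk
#' score >= 2, connectivity tau cutoff 80 (strict), signature size
#' q = 150 in the MCF7 cell line.
#'
#' @param mode "synthetic" (generate inputs), "fixture" (bundled
#'   case study) or "files" (read user files from `paths`).
#' @param seed integer master seed (synthetic mode).
#' @param outdir output directory; created if absent.
#' @param sim a [sim_config()] (synthetic mode); its seed is overridden
#'   by `seed`.
#' @param fdr FDR threshold shared by ORA and DEG adjustment.
#' @param logfc_min log2 fold-change cutoff.
#' @param absolute_logfc call DEGs in both directions.
#' @param score_min risk-gene score threshold.
#' @param tau_min candidate tau threshold.
#' @param tau_ge use tau >= tau_min instead of strict >.
#' @param q signature tail size.
#' @param cell_line analysis cell line.
#' @param summarize_cells "single" scores the analysis cell line only;
#'   "max" takes each compound's maximum tau over the cell lines in
#'   which it was profiled.
#' @param allowed_statuses drug statuses admitted to the pool.
#' @param prior_df,prior_var moderated-t prior (see [moderated_t()]).
#' @param min_set_size,max_set_size ORA set-size window.
#' @param reference reference compound name.
#' @param paths named list of input paths (files mode): `gene_list`,
#'   `gmt` (named character vector kegg/bp/ko/glad4u), `expression`
#'   (character vector of matrix TSVs; sidecar `<path>.labels` files),
#'   `drug_targets`, `rank_profiles`, `evidence`.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("synthetic", "fixture", "files"),
                            seed = 1L, outdir = tempfile("drugfunnel_"),
                            sim = sim_config(seed = seed),
                            fdr = 0.05, logfc_min = 2,
                            absolute_logfc = FALSE, score_min = 2L,
                            tau_min = 80, tau_ge = FALSE, q = 150L,
                            cell_line = "MCF7",
                            summarize_cells = c("single", "max"),
                            allowed_statuses = c("approved", "clinical",
                                                 "experimental"),
                            prior_df = 4, prior_var = NULL,
                            min_set_size = 5L, max_set_size = 2000L,
                            reference = "gemcitabine", paths = list()) {
  mode <- match.arg(mode)
  if (fdr <= 0 || fdr >= 1) stop_config("fdr must lie in (0, 1)")
  if (score_min < 0) stop_config("score_min must be >= 0")
  if (abs(tau_min) > 100) stop_config("tau_min must lie in [-100, 100]")
  if (q < 1) stop_config("q must be >= 1")
  sim$seed <- as.integer(seed)
  if (mode == "files") {
    req <- c("gene_list", "gmt", "expression", "drug_targets",
             "rank_profiles", "evidence")
    miss <- setdiff(req, names(paths))
    if (length(miss)) {
      stop_config("files mode needs paths: ", paste(miss, collapse = ", "))
    }
    flat <- c(paths$gene_list, unlist(paths$gmt), paths$expression,
              paths$drug_targets, paths$rank_profiles, paths$evidence)
    absent <- flat[!file.exists(flat)]
    if (length(absent)) {
      stop_config("input path(s) not found: ",
                  paste(utils::head(absent, 5), collapse = ", "))
    }
  }
  structure(list(mode = mode, seed = as.integer(seed), outdir = outdir,
                 sim = validate_sim_config(sim), fdr = fdr,
                 logfc_min = logfc_min, absolute_logfc = absolute_logfc,
                 score_min = as.integer(score_min), tau_min = tau_min,
                 tau_ge = tau_ge, q = as.integer(q), cell_line = cell_line,
                 summarize_cells = match.arg(summarize_cells),
                 allowed_statuses = allowed_statuses, prior_df = prior_df,
                 prior_var = prior_var, min_set_size = min_set_size,
                 max_set_size = max_set_size, reference = reference,
                 paths = paths),
            class = "pipeline_config")
}

run_stage <- function(state, stage, expr) {
  # single handler: a later-listed handler would otherwise re-catch the
  # rethrow of an already-classed df_error and mislabel it a stage failure
  tryCatch(expr, error = function(e) {
    if (inherits(e, "df_error")) stop(e)
    stop_stage(stage, conditionMessage(e))
  })
}

#' Run the full repurposing funnel
#'
#' Executes, in order: input acquisition (generate, load fixture, or read
#' files), per-dataset differential expression, per-channel
#' over-representation, five-channel scoring, druggability intersection,
#' connectivity ranking, and evidence triage. Every intermediate table is
#' written under `config$outdir`, a MANIFEST with md5 content hashes is
#' emitted, and the funnel summary is returned. Identical config + seed
#' give byte-identical output trees.
#'
#' @param config a [pipeline_config()].
#' @return list of class `funnel_summary`: counts at each funnel stage
#'   (`universe`, `risk`, `druggable`, `pooled_drugs`, `positive`,
#'   `candidates`), `channel_pct` (per-channel hit percentages over the
#'   universe), `evidence` (clinical/preclinical/none counts), `outdir`.
#'   The full stage artifacts are attached as attribute `artifacts`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    stop_config("config must come from pipeline_config()")
  }
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  emit <- function(writer, object, file) {
    path <- file.path(config$outdir, file)
    writer(object, path)
    written <<- c(written, path)
    path
  }
  on.exit({
    # on abort, leave a MANIFEST marking the run incomplete
    if (!file.exists(file.path(config$outdir, "MANIFEST.tsv"))) {
      write_manifest(config$outdir, written, complete = FALSE)
    }
  })
  if (config$mode == "fixture") {
    out <- run_pipeline_fixture(config, emit)
  } else {
    out <- run_pipeline_data(config, emit)
  }
  written <- c(written, file.path(config$outdir, "funnel.tsv"))
  write_funnel(out, file.path(config$outdir, "funnel.tsv"))
  write_manifest(config$outdir, written, complete = TRUE)
  on.exit()
  out
}

run_pipeline_fixture <- function(config, emit) {
  fx <- run_stage(NULL, "fixture", pc_fixture())
  ones <- function(g) stats::setNames(rep(1L, length(g)), g)
  genes <- fx$score5_genes
  table <- run_stage(NULL, "scoring",
                     aggregate_scores(ones(genes), ones(genes), ones(genes),
                                      ones(genes), ones(genes), genes,
                                      score_min = config$score_min))
  risk <- select_risk_genes(table, config$score_min)
  cand <- data.frame(drug = fx$candidates$drug,
                     targets = fx$candidates$target,
                     n_targets = 1L, stringsAsFactors = FALSE)
  results <- structure(
    data.frame(compound = fx$candidates$drug, cell_line = config$cell_line,
               es_up = NA_real_, es_down = NA_real_,
               w = fx$candidates$cmap_score / 100,
               tau = fx$candidates$cmap_score, stringsAsFactors = FALSE),
    class = c("connectivity_result", "data.frame"))
  kept <- run_stage(NULL, "connectivity",
                    rank_and_filter(results, config$tau_min, config$tau_ge))
  rep <- run_stage(NULL, "evidence",
                   build_candidate_report(cand, kept, fx$registry))
  emit(function(o, p) utils::write.table(o, p, sep = "\t", quote = FALSE,
                                         row.names = FALSE),
       table, "gene_scores.tsv")
  emit(function(o, p) utils::write.table(o, p, sep = "\t", quote = FALSE,
                                         row.names = FALSE),
       kept, "connectivity.tsv")
  emit(function(o, p) utils::write.csv(o, p, row.names = FALSE),
       rep$report, "candidates.csv")
  emit(function(o, p) utils::write.table(o, p, sep = "\t", quote = FALSE,
                                         row.names = FALSE),
       rep$edges, "edges.tsv")
  funnel_summary(config,
                 universe = length(genes), risk = length(risk),
                 druggable = length(unique(cand$targets)),
                 pooled = nrow(cand),
                 positive = attr(kept, "n_positive"),
                 candidates = nrow(kept),
                 channel_pct = 100 * colMeans(table[score_channels]),
                 evidence = rep$summary,
                 artifacts = list(scores = table, results = results,
                                  kept = kept, report = rep))
}

run_pipeline_data <- function(config, emit) {
  cfg <- config$sim
  if (config$mode == "synthetic") {
    universe <- run_stage(NULL, "simulate", gen_gene_universe(cfg))
    collections <- run_stage(NULL, "simulate",
                             gen_geneset_collections(cfg, universe))
    risk_planted <- universe$gene[universe$risk]
    up_genes <- with_seed(cfg$seed + 600L,
                          sample(risk_planted,
                                 round(cfg$deg_fraction * length(risk_planted))))
    datasets <- lapply(seq_len(nrow(cfg$datasets)), function(i) {
      gen_expression_dataset(cfg, universe, up_genes,
                             cfg$datasets$n_normal[i], cfg$datasets$n_tumor[i],
                             name = cfg$datasets$name[i])
    })
    drug_map <- run_stage(NULL, "simulate", gen_drug_target_map(cfg, universe))
    emit(function(o, p) write_gene_list(o, p), universe$gene, "universe.txt")
    for (ch in names(collections)) {
      emit(write_gmt, collections[[ch]], sprintf("%s.gmt", tolower(ch)))
    }
    for (ds in datasets) {
      emit(write_expression, ds, sprintf("%s.tsv", ds$name))
    }
    emit(write_drug_targets, drug_map, "drug_targets.tsv")
  } else {
    universe_genes <- run_stage(NULL, "read",
                                read_gene_list(config$paths$gene_list))
    universe <- data.frame(gene = universe_genes, risk = FALSE,
                           stringsAsFactors = FALSE)
    gmt <- config$paths$gmt
    collections <- run_stage(NULL, "read", {
      cl <- lapply(names(gmt), function(ch) {
        read_gmt(gmt[[ch]], channel = toupper(ch))
      })
      names(cl) <- toupper(names(gmt))
      cl
    })
    datasets <- run_stage(NULL, "read",
                          lapply(config$paths$expression, read_expression))
    drug_map <- run_stage(NULL, "read",
                          read_drug_targets(config$paths$drug_targets))
  }

  deg_tables <- run_stage(NULL, "deg", lapply(datasets, function(ds) {
    run_deg(ds, prior_df = config$prior_df, prior_var = config$prior_var,
            adj_p_max = config$fdr, logfc_min = config$logfc_min,
            absolute_logfc = config$absolute_logfc)
  }))
  names(deg_tables) <- vapply(datasets, function(d) d$name, character(1))
  up_sets <- lapply(deg_tables, function(t) t$gene[t$up_flag])
  geo_ind <- geo_channel_indicator(up_sets, universe)

  chan_names <- c(kegg = "KEGG", bp = "BP", ko = "KO", glad4u = "GLAD4U")
  ora_tables <- run_stage(NULL, "ora", lapply(chan_names, function(ch) {
    enrich_collection(universe$gene, collections[[ch]],
                      min_set_size = config$min_set_size,
                      max_set_size = config$max_set_size,
                      fdr_max = config$fdr)
  }))
  inds <- lapply(names(chan_names), function(lc) {
    ind <- channel_indicator(universe$gene, ora_tables[[lc]],
                             collections[[chan_names[[lc]]]])
    ind[universe$gene]
  })
  names(inds) <- names(chan_names)

  table <- run_stage(NULL, "scoring",
                     aggregate_scores(inds$kegg, inds$bp, inds$ko,
                                      inds$glad4u, geo_ind, universe,
                                      score_min = config$score_min))
  risk <- select_risk_genes(table, config$score_min)

  filtered <- run_stage(NULL, "druggability",
                        filter_drug_status(drug_map, config$allowed_statuses))
  dr <- run_stage(NULL, "druggability", map_risk_to_drugs(risk, filtered))

  if (config$mode == "synthetic") {
    correlated <- utils::head(dr$candidate_drugs$drug,
                              cfg$correlated_compounds)
    profiles <- run_stage(NULL, "simulate",
                          gen_rank_profiles(cfg,
                                            compounds = unique(filtered$drug),
                                            correlated = correlated,
                                            reference_name = config$reference))
    registry <- run_stage(NULL, "simulate",
                          gen_evidence_registry(cfg, unique(filtered$drug)))
    emit(write_rank_profiles, profiles, "rank_profiles.tsv")
    emit(write_evidence, registry, "evidence.tsv")
  } else {
    profiles <- run_stage(NULL, "read",
                          read_rank_profiles(config$paths$rank_profiles,
                                             reference = config$reference))
    registry <- run_stage(NULL, "read",
                          read_evidence(config$paths$evidence))
  }

  results <- run_stage(NULL, "connectivity", {
    sig <- build_signature(extract_profile(profiles, config$reference,
                                           config$cell_line), q = config$q)
    if (config$summarize_cells == "max") {
      per_cell <- lapply(unique(profiles$cell_line), function(cl) {
        connectivity_scores(profiles, sig, cl, config$tau_min, config$tau_ge)
      })
      all <- do.call(rbind, per_cell)
      best <- tapply(seq_len(nrow(all)), all$compound,
                     function(ix) ix[which.max(all$tau[ix])])
      out <- all[unlist(best), , drop = FALSE]
      rownames(out) <- NULL
      structure(out, class = c("connectivity_result", "data.frame"))
    } else {
      connectivity_scores(profiles, sig, config$cell_line, config$tau_min,
                          config$tau_ge)
    }
  })
  pool <- results[results$compound %in% dr$candidate_drugs$drug &
                    results$compound != config$reference, , drop = FALSE]
  kept <- run_stage(NULL, "connectivity",
                    rank_and_filter(pool, config$tau_min, config$tau_ge))
  rep <- run_stage(NULL, "evidence",
                   build_candidate_report(dr$candidate_drugs, kept, registry))

  tw <- function(o, p) utils::write.table(o, p, sep = "\t", quote = FALSE,
                                          row.names = FALSE)
  for (nm in names(deg_tables)) {
    emit(tw, deg_tables[[nm]], sprintf("deg_%s.tsv", nm))
  }
  for (nm in names(ora_tables)) {
    emit(tw, ora_tables[[nm]], sprintf("ora_%s.tsv", nm))
  }
  emit(tw, table, "gene_scores.tsv")
  emit(function(o, p) write_gene_list(o, p), risk, "risk_genes.txt")
  emit(function(o, p) write_gene_list(o, p), dr$druggable_genes,
       "druggable_genes.txt")
  emit(tw, dr$candidate_drugs, "candidate_pool.tsv")
  emit(tw, results, "connectivity.tsv")
  emit(function(o, p) utils::write.csv(o, p, row.names = FALSE),
       rep$report, "candidates.csv")
  emit(tw, rep$edges, "edges.tsv")

  funnel_summary(config,
                 universe = nrow(universe), risk = length(risk),
                 druggable = length(dr$druggable_genes),
                 pooled = nrow(dr$candidate_drugs),
                 positive = attr(kept, "n_positive"),
                 candidates = nrow(kept),
                 channel_pct = 100 * colMeans(table[score_channels]),
                 evidence = rep$summary,
                 artifacts = list(universe = universe, scores = table,
                                  deg = deg_tables, ora = ora_tables,
                                  druggability = dr, profiles = profiles,
                                  results = results, kept = kept,
                                  report = rep, registry = registry))
}

funnel_summary <- function(config, universe, risk, druggable, pooled,
                           positive, candidates, channel_pct, evidence,
                           artifacts) {
  if (!(universe >= risk && risk >= druggable)) {
    stop_stage("funnel", "gene counts must be non-increasing: ",
               universe, " >= ", risk, " >= ", druggable)
  }
  if (!(candidates <= positive && positive <= pooled)) {
    stop_stage("funnel", "drug counts must be non-increasing: ",
               pooled, " >= ", positive, " >= ", candidates)
  }
  structure(list(universe = universe, risk = risk, druggable = druggable,
                 pooled_drugs = pooled, positive = positive,
                 candidates = candidates, channel_pct = channel_pct,
                 evidence = evidence, outdir = config$outdir),
            artifacts = artifacts, class = "funnel_summary")
}

#' @export
print.funnel_summary <- function(x, ...) {
  cat(sprintf("funnel: %d genes -> %d risk -> %d druggable -> %d drugs -> %d positive -> %d candidates\n",
              x$universe, x$risk, x$druggable, x$pooled_drugs, x$positive,
              x$candidates))
  cat(sprintf("channel hits (%%): %s\n",
              paste(sprintf("%s %.1f", names(x$channel_pct), x$channel_pct),
                    collapse = ", ")))
  cat(sprintf("evidence: clinical %d / preclinical %d / none %d\n",
              x$evidence[["clinical"]], x$evidence[["preclinical"]],
              x$evidence[["none"]]))
  invisible(x)
}

write_funnel <- function(funnel, path) {
  df <- data.frame(stage = c("universe", "risk", "druggable", "pooled_drugs",
                             "positive", "candidates"),
                   count = c(funnel$universe, funnel$risk, funnel$druggable,
                             funnel$pooled_drugs, funnel$positive,
                             funnel$candidates))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_manifest <- function(outdir, files, complete) {
  files <- unique(files[file.exists(files)])
  df <- data.frame(file = basename(files),
                   md5 = unname(tools::md5sum(files)),
                   stringsAsFactors = FALSE)
  df <- df[order(df$file), , drop = FALSE]
  lines <- c(sprintf("# status: %s",
                     if (complete) "complete" else "incomplete"),
             "file\tmd5", paste(df$file, df$md5, sep = "\t"))
  writeLines(lines, file.path(outdir, "MANIFEST.tsv"), useBytes = TRUE)
  invisible(df)
}

#' Verify a pipeline output directory against its MANIFEST
#'
#' @param outdir a directory written by [run_pipeline()].
#' @return TRUE invisibly if every hashed artifact matches; otherwise an
#'   error naming the first mismatch.
#' @export
verify_manifest <- function(outdir) {
  path <- file.path(outdir, "MANIFEST.tsv")
  if (!file.exists(path)) stop_format("no MANIFEST.tsv in ", outdir)
  lines <- readLines(path)
  df <- utils::read.delim(text = lines[!startsWith(lines, "#")],
                          stringsAsFactors = FALSE)
  for (i in seq_len(nrow(df))) {
    f <- file.path(outdir, df$file[i])
    h <- unname(tools::md5sum(f))
    if (is.na(h) || h != df$md5[i]) {
      stop_format("artifact hash mismatch for ", df$file[i])
    }
  }
  invisible(TRUE)
}
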