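# Synthetic-data generators. Each generator derives its own RNG stream from
# cfg$seed (constant offsets) so the full input tree is a pure function of
# the config, and individual generators can be re-run in isolation.

seed_offset <- c(universe = 1L, sets = 100L, expression = 200L,
                 drugs = 300L, profiles = 400L, evidence = 500L)

#' Generate the mutation-derived gene universe with planted risk genes
#'
#' Emulates a somatic-mutation gene list pooled across tumor studies: a set
#' of unique symbolic gene identifiers of which a hidden subset is "truly"
#' disease associated. Downstream, the planted label is the ground truth
#' for parameter-recovery tests; the pipeline itself never sees it.
#'
#' @param cfg a [sim_config()].
#' @return data.frame of class `gene_universe` with columns `gene`
#'   (character, unique, deterministic order) and `risk` (logical,
#'   exactly `n_true_risk` TRUE).
#' @export
gen_gene_universe <- function(cfg) {
  cfg <- validate_sim_config(cfg)
  genes <- sprintf("G%04d", seq_len(cfg$n_genes))
  risk <- rep(FALSE, cfg$n_genes)
  if (cfg$n_true_risk > 0L) {
    idx <- with_seed(cfg$seed + seed_offset[["universe"]],
                     sample.int(cfg$n_genes, cfg$n_true_risk))
    risk[idx] <- TRUE
  }
  structure(data.frame(gene = genes, risk = risk, stringsAsFactors = FALSE),
            class = c("gene_universe", "data.frame"))
}

#' Generate the four annotation-channel gene-set collections
#'
#' Builds KEGG-like, BP-like, KO-like and GLAD4U-like collections over an
#' annotation pool consisting of the universe plus `background_multiplier`
#' times as many annotation-only background genes (genes annotated in the
#' channel but never mutated). A designated fraction of each channel's
#' sets is enriched: each member slot of an enriched set is filled with a
#' planted risk gene with probability `enrichment_strength`, otherwise
#' uniformly from the non-risk pool. Non-enriched sets draw uniformly from
#' the whole pool, so their universe-gene content matches the pool base
#' rate and they are null for over-representation.
#'
#' @param cfg a [sim_config()].
#' @param universe a [gen_gene_universe()] result.
#' @return named list of four `geneset_collection` objects
#'   (KEGG, BP, KO, GLAD4U); each carries the enriched set names in
#'   `attr(, "enriched")`.
#' @export
gen_geneset_collections <- function(cfg, universe) {
  cfg <- validate_sim_config(cfg)
  background <- if (cfg$background_multiplier > 0L) {
    sprintf("B%05d", seq_len(cfg$background_multiplier * cfg$n_genes))
  } else character()
  pool <- c(universe$gene, background)
  if (cfg$set_size_range[2] > length(pool)) {
    stop_config("set_size_range upper bound (", cfg$set_size_range[2],
                ") exceeds annotation pool size (", length(pool), ")")
  }
  risk_genes <- universe$gene[universe$risk]
  nonrisk_pool <- setdiff(pool, risk_genes)
  channels <- c("KEGG", "BP", "KO", "GLAD4U")
  out <- lapply(seq_along(channels), function(ci) {
    ch <- channels[ci]
    with_seed(cfg$seed + seed_offset[["sets"]] + ci, {
      n_sets <- cfg$n_sets_per_channel
      if (n_sets == 0L) {
        return(geneset_collection(ch, list(), pool, enriched = character()))
      }
      n_enr <- round(cfg$enriched_fraction * n_sets)
      sizes <- sample(seq(cfg$set_size_range[1], cfg$set_size_range[2]),
                      n_sets, replace = TRUE)
      sets <- vector("list", n_sets)
      names(sets) <- sprintf("%s_S%03d", ch, seq_len(n_sets))
      for (i in seq_len(n_sets)) {
        s <- sizes[i]
        if (i <= n_enr && length(risk_genes) > 0L) {
          m <- min(rbinom(1L, s, cfg$enrichment_strength), length(risk_genes))
          sets[[i]] <- c(sample(risk_genes, m),
                         sample(nonrisk_pool, s - m))
        } else {
          sets[[i]] <- sample(pool, s)
        }
      }
      geneset_collection(ch, sets, pool,
                         enriched = names(sets)[seq_len(n_enr)])
    })
  })
  names(out) <- channels
  out
}

#' Construct a gene-set collection object
#'
#' @param channel channel label (e.g. "KEGG").
#' @param sets named list of character vectors.
#' @param annotation_universe all genes annotated in this channel.
#' @param enriched optional character vector of planted-enriched set names.
#' @return object of class `geneset_collection`.
#' @export
geneset_collection <- function(channel, sets, annotation_universe,
                               enriched = NULL) {
  if (length(sets) && is.null(names(sets))) {
    stop_format("gene sets must be named")
  }
  if (anyDuplicated(names(sets))) {
    stop_format("duplicate set names in channel ", channel)
  }
  stray <- setdiff(unique(unlist(sets, use.names = FALSE)), annotation_universe)
  if (length(stray)) {
    stop_format("sets contain genes outside the annotation universe: ",
                paste(utils::head(stray, 5), collapse = ", "))
  }
  structure(list(channel = channel, sets = sets,
                 annotation_universe = annotation_universe),
            enriched = enriched, class = "geneset_collection")
}

#' @export
print.geneset_collection <- function(x, ...) {
  cat(sprintf("geneset_collection [%s]: %d sets over %d annotated genes\n",
              x$channel, length(x$sets), length(x$annotation_universe)))
  invisible(x)
}

#' Generate a two-group log2 expression dataset with planted up-regulation
#'
#' Genes x samples matrix on the log2 scale: per-gene baseline ~N(8, 1.5),
#' i.i.d. N(0, noise_sd) noise, and `effect_size` added to the tumor
#' columns of the planted `up_genes`.
#'
#' @param cfg a [sim_config()].
#' @param universe a [gen_gene_universe()] result.
#' @param up_genes character; planted up-regulated genes (subset of the
#'   universe).
#' @param n_normal,n_tumor group sizes (each >= 2).
#' @param name dataset label, used in sample ids and as the seed salt.
#' @return `expr_dataset`: list with `values` (matrix), `group` (factor
#'   normal/tumor named by sample id), `name`.
#' @export
gen_expression_dataset <- function(cfg, universe, up_genes,
                                   n_normal, n_tumor, name = "sim") {
  cfg <- validate_sim_config(cfg)
  if (n_normal < 2L || n_tumor < 2L) {
    stop_config("each group needs >= 2 samples (variance undefined); got ",
                n_normal, "/", n_tumor)
  }
  bad <- setdiff(up_genes, universe$gene)
  if (length(bad)) {
    stop_config("up_genes not in universe: ",
                paste(utils::head(bad, 5), collapse = ", "))
  }
  salt <- sum(utf8ToInt(name)) %% 10000L
  with_seed(cfg$seed + seed_offset[["expression"]] + salt, {
    n <- n_normal + n_tumor
    g <- cfg$n_genes
    baseline <- rnorm(g, mean = 8, sd = 1.5)
    values <- matrix(rnorm(g * n, sd = cfg$noise_sd), g, n) + baseline
    rownames(values) <- universe$gene
    colnames(values) <- c(sprintf("%s_N%02d", name, seq_len(n_normal)),
                          sprintf("%s_T%02d", name, seq_len(n_tumor)))
    tumor_cols <- n_normal + seq_len(n_tumor)
    values[up_genes, tumor_cols] <- values[up_genes, tumor_cols] + cfg$effect_size
    group <- factor(rep(c("normal", "tumor"), c(n_normal, n_tumor)),
                    levels = c("normal", "tumor"))
    names(group) <- colnames(values)
    expr_dataset(values, group, name)
  })
}

#' Construct an expression dataset object
#'
#' @param values numeric matrix, genes x samples, unique rownames.
#' @param group factor with levels normal/tumor, one per column.
#' @param name dataset label.
#' @return object of class `expr_dataset`.
#' @export
expr_dataset <- function(values, group, name = "dataset") {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_format("expression values must be a numeric matrix")
  }
  if (is.null(rownames(values)) || anyDuplicated(rownames(values))) {
    stop_format("expression matrix needs unique gene rownames")
  }
  if (length(group) != ncol(values)) {
    stop_format("group labels (", length(group),
                ") do not match sample count (", ncol(values), ")")
  }
  group <- factor(as.character(group), levels = c("normal", "tumor"))
  if (anyNA(group)) stop_format("group labels must be 'normal' or 'tumor'")
  names(group) <- colnames(values)
  structure(list(values = values, group = group, name = name),
            class = "expr_dataset")
}

#' @export
print.expr_dataset <- function(x, ...) {
  cat(sprintf("expr_dataset '%s': %d genes x %d samples (%d normal / %d tumor)\n",
              x$name, nrow(x$values), ncol(x$values),
              sum(x$group == "normal"), sum(x$group == "tumor")))
  invisible(x)
}

#' Generate a drug-target map with a druggable subset of risk genes
#'
#' A `druggable_fraction` of the planted risk genes each receive one to
#' five drugs (long-tailed, mean ~2.7, chosen so ~77 druggable genes map
#' to ~200+ drugs at default scale); decoy drugs targeting non-risk
#' universe genes are added at `extra_drug_fraction`. A small fraction of
#' drugs picks up a second target. Statuses are sampled from
#' `status_probs`.
#'
#' @param cfg a [sim_config()].
#' @param universe a [gen_gene_universe()] result.
#' @return `drug_target_map` data.frame: drug, target, status, action.
#' @export
gen_drug_target_map <- function(cfg, universe) {
  cfg <- validate_sim_config(cfg)
  risk_genes <- universe$gene[universe$risk]
  with_seed(cfg$seed + seed_offset[["drugs"]], {
    druggable <- if (length(risk_genes)) {
      sample(risk_genes, round(cfg$druggable_fraction * length(risk_genes)))
    } else character()
    per_gene <- if (length(druggable)) {
      sample(1:5, length(druggable), replace = TRUE,
             prob = c(0.25, 0.25, 0.2, 0.15, 0.15))
    } else integer()
    targets <- rep(druggable, per_gene)
    nonrisk <- setdiff(universe$gene, risk_genes)
    n_extra <- round(cfg$extra_drug_fraction * length(targets))
    if (n_extra > 0L && length(nonrisk)) {
      targets <- c(targets, sample(nonrisk, n_extra, replace = TRUE))
    }
    n_drugs <- length(targets)
    if (n_drugs == 0L) {
      return(drug_target_map(data.frame(drug = character(),
                                        target = character(),
                                        status = character(),
                                        action = character(),
                                        stringsAsFactors = FALSE)))
    }
    drugs <- sprintf("DRUG%04d", seq_len(n_drugs))
    status <- sample(names(cfg$status_probs), n_drugs, replace = TRUE,
                     prob = cfg$status_probs)
    action <- sample(c("inhibitor", "antagonist", "agonist", "modulator",
                       "binder"), n_drugs, replace = TRUE)
    df <- data.frame(drug = drugs, target = targets, status = status,
                     action = action, stringsAsFactors = FALSE)
    # ~10% of drugs gain a second target among the druggable genes
    if (length(druggable) > 1L) {
      second <- which(runif(n_drugs) < 0.1)
      for (i in second) {
        tg <- sample(setdiff(druggable, df$target[i]), 1L)
        df <- rbind(df, data.frame(drug = df$drug[i], target = tg,
                                   status = df$status[i],
                                   action = df$action[i],
                                   stringsAsFactors = FALSE))
      }
    }
    drug_target_map(df[order(df$drug, df$target), , drop = FALSE])
  })
}

#' Construct/validate a drug-target map
#'
#' @param df data.frame with columns drug, target, status, action.
#' @return validated data.frame of class `drug_target_map`.
#' @export
drug_target_map <- function(df) {
  req <- c("drug", "target", "status", "action")
  if (!all(req %in% names(df))) {
    stop_format("drug-target map needs columns: ", paste(req, collapse = ", "))
  }
  if (any(!nzchar(trimws(df$drug)))) stop_format("empty drug name in map")
  unknown <- setdiff(unique(df$status), drug_statuses())
  if (length(unknown)) {
    stop_format("unknown drug status token(s): ",
                paste(unknown, collapse = ", "))
  }
  if (anyDuplicated(df[c("drug", "target")])) {
    dup <- df[duplicated(df[c("drug", "target")]), , drop = FALSE]
    stop_format("duplicate (drug, target) pair: ", dup$drug[1], " -> ",
                dup$target[1])
  }
  rownames(df) <- NULL
  structure(df, class = c("drug_target_map", "data.frame"))
}

#' Generate compound rank profiles (touchstone surrogate)
#'
#' One complete ranking (permutation; rank 1 = most up-regulated) of a
#' profiled gene space per (compound, cell line). The reference compound
#' is profiled in the A549, MCF7 and PC3 cell lines; `correlated`
#' compounds are derived from the reference MCF7 ranking by a drawn
#' number of adjacent transpositions (a monotone similarity knob); all
#' other compounds are independent uniform permutations in MCF7.
#'
#' @param cfg a [sim_config()].
#' @param compounds character; compound names to profile. Defaults to
#'   `cfg$n_compounds` synthetic names `CP0001`, ...
#' @param correlated character; subset of `compounds` planted as
#'   reference-correlated. Defaults to the first
#'   `cfg$correlated_compounds` entries.
#' @param reference_name name of the reference compound (default
#'   "gemcitabine").
#' @return object of class `rank_profiles`: list with `genes`, integer
#'   matrix `ranks` (genes x profiles), `compound` and `cell_line`
#'   per column, and `reference`.
#' @export
gen_rank_profiles <- function(cfg, compounds = NULL, correlated = NULL,
                              reference_name = "gemcitabine") {
  cfg <- validate_sim_config(cfg)
  if (is.null(compounds)) {
    n <- cfg$n_compounds %||% 100L
    compounds <- sprintf("CP%04d", seq_len(n))
  }
  if (anyDuplicated(compounds)) {
    stop_config("duplicate compound names: ",
                paste(unique(compounds[duplicated(compounds)]), collapse = ", "))
  }
  if (reference_name %in% compounds) {
    stop_config("reference compound '", reference_name,
                "' also appears in the compound list")
  }
  if (is.null(correlated)) {
    correlated <- utils::head(compounds, cfg$correlated_compounds)
  }
  if (!all(correlated %in% compounds)) {
    stop_config("correlated compounds must be a subset of compounds")
  }
  N <- cfg$n_profiled_genes
  genes <- sprintf("L%04d", seq_len(N))
  with_seed(cfg$seed + seed_offset[["profiles"]], {
    ref <- sample.int(N)  # reference ranking (MCF7)
    ref_lines <- c("A549", "MCF7", "PC3")
    n_prof <- length(ref_lines) + length(compounds)
    ranks <- matrix(NA_integer_, N, n_prof)
    compound <- character(n_prof)
    cell_line <- character(n_prof)
    k_rng <- cfg$transposition_range
    j <- 0L
    for (cl in ref_lines) {
      j <- j + 1L
      compound[j] <- reference_name
      cell_line[j] <- cl
      ranks[, j] <- if (cl == "MCF7") ref else {
        perturb_ranking(ref, sample(seq(k_rng[1], k_rng[2]), 1L))
      }
    }
    for (cp in compounds) {
      j <- j + 1L
      compound[j] <- cp
      cell_line[j] <- "MCF7"
      ranks[, j] <- if (cp %in% correlated) {
        perturb_ranking(ref, sample(seq(k_rng[1], k_rng[2]), 1L))
      } else {
        sample.int(N)
      }
    }
    rownames(ranks) <- genes
    colnames(ranks) <- paste(compound, cell_line, sep = ":")
    structure(list(genes = genes, ranks = ranks, compound = compound,
                   cell_line = cell_line, reference = reference_name),
              correlated = correlated, class = "rank_profiles")
  })
}

# k adjacent transpositions in rank order: swap the genes holding ranks
# (i, i+1). k = 0 returns the ranking unchanged.
perturb_ranking <- function(ranking, k) {
  ord <- order(ranking)  # ord[r] = index of the gene at rank r
  N <- length(ranking)
  if (k > 0L) {
    for (pos in sample.int(N - 1L, k, replace = TRUE)) {
      ord[c(pos, pos + 1L)] <- ord[c(pos + 1L, pos)]
    }
  }
  out <- integer(N)
  out[ord] <- seq_len(N)
  out
}

#' @export
print.rank_profiles <- function(x, ...) {
  cat(sprintf("rank_profiles: %d genes x %d profiles (%d compounds; reference '%s' in %s)\n",
              length(x$genes), ncol(x$ranks),
              length(unique(x$compound)) - 1L, x$reference,
              paste(sort(unique(x$cell_line[x$compound == x$reference])),
                    collapse = "/")))
  invisible(x)
}

#' Generate an evidence registry for a set of drugs
#'
#' Each drug independently receives trial records (phase 1-4,
#' NCT-style ids) with probability `evidence_probs["trial"]`,
#' publication records (PMID-style ids) with probability
#' `evidence_probs["pub"]`, or neither.
#'
#' @param cfg a [sim_config()].
#' @param drugs character; nonempty drug names.
#' @return `evidence_registry` data.frame: drug, kind (trial/publication),
#'   phase (NA for publications), id. Drugs with no records are absent.
#' @export
gen_evidence_registry <- function(cfg, drugs) {
  cfg <- validate_sim_config(cfg)
  if (!length(drugs)) stop_config("drugs must be nonempty")
  with_seed(cfg$seed + seed_offset[["evidence"]], {
    rows <- lapply(drugs, function(d) {
      out <- NULL
      if (runif(1) < cfg$evidence_probs[["trial"]]) {
        n <- sample(1:2, 1L)
        out <- rbind(out, data.frame(
          drug = d, kind = "trial", phase = sample(1:4, n, replace = TRUE),
          id = sprintf("NCT%08d", sample.int(99999999L, n)),
          stringsAsFactors = FALSE))
      }
      if (runif(1) < cfg$evidence_probs[["pub"]]) {
        n <- sample(1:2, 1L)
        out <- rbind(out, data.frame(
          drug = d, kind = "publication", phase = NA_integer_,
          id = sprintf("PMID:%d", sample.int(39999999L, n)),
          stringsAsFactors = FALSE))
      }
      out
    })
    rows <- Filter(Negate(is.null), rows)
    evidence_registry(if (length(rows)) do.call(rbind, rows) else empty_evidence())
  })
}

empty_evidence <- function() {
  data.frame(drug = character(), kind = character(), phase = integer(),
             id = character(), stringsAsFactors = FALSE)
}

#' Construct/validate an evidence registry
#'
#' @param df data.frame with columns drug, kind, phase, id.
#' @return validated data.frame of class `evidence_registry`.
#' @export
evidence_registry <- function(df) {
  if (is.null(df) || nrow(df) == 0L) {
    df <- empty_evidence()
  }
  req <- c("drug", "kind", "phase", "id")
  if (!all(req %in% names(df))) {
    stop_format("evidence registry needs columns: ",
                paste(req, collapse = ", "))
  }
  bad_kind <- !df$kind %in% c("trial", "publication")
  if (any(bad_kind)) {
    stop_format("unknown evidence kind for drug ", df$drug[bad_kind][1])
  }
  trial <- df$kind == "trial"
  if (any(trial & (is.na(df$phase) | !df$phase %in% 1:4))) {
    bad <- df$drug[trial & (is.na(df$phase) | !df$phase %in% 1:4)][1]
    stop_format("trial record with invalid phase for drug ", bad)
  }
  if (any(!nzchar(trimws(df$id)))) {
    stop_format("empty evidence id for drug ",
                df$drug[!nzchar(trimws(df$id))][1])
  }
  rownames(df) <- NULL
  structure(df, class = c("evidence_registry", "data.frame"))
}
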