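#' Simulation configuration for the synthetic pipeline world
#'
#' Bundles every generative knob used by the `gen_*()` functions. The
#' defaults encode the scale of the pancreatic-cancer case study the
#' package ships as its worked example: an 895-gene mutation-derived
#' universe with 318 planted risk genes, four two-group expression series
#' at sample sizes 61/69, 42/36, 16/36 and 7/15, a drug-target map in
#' which about a quarter of risk genes are druggable, and a touchstone
#' panel in which 40 compounds share signature direction with the
#' reference compound (a gemcitabine surrogate profiled in the A549, MCF7
#' and PC3 cell lines).
#'
#' @param seed integer; master seed. Every generator derives its own
#'   stream from it, so one config yields one byte-identical output tree.
#' @param n_genes universe size (default 895).
#' @param n_true_risk number of planted risk genes (default 318).
#' @param n_sets_per_channel gene sets per annotation channel.
#' @param set_size_range integer pair; uniform range of set sizes.
#' @param enriched_fraction fraction of each channel's sets that are
#'   enriched for planted risk genes.
#' @param enrichment_strength probability that a member slot of an
#'   enriched set is filled with a planted risk gene; the remaining slots
#'   and all non-enriched sets draw uniformly from the annotation pool
#'   (the implicit base rate).
#' @param background_multiplier annotation-only background genes are
#'   generated at this multiple of the universe size.
#' @param datasets data.frame with columns `name`, `n_normal`, `n_tumor`;
#'   one row per expression series.
#' @param effect_size planted log2 up-regulation shift in tumor samples.
#' @param noise_sd residual log2 noise standard deviation.
#' @param deg_fraction fraction of risk genes planted as up-regulated.
#' @param druggable_fraction fraction of risk genes that receive >= 1 drug.
#' @param extra_drug_fraction drugs targeting non-risk universe genes, as
#'   a fraction of the risk-targeting drug count (decoys).
#' @param n_compounds optional total compound count for standalone rank
#'   profile generation; the pipeline instead profiles the drug pool.
#' @param n_profiled_genes size of the profiled (landmark-like) gene
#'   space; default 978.
#' @param correlated_compounds number of compounds perturbed from the
#'   reference permutation (planted connectivity signal).
#' @param transposition_range integer pair; per correlated compound the
#'   number of adjacent transpositions applied to the reference ranking
#'   is drawn uniformly from this range (fewer = more similar).
#' @param status_probs named numeric; sampling weights of drug status
#'   over approved/clinical/experimental/withdrawn.
#' @param evidence_probs named numeric with entries `trial` and `pub`:
#'   marginal probabilities that a drug carries trial / publication
#'   records in a generated evidence registry.
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 895L,
                       n_true_risk = 318L,
                       n_sets_per_channel = 30L,
                       set_size_range = c(40L, 120L),
                       enriched_fraction = 0.3,
                       enrichment_strength = 0.5,
                       background_multiplier = 10L,
                       datasets = data.frame(
                         name = c("GSE28735_sim", "GSE15471_sim",
                                  "GSE16515_sim", "GSE19650_sim"),
                         n_normal = c(61L, 42L, 16L, 7L),
                         n_tumor = c(69L, 36L, 36L, 15L),
                         stringsAsFactors = FALSE),
                       effect_size = 4,
                       noise_sd = 1,
                       deg_fraction = 0.5,
                       druggable_fraction = 0.24,
                       extra_drug_fraction = 0.15,
                       n_compounds = NULL,
                       n_profiled_genes = 978L,
                       correlated_compounds = 40L,
                       transposition_range = c(10L, 60L),
                       status_probs = c(approved = 0.5, clinical = 0.2,
                                        experimental = 0.25, withdrawn = 0.05),
                       evidence_probs = c(trial = 0.4, pub = 0.3)) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              n_true_risk = as.integer(n_true_risk),
              n_sets_per_channel = as.integer(n_sets_per_channel),
              set_size_range = as.integer(set_size_range),
              enriched_fraction = enriched_fraction,
              enrichment_strength = enrichment_strength,
              background_multiplier = as.integer(background_multiplier),
              datasets = datasets, effect_size = effect_size,
              noise_sd = noise_sd, deg_fraction = deg_fraction,
              druggable_fraction = druggable_fraction,
              extra_drug_fraction = extra_drug_fraction,
              n_compounds = if (is.null(n_compounds)) NULL else as.integer(n_compounds),
              n_profiled_genes = as.integer(n_profiled_genes),
              correlated_compounds = as.integer(correlated_compounds),
              transposition_range = as.integer(transposition_range),
              status_probs = status_probs, evidence_probs = evidence_probs)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  if (cfg$n_genes < 1L) stop_config("n_genes must be >= 1")
  if (cfg$n_true_risk < 0L || cfg$n_true_risk > cfg$n_genes) {
    stop_config("n_true_risk must lie in [0, n_genes]; got ",
                cfg$n_true_risk, " with n_genes = ", cfg$n_genes)
  }
  fracs <- c(enriched_fraction = cfg$enriched_fraction,
             enrichment_strength = cfg$enrichment_strength,
             deg_fraction = cfg$deg_fraction,
             druggable_fraction = cfg$druggable_fraction)
  bad <- fracs < 0 | fracs > 1
  if (any(bad)) {
    stop_config("fractions must lie in [0,1]: ",
                paste(names(fracs)[bad], collapse = ", "))
  }
  if (length(cfg$set_size_range) != 2L ||
      cfg$set_size_range[1] > cfg$set_size_range[2] ||
      cfg$set_size_range[1] < 1L) {
    stop_config("set_size_range must be an increasing positive integer pair")
  }
  req <- c("name", "n_normal", "n_tumor")
  if (!is.data.frame(cfg$datasets) || !all(req %in% names(cfg$datasets))) {
    stop_config("datasets must be a data.frame with columns name/n_normal/n_tumor")
  }
  if (length(cfg$transposition_range) != 2L ||
      cfg$transposition_range[1] > cfg$transposition_range[2] ||
      cfg$transposition_range[1] < 0L) {
    stop_config("transposition_range must be a non-decreasing non-negative pair")
  }
  if (cfg$n_profiled_genes < 2L) stop_config("n_profiled_genes must be >= 2")
  if (is.null(names(cfg$status_probs)) ||
      !all(names(cfg$status_probs) %in% drug_statuses())) {
    stop_config("status_probs must be named with known drug statuses")
  }
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:",
      sprintf("%d genes (%d planted risk), %d sets/channel (%.0f%% enriched @ %.2f),",
              x$n_genes, x$n_true_risk, x$n_sets_per_channel,
              100 * x$enriched_fraction, x$enrichment_strength),
      sprintf("%d expression series, effect %.1f log2 / sd %.1f,",
              nrow(x$datasets), x$effect_size, x$noise_sd),
      sprintf("%d profiled genes, %d correlated compounds, seed %d\n",
              x$n_profiled_genes, x$correlated_compounds, x$seed))
  invisible(x)
}

#' Recognized drug status tokens
#'
#' @return character vector of the valid status values of a
#'   [drug_target_map()].
#' @export
drug_statuses <- function() c("approved", "clinical", "experimental", "withdrawn")
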