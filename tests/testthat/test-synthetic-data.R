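test_that("gene universe planting covers the stated cases", {
  cases <- list(list(n = 895L, risk = 318L), list(n = 10L, risk = 0L),
                list(n = 50L, risk = 50L))
  for (cs in cases) {
    u <- gen_gene_universe(sim_config(seed = 1, n_genes = cs$n,
                                      n_true_risk = cs$risk))
    expect_equal(nrow(u), cs$n)
    expect_equal(anyDuplicated(u$gene), 0L)
    expect_equal(sum(u$risk), cs$risk)
  }
  expect_error(sim_config(n_genes = 10, n_true_risk = 11), "n_true_risk",
               class = "df_config_error")
})

test_that("generators are pure functions of (config, seed)", {
  cfg <- small_sim(seed = 7)
  u1 <- gen_gene_universe(cfg)
  # a polluted RNG state in the session must not leak in
  set.seed(999); runif(3)
  u2 <- gen_gene_universe(cfg)
  expect_identical(u1, u2)
  expect_identical(gen_geneset_collections(cfg, u1),
                   gen_geneset_collections(cfg, u2))
  expect_false(identical(gen_gene_universe(small_sim(seed = 8))$risk, u1$risk))
})

test_that("gene-set collections respect structure and enrichment planting", {
  cfg <- small_sim(seed = 3)
  u <- gen_gene_universe(cfg)
  cl <- gen_geneset_collections(cfg, u)
  expect_named(cl, c("KEGG", "BP", "KO", "GLAD4U"))
  risk <- u$gene[u$risk]
  for (ch in cl) {
    expect_length(ch$sets, cfg$n_sets_per_channel)
    sizes <- lengths(ch$sets)
    expect_true(all(sizes >= cfg$set_size_range[1] &
                      sizes <= cfg$set_size_range[2]))
    expect_true(all(unlist(ch$sets) %in% ch$annotation_universe))
    enr <- attr(ch, "enriched")
    expect_length(enr, round(cfg$enriched_fraction * cfg$n_sets_per_channel))
    # planted risk genes over-represented in enriched sets vs the rest
    frac <- vapply(ch$sets, function(s) mean(s %in% risk), numeric(1))
    other <- setdiff(names(frac), enr)
    expect_gt(mean(frac[enr]), 0.35)        # strength 0.5, binomial spread
    expect_lt(mean(frac[other]), 0.15)      # pool base rate ~ 70/1200
    expect_gt(min(frac[enr]), max(frac[other]))
  }
})

test_that("degenerate and infeasible set configurations behave", {
  cfg <- small_sim(seed = 1, n_sets_per_channel = 0L)
  u <- gen_gene_universe(cfg)
  cl <- gen_geneset_collections(cfg, u)
  expect_length(cl$KEGG$sets, 0L)
  gmt <- tempfile(fileext = ".gmt")
  write_gmt(cl$KEGG, gmt)   # valid GMT with zero records
  expect_identical(readLines(gmt), character())
  bad <- small_sim(seed = 1, background_multiplier = 0L,
                   set_size_range = c(150L, 5000L))
  expect_error(gen_geneset_collections(bad, gen_gene_universe(bad)),
               "annotation pool", class = "df_config_error")
})

test_that("expression generator plants the effect at the stated sample sizes", {
  cfg <- sim_config(seed = 2, n_genes = 300, n_true_risk = 100,
                    effect_size = 3, noise_sd = 1)
  u <- gen_gene_universe(cfg)
  up <- u$gene[u$risk][1:40]
  ds <- gen_expression_dataset(cfg, u, up, 61, 69, name = "GSE28735_sim")
  expect_equal(ncol(ds$values), 130)   # 61 normal + 69 tumor
  expect_equal(as.vector(table(ds$group)), c(61, 69))
  diff <- rowMeans(ds$values[, ds$group == "tumor"]) -
    rowMeans(ds$values[, ds$group == "normal"])
  expect_equal(mean(diff[up]), 3, tolerance = 0.15)
  expect_equal(mean(diff[setdiff(u$gene, up)]), 0, tolerance = 0.1)
  expect_error(gen_expression_dataset(cfg, u, up, 1, 10),
               ">= 2 samples", class = "df_config_error")
  expect_error(gen_expression_dataset(cfg, u, c(up, "NOPE"), 5, 5),
               "NOPE", class = "df_config_error")
})

test_that("drug-target map honours druggable fraction and dedupes pairs", {
  cfg <- sim_config(seed = 4)
  u <- gen_gene_universe(cfg)
  map <- gen_drug_target_map(cfg, u)
  risk <- u$gene[u$risk]
  druggable_risk <- intersect(unique(map$target), risk)
  expect_equal(length(druggable_risk), round(0.24 * length(risk)))
  expect_true(all(map$status %in% c("approved", "clinical", "experimental",
                                    "withdrawn")))
  expect_equal(anyDuplicated(map[c("drug", "target")]), 0L)
  # zero fraction -> no risk gene druggable
  map0 <- gen_drug_target_map(sim_config(seed = 4, druggable_fraction = 0,
                                         extra_drug_fraction = 0), u)
  expect_equal(nrow(map0), 0L)
})

test_that("rank profiles are permutations with the reference in three cell lines", {
  cfg <- small_sim(seed = 5)
  rp <- gen_rank_profiles(cfg, compounds = sprintf("CP%03d", 1:30))
  N <- cfg$n_profiled_genes
  for (j in seq_len(ncol(rp$ranks))) {
    expect_identical(sort(unname(rp$ranks[, j])), seq_len(N))
  }
  expect_setequal(rp$cell_line[rp$compound == "gemcitabine"],
                  c("A549", "MCF7", "PC3"))
  expect_error(gen_rank_profiles(cfg, compounds = c("a", "a")),
               "duplicate", class = "df_config_error")
})

test_that("zero transpositions reproduce the reference exactly (tau 100)", {
  cfg <- small_sim(seed = 6, transposition_range = c(0L, 0L))
  rp <- gen_rank_profiles(cfg, compounds = sprintf("CP%03d", 1:20),
                          correlated = "CP001")
  ref <- extract_profile(rp, "gemcitabine", "MCF7")
  twin <- extract_profile(rp, "CP001", "MCF7")
  expect_identical(ref$ranking, stats::setNames(twin$ranking,
                                                names(ref$ranking)))
  sig <- build_signature(ref, q = 50)
  # against the compound touchstone (reference excluded: it ties exactly),
  # the identical compound reaches tau = 100
  comp <- setdiff(unique(rp$compound), "gemcitabine")
  w <- vapply(comp, function(cp) {
    pr <- extract_profile(rp, cp, "MCF7")
    combined_score(ks_enrichment(sig$up_set, pr),
                   ks_enrichment(sig$down_set, pr))
  }, numeric(1))
  expect_equal(tau_normalize(w[["CP001"]], w[names(w) != "CP001"]), 100)
  # within connectivity_scores the tie with the reference caps the strict
  # percentile below 100, but the twin still matches the reference exactly
  res <- connectivity_scores(rp, sig, "MCF7")
  expect_equal(res$w[res$compound == "CP001"],
               res$w[res$compound == "gemcitabine"])
  expect_equal(res$tau[res$compound == "CP001"], max(res$tau))
})

test_that("evidence registry records are well formed and configurable", {
  cfg <- small_sim(seed = 9, evidence_probs = c(trial = 0.5, pub = 0.5))
  reg <- gen_evidence_registry(cfg, sprintf("D%02d", 1:50))
  expect_s3_class(reg, "evidence_registry")
  expect_true(all(reg$kind %in% c("trial", "publication")))
  expect_true(all(reg$phase[reg$kind == "trial"] %in% 1:4))
  expect_true(all(is.na(reg$phase[reg$kind == "publication"])))
  none <- gen_evidence_registry(small_sim(seed = 9,
                                          evidence_probs = c(trial = 0, pub = 0)),
                                c("d1", "d2"))
  expect_equal(nrow(none), 0L)
  expect_error(gen_evidence_registry(cfg, character()), "nonempty",
               class = "df_config_error")
})

test_that("bundled case-study fixture matches its published shape", {
  fx <- pc_fixture()
  expect_equal(nrow(fx$candidates), 13L)
  expect_length(fx$score5_genes, 12L)
  expect_true(all(fx$candidates$cmap_score > -100 &
                    fx$candidates$cmap_score <= 100))
  clom <- fx$candidates[fx$candidates$drug == "Clomifene", ]
  expect_equal(clom$cmap_score, 97.84)
  expect_equal(clom$target, "ESR1")
  expect_true("CDKN2A" %in% fx$score5_genes)
  expect_equal(fx$thresholds,
               list(fdr = 0.05, logfc_min = 2, score_min = 2, tau_min = 80))
})
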