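test_that("normalization centers sample medians and preserves group effects", {
  # all-constant matrix is already centered
  v <- matrix(5, 10, 4, dimnames = list(sprintf("g%d", 1:10), sprintf("s%d", 1:4)))
  ds <- expr_dataset(v, rep(c("normal", "tumor"), each = 2))
  expect_equal(normalize_expression(ds)$values, v)

  # a +3 log2 shift on one sample is removed
  ds2 <- make_dataset(n_genes = 200, n1 = 4, n2 = 4, seed = 11)
  ds2$values[, 3] <- ds2$values[, 3] + 3
  norm <- normalize_expression(ds2)
  med <- apply(norm$values, 2, median)
  expect_true(max(abs(med - med[1])) < 1e-9)

  # linear-scale input gets log2(x+1) first
  lin <- expr_dataset(matrix(2^seq(2, 13, length.out = 40), 10, 4,
                             dimnames = list(sprintf("g%d", 1:10),
                                             sprintf("s%d", 1:4))),
                      rep(c("normal", "tumor"), each = 2))
  expect_lt(max(normalize_expression(lin)$values), 50)

  # planted group separation is invariant to column centering
  cfg <- small_sim(seed = 12, effect_size = 2.5)
  u <- gen_gene_universe(cfg)
  up <- u$gene[u$risk][1:20]
  raw <- gen_expression_dataset(cfg, u, up, 8, 8)
  nrm <- normalize_expression(raw)
  d_raw <- rowMeans(raw$values[, raw$group == "tumor"]) -
    rowMeans(raw$values[, raw$group == "normal"])
  d_nrm <- rowMeans(nrm$values[, nrm$group == "tumor"]) -
    rowMeans(nrm$values[, nrm$group == "normal"])
  expect_equal(cor(d_raw, d_nrm), 1, tolerance = 0.02)
  expect_equal(mean(d_nrm[up]) - mean(d_nrm[setdiff(u$gene, up)]), 2.5,
               tolerance = 0.3)

  ds2$values[1, 1] <- NaN
  expect_error(normalize_expression(ds2), "non-finite",
               class = "df_format_error")
})

test_that("moderated t matches the hand-computed shrinkage example", {
  v <- rbind(gA = c(0, 1, 2, 4, 5, 6))  # means 1 vs 5, pooled s2 = 1
  ds <- expr_dataset(v, rep(c("normal", "tumor"), each = 3))
  res <- moderated_t(ds, prior_df = 4, prior_var = 1)
  expect_equal(res$logFC, 4)
  expect_equal(res$t, 4 / sqrt(2 / 3), tolerance = 1e-12)  # ~4.899
  expect_equal(res$df, 8)
  expect_equal(res$p, 2 * pt(-4 / sqrt(2 / 3), df = 8), tolerance = 1e-12)
})

test_that("moderated t limiting cases: d0 = 0 is the pooled t, huge d0 pins the prior", {
  ds <- make_dataset(n_genes = 40, n1 = 5, n2 = 7, seed = 13)
  r0 <- moderated_t(ds, prior_df = 0)
  for (i in c(1, 17, 40)) {
    tt <- t.test(ds$values[i, ds$group == "tumor"],
                 ds$values[i, ds$group == "normal"], var.equal = TRUE)
    expect_equal(r0$t[i], unname(tt$statistic), tolerance = 1e-12)
    expect_equal(r0$p[i], tt$p.value, tolerance = 1e-12)
  }
  rb <- moderated_t(ds, prior_df = 1e9, prior_var = 1)
  expect_equal(rb$t, r0$logFC / sqrt(1 / 5 + 1 / 7), tolerance = 1e-6)
})

test_that("zero shrunken variance with nonzero logFC is flagged", {
  v <- rbind(flat = c(1, 1, 2, 2))
  ds <- expr_dataset(v, rep(c("normal", "tumor"), each = 2))
  expect_warning(res <- moderated_t(ds, prior_df = 0), "zero shrunken")
  expect_equal(res$p, .Machine$double.xmin)
})

test_that("bh_adjust reproduces the worked step-up example and the cap", {
  expect_equal(bh_adjust(c(0.01, 0.04, 0.03, 0.005)),
               c(0.02, 0.04, 0.04, 0.02))
  expect_equal(bh_adjust(c(1, 1)), c(1, 1))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]",
               class = "df_config_error")
})

test_that("bh_adjust agrees with brute force and p.adjust on random vectors", {
  with_seed(14, {
    for (rep in 1:200) {
      p <- runif(sample(1:60, 1))
      adj <- bh_adjust(p)
      expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
      expect_equal(adj, p.adjust(p, method = "BH"), tolerance = 1e-12)
      expect_true(all(adj >= p - 1e-15))
      ord <- order(p)
      expect_true(all(diff(adj[ord]) >= -1e-15))  # monotone after sorting
    }
  })
})

test_that("up-DEG calling uses strict cutoffs and direction", {
  res <- data.frame(gene = c("a", "b", "c", "d", "e"),
                    logFC = c(2.5, 5, -4, 2.0, 3),
                    adj_p = c(0.01, 0.06, 0.001, 0.01, 0.05))
  expect_equal(call_up_degs(res), "a")           # b fails p, c down, d/e ties
  expect_setequal(call_up_degs(res, absolute_logfc = TRUE), c("a", "c"))
})

test_that("expression-channel indicator is the union over datasets", {
  universe <- c("g1", "g2", "g3", "g4")
  ind <- geo_channel_indicator(list(c("g1"), c("g1", "g3"), character()),
                               universe)
  expect_equal(ind, c(g1 = 1L, g2 = 0L, g3 = 1L, g4 = 0L))
  # union recall is at least per-dataset recall on planted data
  cfg <- small_sim(seed = 15, effect_size = 4, noise_sd = 0.5)
  u <- gen_gene_universe(cfg)
  up <- u$gene[u$risk][1:30]
  sets <- lapply(1:3, function(i) {
    ds <- gen_expression_dataset(cfg, u, up, 10, 10, name = paste0("d", i))
    call_up_degs(run_deg(ds))
  })
  per <- vapply(sets, function(s) mean(up %in% s), numeric(1))
  uni <- mean(up %in% unique(unlist(sets)))
  expect_gte(uni, max(per))
  expect_gte(uni, 0.99)   # power ~1 at effect 4, sd 0.5, n = 10+10
})
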