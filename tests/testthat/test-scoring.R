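ind_vec <- function(universe, hits) {
  stats::setNames(as.integer(universe %in% hits), universe)
}

test_that("score aggregation implements the 0-5 sum and the >= 2 risk rule", {
  genes <- c("g1", "g2", "g3")
  tab <- aggregate_scores(ind_vec(genes, c("g1", "g2", "g3")),
                          ind_vec(genes, c("g1", "g2")),
                          ind_vec(genes, "g1"),
                          ind_vec(genes, "g1"),
                          ind_vec(genes, "g1"), genes)
  expect_equal(tab$score[tab$gene == "g1"], 5L)   # all five criteria
  expect_equal(tab$score[tab$gene == "g2"], 2L)
  expect_equal(tab$score[tab$gene == "g3"], 1L)
  expect_equal(tab$risk_flag, c(TRUE, TRUE, FALSE))
  expect_equal(tab$gene, c("g1", "g2", "g3"))     # score desc, symbol asc
  expect_equal(as.numeric(tab$score),
               unname(rowSums(tab[c("kegg", "bp", "ko", "glad4u", "geo")])))
})

test_that("mismatched channel universes are rejected with the missing genes", {
  genes <- c("g1", "g2")
  short <- c(g1 = 1L)
  expect_error(aggregate_scores(short, short, short, short, short, genes),
               "g2", class = "df_config_error")
})

test_that("aggregation is permutation-invariant and risk counts shrink with score_min", {
  genes <- sprintf("g%02d", 1:40)
  chans <- with_seed(31, lapply(1:5, function(i)
    stats::setNames(rbinom(40, 1, 0.4), genes)))
  t1 <- do.call(aggregate_scores, c(chans, list(universe = genes)))
  perm <- with_seed(32, sample(40))
  chans_p <- lapply(chans, function(v) v[perm])
  t2 <- do.call(aggregate_scores, c(chans_p, list(universe = genes)))
  expect_identical(t1, t2)
  counts <- vapply(0:6, function(m) length(select_risk_genes(t1, m)), numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_equal(counts[1], 40)                      # score_min = 0: everything
  expect_length(select_risk_genes(t1, 6), 0L)      # unreachable score
  expect_equal(sum(table(t1$score)), 40)           # histogram sums to universe
})

test_that("channel correlation is the phi coefficient with NA for constants", {
  genes <- sprintf("g%d", 1:4)
  x <- stats::setNames(c(1L, 1L, 0L, 0L), genes)
  y <- stats::setNames(c(1L, 0L, 1L, 0L), genes)
  tab <- aggregate_scores(x, x, y, y, y, genes)
  cc <- channel_correlation(tab)
  expect_equal(cc["kegg", "bp"], 1)
  expect_equal(cc["kegg", "ko"], 0)        # hand-computed phi
  expect_equal(diag(cc), rep(1, 5), ignore_attr = TRUE)
  expect_equal(cc, t(cc))
  const <- stats::setNames(rep(1L, 4), genes)
  tab2 <- aggregate_scores(x, y, const, y, x, genes)
  expect_warning(cc2 <- channel_correlation(tab2), "constant")
  expect_true(all(is.na(cc2["ko", -3])))
  expect_equal(cc2["ko", "ko"], 1)
})

test_that("venn counts: exclusives, all-five intersection, partition identity", {
  genes <- c(sprintf("top%02d", 1:12), "only_kegg", "mixed")
  all5 <- ind_vec(genes, genes[1:12])
  kegg <- all5; kegg[["only_kegg"]] <- 1L; kegg[["mixed"]] <- 1L
  bp <- all5; bp[["mixed"]] <- 1L
  tab <- aggregate_scores(kegg, bp, all5, all5, all5, genes)
  vc <- venn_counts(tab)
  expect_equal(vc$intersection, 12L)
  expect_equal(vc$exclusive[["kegg"]], 1L)
  expect_equal(sum(vc$exclusive[-1]), 0L)

  # partition identity on a random table, vs brute-force pattern counting
  g2 <- sprintf("r%03d", 1:150)
  chans <- with_seed(33, lapply(1:5, function(i)
    stats::setNames(rbinom(150, 1, 0.3), g2)))
  t2 <- do.call(aggregate_scores, c(chans, list(universe = g2)))
  m <- as.matrix(t2[c("kegg", "bp", "ko", "glad4u", "geo")])
  patterns <- table(apply(m, 1, paste, collapse = ""))
  nonzero <- patterns[names(patterns) != "00000"]
  expect_equal(sum(nonzero), sum(t2$score >= 1))
  expect_equal(unname(patterns["11111"]), venn_counts(t2)$intersection)
  excl_codes <- diag(5)
  vc2 <- venn_counts(t2)
  for (i in 1:5) {
    code <- paste(excl_codes[i, ], collapse = "")
    want <- if (code %in% names(patterns)) as.integer(patterns[[code]]) else 0L
    expect_equal(vc2$exclusive[[i]], want)
  }
})
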