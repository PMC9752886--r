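named_perm <- function(ranks) {
  stats::setNames(ranks, sprintf("g%02d", seq_along(ranks)))
}

test_that("signature extraction takes the rank extremes", {
  p <- named_perm(1:10)
  sig <- build_signature(p, q = 2)
  expect_equal(sig$up_set, c("g01", "g02"))
  expect_equal(sig$down_set, c("g09", "g10"))
  half <- build_signature(p, q = 5)
  expect_setequal(c(half$up_set, half$down_set), names(p))   # partition
  expect_error(build_signature(p, q = 6), "smaller signature",
               class = "df_config_error")
})

test_that("ks_enrichment reproduces the hand-evaluated running sums", {
  p <- named_perm(1:10)
  expect_equal(ks_enrichment(c("g01", "g02", "g03"), p), 0.7)
  expect_equal(ks_enrichment(c("g08", "g09", "g10"), p), -0.8)
  expect_equal(ks_enrichment(names(p), p), -1 / 10)   # degenerate full set
  expect_error(ks_enrichment(character(), p), "empty",
               class = "df_config_error")
  expect_error(ks_enrichment("nope", p), "absent", class = "df_config_error")
})

test_that("ks_enrichment equals the step-function oracle exhaustively and at random", {
  for (N in c(4, 8, 12)) {
    p <- named_perm(seq_len(N))
    for (n in 1:min(4, N)) {
      combos <- utils::combn(N, n)
      for (j in seq_len(ncol(combos))) {
        genes <- names(p)[combos[, j]]
        expect_equal(ks_enrichment(genes, p), oracle_ks(combos[, j], N),
                     tolerance = 1e-12)
      }
    }
  }
  with_seed(51, {
    for (rep in 1:200) {
      N <- sample(50:400, 1)
      perm <- named_perm(sample.int(N))
      n <- sample(2:30, 1)
      genes <- sample(names(perm), n)
      expect_equal(ks_enrichment(genes, perm),
                   oracle_ks(sort(unname(perm[genes])), N),
                   tolerance = 1e-12)
    }
  })
})

test_that("reversing a ranking negates es (up to the tie convention)", {
  # Under reversal the two running-sum tails swap with an exact 1/N offset:
  # a(rev) = b - 1/N, b(rev) = a + 1/N. Strict antisymmetry therefore holds
  # to within 1/N whenever the dominant tail is unambiguous (|a - b| >
  # 2/N); when a ~ b the 'else -b' tie rule picks the negative branch on
  # both orientations and antisymmetry genuinely fails.
  checked <- 0L
  with_seed(52, {
    for (rep in 1:200) {
      N <- sample(20:200, 1)
      perm <- named_perm(sample.int(N))
      rev_perm <- stats::setNames(N + 1L - perm, names(perm))
      genes <- sample(names(perm), sample(2:15, 1))
      r <- sort(unname(perm[genes])); n <- length(r); j <- seq_len(n)
      a <- max(j / n - r / N); b <- max(r / N - (j - 1) / n)
      if (abs(a - b) > 2 / N + 1e-9) {   # margin: |a-b| = 2/N is itself a tie
        es <- ks_enrichment(genes, perm)
        es_rev <- ks_enrichment(genes, rev_perm)
        expect_lte(abs(es + es_rev), 1 / N + 1e-12)
        checked <- checked + 1L
      }
    }
  })
  expect_gte(checked, 50L)
})

test_that("combined score applies the discordance and zero-sign rules", {
  expect_equal(combined_score(0.7, -0.8), 0.75)
  expect_equal(combined_score(0.5, 0.4), 0)        # concordant tails
  expect_equal(combined_score(-0.3, -0.6), 0)
  expect_equal(combined_score(0, -0.4), 0.2)       # zero is discordant
  expect_equal(combined_score(0.4, 0), 0.2)
  expect_equal(combined_score(0, 0), 0)
  expect_error(combined_score(1.2, 0), class = "df_config_error")
})

test_that("tau normalization counts strictly smaller background magnitudes", {
  bg <- c(0.1, 0.2, 0.3, 0.4)
  expect_equal(tau_normalize(0.35, bg), 75)
  expect_equal(tau_normalize(-0.35, bg), -75)
  expect_equal(tau_normalize(0, bg), 0)
  expect_equal(tau_normalize(0.99, bg), 100)       # above every background
  expect_error(tau_normalize(0.5, numeric()), class = "df_config_error")
})

test_that("self-similarity: the reference attains |tau| = 100 in its background", {
  cfg <- small_sim(seed = 53)
  # no correlated compounds: ties at the maximum w would otherwise drag
  # the strict percentile below 100
  rp <- gen_rank_profiles(cfg, compounds = sprintf("CP%03d", 1:40),
                          correlated = character())
  sig <- build_signature(extract_profile(rp, "gemcitabine", "MCF7"), q = 80)
  res <- connectivity_scores(rp, sig, "MCF7")
  ref <- res[res$compound == "gemcitabine", ]
  expect_equal(ref$w, max(res$w))
  expect_equal(abs(ref$tau), 100)
  expect_true(all(res$tau >= -100 & res$tau <= 100))
})

test_that("rank_and_filter applies positivity then the strict tau cutoff", {
  fx <- pc_fixture()
  results <- data.frame(compound = c(fx$candidates$drug, "borderline", "neg"),
                        w = c(fx$candidates$cmap_score / 100, 0.5, -0.9),
                        tau = c(fx$candidates$cmap_score, 79.9, 95),
                        stringsAsFactors = FALSE)
  kept <- rank_and_filter(results, threshold = 80)
  expect_equal(nrow(kept), 13L)                    # 79.9 and negative excluded
  expect_equal(kept$compound[1], "Clomifene")
  expect_equal(kept$tau[1], 97.84)
  expect_equal(min(kept$tau), 80.4)
  expect_equal(attr(kept, "n_positive"), 14L)
  # >= variant admits an exact-80 tie
  results$tau[results$compound == "borderline"] <- 80
  expect_equal(nrow(rank_and_filter(results, 80, ge = TRUE)), 14L)
  expect_false(all(diff(kept$tau) > 0))            # sorted descending
  expect_true(all(diff(kept$tau) <= 0))
})

test_that("null profiles rarely reach the tau threshold; planted ones clear it", {
  cfg <- small_sim(seed = 54, n_profiled_genes = 400L)
  compounds <- sprintf("CP%03d", 1:73)
  corr <- compounds[1:13]
  rp <- gen_rank_profiles(cfg, compounds = compounds, correlated = corr)
  sig <- build_signature(extract_profile(rp, "gemcitabine", "MCF7"), q = 100)
  res <- connectivity_scores(rp, sig, "MCF7")
  nulls <- setdiff(compounds, corr)
  expect_gte(mean(abs(res$tau[res$compound %in% nulls]) < 80), 0.95)
  expect_gte(mean(res$tau[res$compound %in% corr] >= 80), 0.9)
})
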