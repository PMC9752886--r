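# Independent reference implementations used as oracles. Each one takes a
# different computational route from the package code it checks.

# Exact hypergeometric upper tail by direct enumeration of the tail sum in
# plain (non-log) arithmetic; exact for M <= 25 since every choose() value
# fits an integer-valued double.
oracle_hyper_tail <- function(x, K, M, n) {
  if (x == 0) return(1)
  k <- seq.int(x, min(K, n))
  sum(choose(K, k) * choose(M - K, n - k)) / choose(M, n)
}

# Brute-force BH step-up straight from the definition:
# adj(i) = min over j with p(j) >= p(i) of m * p(j) / rank(j), capped at 1.
# Assumes distinct p-values (the random test vectors are distinct a.s.).
oracle_bh <- function(p) {
  m <- length(p)
  r <- rank(p)
  vapply(seq_len(m), function(i) {
    j <- which(p >= p[i])
    min(1, m * p[j] / r[j])
  }, numeric(1))
}

# KS enrichment via full evaluation of both running-sum step functions at
# every position t = 1..N (not just at member ranks).
oracle_ks <- function(member_ranks, N) {
  n <- length(member_ranks)
  Ft <- cumsum(seq_len(N) %in% member_ranks) / n   # F(t), t = 1..N
  a <- max(Ft - seq_len(N) / N)
  Fprev <- c(0, Ft[-N])                            # F(t - 1)
  b <- max(seq_len(N) / N - Fprev)
  if (a > b) a else -b
}

# Random two-group dataset for DEG tests.
make_dataset <- function(n_genes = 50, n1 = 4, n2 = 4, effect = 0,
                         up = character(), sd = 1, seed = 42) {
  with_seed(seed, {
    v <- matrix(rnorm(n_genes * (n1 + n2), mean = 8, sd = sd),
                n_genes, n1 + n2)
    rownames(v) <- sprintf("G%03d", seq_len(n_genes))
    colnames(v) <- c(sprintf("N%02d", seq_len(n1)),
                     sprintf("T%02d", seq_len(n2)))
    if (length(up)) {
      v[up, n1 + seq_len(n2)] <- v[up, n1 + seq_len(n2)] + effect
    }
    expr_dataset(v, rep(c("normal", "tumor"), c(n1, n2)), "test")
  })
}

# Tiny YAML override file for CLI tests.
write_tiny_yaml <- function() {
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(
    list(sim = list(n_genes = 150L, n_true_risk = 50L,
                    n_sets_per_channel = 8L, set_size_range = c(10L, 25L),
                    background_multiplier = 4L,
                    datasets = list(list(name = "d1", n_normal = 4L,
                                         n_tumor = 4L)),
                    n_profiled_genes = 300L, correlated_compounds = 5L)),
    path)
  path
}

# Small-but-complete sim config for fast pipeline-level tests; any
# sim_config() argument can be overridden.
small_sim <- function(seed = 1, ...) {
  defaults <- list(seed = seed, n_genes = 200L, n_true_risk = 70L,
                   n_sets_per_channel = 15L, set_size_range = c(15L, 40L),
                   background_multiplier = 5L,
                   datasets = data.frame(name = c("dsA", "dsB"),
                                         n_normal = c(8L, 6L),
                                         n_tumor = c(8L, 6L),
                                         stringsAsFactors = FALSE),
                   n_profiled_genes = 400L, correlated_compounds = 10L)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}
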