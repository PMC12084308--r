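# a small two-community network with a tunable doctor-man vs doctor-woman
# asymmetry, for the bias-probe checks
bias_fixture_graph <- function(w_consistent, w_inconsistent) {
  ug(c("doctor", "doctor", "nurse", "nurse", "man", "hospital", "hospital"),
     c("man", "woman", "woman", "man", "woman", "doctor", "nurse"),
     c(w_consistent, w_inconsistent, w_consistent, w_inconsistent, 2, 3, 3))
}

test_that("rank-biserial effect size hits the extremes and is antisymmetric", {
  x <- c(1, 2, 3, 4, 5, 6)
  y <- x + c(2, 1, 3, 2, 5, 4)
  all_neg <- wilcoxon_paired(x, y)
  expect_equal(all_neg$effect_size, -1)
  all_pos <- wilcoxon_paired(y, x)
  expect_equal(all_pos$effect_size, 1)
  # antisymmetry on mixed-sign data
  a <- c(3.2, 1.1, -0.4, 2.2, -5, 0.7, 1.9)
  b <- c(1.0, 2.3, 0.1, -2, 3, 0.2, 0.4)
  expect_equal(wilcoxon_paired(a, b)$effect_size,
               -wilcoxon_paired(b, a)$effect_size)
})

test_that("differences symmetric about zero give effect size zero", {
  x <- c(1, 2, 3, 4, 5, 6)
  y <- x + c(-3, 3, -2, 2, -1, 1)   # mirrored ranks cancel exactly
  expect_equal(wilcoxon_paired(x, y)$effect_size, 0)
})

test_that("all-zero differences short-circuit; tiny samples are refused", {
  z <- wilcoxon_paired(c(1, 2, 3), c(1, 2, 3))
  expect_equal(z$effect_size, 0)
  expect_equal(z$p_value, 1)
  expect_equal(z$n_used, 0)
  expect_error(wilcoxon_paired(c(1, 2), c(0, 0)), "at least 5")
})

test_that("the exact p-value matches enumeration over all sign assignments", {
  d <- c(1.5, -2.3, 3.1, 4.7, -0.6, 5.2, 2.9, -3.8)
  res <- wilcoxon_paired(d, rep(0, 8))
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  expect_equal(res$statistic, v)
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), 8)))
  Vs <- apply(signs, 1, function(s) sum(r[s > 0]))
  p_oracle <- min(1, 2 * min(mean(Vs <= v), mean(Vs >= v)))
  expect_equal(res$p_value, p_oracle, tolerance = 1e-12)
})

test_that("Spearman correlation handles monotone and tied data", {
  a <- 1:6
  expect_equal(spearman_rho(a, rev(a))$rho, -1)
  expect_equal(spearman_rho(a, a * 2 + 1)$rho, 1)
  # ties: compare to Pearson on hand-computed average ranks
  x <- c(1, 2, 2, 3, 4, 4)
  y <- c(2, 1, 3, 3, 5, 4)
  avg_rank <- function(v) {
    vapply(v, function(vi) sum(v < vi) + (1 + sum(v == vi)) / 2, numeric(1))
  }
  expect_equal(spearman_rho(x, y)$rho,
               stats::cor(avg_rank(x), avg_rank(y)), tolerance = 1e-12)
  expect_error(spearman_rho(rep(1, 5), 1:5), "constant")
  expect_error(spearman_rho(1:2, 2:1), "at least 3")
})

test_that("pairs with absent nodes are excluded with bookkeeping intact", {
  g <- ug(c("a", "b", "c", "d"), c("b", "c", "d", "a"), c(2, 2, 2, 2))
  pairs <- data.frame(
    target = c("a", "a", "ghost"),
    related_prime = c("b", "b", "b"),
    unrelated_prime = c("c", "missing", "c"),
    stringsAsFactors = FALSE)
  out <- run_priming(g, pairs, spread_params(time_steps = 2))
  excl <- attr(out, "exclusions")
  expect_equal(nrow(out) / 2 + nrow(excl), nrow(pairs))
  expect_equal(nrow(excl), 2)
  expect_match(excl$reason[1], "missing")
  expect_match(excl$reason[2], "ghost")
  expect_error(run_priming(g, pairs[3, , drop = FALSE]), "no usable")
})

test_that("identical related and unrelated primes yield equal activations", {
  g <- ug(c("a", "b", "c", "d", "e"), c("b", "c", "d", "e", "a"),
          c(2, 3, 2, 3, 2))
  pairs <- data.frame(target = c("a", "b", "c"),
                      related_prime = c("c", "d", "e"),
                      unrelated_prime = c("c", "d", "e"),
                      stringsAsFactors = FALSE)
  out <- run_priming(g, pairs, spread_params(time_steps = 2))
  rel <- out$activation[out$prime_type == "related"]
  unr <- out$activation[out$prime_type == "unrelated"]
  expect_equal(rel, unr)
})

test_that("planted related pairs strictly out-activate unrelated ones at zero noise", {
  cfg <- synth_config(n_cues = 60L, vocabulary_size = 180L,
                      n_communities = 4L, repetitions = 40L,
                      noise = zero_noise(), n_probe_pairs = 15L,
                      rt_model = list(intercept = 1, slope = 3, noise_sd = 0),
                      seed = 11L)
  gen <- generate_norms(cfg)
  net <- filter_network(fold_undirected(build_directed(gen$truth$canonical)),
                        gen$truth$lexicon)
  pairs <- generate_probe_pairs(cfg, gen$truth)
  out <- run_priming(net, pairs)
  rel <- out$activation[out$prime_type == "related"]
  unr <- out$activation[out$prime_type == "unrelated"]
  expect_true(all(rel > unr))
  st <- priming_report(out)
  expect_equal(st$effect_size, 1)
  expect_lt(st$spearman_rho, -0.3)
  expect_lt(st$p_value, 0.001)
})

test_that("a symmetric network shows no stereotype bias; a planted one does", {
  probes <- data.frame(target = c("doctor", "nurse"),
                       consistent_prime = c("man", "woman"),
                       inconsistent_prime = c("woman", "man"),
                       stringsAsFactors = FALSE)
  sym <- bias_fixture_graph(4, 4)
  # symmetric weights: both probes give identical activations, so the
  # paired test short-circuits to effect size 0 (too few nonzero diffs)
  probe_pairs <- data.frame(target = probes$target,
                            related_prime = probes$consistent_prime,
                            unrelated_prime = probes$inconsistent_prime,
                            stringsAsFactors = FALSE)
  out_sym <- run_priming(sym, probe_pairs, spread_params(time_steps = 4))
  d <- out_sym$activation[out_sym$prime_type == "related"] -
    out_sym$activation[out_sym$prime_type == "unrelated"]
  expect_equal(max(abs(d)), 0, tolerance = 1e-12)

  # planted doctor-man >> doctor-woman: consistent primes win, and five
  # probe replicates clear the minimum sample size
  biased <- bias_fixture_graph(9, 1)
  probes5 <- probes[rep(1:2, length.out = 5), ]
  st <- bias_probe(biased, probes5, spread_params(time_steps = 4))
  expect_gt(st$effect_size, 0.9)

  expect_error(bias_probe(biased, probes[1, , drop = FALSE],
                          spread_params(time_steps = 4)), "at least 5")
})

test_that("bias probes split by label analyze each group separately", {
  biased <- bias_fixture_graph(9, 1)
  probes <- data.frame(
    target = rep(c("doctor", "nurse"), each = 5),
    consistent_prime = rep(c("man", "woman"), each = 5),
    inconsistent_prime = rep(c("woman", "man"), each = 5),
    label = rep(c("gender_a", "gender_b"), each = 5),
    stringsAsFactors = FALSE)
  res <- bias_probe(biased, probes, spread_params(time_steps = 4))
  expect_named(res, c("gender_a", "gender_b"))
  expect_s3_class(res$gender_a, "priming_stats")
})

test_that("recovered effect-size sign always matches the planted RT direction", {
  for (seed in c(51L, 52L, 53L)) {
    cfg <- synth_config(n_cues = 30L, vocabulary_size = 90L,
                        n_communities = 3L, repetitions = 20L,
                        noise = zero_noise(), n_probe_pairs = 10L,
                        rt_model = list(intercept = 1, slope = 3,
                                        noise_sd = 0.05),
                        seed = seed)
    gen <- generate_norms(cfg)
    pairs <- generate_probe_pairs(cfg, gen$truth)
    # gap (slope x relatedness) dominates the small RT noise
    w <- wilcoxon_paired(pairs$rt_related, pairs$rt_unrelated)
    expect_lt(w$effect_size, 0)
  }
})
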