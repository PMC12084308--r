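test_that("zero noise yields the canonical table and an empty ledger", {
  cfg <- synth_config(n_cues = 12L, vocabulary_size = 36L, n_communities = 3L,
                      repetitions = 6L, noise = zero_noise(), seed = 61L)
  gen <- generate_norms(cfg)
  expect_norms_equal(gen$norms, gen$truth$canonical)
  expect_equal(nrow(gen$truth$ledger), 0)
})

test_that("canonical rows hold three distinct within-vocabulary non-echo responses", {
  cfg <- synth_config(n_cues = 15L, vocabulary_size = 45L, n_communities = 3L,
                      repetitions = 10L, seed = 62L)
  canon <- generate_norms(cfg)$truth$canonical
  expect_equal(nrow(canon), 15 * 10)
  expect_true(all(canon$R1 != canon$R2 & canon$R1 != canon$R3 &
                    canon$R2 != canon$R3))
  expect_true(all(canon$R1 != canon$cue & canon$R2 != canon$cue &
                    canon$R3 != canon$cue))
  lex <- generate_norms(cfg)$truth$lexicon
  expect_true(all(unlist(as.data.frame(canon)[c("R1", "R2", "R3")]) %in% lex))
})

test_that("a blank rate of one blanks every response", {
  cfg <- synth_config(n_cues = 5L, vocabulary_size = 15L, n_communities = 3L,
                      repetitions = 4L,
                      noise = list(misspelling = 0, leading_article = 0,
                                   blank = 1, nonsense_token = 0,
                                   pluralization = 0),
                      seed = 63L)
  gen <- generate_norms(cfg)
  s <- dataset_stats(gen$norms)
  expect_equal(s$pct_missing, 100)
  expect_equal(s$total_responses, 0)
})

test_that("corruption counts match the ledger and the binomial rate", {
  cfg <- synth_config(n_cues = 20L, vocabulary_size = 60L, n_communities = 3L,
                      repetitions = 20L,
                      noise = list(misspelling = 0.1, leading_article = 0,
                                   blank = 0, nonsense_token = 0,
                                   pluralization = 0),
                      seed = 64L)
  gen <- generate_norms(cfg)
  led <- gen$truth$ledger
  # every ledger entry records a real cell change, individually invertible
  df_noisy <- as.data.frame(gen$norms)
  df_canon <- as.data.frame(gen$truth$canonical)
  for (i in seq_len(nrow(led))) {
    expect_identical(df_noisy[led$row[i], led$field[i]], led$corrupted[i])
    expect_identical(df_canon[led$row[i], led$field[i]], led$original[i])
  }
  changed <- sum(df_noisy$cue != df_canon$cue) +
    sum(unlist(df_noisy[c("R1", "R2", "R3")]) !=
          unlist(df_canon[c("R1", "R2", "R3")]))
  expect_equal(changed, nrow(led))
  # 99% binomial band around rate x cells (4 cells per row incl. the cue)
  cells <- nrow(df_noisy) * 4
  band <- stats::qbinom(c(0.005, 0.995), cells, 0.1)
  expect_gte(nrow(led), band[1])
  expect_lte(nrow(led), band[2])
})

test_that("generation is deterministic in the seed", {
  cfg <- synth_config(n_cues = 10L, vocabulary_size = 30L, n_communities = 3L,
                      repetitions = 5L, seed = 65L)
  a <- generate_norms(cfg)
  b <- generate_norms(cfg)
  expect_norms_equal(a$norms, b$norms)
  expect_identical(a$truth$ledger, b$truth$ledger)
  pa <- generate_probe_pairs(cfg, a$truth)
  pb <- generate_probe_pairs(cfg, b$truth)
  expect_identical(as.data.frame(pa), as.data.frame(pb))
})

test_that("network weights from noiseless norms equal independent tallies", {
  cfg <- synth_config(n_cues = 10L, vocabulary_size = 30L, n_communities = 3L,
                      repetitions = 8L, noise = zero_noise(), seed = 66L)
  canon <- generate_norms(cfg)$truth$canonical
  g <- build_directed(canon)
  df <- as.data.frame(canon)
  long <- data.frame(from = rep(df$cue, 3),
                     to = c(df$R1, df$R2, df$R3), n = 1L,
                     stringsAsFactors = FALSE)
  tally <- stats::aggregate(n ~ from + to, data = long, FUN = sum)
  expect_equal(igraph::ecount(g), nrow(tally))
  for (i in sample(nrow(tally), 20)) {
    eid <- igraph::get_edge_ids(g, c(tally$from[i], tally$to[i]))
    expect_equal(igraph::E(g)$weight[eid], tally$n[i])
  }
})

test_that("noiseless probe RTs order related below unrelated; null slope kills it", {
  base <- function(slope, sd, seed) {
    synth_config(n_cues = 20L, vocabulary_size = 60L, n_communities = 4L,
                 repetitions = 15L, noise = zero_noise(), n_probe_pairs = 12L,
                 rt_model = list(intercept = 1, slope = slope, noise_sd = sd),
                 seed = seed)
  }
  cfg <- base(3, 0, 67L)
  gen <- generate_norms(cfg)
  pairs <- generate_probe_pairs(cfg, gen$truth)
  expect_true(all(pairs$rt_related < pairs$rt_unrelated))
  expect_true(all(pairs$relatedness_related > pairs$relatedness_unrelated))
  expect_true(all(pairs$related_prime != pairs$unrelated_prime))

  # slope 0: RTs carry no relatedness signal; mean effect over seeds ~ 0
  es <- vapply(70:79, function(s) {
    cfg0 <- base(0, 0.3, as.integer(s))
    gen0 <- generate_norms(cfg0)
    p0 <- generate_probe_pairs(cfg0, gen0$truth)
    wilcoxon_paired(p0$rt_related, p0$rt_unrelated)$effect_size
  }, numeric(1))
  expect_lt(abs(mean(es)), 0.25)
})

test_that("unrelated-prime sampling needs at least two communities", {
  cfg <- synth_config(n_cues = 6L, vocabulary_size = 12L, n_communities = 1L,
                      repetitions = 4L, seed = 68L)
  gen <- generate_norms(cfg)
  expect_error(generate_probe_pairs(cfg, gen$truth), "communities")
})

test_that("RT-based priming strengthens monotonically with the planted gap", {
  es_at_slope <- function(slope) {
    cfg <- synth_config(n_cues = 25L, vocabulary_size = 75L,
                        n_communities = 3L, repetitions = 15L,
                        noise = zero_noise(), n_probe_pairs = 15L,
                        rt_model = list(intercept = 1, slope = slope,
                                        noise_sd = 0.15),
                        seed = 80L)
    gen <- generate_norms(cfg)
    pairs <- generate_probe_pairs(cfg, gen$truth)
    wilcoxon_paired(pairs$rt_related, pairs$rt_unrelated)$effect_size
  }
  es <- vapply(c(0.15, 0.75, 3), es_at_slope, numeric(1))
  expect_true(all(diff(es) <= 0))  # increasingly negative
  expect_equal(es[3], -1)          # gap >> noise saturates the effect
})

test_that("the tiny fixture bundle is complete and byte-stable", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  reference_pipeline_fixture("tiny", d1)
  reference_pipeline_fixture("tiny", d2)
  files <- c("norms.csv", "canonical.csv", "spelling.txt", "cues.txt",
             "lexicon.txt", "pairs.csv", "config.json", "expected.json")
  expect_true(all(file.exists(file.path(d1, files))))
  for (f in files) {
    expect_identical(readBin(file.path(d1, f), "raw", file.size(file.path(d1, f))),
                     readBin(file.path(d2, f), "raw", file.size(file.path(d2, f))),
                     label = f)
  }
})

test_that("invalid synthetic configurations are rejected", {
  expect_error(synth_config(n_cues = 50, vocabulary_size = 20), "n_cues")
  expect_error(synth_config(noise = list(misspelling = 0.9,
                                         leading_article = 0.9, blank = 0,
                                         nonsense_token = 0,
                                         pluralization = 0)), "noise rates")
  expect_error(synth_config(within_community_response_prob = 1.2), "\\[0, 1\\]")
  expect_error(synth_config(response_distribution_exponent = 0), "> 0")
})
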