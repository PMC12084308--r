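#' Synthetic norms configuration
#'
#' Parameters of the synthetic free-association generator. The generator
#' emulates a cue/three-response norms table with 100 repetitions per cue:
#' a vocabulary partitioned into communities, responses drawn from a
#' heavy-tailed (Zipf-like) distribution concentrated in the cue's
#' community, and realistic noise (misspellings, leading articles, blanks,
#' nonsense tokens, spurious pluralization) applied on top of a retained
#' canonical table. Probe prime-target pairs carry a planted relatedness,
#' and reaction times follow `rt = intercept - slope * relatedness + noise`
#' — the simplest monotone-negative model linking relatedness to z-scored
#' RTs.
#'
#' @param n_cues number of cue words (must not exceed `vocabulary_size`).
#' @param vocabulary_size total number of canonical word types.
#' @param n_communities number of communities partitioning the vocabulary.
#' @param within_community_response_prob probability that a response is
#'   drawn from the cue's own community (default 0.9).
#' @param response_distribution_exponent Zipf exponent (> 0) of the
#'   within-community response distribution (default 1).
#' @param repetitions response sets per cue (default 100, the norms'
#'   design value).
#' @param noise named list of per-cell corruption rates: `misspelling`,
#'   `leading_article`, `blank`, `nonsense_token`, `pluralization`
#'   (all fractions; they must sum to at most 1).
#' @param n_probe_pairs number of planted prime-target probe pairs
#'   (default 50, the size of the LDT subset used for validation).
#' @param rt_model list `intercept`, `slope` (> 0), `noise_sd` for the
#'   reaction-time model.
#' @param seed integer RNG seed; everything is reproducible from it.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n_cues = 500L,
                         vocabulary_size = 1500L,
                         n_communities = 10L,
                         within_community_response_prob = 0.9,
                         response_distribution_exponent = 1,
                         repetitions = 100L,
                         noise = list(misspelling = 0.02,
                                      leading_article = 0.02,
                                      blank = 0.05,
                                      nonsense_token = 0.01,
                                      pluralization = 0.02),
                         n_probe_pairs = 50L,
                         rt_model = list(intercept = 1, slope = 3,
                                         noise_sd = 0.2),
                         seed = 2026L) {
  n_cues <- as.integer(n_cues)
  vocabulary_size <- as.integer(vocabulary_size)
  n_communities <- as.integer(n_communities)
  if (n_cues > vocabulary_size) stop("n_cues must not exceed vocabulary_size")
  if (n_communities < 1 || n_communities > vocabulary_size) {
    stop("n_communities must be between 1 and vocabulary_size")
  }
  rates <- unlist(noise[c("misspelling", "leading_article", "blank",
                          "nonsense_token", "pluralization")])
  if (anyNA(rates)) stop("noise must name all five corruption rates")
  if (any(rates < 0 | rates > 1) || sum(rates) > 1) {
    stop("noise rates must be fractions in [0, 1] summing to at most 1")
  }
  p <- within_community_response_prob
  if (p < 0 || p > 1) stop("within_community_response_prob must be in [0, 1]")
  if (response_distribution_exponent <= 0) {
    stop("response_distribution_exponent must be > 0")
  }
  if (rt_model$slope < 0) stop("rt_model slope must be nonnegative")
  structure(list(
    n_cues = n_cues, vocabulary_size = vocabulary_size,
    n_communities = n_communities,
    within_community_response_prob = p,
    response_distribution_exponent = response_distribution_exponent,
    repetitions = as.integer(repetitions),
    noise = as.list(rates),
    n_probe_pairs = as.integer(n_probe_pairs),
    rt_model = rt_model,
    seed = as.integer(seed)
  ), class = "synth_config")
}

# Synthetic vocabulary: community k gets words "q<k>w<i>". Tokens start
# with a letter, end with a digit (never "s"), and contain no spaces, so
# every corruption rule below is invertible by the cleaning cascade.
.synth_vocabulary <- function(config) {
  sizes <- rep(config$vocabulary_size %/% config$n_communities,
               config$n_communities)
  extra <- config$vocabulary_size %% config$n_communities
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  words <- character(0)
  comm <- integer(0)
  for (k in seq_len(config$n_communities)) {
    words <- c(words, sprintf("q%02dw%03d", k, seq_len(sizes[k])))
    comm <- c(comm, rep(k, sizes[k]))
  }
  list(words = words, community = comm)
}

.zipf_probs <- function(n, alpha) {
  p <- seq_len(n)^(-alpha)
  p / sum(p)
}

.misspell <- function(tokens) paste0(tokens, "x")

#' Generate synthetic free-association norms
#'
#' Draws a canonical norms table (three distinct, non-echo responses per
#' row; Zipf-weighted within-community sampling) and then corrupts response
#' and cue cells according to the configured noise rates, recording every
#' corruption in an invertible ledger. Misspellings draw from an internal
#' reversible dictionary (returned as the matching spelling map), so the
#' cleaning pipeline restores the canonical table exactly when only
#' reversible noise is enabled; nonsense tokens are guaranteed absent from
#' the lexicon so the lexicon-stage network filter removes them.
#'
#' @param config a [synth_config()].
#' @return list of class `synth_norms` with elements `norms` (the corrupted
#'   [norms_table()]) and `truth` (ground truth: `canonical` table, `ledger`
#'   data frame of corruptions (`row`, `field`, `rule`, `original`,
#'   `corrupted`), `spelling_map`, `lexicon`, `cue_vocabulary`,
#'   `communities`, `config`).
#' @export
generate_norms <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  vocab <- .synth_vocabulary(config)
  K <- config$n_communities
  words_by_comm <- split(vocab$words, vocab$community)
  # cues: the top-ranked (most associable) words of each community, taken
  # round-robin so every community is represented
  per <- ceiling(config$n_cues / K)
  cue_pool <- unlist(lapply(seq_len(per), function(i) {
    vapply(words_by_comm, function(w) if (i <= length(w)) w[i] else NA_character_,
           character(1))
  }))
  cues <- cue_pool[!is.na(cue_pool)][seq_len(config$n_cues)]
  cue_comm <- vocab$community[match(cues, vocab$words)]

  reps <- config$repetitions
  alpha <- config$response_distribution_exponent
  p_within <- config$within_community_response_prob
  zipf_by_comm <- lapply(words_by_comm, function(w) .zipf_probs(length(w), alpha))

  with_seed(config$seed, {
    draw_cells <- function(cue, k, n_cells) {
      within <- stats::runif(n_cells) < p_within
      out <- character(n_cells)
      n_in <- sum(within)
      if (n_in > 0) {
        out[within] <- sample(words_by_comm[[k]], n_in, replace = TRUE,
                              prob = zipf_by_comm[[k]])
      }
      n_out <- n_cells - n_in
      if (n_out > 0) {
        ks <- if (K > 1) sample(setdiff(seq_len(K), k), n_out, replace = TRUE)
              else rep(k, n_out)
        out[!within] <- vapply(ks, function(kk) {
          sample(words_by_comm[[kk]], 1L, prob = zipf_by_comm[[kk]])
        }, character(1))
      }
      out
    }
    rows <- vector("list", length(cues))
    for (ci in seq_along(cues)) {
      cue <- cues[ci]
      k <- cue_comm[ci]
      m <- matrix(draw_cells(cue, k, reps * 3L), nrow = reps, ncol = 3L)
      bad <- which(m[, 1] == m[, 2] | m[, 1] == m[, 3] | m[, 2] == m[, 3] |
                     m[, 1] == cue | m[, 2] == cue | m[, 3] == cue)
      guard <- 0L
      while (length(bad) > 0 && guard < 1000L) {
        guard <- guard + 1L
        m[bad, ] <- matrix(draw_cells(cue, k, length(bad) * 3L),
                           ncol = 3L)
        bad <- which(m[, 1] == m[, 2] | m[, 1] == m[, 3] | m[, 2] == m[, 3] |
                       m[, 1] == cue | m[, 2] == cue | m[, 3] == cue)
      }
      rows[[ci]] <- data.frame(cue = rep(cue, reps), R1 = m[, 1],
                               R2 = m[, 2], R3 = m[, 3],
                               stringsAsFactors = FALSE)
    }
    canon_df <- do.call(rbind, rows)
    canonical <- norms_table(canon_df$cue, canon_df$R1, canon_df$R2,
                             canon_df$R3, source_label = "synthetic")

    # --- corruption ---------------------------------------------------
    rates <- unlist(config$noise)
    rules <- names(rates)
    cum <- cumsum(rates)
    corrupt_many <- function(tokens, rule) {
      switch(rule,
        misspelling = .misspell(tokens),
        leading_article = paste("the", tokens),
        blank = rep(.BLANK, length(tokens)),
        nonsense_token = sprintf("zzq%06d",
          sample.int(999999L, length(tokens), replace = TRUE)),
        pluralization = paste0(tokens, "s"))
    }
    n_rows <- nrow(canon_df)
    ledger <- list()
    noisy <- canon_df
    for (field in c("R1", "R2", "R3")) {
      u <- stats::runif(n_rows)
      # u falling in the r-th subinterval of the cumulative rates selects
      # rule r; u beyond the last boundary leaves the cell clean
      rule_idx <- findInterval(u, c(0, cum))
      for (r in seq_along(rules)) {
        idx <- which(rule_idx == r & u < cum[length(cum)])
        if (length(idx) == 0) next
        orig <- noisy[[field]][idx]
        corr <- corrupt_many(orig, rules[r])
        noisy[[field]][idx] <- corr
        ledger[[length(ledger) + 1L]] <-
          data.frame(row = idx, field = field, rule = rules[r],
                     original = orig, corrupted = corr,
                     stringsAsFactors = FALSE)
      }
    }
    # cues can be misspelled too; spelling correction re-merges row groups
    u <- stats::runif(n_rows)
    idx <- which(u < rates[["misspelling"]])
    if (length(idx) > 0) {
      orig <- noisy$cue[idx]
      corr <- .misspell(orig)
      noisy$cue[idx] <- corr
      ledger[[length(ledger) + 1L]] <-
        data.frame(row = idx, field = "cue", rule = "misspelling",
                   original = orig, corrupted = corr,
                   stringsAsFactors = FALSE)
    }
    ledger <- if (length(ledger) > 0) do.call(rbind, ledger) else
      data.frame(row = integer(0), field = character(0), rule = character(0),
                 original = character(0), corrupted = character(0),
                 stringsAsFactors = FALSE)
    if (nrow(ledger) > 0) {
      ledger <- ledger[order(ledger$row, ledger$field), ]
      rownames(ledger) <- NULL
    }

    norms <- norms_table(noisy$cue, noisy$R1, noisy$R2, noisy$R3,
                         source_label = "synthetic")
    truth <- structure(list(
      canonical = canonical,
      ledger = ledger,
      spelling_map = spelling_map(.misspell(vocab$words), vocab$words),
      lexicon = vocab$words,
      cue_vocabulary = cues,
      communities = stats::setNames(vocab$community, vocab$words),
      config = config
    ), class = "synth_truth")
    structure(list(norms = norms, truth = truth), class = "synth_norms")
  })
}

#' Cleaning configuration matching a synthetic ground truth
#'
#' Convenience: builds the [cleaning_config()] whose spelling map, cue
#' vocabulary, lexicon and repetition target invert the generator's
#' reversible corruptions.
#'
#' @param truth the `truth` element of [generate_norms()].
#' @return a [cleaning_config()].
#' @export
cleaning_config_from_truth <- function(truth) {
  cleaning_config(
    cue_vocabulary = truth$cue_vocabulary,
    spelling = truth$spelling_map,
    compound_map = build_compound_map(truth$lexicon),
    lexicon = truth$lexicon,
    target_repetitions = truth$config$repetitions,
    rng_seed = truth$config$seed
  )
}

#' Generate planted prime-target probe pairs
#'
#' For each sampled target cue, the related prime is the target's most
#' frequent within-community response in the canonical table (guaranteeing
#' a strong direct association), and the unrelated prime is a cue from a
#' different community with no direct co-association with the target.
#' Planted relatedness is the response share (count / repetitions) — zero
#' for unrelated primes — and both reaction times are drawn from the
#' configured linear model `rt = intercept - slope * relatedness + noise`.
#'
#' @param config a [synth_config()].
#' @param truth ground truth from [generate_norms()].
#' @return a `data.frame` of class `prime_target_pairs` with the canonical
#'   pair columns plus `relatedness_related` and `relatedness_unrelated`.
#' @export
generate_probe_pairs <- function(config, truth) {
  if (config$n_communities < 2) {
    stop("need at least 2 communities to sample unrelated primes")
  }
  canon <- truth$canonical
  comm <- truth$communities
  cues <- truth$cue_vocabulary
  reps <- config$repetitions
  n_pairs <- min(config$n_probe_pairs, length(cues))
  with_seed(config$seed + 1L, {
    targets <- sample(cues, n_pairs)
    resp_by_cue <- split(
      c(canon$R1, canon$R2, canon$R3),
      rep(canon$cue, 3L)
    )
    build <- function(target) {
      k <- comm[[target]]
      tally <- sort(table(resp_by_cue[[target]]), decreasing = TRUE)
      cand <- names(tally)[comm[names(tally)] == k & names(tally) != target]
      if (length(cand) == 0) cand <- names(tally)[names(tally) != target]
      related <- cand[1L]
      rel_score <- as.integer(tally[[related]]) / reps
      other_cues <- cues[comm[cues] != k]
      # prefer unrelated primes with zero direct co-association
      zero <- other_cues[!(other_cues %in% names(tally))]
      unrelated <- if (length(zero) > 0) sample(zero, 1L) else
        sample(other_cues, 1L)
      unrel_score <- if (unrelated %in% names(tally)) {
        as.integer(tally[[unrelated]]) / reps
      } else 0
      data.frame(target = target, related_prime = related,
                 unrelated_prime = unrelated,
                 relatedness_related = rel_score,
                 relatedness_unrelated = unrel_score,
                 stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, lapply(targets, build))
    rt <- config$rt_model
    out$rt_related <- rt$intercept - rt$slope * out$relatedness_related +
      stats::rnorm(n_pairs, sd = rt$noise_sd)
    out$rt_unrelated <- rt$intercept - rt$slope * out$relatedness_unrelated +
      stats::rnorm(n_pairs, sd = rt$noise_sd)
    out <- out[c("target", "related_prime", "unrelated_prime",
                 "rt_related", "rt_unrelated",
                 "relatedness_related", "relatedness_unrelated")]
    class(out) <- c("prime_target_pairs", "data.frame")
    out
  })
}

#' Write a self-contained pipeline fixture
#'
#' Generates a complete, deterministic test bundle in `dir`: corrupted
#' norms (`norms.csv`), the canonical pre-noise table (`canonical.csv`),
#' the matching spelling dictionary (`spelling.txt`), cue list
#' (`cues.txt`), lexicon (`lexicon.txt`), probe pairs (`pairs.csv`), the
#' generator configuration (`config.json`), and `expected.json` — dataset
#' and reduced-network statistics computed by running the pipeline at
#' generation time. Regeneration with the same scale is byte-identical.
#'
#' @param scale `"tiny"` (20 cues, seconds) or `"small"` (500 cues,
#'   exercises filtering and the largest-connected-component step).
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
reference_pipeline_fixture <- function(scale = c("tiny", "small"),
                                       dir = tempfile("fixture")) {
  scale <- match.arg(scale)
  config <- switch(scale,
    tiny = synth_config(n_cues = 20L, vocabulary_size = 60L,
                        n_communities = 3L, repetitions = 25L,
                        n_probe_pairs = 8L, seed = 101L),
    small = synth_config(seed = 202L))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gen <- generate_norms(config)
  pairs <- generate_probe_pairs(config, gen$truth)

  write_norms_csv(gen$norms, file.path(dir, "norms.csv"))
  write_norms_csv(gen$truth$canonical, file.path(dir, "canonical.csv"))
  sm <- gen$truth$spelling_map
  writeLines(paste(names(sm), unname(sm)), file.path(dir, "spelling.txt"))
  writeLines(gen$truth$cue_vocabulary, file.path(dir, "cues.txt"))
  writeLines(gen$truth$lexicon, file.path(dir, "lexicon.txt"))
  write_ldt_pairs(pairs, file.path(dir, "pairs.csv"))

  cfg <- unclass(config)
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  res <- preprocess_norms(gen$norms, cleaning_config_from_truth(gen$truth))
  net <- filter_network(fold_undirected(build_directed(res$table)),
                        gen$truth$lexicon)
  ns <- network_stats(net)
  expected <- list(
    dataset_stats = res$report$stats,
    reduced_network = list(n_nodes = ns$n_nodes, n_edges = ns$n_edges,
                           density = ns$density,
                           average_degree = ns$average_degree),
    diameter = net_diameter(net)
  )
  jsonlite::write_json(expected, file.path(dir, "expected.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
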