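#' Cleaning configuration
#'
#' Bundles everything the cleaning pipeline needs: the original cue
#' vocabulary (leading articles are never stripped from a response that is
#' itself a cue, e.g. "a lot"), the leading tokens to strip, the spelling
#' map, the compound-restoration map, an optional lexicon used to guard
#' lemmatization, the target repetition count per cue, and the RNG seed
#' used when a cue has more repetitions than the target and must be
#' downsampled.
#'
#' @param cue_vocabulary character vector of original cue tokens.
#' @param articles leading tokens stripped from responses (order matters
#'   only for reporting); default the articles `a`, `an`, `the` and the
#'   preposition `to`.
#' @param spelling a [spelling_map()] (may be empty).
#' @param compound_map named character vector from [build_compound_map()]
#'   (may be empty).
#' @param lexicon optional normalized lexicon (see [normalize_lexicon()]).
#'   When supplied, a singularized noun is only accepted if the singular
#'   form is a lexicon entry.
#' @param target_repetitions repetitions per cue to enforce (default 100).
#' @param rng_seed integer seed for the downsampling step.
#' @return a list of class `cleaning_config`.
#' @export
cleaning_config <- function(cue_vocabulary = character(0),
                            articles = c("a", "an", "the", "to"),
                            spelling = spelling_map(character(0), character(0)),
                            compound_map = character(0),
                            lexicon = NULL,
                            target_repetitions = 100L,
                            rng_seed = 1L) {
  target_repetitions <- as.integer(target_repetitions)
  if (is.na(target_repetitions) || target_repetitions < 1L) {
    stop("target_repetitions must be a positive integer")
  }
  if (length(compound_map) > 0) {
    if (any(grepl("[ -]", names(compound_map)))) {
      stop("compound_map keys must contain no spaces or hyphens")
    }
    if (anyDuplicated(names(compound_map))) {
      stop("compound_map must be one-to-one (duplicate keys found)")
    }
  }
  structure(list(
    cue_vocabulary = tolower(as.character(cue_vocabulary)),
    articles = tolower(as.character(articles)),
    spelling = spelling,
    compound_map = compound_map,
    lexicon = lexicon,
    target_repetitions = target_repetitions,
    rng_seed = as.integer(rng_seed)
  ), class = "cleaning_config")
}

#' Build a compound-restoration map from a lexicon
#'
#' Some responses incorrectly lack the spaces or hyphens of a multiword
#' expression (e.g. `throwout`, `checkin`). For every lexicon entry that
#' contains a space or hyphen, the map keys the entry with those characters
#' removed and restores the original form. Keys that would map to two
#' distinct entries are dropped entirely, keeping the map one-to-one.
#'
#' @param lexicon character vector of lowercase lexicon entries (multiword
#'   entries separated by spaces or hyphens).
#' @return named character vector: de-spaced/de-hyphenated key -> original
#'   multiword entry.
#' @export
build_compound_map <- function(lexicon) {
  lexicon <- unique(tolower(as.character(lexicon)))
  multi <- lexicon[grepl("[ -]", lexicon)]
  if (length(multi) == 0) return(stats::setNames(character(0), character(0)))
  keys <- gsub("[ -]", "", multi)
  # a key backed by more than one distinct multiword form is ambiguous
  tab <- split(multi, keys)
  uniq <- vapply(tab, function(v) length(unique(v)) == 1L, logical(1))
  tab <- tab[uniq]
  stats::setNames(vapply(tab, `[[`, "", 1L), names(tab))
}

# irregular English plurals handled before suffix rules
.IRREGULAR_PLURALS <- c(
  men = "man", women = "woman", children = "child", feet = "foot",
  teeth = "tooth", geese = "goose", mice = "mouse", people = "person",
  oxen = "ox", lice = "louse"
)

# Noun-only singularization of a single word. Tensed verbs are never
# reduced (no -ing/-ed handling); words not ending in a plural suffix pass
# through unchanged.
.singularize_word <- function(w, lexicon = NULL) {
  irr <- .IRREGULAR_PLURALS[w]
  if (!is.na(irr)) return(unname(irr))
  n <- nchar(w)
  cand <- NULL
  if (n >= 4 && endsWith(w, "ies")) {
    cand <- paste0(substr(w, 1, n - 3L), "y")
  } else if (n >= 4 && (endsWith(w, "xes") || endsWith(w, "ses") ||
                        endsWith(w, "zes") || endsWith(w, "ches") ||
                        endsWith(w, "shes"))) {
    cand <- substr(w, 1, n - 2L)
  } else if (n >= 4 && endsWith(w, "oes")) {
    cand <- substr(w, 1, n - 2L)
  } else if (n >= 3 && endsWith(w, "s") &&
             !endsWith(w, "ss") && !endsWith(w, "us") && !endsWith(w, "is")) {
    cand <- substr(w, 1, n - 1L)
  }
  if (is.null(cand)) return(w)
  if (!is.null(lexicon) && !(cand %in% lexicon)) return(w)
  cand
}

# Lemmatize: map plural nouns to singular, leaving everything else alone.
# Multiword tokens are lemmatized on their final word only. Irregular
# plurals (men, feet, ...) do not end in -s, so they are matched explicitly.
.lemmatize <- function(tokens, lexicon = NULL) {
  out <- tokens
  last <- sub("^.* ", "", tokens)
  todo <- which(!is_blank(tokens) &
                  (grepl("s$", last) | last %in% names(.IRREGULAR_PLURALS)))
  for (i in todo) {
    tok <- tokens[i]
    sp <- regexpr(" [^ ]*$", tok)
    if (sp > 0) {
      head_part <- substr(tok, 1, sp)          # includes trailing space
      last <- substr(tok, sp + 1L, nchar(tok))
      out[i] <- paste0(head_part, .singularize_word(last, lexicon))
    } else {
      out[i] <- .singularize_word(tok, lexicon)
    }
  }
  out
}

# Core token normalization with per-rule counting. Applies, in order:
# lowercase; strip one leading article/preposition (responses only, unless
# the whole string is an original cue, and only when the remainder is
# non-empty); underscores -> spaces; compound restoration; spelling
# correction; noun lemmatization. Blanks stay blank throughout.
.normalize_tokens <- function(x, config, is_cue = FALSE) {
  counts <- c(lowercased = 0L, articles_stripped = 0L, underscores_fixed = 0L,
              compounds_restored = 0L, spelling_corrected = 0L,
              lemmatized = 0L)
  x <- normalize_encoding(x)
  blank <- is_blank(x)
  x[blank] <- .BLANK

  y <- tolower(x)
  counts["lowercased"] <- sum(y != x & !blank)
  x <- y

  if (!is_cue && length(config$articles) > 0) {
    first <- sub(" .*$", "", x)
    rest <- sub("^[^ ]+ +", "", x)
    strip <- !blank & grepl(" ", x, fixed = TRUE) &
      first %in% config$articles & !(x %in% config$cue_vocabulary) &
      nzchar(rest)
    x[strip] <- rest[strip]
    counts["articles_stripped"] <- sum(strip)
  }

  y <- gsub("_", " ", x, fixed = TRUE)
  counts["underscores_fixed"] <- sum(y != x)
  x <- y

  if (length(config$compound_map) > 0) {
    hit <- match(x, names(config$compound_map))
    hit[blank] <- NA_integer_
    counts["compounds_restored"] <- sum(!is.na(hit))
    x[!is.na(hit)] <- unname(config$compound_map[hit[!is.na(hit)]])
  }

  y <- apply_spelling(x, config$spelling)
  y[blank] <- .BLANK
  counts["spelling_corrected"] <- sum(y != x)
  x <- y

  y <- .lemmatize(x, config$lexicon)
  counts["lemmatized"] <- sum(y != x)
  x <- y

  list(tokens = x, counts = counts)
}

#' Normalize a single token (or vector of tokens)
#'
#' Applies the full token-cleaning cascade: lowercasing, leading-article
#' stripping (responses only, never when the whole string is an original
#' cue), underscore repair, compound restoration, spelling correction, and
#' plural-noun lemmatization. Blank input stays blank; the function is
#' total.
#'
#' @param raw character vector of raw tokens.
#' @param config a [cleaning_config()].
#' @param is_cue logical; cues never have leading articles stripped.
#' @return character vector of cleaned tokens.
#' @export
normalize_token <- function(raw, config, is_cue = FALSE) {
  .normalize_tokens(raw, config, is_cue = is_cue)$tokens
}

#' Enforce an exact repetition count per cue
#'
#' Cues with fewer than `target_repetitions` rows are padded with all-blank
#' rows; cues with more are downsampled uniformly at random (without
#' replacement) under `config$rng_seed`, so repeated runs are identical.
#' Cue groups keep their first-appearance order; rows within a kept group
#' keep their input order.
#'
#' @param table a [norms_table()] whose cues are already normalized.
#' @param config a [cleaning_config()].
#' @return a [norms_table()] with exactly `target_repetitions` rows per cue,
#'   with attributes `rows_padded` and `rows_sampled_out`.
#' @export
enforce_repetitions <- function(table, config) {
  k <- config$target_repetitions
  cues <- unique(table$cue)
  idx <- split(seq_len(nrow(table)), factor(table$cue, levels = cues))
  padded <- 0L
  sampled_out <- 0L
  pieces <- with_seed(config$rng_seed, {
    lapply(cues, function(cu) {
      rows <- idx[[cu]]
      n <- length(rows)
      if (n == k) {
        table[rows, , drop = FALSE]
      } else if (n < k) {
        padded <<- padded + (k - n)
        pad <- data.frame(cue = rep(cu, k - n), R1 = .BLANK, R2 = .BLANK,
                          R3 = .BLANK, stringsAsFactors = FALSE)
        rbind(table[rows, , drop = FALSE], pad)
      } else {
        sampled_out <<- sampled_out + (n - k)
        keep <- sort(sample.int(n, k))
        table[rows[keep], , drop = FALSE]
      }
    })
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out <- norms_table(out$cue, out$R1, out$R2, out$R3,
                     source_label = attr(table, "source_label"))
  attr(out, "rows_padded") <- padded
  attr(out, "rows_sampled_out") <- sampled_out
  out
}

#' Blank echoes and within-triple duplicate responses
#'
#' A response identical to its cue is blanked; the second and third
#' occurrence of a repeated response within the same triple are blanked
#' (earlier positions win).
#'
#' @param table a normalized [norms_table()].
#' @return the table with offending responses blanked, with attributes
#'   `echoes_removed` and `within_triple_duplicates_removed`.
#' @export
drop_echo_and_duplicates <- function(table) {
  echoes <- 0L
  dups <- 0L
  r <- as.matrix(as.data.frame(table)[.response_cols])
  for (j in 1:3) {
    hit <- !is_blank(r[, j]) & r[, j] == table$cue
    echoes <- echoes + sum(hit)
    r[hit, j] <- .BLANK
  }
  for (j in 2:3) {
    dup <- !is_blank(r[, j]) & (r[, j] == r[, 1] | (j == 3 & r[, j] == r[, 2]))
    dups <- dups + sum(dup)
    r[dup, j] <- .BLANK
  }
  out <- norms_table(table$cue, r[, 1], r[, 2], r[, 3],
                     source_label = attr(table, "source_label"))
  attr(out, "echoes_removed") <- echoes
  attr(out, "within_triple_duplicates_removed") <- dups
  out
}

#' Clean a norms table end-to-end
#'
#' The full cleaning pipeline: token normalization of cues and responses
#' (see [normalize_token()]); merging of row groups whose corrected cues
#' coincide; enforcement of an exact repetition count per cue (padding with
#' blanks / seeded downsampling); removal of echo responses and
#' within-triple duplicates. A second pass over the output is a no-op.
#'
#' @param raw a [norms_table()].
#' @param config a [cleaning_config()].
#' @return a list of class `preprocess_result` with elements `table` (the
#'   cleaned [norms_table()]) and `report` (a `cleaning_report`: per-rule
#'   counters plus dataset statistics and the downsampling seed).
#' @export
preprocess_norms <- function(raw, config) {
  cue_res <- .normalize_tokens(raw$cue, config, is_cue = TRUE)
  resp_counts <- NULL
  resp <- list()
  for (col in .response_cols) {
    r <- .normalize_tokens(raw[[col]], config, is_cue = FALSE)
    resp[[col]] <- r$tokens
    resp_counts <- if (is.null(resp_counts)) r$counts else resp_counts + r$counts
  }
  counts <- cue_res$counts + resp_counts

  tab <- norms_table(cue_res$tokens, resp$R1, resp$R2, resp$R3,
                     source_label = attr(raw, "source_label"))
  tab <- enforce_repetitions(tab, config)
  rows_padded <- attr(tab, "rows_padded")
  rows_sampled_out <- attr(tab, "rows_sampled_out")
  tab <- drop_echo_and_duplicates(tab)

  report <- structure(list(
    counters = c(as.list(counts),
                 rows_padded = rows_padded,
                 rows_sampled_out = rows_sampled_out,
                 echoes_removed = attr(tab, "echoes_removed"),
                 within_triple_duplicates_removed =
                   attr(tab, "within_triple_duplicates_removed")),
    stats = dataset_stats(tab),
    target_repetitions = config$target_repetitions,
    rng_seed = config$rng_seed
  ), class = "cleaning_report")

  structure(list(table = tab, report = report), class = "preprocess_result")
}

#' Dataset statistics of a cleaned norms table
#'
#' @param table a cleaned [norms_table()].
#' @return list with `unique_cues`, `total_responses` (non-blank),
#'   `unique_responses` (distinct non-blank tokens), and `pct_missing`
#'   (percentage of blank response cells).
#' @export
dataset_stats <- function(table) {
  r <- unlist(as.data.frame(table)[.response_cols], use.names = FALSE)
  blank <- is_blank(r)
  list(
    unique_cues = length(unique(table$cue)),
    total_responses = sum(!blank),
    unique_responses = length(unique(r[!blank])),
    pct_missing = 100 * sum(blank) / length(r)
  )
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat("Cleaning report\n")
  cat("  counters:\n")
  for (nm in names(x$counters)) {
    cat(sprintf("    %-36s %d\n", nm, x$counters[[nm]]))
  }
  s <- x$stats
  cat(sprintf("  unique cues: %d | responses: %d (unique %d) | missing: %.1f%%\n",
              s$unique_cues, s$total_responses, s$unique_responses,
              s$pct_missing))
  cat(sprintf("  repetitions per cue: %d (downsampling seed %d)\n",
              x$target_repetitions, x$rng_seed))
  invisible(x)
}
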