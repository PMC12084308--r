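#' Create a norms table
#'
#' A norms table holds free-association data: one row per repetition of a
#' cue, with up to three responses (`R1`, `R2`, `R3`). Blank responses are
#' stored as [blank_token()]; cues are never blank. Row order is preserved
#' as given.
#'
#' @param cue,R1,R2,R3 character vectors of equal length. `NA` responses
#'   become the blank sentinel.
#' @param source_label free-text label for the data source (e.g. `"Humans"`,
#'   `"Mistral"`).
#' @return A `norms_table`: a `data.frame` with columns `cue`, `R1`, `R2`,
#'   `R3` and attribute `source_label`.
#' @export
norms_table <- function(cue, R1, R2, R3, source_label = "unknown") {
  cue <- normalize_encoding(cue)
  fix <- function(x) {
    x <- normalize_encoding(x)
    x[is.na(x)] <- .BLANK
    x
  }
  if (any(is_blank(cue))) stop("cue values must not be blank")
  out <- data.frame(cue = cue, R1 = fix(R1), R2 = fix(R2), R3 = fix(R3),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "source_label") <- source_label
  class(out) <- c("norms_table", "data.frame")
  out
}

.response_cols <- c("R1", "R2", "R3")

#' Read a free-association norms CSV
#'
#' Two dialects are supported. `"lwow"` expects exactly the four columns
#' `cue,R1,R2,R3`. `"swow_r100"` accepts the SWOW-EN R100 layout: any header
#' that contains `cue`, `R1`, `R2`, `R3`; participant metadata columns are
#' read and discarded, since only cue/response content is used downstream.
#' Empty or `NA` cells become the blank sentinel. Encoding is fixed to
#' UTF-8 and the Unicode minus is normalized to ASCII hyphen-minus.
#'
#' @param path path to a CSV file.
#' @param dialect `"lwow"` or `"swow_r100"`.
#' @param source_label label recorded on the result; defaults to the file
#'   base name.
#' @return A [norms_table()] with one row per input row.
#' @export
read_norms_csv <- function(path, dialect = c("lwow", "swow_r100"),
                           source_label = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character",
                        na.strings = character(0), check.names = FALSE,
                        fileEncoding = "UTF-8")
  need <- c("cue", .response_cols)
  if (dialect == "lwow") {
    if (!identical(names(df), need)) {
      stop("malformed header for dialect 'lwow': expected columns ",
           paste(need, collapse = ","), " but found ",
           paste(names(df), collapse = ","))
    }
  } else {
    if (!all(need %in% names(df))) {
      stop("malformed header for dialect 'swow_r100': expected columns ",
           paste(need, collapse = ","), " to be present; found ",
           paste(names(df), collapse = ","))
    }
    df <- df[need]
  }
  bad <- which(is_blank(df$cue))
  if (length(bad) > 0) {
    stop("unreadable row(s): blank cue at data row ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  if (is.null(source_label)) {
    source_label <- sub("\\.[^.]*$", "", basename(path))
  }
  norms_table(df$cue, df$R1, df$R2, df$R3, source_label = source_label)
}

#' Write a norms table as CSV
#'
#' Canonical RFC-4180 form: UTF-8, LF line endings, all fields quoted.
#' `read_norms_csv()` on the output reproduces the table exactly, and
#' rewriting the re-read table is byte-identical.
#'
#' @param table a [norms_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_norms_csv <- function(table, path) {
  df <- as.data.frame(table)[c("cue", .response_cols)]
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.csv(df, con, row.names = FALSE, quote = TRUE, eol = "\n",
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a spelling-correction dictionary
#'
#' Reads a two-column token mapping (misspelled or variant form -> corrected
#' form), separated by whitespace, a comma, or a tab. Keys are lowercased.
#' Chains (a key whose corrected value is itself a key) are resolved at load
#' so that applying the map twice equals applying it once.
#'
#' @param path path to the dictionary file. Blank lines and `#` comments are
#'   ignored.
#' @return A `spelling_map`: a named character vector, `names` = misspelled
#'   form, values = correction.
#' @export
read_spelling_map <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- normalize_encoding(trimws(lines))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) return(spelling_map(character(0), character(0)))
  parts <- strsplit(lines, "[,\t ]+")
  n <- lengths(parts)
  if (any(n < 2)) {
    stop("malformed spelling entry (need two columns) at line: ",
         lines[which(n < 2)[1]])
  }
  keys <- tolower(vapply(parts, `[[`, "", 1L))
  # variant form may itself contain spaces only if comma/tab separated;
  # whitespace-separated files are strictly two tokens
  vals <- vapply(parts, function(p) paste(p[-1L], collapse = " "), "")
  spelling_map(keys, vals)
}

#' Construct a spelling map
#'
#' @param keys misspelled/variant tokens (lowercased on construction).
#' @param values corrected tokens.
#' @return a named character vector of class `spelling_map`.
#' @export
spelling_map <- function(keys, values) {
  keys <- tolower(as.character(keys))
  values <- as.character(values)
  if (anyDuplicated(keys)) {
    dup <- unique(keys[duplicated(keys)])
    conflicting <- dup[vapply(dup, function(k) {
      length(unique(values[keys == k])) > 1L
    }, logical(1))]
    if (length(conflicting) > 0) {
      stop("duplicate spelling key(s) with conflicting values: ",
           paste(conflicting, collapse = ", "))
    }
    keep <- !duplicated(keys)
    keys <- keys[keep]
    values <- values[keep]
  }
  # resolve chains (key -> value that is itself a key) so that applying the
  # map twice equals applying it once
  map <- stats::setNames(values, keys)
  iter <- 0L
  repeat {
    hit <- match(unname(map), names(map))
    again <- !is.na(hit) & unname(map[hit]) != unname(map)
    if (!any(again)) break
    iter <- iter + 1L
    if (iter > length(map)) {
      stop("cyclic spelling corrections involving: ",
           paste(utils::head(names(map)[again], 5L), collapse = ", "))
    }
    map[again] <- unname(map[hit[again]])
  }
  class(map) <- c("spelling_map", class(map))
  map
}

#' Apply a spelling map to tokens
#'
#' @param tokens character vector.
#' @param map a [spelling_map()].
#' @return corrected tokens; unmapped tokens pass through unchanged.
#' @export
apply_spelling <- function(tokens, map) {
  if (length(map) == 0) return(tokens)
  hit <- match(tokens, names(map))
  tokens[!is.na(hit)] <- unname(map[hit[!is.na(hit)]])
  tokens
}

#' Read lexical-decision prime-target pairs
#'
#' Reads a CSV of priming items: each row gives a target word, a related
#' prime, an unrelated prime, and the mean z-scored reaction times for the
#' target under each prime. Because exports of LDT data differ in their
#' header names, a column mapping can be supplied.
#'
#' @param path path to the CSV file.
#' @param columns named character vector mapping the canonical names
#'   `target`, `related_prime`, `unrelated_prime`, `rt_related`,
#'   `rt_unrelated` to the column names used in the file.
#' @return a `data.frame` of class `prime_target_pairs` with the canonical
#'   columns; zero rows are allowed.
#' @export
read_ldt_pairs <- function(path,
                           columns = c(target = "target",
                                       related_prime = "related_prime",
                                       unrelated_prime = "unrelated_prime",
                                       rt_related = "rt_related",
                                       rt_unrelated = "rt_unrelated")) {
  need <- c("target", "related_prime", "unrelated_prime",
            "rt_related", "rt_unrelated")
  if (!all(need %in% names(columns))) {
    stop("columns mapping must name: ", paste(need, collapse = ", "))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        colClasses = "character",
                        na.strings = character(0), fileEncoding = "UTF-8")
  missing_cols <- setdiff(unname(columns[need]), names(df))
  if (length(missing_cols) > 0) {
    stop("LDT file is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  out <- data.frame(
    target = normalize_encoding(df[[columns[["target"]]]]),
    related_prime = normalize_encoding(df[[columns[["related_prime"]]]]),
    unrelated_prime = normalize_encoding(df[[columns[["unrelated_prime"]]]]),
    stringsAsFactors = FALSE
  )
  for (rt in c("rt_related", "rt_unrelated")) {
    raw <- normalize_encoding(df[[columns[[rt]]]])
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val) | !is.finite(val))
    if (length(bad) > 0) {
      stop("non-numeric ", rt, " at data row ",
           paste(utils::head(bad, 5L), collapse = ", "))
    }
    out[[rt]] <- val
  }
  if (nrow(out) > 0 && any(out$related_prime == out$unrelated_prime)) {
    stop("related and unrelated prime are identical at data row ",
         which(out$related_prime == out$unrelated_prime)[1])
  }
  class(out) <- c("prime_target_pairs", "data.frame")
  out
}

#' Write prime-target pairs as CSV
#'
#' @param pairs a `data.frame` with the canonical pair columns (see
#'   [read_ldt_pairs()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ldt_pairs <- function(pairs, path) {
  df <- as.data.frame(pairs)[c("target", "related_prime", "unrelated_prime",
                               "rt_related", "rt_unrelated")]
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.csv(df, con, row.names = FALSE, quote = TRUE, eol = "\n",
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a lexicon word list
#'
#' One entry per line. Entries are lowercased and the multiword separator
#' (WordNet-style underscore by default) is mapped to a space, so lexicon
#' membership tests against cleaned tokens are plain string equality.
#'
#' @param path path to the word list.
#' @param multiword_sep separator used for multiword entries in the file.
#' @return character vector of normalized lexicon entries.
#' @export
read_lexicon <- function(path, multiword_sep = "_") {
  x <- readLines(path, encoding = "UTF-8", warn = FALSE)
  normalize_lexicon(x, multiword_sep)
}

#' @rdname read_lexicon
#' @param entries character vector of raw lexicon entries.
#' @export
normalize_lexicon <- function(entries, multiword_sep = "_") {
  x <- tolower(normalize_encoding(trimws(entries)))
  x <- gsub(multiword_sep, " ", x, fixed = TRUE)
  unique(x[nzchar(x)])
}

#' The free-association generation prompt
#'
#' Returns, verbatim, the task prompt used to elicit three comma-separated
#' associations per cue from a language model (mirroring the instructions
#' given to human participants). Stored as a plain-text fixture for
#' provenance only; the package never transmits it anywhere.
#'
#' @return character scalar (multi-line).
#' @export
generation_prompt <- function() {
  path <- system.file("extdata", "generation-prompt.txt", package = "assocnet")
  paste(readLines(path, encoding = "UTF-8", warn = FALSE), collapse = "\n")
}
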