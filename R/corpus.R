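#' Read a token-per-line annotated corpus
#'
#' Parses a CoNLL-like TSV file with one token per line and 1--3 tab-separated
#' fields: `surface[ TAB lemma[ TAB tag]]`. Blank lines (sentence breaks) and
#' lines starting with `#` are skipped. Types are compared as exact strings;
#' no case folding is applied.
#'
#' @param path Path to the corpus file (UTF-8).
#' @param lexicon Optional character vector of surface forms (a dictionary);
#'   when given, each token is flagged by membership of its surface form.
#'   Use [read_lexicon()] to load one from disk.
#' @return A tibble of token records with columns `surface`, `lemma`, `tag`
#'   (`NA` when absent) and `in_lexicon` (all `TRUE` when no lexicon given).
#'   An empty file yields a zero-row tibble.
#' @examples
#' f <- tempfile()
#' writeLines(c("houses\thouse\tNNS", "ran\trun\tVBD"), f)
#' read_corpus(f)
#' @export
read_corpus <- function(path, lexicon = NULL) {
  if (!file.exists(path)) stop("corpus file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- !grepl("^\\s*$", lines) & !startsWith(lines, "#")
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) {
    return(tibble::tibble(surface = character(), lemma = character(),
                          tag = character(), in_lexicon = logical()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf > 3 | vapply(parts, function(p) length(p) == 0 || p[1] == "",
                               logical(1)))
  if (length(bad)) {
    stop("malformed corpus line ", lineno[bad[1]],
         ": expected 1-3 tab-separated fields with a non-empty surface form")
  }
  field <- function(k) vapply(parts, function(p)
    if (length(p) >= k && nzchar(p[k])) p[k] else NA_character_, character(1))
  surface <- field(1)
  tokens <- tibble::tibble(
    surface = surface,
    lemma = field(2),
    tag = field(3),
    in_lexicon = if (is.null(lexicon)) TRUE else surface %in% lexicon
  )
  tokens
}

#' Read a lexicon (dictionary) file
#'
#' One surface form per line; anything after the first tab is ignored, as are
#' blank and `#`-comment lines.
#'
#' @param path Path to the lexicon file.
#' @return Character vector of surface forms.
#' @export
read_lexicon <- function(path) {
  if (!file.exists(path)) stop("lexicon file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines) & !startsWith(lines, "#")]
  unique(sub("\t.*$", "", lines))
}

#' Naive whitespace/punctuation tokenizer (demos only)
#'
#' Splits plain text into lowercase-preserving word tokens on anything that is
#' not a letter, digit, apostrophe or hyphen. Real corpora should be tokenized
#' and lemmatized by dedicated NLP tools; this exists only so small demos can
#' run without annotations, hence the explicit flag.
#'
#' @param text Character vector of raw text.
#' @param naive Must be set to `TRUE` to acknowledge that this is not a
#'   linguistically adequate tokenizer.
#' @return A token-record tibble (lemma and tag absent).
#' @export
naive_tokenize <- function(text, naive = FALSE) {
  if (!isTRUE(naive)) {
    stop("set naive = TRUE to use the demo tokenizer; ",
         "real corpora should be pre-tokenized by NLP tools")
  }
  toks <- unlist(strsplit(text, "[^\\p{L}\\p{N}'-]+", perl = TRUE))
  toks <- toks[nzchar(toks)]
  tibble::tibble(surface = toks, lemma = NA_character_,
                 tag = NA_character_, in_lexicon = TRUE)
}

#' Count type frequencies under a unit definition
#'
#' Builds a frequency table from token records under one of four unit
#' definitions: plain word forms (`word`), lemmas (`lemma`), lemma plus main
#' part of speech -- the first character of the tag -- (`lemma_pos`), or the
#' full surface+lemma+tag triple (`word_lemma_tag`). With
#' `lexicon_filter = TRUE` only tokens whose surface form is in the dictionary
#' contribute, mirroring the restriction of counting only tokens of lemmas
#' whose word types are found in the lemmatizer's dictionary.
#'
#' @param tokens Token-record tibble from [read_corpus()] (or compatible).
#' @param unit One of `"word"`, `"lemma"`, `"lemma_pos"`, `"word_lemma_tag"`.
#' @param lexicon_filter Restrict to tokens with `in_lexicon = TRUE`?
#' @return A `freq_tbl`: tibble with columns `type` and `n`, sorted by
#'   decreasing `n` then type, carrying the unit as an attribute. Use
#'   [generics::glance()] for the summary statistics (`L`, `V`, `n_m`, `V1`,
#'   mean frequency and second moment).
#' @examples
#' toks <- tibble::tibble(surface = c("houses", "house", "housed"),
#'                        lemma = "house", tag = NA, in_lexicon = TRUE)
#' count_types(toks, "lemma")
#' @export
count_types <- function(tokens, unit = c("word", "lemma", "lemma_pos",
                                         "word_lemma_tag"),
                        lexicon_filter = FALSE) {
  unit <- match.arg(unit)
  stopifnot(is.data.frame(tokens))
  if (lexicon_filter) tokens <- dplyr::filter(tokens, .data$in_lexicon)
  if (unit != "word") {
    missing_lemma <- which(is.na(tokens$lemma))
    if (length(missing_lemma)) {
      if (unit == "lemma") {
        tokens <- tokens[-missing_lemma, , drop = FALSE]
      } else {
        stop("unit '", unit, "' requires a lemma on every record; first ",
             "offending record: ", missing_lemma[1])
      }
    }
  }
  if (unit %in% c("lemma_pos", "word_lemma_tag")) {
    missing_tag <- which(is.na(tokens$tag))
    if (length(missing_tag)) {
      stop("unit '", unit, "' requires a tag on every record; first ",
           "offending record: ", missing_tag[1])
    }
  }
  label <- switch(unit,
    word = tokens$surface,
    lemma = tokens$lemma,
    lemma_pos = paste0(tokens$lemma, "_", substr(tokens$tag, 1, 1)),
    word_lemma_tag = paste0(tokens$surface, "_", tokens$lemma, "_", tokens$tag)
  )
  if (length(label) == 0) stop("empty frequency table: no contributing tokens")
  freq_table(table_to_tibble(label), unit = unit)
}

table_to_tibble <- function(label) {
  tab <- table(label)
  tibble::tibble(type = names(tab), n = as.integer(tab))
}

#' Construct a frequency table
#'
#' @param x A data frame with columns `type` and `n` (positive integer
#'   counts), or a named integer vector.
#' @param unit Optional unit label (`"word"`, `"lemma"`, ...).
#' @return A `freq_tbl` tibble sorted by decreasing count, ties by type.
#' @export
freq_table <- function(x, unit = NULL) {
  if (!is.data.frame(x)) {
    x <- tibble::tibble(type = names(x), n = as.integer(x))
  }
  stopifnot(all(c("type", "n") %in% names(x)))
  if (nrow(x) == 0) stop("empty frequency table")
  if (any(x$n < 1) || any(x$n != floor(x$n))) {
    stop("counts must be positive integers")
  }
  if (anyDuplicated(x$type)) stop("duplicate type labels in frequency table")
  out <- dplyr::arrange(tibble::as_tibble(x[c("type", "n")]),
                        dplyr::desc(.data$n), .data$type)
  structure(out, unit = unit, class = c("freq_tbl", class(out)))
}

#' @method glance freq_tbl
#' @export
glance.freq_tbl <- function(x, ...) {
  n <- x$n
  tibble::tibble(
    unit = attr(x, "unit", exact = TRUE) %||% NA_character_,
    L = sum(n), V = length(n), n_m = max(n), V1 = sum(n == 1),
    mean_n = sum(n) / length(n), mean_n2 = sum(n^2) / length(n)
  )
}

#' Rank-frequency profile of a frequency table
#'
#' @param table A `freq_tbl`.
#' @return Tibble with columns `rank`, `n` and `type`; `n` is non-increasing
#'   in `rank`, ties broken by lexicographic type label.
#' @export
rank_frequency <- function(table) {
  counts <- as_counts(table)
  ord <- order(-counts, if (is.data.frame(table)) table$type else
    seq_along(counts))
  tibble::tibble(
    rank = seq_along(counts),
    n = counts[ord],
    type = if (is.data.frame(table)) table$type[ord] else NA_character_
  )
}

#' Lexicon coverage of a corpus
#'
#' Fraction of tokens and of distinct surface types found in the dictionary.
#'
#' @param tokens Token-record tibble.
#' @param lexicon Character vector of dictionary surface forms.
#' @return One-row tibble with `token_coverage` and `type_coverage`.
#' @export
coverage <- function(tokens, lexicon) {
  if (nrow(tokens) == 0) stop("empty token sequence")
  types <- unique(tokens$surface)
  tibble::tibble(
    token_coverage = mean(tokens$surface %in% lexicon),
    type_coverage = mean(types %in% lexicon)
  )
}

#' Read / write frequency-table TSV files
#'
#' The on-disk format is two tab-separated columns, `type` and `n`, with a
#' header line.
#'
#' @param path File path.
#' @param table A `freq_tbl`.
#' @param unit Optional unit label attached on read.
#' @return `read_freq_table()` returns a `freq_tbl`; `write_freq_table()`
#'   returns `table` invisibly.
#' @export
read_freq_table <- function(path, unit = NULL) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    type = readr::col_character(), n = readr::col_integer()))
  freq_table(df, unit = unit)
}

#' @rdname read_freq_table
#' @export
write_freq_table <- function(table, path) {
  readr::write_tsv(tibble::as_tibble(table), path)
  invisible(table)
}
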