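#' Specification for a synthetic word/lemma corpus
#'
#' Defines the generating conditions: lemma type frequencies are drawn iid
#' from a discrete power law with exponent `gamma` and lower cutoff `a`;
#' lemmas then split into word forms under a broken-stick rule; and a stated
#' fraction of word types gets linked to a second lemma to emulate
#' morphological ambiguity.
#'
#' @param gamma Target lemma-frequency exponent (`> 1`); around 2 for
#'   Zipf-like corpora.
#' @param a Lower cutoff of the lemma frequency law (positive integer).
#' @param V_lemmas Number of lemma types.
#' @param splitting `"identity"` (words = lemmas), `"broken_stick_2"` (every
#'   lemma with `n >= 2` splits once into two word forms) or
#'   `"broken_stick_k"` (recursive `k - 1` splits; set `k`).
#' @param k Number of parts for `"broken_stick_k"`.
#' @param ambiguity_rate Fraction of word types additionally linked to a
#'   second lemma (association only; counts are unchanged), in `[0, 1)`.
#' @param seed Integer seed making the whole generation reproducible.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(gamma = 2, a = 1, V_lemmas = 5000,
                           splitting = c("identity", "broken_stick_2",
                                         "broken_stick_k"),
                           k = 2, ambiguity_rate = 0, seed = 1) {
  splitting <- match.arg(splitting)
  stopifnot(gamma > 1, V_lemmas >= 1, a >= 1, a == floor(a),
            ambiguity_rate >= 0, ambiguity_rate < 1, k >= 2)
  structure(list(gamma = gamma, a = as.integer(a),
                 V_lemmas = as.integer(V_lemmas), splitting = splitting,
                 k = as.integer(k), ambiguity_rate = ambiguity_rate,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Draw a synthetic lemma frequency table
#'
#' `V_lemmas` counts drawn iid from the discrete power law of the spec,
#' labelled `lemma_000001`, `lemma_000002`, ...
#'
#' @param spec A [synthetic_spec()].
#' @return A `freq_tbl` with unit `"lemma"`.
#' @export
sample_lemma_table <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  counts <- rpowerlaw(spec$V_lemmas, spec$gamma, spec$a,
                      seed = derive_seed(spec$seed, 1L))
  freq_table(
    tibble::tibble(
      type = sprintf("lemma_%06d", seq_len(spec$V_lemmas)),
      n = as.integer(counts)
    ),
    unit = "lemma"
  )
}

#' Broken-stick split of an integer frequency
#'
#' Splits `n` into two nonzero parts `(m, n - m)` with `m` uniform on
#' `{1, ..., n - 1}`: the discrete analogue of breaking a stick at a uniform
#' point, with both parts forced nonzero so the split genuinely creates two
#' word forms. Vectorized over `n`.
#'
#' @param n Integer frequencies, each `>= 2`.
#' @return Tibble with columns `m` and `rest` (`m + rest = n` rowwise).
#' @export
broken_stick_split <- function(n) {
  if (any(n < 2)) stop("cannot split n < 2 into two nonzero parts")
  m <- 1L + as.integer(floor(stats::runif(length(n)) * (n - 1)))
  m <- pmin(m, n - 1L)  # guard the measure-zero runif upper edge
  tibble::tibble(m = m, rest = as.integer(n) - m)
}

#' Derive a word frequency table from a lemma table
#'
#' Applies the spec's splitting law to every lemma count: under
#' `broken_stick_2` each lemma with `n >= 2` breaks once into two word forms
#' with a uniform split point; under `broken_stick_k` the splitting is applied
#' recursively `k - 1` times (always splitting the largest remaining part);
#' hapax lemmas stay unsplit. Word counts always sum to the lemma counts, so
#' the token total `L` is conserved. If `ambiguity_rate > 0` that fraction of
#' word types is additionally linked to a second random lemma in the map
#' (association only; no counts change). Under the broken-stick rule the word
#' frequency distribution retains the power-law exponent of the lemma
#' distribution, which is what makes the word/lemma comparison non-trivial.
#'
#' @param lemma_table A `freq_tbl` of lemma counts.
#' @param spec The [synthetic_spec()] used to generate it.
#' @return List with elements `words` (a `freq_tbl`, unit `"word"`) and `map`
#'   (a `lemma_map`).
#' @export
derive_word_table <- function(lemma_table, spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  run <- function() {
    lem <- tibble::as_tibble(lemma_table)
    parts <- switch(spec$splitting,
      identity = purrr::map(lem$n, function(n) n),
      broken_stick_2 = split_counts(lem$n, 2L),
      broken_stick_k = split_counts(lem$n, spec$k)
    )
    map <- tibble::tibble(
      lemma = rep(lem$type, lengths(parts)),
      n_pair = as.integer(unlist(parts))
    )
    map$word <- if (spec$splitting == "identity") map$lemma else
      sprintf("%s_w%d", map$lemma,
              stats::ave(map$n_pair, map$lemma, FUN = seq_along))
    map$n_w <- map$n_pair
    map <- dplyr::left_join(map,
                            tibble::tibble(lemma = lem$type, n_l = lem$n),
                            by = "lemma")
    if (spec$ambiguity_rate > 0) {
      n_amb <- floor(spec$ambiguity_rate * nrow(map))
      if (n_amb >= 1 && nrow(lem) >= 2) {
        amb_words <- sample(seq_len(nrow(map)), n_amb)
        extra <- purrr::map_dfr(amb_words, function(i) {
          other <- sample(setdiff(seq_len(nrow(lem)), match(map$lemma[i],
                                                            lem$type)), 1)
          tibble::tibble(lemma = lem$type[other], n_pair = 0L,
                         word = map$word[i], n_w = map$n_w[i],
                         n_l = lem$n[other])
        })
        map <- dplyr::bind_rows(map, extra)
      }
    }
    words <- freq_table(
      tibble::tibble(type = map$word[map$n_pair > 0],
                     n = map$n_pair[map$n_pair > 0]),
      unit = "word"
    )
    map <- structure(
      dplyr::arrange(map[c("word", "lemma", "n_pair", "n_w", "n_l")],
                     .data$lemma, .data$word),
      class = c("lemma_map", "tbl_df", "tbl", "data.frame"))
    list(words = words, map = map)
  }
  withr::with_seed(derive_seed(spec$seed, 2L), run())
}

# Split each count into at most k nonzero parts; counts < 2 stay whole.
split_counts <- function(n, k) {
  purrr::map(n, function(ni) {
    parts <- ni
    for (j in seq_len(k - 1)) {
      big <- which.max(parts)
      if (parts[big] < 2) break
      sp <- broken_stick_split(parts[big])
      parts <- c(parts[-big], sp$m, sp$rest)
    }
    parts
  })
}

#' Write a synthetic annotated corpus file
#'
#' Realizes the word table as a token stream: each word type occurs exactly
#' `n` times with its (primary) lemma, the order shuffled under the seed, in
#' the token-per-line TSV format of [read_corpus()]. Re-reading and
#' re-counting the file reproduces the input tables exactly. The tag column
#' is a placeholder (`X`).
#'
#' @param words A `freq_tbl` of word counts.
#' @param map The corresponding `lemma_map`.
#' @param path Output file path.
#' @param seed Integer seed for the token shuffle.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(words, map, path, seed = 1) {
  wt <- tibble::as_tibble(words)
  primary <- map[map$n_pair > 0, c("word", "lemma")]
  if (anyDuplicated(primary$word)) {
    primary <- primary[!duplicated(primary$word), ]
  }
  wl <- dplyr::left_join(wt, primary, by = c(type = "word"))
  if (anyNA(wl$lemma)) stop("word table and lemma map are inconsistent")
  surface <- rep(wl$type, wl$n)
  lemma <- rep(wl$lemma, wl$n)
  ord <- withr::with_seed(seed, sample(length(surface)))
  writeLines(paste(surface[ord], lemma[ord], "X", sep = "\t"), path,
             useBytes = TRUE)
  invisible(path)
}

#' Generate a full synthetic corpus in one call
#'
#' Convenience wrapper: draws the lemma table, derives the word table and
#' map, and optionally writes the token stream to disk.
#'
#' @param spec A [synthetic_spec()].
#' @param path Optional corpus output path.
#' @return List with `lemmas` (`freq_tbl`), `words` (`freq_tbl`), `map`
#'   (`lemma_map`) and `path` (or `NULL`).
#' @export
simulate_corpus <- function(spec, path = NULL) {
  lemmas <- sample_lemma_table(spec)
  dw <- derive_word_table(lemmas, spec)
  if (!is.null(path)) write_corpus(dw$words, dw$map, path,
                                   seed = derive_seed(spec$seed, 3L))
  list(lemmas = lemmas, words = dw$words, map = dw$map, path = path)
}
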