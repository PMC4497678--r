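#' Word-lemma association map
#'
#' Collects every distinct (surface, lemma) pairing observed in the token
#' records, together with the word-type and lemma-type frequencies counted
#' from the same records. A minority of word forms can be associated with more
#' than one lemma (e.g. an English word form that is the past tense of one
#' verb and the base form of another); such ambiguity makes the sum of word
#' frequencies over a lemma differ from the lemma frequency.
#'
#' @param tokens Token-record tibble with lemmas.
#' @return A `lemma_map`: tibble with one row per observed (word, lemma) pair
#'   and columns `word`, `lemma`, `n_pair` (tokens with that pairing), `n_w`
#'   (total frequency of the word type) and `n_l` (total frequency of the
#'   lemma type).
#' @export
build_lemma_map <- function(tokens) {
  stopifnot(is.data.frame(tokens))
  tokens <- dplyr::filter(tokens, !is.na(.data$lemma))
  if (nrow(tokens) == 0) stop("no lemma-annotated tokens")
  pairs <- tokens |>
    dplyr::count(word = .data$surface, lemma = .data$lemma, name = "n_pair")
  word_freqs <- dplyr::count(tokens, word = .data$surface, name = "n_w")
  lemma_freqs <- dplyr::count(tokens, lemma = .data$lemma, name = "n_l")
  out <- pairs |>
    dplyr::left_join(word_freqs, by = "word") |>
    dplyr::left_join(lemma_freqs, by = "lemma") |>
    dplyr::arrange(.data$lemma, .data$word)
  structure(out, class = c("lemma_map", class(out)))
}

#' @method glance lemma_map
#' @export
glance.lemma_map <- function(x, ...) {
  per_lemma <- dplyr::count(x, .data$lemma, name = "n_words")
  per_word <- dplyr::count(x, .data$word, name = "n_lemmas")
  tibble::tibble(
    n_pairs = nrow(x),
    V_w = nrow(per_word),
    V_l = nrow(per_lemma),
    l1 = sum(per_lemma$n_words == 1),
    ambiguous_words = sum(per_word$n_lemmas > 1)
  )
}

#' Number of lemmas associated with exactly one word form
#'
#' @param map A `lemma_map`.
#' @return Integer count of single-word lemmas.
#' @export
l1_lemmas <- function(map) {
  glance(map)$l1
}

#' Words per lemma as a function of lemma frequency
#'
#' @param map A `lemma_map`.
#' @return Tibble with one row per lemma: `lemma`, `n_l` (lemma frequency)
#'   and `n_words` (number of distinct associated word forms, `>= 1`).
#' @export
words_per_lemma <- function(map) {
  if (nrow(map) == 0) stop("empty lemma map")
  map |>
    dplyr::group_by(.data$lemma) |>
    dplyr::summarise(n_l = .data$n_l[1], n_words = dplyr::n(),
                     .groups = "drop")
}

#' Log-binned density of the lemma/word frequency ratio
#'
#' For every observed (word, lemma) pair, the ratio \eqn{n_l / n_w} measures
#' how much of the lemma's frequency mass the word form carries. Pairs with
#' \eqn{n_l < n_w} are disregarded: they arise from word forms associated with
#' more than one lemma, for which the ratio is not meaningful. The remaining
#' ratios are accumulated into geometric bins and normalized so the density
#' integrates to one.
#'
#' @param map A `lemma_map`.
#' @param bins_per_decade Number of geometric bins per order of magnitude.
#' @return Tibble with columns `lo`, `hi`, `mid` (geometric bin edges and
#'   center), `count` and `density`.
#' @export
frequency_ratio_density <- function(map, bins_per_decade = 5) {
  if (nrow(map) == 0) stop("empty lemma map")
  stopifnot(bins_per_decade >= 1)
  ratio <- map$n_l / map$n_w
  ratio <- ratio[ratio >= 1]
  if (length(ratio) == 0) stop("no qualifying (word, lemma) pairs")
  k_max <- ceiling(max(log10(ratio)) * bins_per_decade) + 1
  edges <- 10^(seq(0, k_max) / bins_per_decade)
  edges[1] <- 1 - 1e-12
  bin <- findInterval(ratio, edges, rightmost.closed = FALSE)
  counts <- tabulate(bin, nbins = length(edges) - 1)
  width <- diff(edges)
  keep <- seq_len(max(bin))
  tibble::tibble(
    lo = edges[keep], hi = edges[keep + 1],
    mid = sqrt(edges[keep] * edges[keep + 1]),
    count = counts[keep],
    density = counts[keep] / (length(ratio) * width[keep])
  )
}
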