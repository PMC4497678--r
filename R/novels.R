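#' Published tail-fit parameters for ten classic novels
#'
#' Fitted Zipf parameters, as published in the quantitative-linguistics
#' literature, for ten long single-author novels in four languages (English,
#' Spanish, French, Finnish), for word forms (`_w`) and lemmas (`_l`):
#' vocabulary size `V`, maximum frequency `n_m`, number of tail types `N_a`,
#' lower cutoff `a`, exponent `gamma` with standard deviation `sigma`, the
#' published `two_sigma_d` of the exponent difference, and `l1`, the number
#' of lemmas associated with a single word form. This table is the reference
#' input for the cross-text battery of [compare_texts()]: every downstream
#' statistic can be recomputed from it.
#'
#' @return A tibble with one row per novel.
#' @examples
#' compare_texts(ten_novels(), n_sims = 1000, seed = 1)
#' @export
ten_novels <- function() {
  path <- system.file("extdata", "ten_novels.tsv", package = "zipflemma",
                      mustWork = TRUE)
  readr::read_tsv(path, col_types = readr::cols(
    label = readr::col_character(), language = readr::col_character(),
    .default = readr::col_double()
  ))
}
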