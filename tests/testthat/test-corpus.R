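test_that("annotated corpus parsing handles full, partial and malformed lines", {
  f <- write_tmp_corpus(c("houses\thouse\tNNS", "", "# a comment",
                          "ran\trun\tVBD", "word"))
  toks <- read_corpus(f)
  expect_equal(nrow(toks), 3)
  expect_equal(toks$lemma, c("house", "run", NA))
  expect_equal(toks$tag, c("NNS", "VBD", NA))
  expect_true(all(toks$in_lexicon))

  bad <- write_tmp_corpus(c("a\tb\tc", "a\tb\tc\td"))
  expect_error(read_corpus(bad), "line 2")
  empty <- write_tmp_corpus(character())
  expect_equal(nrow(read_corpus(empty)), 0)
})

test_that("lexicon flags membership of the surface form", {
  f <- write_tmp_corpus(c("a\tx", "a\tx", "a\tx", "b\ty"))
  toks <- read_corpus(f, lexicon = c("a"))
  expect_equal(toks$in_lexicon, c(TRUE, TRUE, TRUE, FALSE))
  cov <- coverage(toks, c("a"))
  expect_equal(cov$token_coverage, 0.75)
  expect_equal(cov$type_coverage, 0.5)
  full <- coverage(toks, c("a", "b"))
  expect_equal(unlist(full), c(token_coverage = 1, type_coverage = 1))
  none <- coverage(toks, character())
  expect_equal(unlist(none), c(token_coverage = 0, type_coverage = 0))
})

test_that("unit definitions aggregate correctly and conserve token totals", {
  toks <- tibble::tibble(
    surface = c("houses", "house", "housed"),
    lemma = "house", tag = c("NNS", "NN", "VBD"), in_lexicon = TRUE
  )
  w <- count_types(toks, "word")
  expect_setequal(w$type, c("houses", "house", "housed"))
  expect_true(all(w$n == 1))
  g <- glance(w)
  expect_equal(g$V, 3)
  expect_equal(g$L, 3)

  l <- count_types(toks, "lemma")
  expect_equal(nrow(l), 1)
  expect_equal(l$n, 3L)
  expect_equal(glance(l)$mean_n, 3)

  # L conserved across all unit definitions on fully annotated records
  full <- toy_tokens()
  for (u in c("word", "lemma", "lemma_pos", "word_lemma_tag")) {
    expect_equal(glance(count_types(full, u))$L, nrow(full))
  }
  # aggregation never increases type count
  v <- vapply(c("lemma", "lemma_pos", "word_lemma_tag", "word"),
              function(u) glance(count_types(full, u))$V, numeric(1))
  expect_true(v["lemma"] <= v["lemma_pos"])
  expect_true(v["lemma_pos"] <= v["word_lemma_tag"])
  expect_true(v["lemma"] <= v["word"])
})

test_that("unit preconditions and lexicon filtering are enforced", {
  toks <- tibble::tibble(surface = c("a", "b"), lemma = c("a", NA),
                         tag = NA_character_, in_lexicon = c(TRUE, FALSE))
  expect_error(count_types(toks, "lemma_pos"), "tag|lemma")
  # lemma unit: lemma-less tokens are excluded, not an error
  l <- count_types(toks, "lemma")
  expect_equal(l$type, "a")
  filt <- count_types(toks, "word", lexicon_filter = TRUE)
  expect_equal(filt$type, "a")
  expect_error(count_types(toks[toks$in_lexicon & is.na(toks$lemma), ], "word"),
               "empty")
})

test_that("multi-lemma word forms keep per-token lemma assignment", {
  toks <- tibble::tibble(surface = c("found", "found"),
                         lemma = c("find", "found"),
                         tag = "V", in_lexicon = TRUE)
  l <- count_types(toks, "lemma")
  expect_setequal(l$type, c("find", "found"))
  expect_true(all(l$n == 1))
  map <- build_lemma_map(toks)
  expect_equal(sum(map$word == "found"), 2)
  expect_true(all(map$n_w[map$word == "found"] == 2))
  expect_equal(glance(map)$ambiguous_words, 1)
})

test_that("lemma map conserves frequencies for unambiguous corpora", {
  toks <- toy_tokens()[1:5, ]  # unambiguous part
  map <- build_lemma_map(toks)
  agg <- dplyr::summarise(dplyr::group_by(map, lemma),
                          s = sum(n_pair), n_l = n_l[1], .groups = "drop")
  expect_equal(agg$s, agg$n_l)
  wpl <- words_per_lemma(map)
  expect_equal(sort(wpl$n_words), c(2, 3))
  expect_equal(wpl$n_l[wpl$lemma == "house"], 3)

  # identity lemmatization: l1 = V and words-per-lemma all 1
  ident <- tibble::tibble(surface = c("a", "b", "b"), lemma = c("a", "b", "b"),
                          tag = NA, in_lexicon = TRUE)
  imap <- build_lemma_map(ident)
  expect_equal(l1_lemmas(imap), 2)
  expect_true(all(words_per_lemma(imap)$n_words == 1))
})

test_that("frequency ratio density bins log-ratios and excludes ratios < 1", {
  map <- structure(
    tibble::tibble(word = c("w1", "w2"), lemma = c("l1", "l2"),
                   n_pair = c(1L, 1L), n_w = c(1, 1), n_l = c(10, 100)),
    class = c("lemma_map", "tbl_df", "tbl", "data.frame"))
  d <- frequency_ratio_density(map, bins_per_decade = 1)
  # one pair per decade bin [10,100) and [100,1000)
  occupied <- d[d$count > 0, ]
  expect_equal(nrow(occupied), 2)
  expect_equal(occupied$count, c(1, 1))
  # density integrates to 1
  expect_equal(sum(d$density * (d$hi - d$lo)), 1, tolerance = 1e-12)

  # identity map: single spike at ratio 1
  ident <- structure(
    tibble::tibble(word = "a", lemma = "a", n_pair = 5L, n_w = 5, n_l = 5),
    class = c("lemma_map", "tbl_df", "tbl", "data.frame"))
  di <- frequency_ratio_density(ident, bins_per_decade = 1)
  expect_equal(sum(di$count), 1)

  # multi-lemma pairs with n_l < n_w are disregarded
  amb <- structure(
    tibble::tibble(word = c("w", "w"), lemma = c("l1", "l2"),
                   n_pair = c(2L, 1L), n_w = c(3, 3), n_l = c(2, 10)),
    class = c("lemma_map", "tbl_df", "tbl", "data.frame"))
  da <- frequency_ratio_density(amb, bins_per_decade = 1)
  expect_equal(sum(da$count), 1)
  expect_error(frequency_ratio_density(amb[1, ], 1), "no qualifying")
})

test_that("rank-frequency profile is sorted, deterministic, and invertible", {
  tab <- freq_table(tibble::tibble(type = c("a", "b", "c"), n = c(3L, 1L, 1L)))
  rf <- rank_frequency(tab)
  expect_equal(rf$rank, 1:3)
  expect_equal(rf$n, c(3, 1, 1))
  expect_equal(rf$type, c("a", "b", "c"))  # ties lexicographic
  # multiset of values matches the table and is non-increasing
  expect_true(all(diff(rf$n) <= 0))
  expect_equal(sort(rf$n), sort(tab$n))
  # single type
  one <- freq_table(tibble::tibble(type = "x", n = 7L))
  expect_equal(rank_frequency(one)$n, 7)
  # round-trip: spectrum rebuilt from (r, n(r)) equals the original
  spec <- frequency_spectrum(tab)
  rebuilt <- table(rf$n)
  expect_equal(as.numeric(rebuilt[as.character(spec$n)]) / nrow(tab), spec$f)
})

test_that("coverage is monotone in the lexicon", {
  toks <- toy_tokens()
  lex1 <- c("house", "ran")
  lex2 <- c(lex1, "found")
  c1 <- coverage(toks, lex1)
  c2 <- coverage(toks, lex2)
  expect_gte(c2$token_coverage, c1$token_coverage)
  expect_gte(c2$type_coverage, c1$type_coverage)
})

test_that("frequency tables round-trip through TSV", {
  tab <- count_types(toy_tokens(), "word")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_freq_table(tab, f)
  back <- read_freq_table(f, unit = "word")
  expect_equal(tibble::as_tibble(back), tibble::as_tibble(tab))
})
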