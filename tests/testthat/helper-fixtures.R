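# Shared fixtures: tiny token sets and corpus files built in code.

toy_tokens <- function() {
  tibble::tibble(
    surface = c("houses", "house", "housed", "ran", "run", "found", "found"),
    lemma   = c("house", "house", "house", "run", "run", "find", "found"),
    tag     = c("NNS", "NN", "VBD", "VBD", "VB", "VBD", "VB"),
    in_lexicon = TRUE
  )
}

write_tmp_corpus <- function(lines) {
  f <- withr::local_tempfile(fileext = ".tsv",
                             .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

# Student-t style paired vectors mirroring the published ten-novel table
novel_pairs <- function(what = c("a", "gamma")) {
  what <- match.arg(what)
  nov <- ten_novels()
  if (what == "a") paired_params(nov$label, nov$a_w, nov$a_l)
  else paired_params(nov$label, nov$gamma_w, nov$gamma_l)
}
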