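# Brute-force oracles, kept deliberately naive and independent of the
# package's vectorized implementations.

# nested-loop positional bigram probabilities
brute_bigram_table <- function(lex) {
  L <- nchar(lex$word[1])
  tot <- sum(lex$freq_per_million)
  out <- list()
  for (i in 1:(L - 1)) {
    tab <- list()
    for (j in seq_len(nrow(lex))) {
      pair <- substr(lex$word[j], i, i + 1)
      prev <- if (is.null(tab[[pair]])) 0 else tab[[pair]]
      tab[[pair]] <- prev + lex$freq_per_million[j]
    }
    out[[i]] <- vapply(tab, function(v) v / tot, numeric(1))
  }
  out
}

brute_mean_bigram <- function(form, brute_tabs) {
  L <- nchar(form)
  ps <- numeric(L - 1)
  for (i in 1:(L - 1)) {
    pair <- substr(form, i, i + 1)
    ps[i] <- if (!is.null(brute_tabs[[i]][[pair]]) && !is.na(brute_tabs[[i]][pair]))
      brute_tabs[[i]][[pair]] else 0
  }
  mean(ps)
}

# generate-and-filter neighbor enumeration over the full a-z alphabet
brute_neighbors <- function(form, template) {
  out <- character(0)
  for (i in seq_len(nchar(form))) {
    for (a in letters) {
      w <- form
      substr(w, i, i) <- a
      if (w != form && matches_template(w, template)) out <- c(out, w)
    }
  }
  unique(out)
}

random_toy_lexicon <- function(max_words = 20, length = 4) {
  n <- sample(3:max_words, 1)
  words <- character(0)
  while (base::length(words) < n) {
    words <- unique(c(words, paste(sample(letters[1:6], length, replace = TRUE),
                                   collapse = "")))
  }
  lexicon(words, stats::runif(n, 0.5, 50))
}
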