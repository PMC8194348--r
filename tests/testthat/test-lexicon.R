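test_that("load_lexicon filters by length and frequency and dedupes by max frequency", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("word\tfreq_per_million", "cat\t10.0", "dog\t5.0", "plant\t2.0"),
             path)
  lex <- load_lexicon(path, length_filter = 5)
  expect_equal(lex$word, "plant")

  writeLines(c("word\tfreq_per_million", "abcde\t0.32", "fghij\t0.33"), path)
  lex <- load_lexicon(path, min_freq = 0.33)
  expect_equal(lex$word, "fghij")

  writeLines(c("word\tfreq_per_million", "bride\t7", "bride\t3"), path)
  lex <- load_lexicon(path)
  expect_equal(nrow(lex), 1)
  expect_equal(lex$freq_per_million, 7)

  expect_error(load_lexicon(file.path(tempdir(), "no-such-file.tsv")),
               "not found")
  writeLines(c("palabra\tfreq", "x\t1"), path)
  expect_error(load_lexicon(path), "word")
})

test_that("bigram model matches hand computation and validates its inputs", {
  m <- fit_bigram_model(toy_bigram_lexicon())
  expect_equal(m$tables[[1]][["ba"]], 0.75)
  expect_equal(m$tables[[1]][["bo"]], 0.25)
  expect_equal(m$tables[[2]][["ab"]], 0.75)
  expect_equal(m$tables[[2]][["ob"]], 0.25)

  m1 <- fit_bigram_model(lexicon("haner", 1))
  for (i in 1:4) expect_equal(unname(m1$tables[[i]]), 1)

  expect_error(fit_bigram_model(lexicon(c("ab", "abc"), c(1, 1))), "mixed")
  expect_error(fit_bigram_model(lexicon(character(0), numeric(0))), "empty")
})

test_that("bigram model and mean probabilities agree with a brute-force counter", {
  set.seed(401)
  for (rep in 1:20) {
    lex <- random_toy_lexicon()
    m <- fit_bigram_model(lex)
    brute <- brute_bigram_table(lex)
    for (i in seq_along(m$tables)) {
      expect_equal(sum(m$tables[[i]]), 1, tolerance = 1e-9)
      for (pair in names(m$tables[[i]])) {
        expect_equal(m$tables[[i]][[pair]], brute[[i]][[pair]], tolerance = 1e-12)
      }
    }
    probe <- lex$word[sample.int(nrow(lex), 3, replace = TRUE)]
    expect_equal(mean_bigram_probability(probe, m),
                 vapply(probe, brute_mean_bigram, numeric(1), brute_tabs = brute),
                 ignore_attr = TRUE, tolerance = 1e-12)
  }
})

test_that("mean bigram probability averages positional tables with zero for unseen pairs", {
  m <- fit_bigram_model(toy_bigram_lexicon())
  expect_equal(mean_bigram_probability("bab", m), 0.75)
  expect_equal(mean_bigram_probability("bob", m), 0.25)
  expect_equal(mean_bigram_probability("zzz", m), 0)
  expect_error(mean_bigram_probability("ab", m), "length")
})

test_that("biphone model pools phone pairs with token weighting", {
  lex <- lexicon("ab", 1)
  m <- fit_biphone_model(lex, c(ab = "ab"))
  expect_equal(unname(m$table[["a b"]]), 1)

  # two equal-frequency words, no shared biphone: mass proportional to counts
  lex2 <- lexicon(c("abc", "def"), c(1, 1))
  m2 <- fit_biphone_model(lex2, c(abc = "abc", def = "def"))
  expect_equal(sum(m2$table), 1, tolerance = 1e-9)
  expect_equal(unname(m2$table[c("a b", "b c", "d e", "e f")]), rep(0.25, 4))

  expect_error(fit_biphone_model(lex, c(ab = "")), "empty transcription")
  expect_error(fit_biphone_model(lexicon(c("ab", "cd"), c(1, 1)), c(ab = "ab")),
               "cd")
})

test_that("composite z-scores are centered and scaled on the reference set", {
  lex <- bundled_lexicon()
  model <- bundled_model()
  sc <- composite_similarity(lex$word, model, bundled_pron())
  expect_equal(mean(sc$z_ortho), 0, tolerance = 1e-6)
  expect_equal(sd(sc$z_ortho), 1, tolerance = 1e-6)
  expect_equal(mean(sc$z_phono), 0, tolerance = 1e-6)
  expect_equal(sd(sc$z_phono), 1, tolerance = 1e-6)
  expect_equal(sc$composite, (sc$z_ortho + sc$z_phono) / 2, tolerance = 1e-12)
})

test_that("composite similarity matches an independent hand computation on a toy set", {
  lex <- lexicon(c("bab", "bob", "bak"), c(3, 1, 2))
  pron <- rule_based_transcription(lex$word)
  model <- similarity_model(lex, pron, high_pct = 20, low_pct = 99)
  # independent route: brute-force tables + explicit z formulas
  brute <- brute_bigram_table(lex)
  mo <- vapply(lex$word, brute_mean_bigram, numeric(1), brute_tabs = brute)
  m_o <- mean(mo); s_o <- sd(mo)
  sc <- composite_similarity("bab", model, pron)
  expect_equal(sc$z_ortho, (brute_mean_bigram("bab", brute) - m_o) / s_o,
               tolerance = 1e-12)
  # a form whose mean probabilities sit at the reference means scores zero
  expect_equal(
    ((model$ref_mean_bigram - model$ref_mean_bigram) / model$ref_sd_bigram +
       (model$ref_mean_biphone - model$ref_mean_biphone) / model$ref_sd_biphone) / 2,
    0)
})

test_that("percentile thresholds follow the descending-rank convention", {
  thr <- percentile_thresholds(1:100, 20, 99)
  expect_equal(unname(thr["high_threshold"]), 81)
  expect_equal(unname(thr["low_threshold"]), 2)
  expect_equal(sum(1:100 >= thr["high_threshold"]), 20)
  expect_equal(sum(1:100 >= thr["low_threshold"]), 99)

  thr_eq <- percentile_thresholds(rep(5, 10), 20, 99)
  expect_equal(unname(thr_eq), c(5, 5))

  # monotone: raising the percent never raises the threshold
  set.seed(402)
  scores <- rnorm(57)
  prev <- Inf
  for (p in c(5, 20, 50, 80, 99)) {
    cur <- percentile_thresholds(scores, p, 100)[["high_threshold"]]
    expect_lte(cur, prev)
    prev <- cur
  }
  expect_error(percentile_thresholds(numeric(0)), "non-empty")
  expect_error(percentile_thresholds(1:10, 99, 20), "high_pct")
})

test_that("probabilities, z-scores, and thresholds are invariant to frequency scaling", {
  lex <- bundled_lexicon()
  pron <- bundled_pron()
  doubled <- lexicon(lex$word, lex$freq_per_million * 2)
  m1 <- bundled_model()
  m2 <- similarity_model(doubled, pron)
  expect_equal(m1$bigram_model$tables, m2$bigram_model$tables, tolerance = 1e-12)
  expect_equal(m1$biphone_model$table, m2$biphone_model$table, tolerance = 1e-12)
  expect_equal(m1$high_threshold, m2$high_threshold, tolerance = 1e-12)
  expect_equal(m1$low_threshold, m2$low_threshold, tolerance = 1e-12)
  probe <- c("haner", "vobaf")
  expect_equal(composite_similarity(probe, m1), composite_similarity(probe, m2),
               tolerance = 1e-12)
})

test_that("similarity models survive a JSON round-trip", {
  model <- bundled_model()
  path <- withr::local_tempfile(fileext = ".json")
  write_similarity_model(model, path)
  back <- read_similarity_model(path)
  probe <- c("haner", "hajer", "vobaf")
  expect_equal(composite_similarity(probe, back),
               composite_similarity(probe, model), tolerance = 1e-9)
  expect_equal(back$high_threshold, model$high_threshold, tolerance = 1e-12)
})
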