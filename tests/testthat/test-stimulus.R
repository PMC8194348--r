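test_that("candidate generation respects the template, uniqueness, and the seed", {
  lex <- bundled_lexicon()
  tmpl <- cvcvc_template()
  cand <- generate_candidates(2000, tmpl, lex, seed = 7)
  expect_length(cand, 2000)
  expect_false(anyDuplicated(cand) > 0)
  expect_true(all(matches_template(cand, tmpl)))
  expect_true(all(grepl("^[bcdfghjklmnprstvwz][aeiou][bcdfghjklmnprstvwz][aeiou][bcdfghjklmnprstvwz]$",
                        cand)))
  expect_length(intersect(cand, lex$word), 0)
  expect_identical(cand, generate_candidates(2000, tmpl, lex, seed = 7))
  expect_false(identical(cand, generate_candidates(2000, tmpl, lex, seed = 8)))

  tiny <- cvcvc_template("CV", consonants = c("b", "d"), vowels = c("a", "o"))
  expect_error(generate_candidates(10, tiny, NULL, seed = 1), "too small")
})

test_that("substitution neighbors enumerate the template-preserving Hamming-1 set", {
  tmpl <- cvcvc_template()
  nb <- substitution_neighbors("haner", tmpl)
  expect_length(nb, 59)  # 17 alternatives x 3 consonant slots + 4 x 2 vowel slots
  expect_true("hajer" %in% nb)
  expect_false("haner" %in% nb)
  expect_true(all(matches_template(nb, tmpl)))
  expect_true(all(vapply(nb, function(w)
    sum(strsplit(w, "")[[1]] != strsplit("haner", "")[[1]]) == 1, logical(1))))

  set.seed(403)
  for (rep in 1:20) {
    f <- generate_candidates(1, tmpl, NULL, seed = rep + 100)
    expect_setequal(substitution_neighbors(f, tmpl), brute_neighbors(f, tmpl))
  }
  expect_error(substitution_neighbors("qatar", tmpl), "template")
})

test_that("bridge selection respects thresholds and the onset cap", {
  model <- bundled_model()
  cand <- generate_candidates(4000, cvcvc_template(), bundled_lexicon(), seed = 9)
  scored <- composite_similarity(cand, model)

  fam <- select_bridge_list(scored, model, "Familiar", k = 18, seed = 3)
  expect_equal(nrow(fam), 18)
  expect_true(min(fam$composite) > model$high_threshold)
  expect_lte(max(table(substring(fam$form, 1, 1))), ceiling(18 / 18))
  expect_true(all(fam$role == "bridge"))

  unf <- select_bridge_list(scored, model, "Unfamiliar", k = 36, seed = 3)
  expect_true(max(unf$composite) < model$low_threshold)
  expect_lte(max(table(substring(unf$form, 1, 1))), ceiling(36 / 18))

  expect_equal(nrow(select_bridge_list(scored, model, "Familiar", k = 0)), 0)
  expect_error(select_bridge_list(scored[0, ], model, "Familiar", k = 5),
               "shortfall")
})

test_that("terminus items link distinct bridge words at Hamming distance one", {
  design <- bundled_design()
  for (cond in c("familiar", "unfamiliar")) {
    df <- design[[cond]]
    term <- df[df$role == "terminus", ]
    bridge <- df[df$role == "bridge", ]
    expect_equal(nrow(term), 48)
    # bijection into the bridge list
    expect_false(anyDuplicated(term$neighbor_form) > 0)
    expect_true(all(term$neighbor_form %in% bridge$form))
    # Hamming distance exactly 1
    d <- mapply(function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]),
                term$form, term$neighbor_form)
    expect_true(all(d == 1))
    # below the low similarity threshold, non-words, template-conformant
    expect_true(all(term$composite < design$model$low_threshold))
    expect_length(intersect(term$form, bundled_lexicon()$word), 0)
    expect_true(all(matches_template(term$form, cvcvc_template())))
  }
  expect_true(all(design$report$matching_p_values > 0.1))
  # Familiar bridge words are more English-like than Unfamiliar bridge words
  expect_gt(mean(design$familiar$composite[design$familiar$role == "bridge"]),
            mean(design$unfamiliar$composite[design$unfamiliar$role == "bridge"]))
})

test_that("terminus construction skips bridge words whose neighbors are all real words", {
  tiny <- cvcvc_template("CVC", consonants = c("b", "d"), vowels = c("a", "o"))
  # every neighbor of "bad" is a real word; "dob" keeps non-word neighbors
  lex <- lexicon(c("dad", "bod", "bab"), c(5, 3, 2))
  pron <- rule_based_transcription(lex$word)
  model <- similarity_model(lex, pron)
  model$low_threshold <- Inf  # every candidate counts as dissimilar
  bridge <- data.frame(form = c("bad", "dob"), condition = "Familiar",
                       role = "bridge", stringsAsFactors = FALSE)
  expect_error(
    build_terminus_list(bridge, model, lex, tiny, k = 2, seed = 1),
    "only 1 bridge words")
  one <- build_terminus_list(bridge, model, lex, tiny, k = 1, seed = 1)
  expect_equal(one$neighbor_form, "dob")
  expect_true(one$form %in% c("bob", "dab", "dod"))
})

test_that("meaning splits balance classes and match covariates", {
  norms <- bundled_norms()
  sp <- split_meanings(norms, seed = 4)
  expect_equal(nrow(sp$listA), 48)
  expect_equal(nrow(sp$listB), 48)
  expect_equal(sum(sp$listA$class == "concrete"), 24)
  expect_equal(sum(sp$listB$class == "concrete"), 24)
  expect_true(all(sp$p_values > 0.05))
  expect_setequal(c(sp$listA$word, sp$listB$word), norms$word)

  # identical norms: accepted on the first draw with all t = 0
  flat <- norms
  for (v in c("imageability", "aoa", "familiarity", "zipf")) flat[[v]] <- 1
  sp_flat <- split_meanings(flat, seed = 1)
  expect_equal(sp_flat$iterations, 1)
  expect_equal(unname(sp_flat$p_values), rep(1, 4))

  # 4 words, 2 per class: every valid split puts one of each class per list
  four <- data.frame(word = c("w1", "w2", "w3", "w4"), imageability = 1,
                     aoa = 1, familiarity = 1, zipf = 1,
                     class = c("concrete", "concrete", "abstract", "abstract"))
  sp4 <- split_meanings(four, seed = 2)
  expect_equal(sort(table(sp4$listA$class), decreasing = TRUE),
               sort(table(sp4$listB$class), decreasing = TRUE))
  expect_error(split_meanings(four[1:3, ], seed = 1), "even")
})

test_that("counterbalanced pairings swap lists and cover every meaning once", {
  design <- bundled_design()
  g1 <- assign_pairings(design$familiar, 1)
  g2 <- assign_pairings(design$familiar, 2)
  expect_setequal(g1$meaning, bundled_norms()$word)
  expect_setequal(g2$meaning, bundled_norms()$word)
  b <- design$familiar$role == "bridge"
  expect_identical(g1$meaning[b], g2$meaning[!b])
  expect_identical(g1$meaning[!b], g2$meaning[b])
  empty <- design$familiar[0, ]
  expect_equal(nrow(assign_pairings(empty, 1)), 0)
})

test_that("bigram overlap counting matches enumerated cases", {
  expect_equal(bigram_overlap_count("cohuz", "command"), 1L)  # shared "co"
  expect_equal(bigram_overlap_count("vobaf", "cloud"), 0L)
  expect_equal(bigram_overlap_count("haner", "haner"), 1L)
  expect_equal(bigram_overlap_count(c("cohuz", "vobaf"), c("command", "cloud")), 1L)
  expect_equal(bigram_overlap_count(character(0), character(0)), 0L)
})

test_that("the stimulus design is deterministic and writes byte-identical files", {
  design <- bundled_design()
  again <- design_stimuli(bundled_lexicon(), bundled_pron(), bundled_norms(),
                          seed = 1)
  expect_identical(design$familiar, again$familiar)
  expect_identical(design$unfamiliar, again$unfamiliar)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_stimulus_design(design, d1)
  write_stimulus_design(again, d2)
  for (f in c("familiar_stimuli.csv", "unfamiliar_stimuli.csv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})
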