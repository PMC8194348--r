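#' CVCVC stimulus template
#'
#' Slot template for pseudoword generation: a pattern over consonant (`C`) and
#' vowel (`V`) slots with the letter alphabets allowed in each. The default is
#' the five-letter alternating template with 18 consonants (the alphabet minus
#' a, e, i, o, u, q, x, y) and the 5 vowels.
#'
#' @param pattern String over `{C, V}`.
#' @param consonants,vowels Character vectors of single letters.
#' @return A `stim_template` list with `pattern`, `consonants`, `vowels`, and
#'   `slots` (the per-position alphabets).
#' @export
cvcvc_template <- function(pattern = "CVCVC",
                           consonants = setdiff(letters, c("a", "e", "i", "o", "u",
                                                           "q", "x", "y")),
                           vowels = c("a", "e", "i", "o", "u")) {
  if (!grepl("^[CV]+$", pattern)) stop("pattern must be a string over {C, V}")
  if (length(intersect(consonants, vowels)))
    stop("consonant and vowel sets must be disjoint")
  if (any(c("q", "x", "y") %in% c(consonants, vowels)))
    stop("q, x, and y are excluded from the template alphabets")
  slots <- lapply(strsplit(pattern, "")[[1]],
                  function(s) if (s == "C") consonants else vowels)
  structure(list(pattern = pattern, consonants = consonants, vowels = vowels,
                 slots = slots),
            class = "stim_template")
}

#' Does a form match a template?
#'
#' @param forms Character vector.
#' @param template A `stim_template`.
#' @return Logical vector.
#' @export
matches_template <- function(forms, template) {
  L <- nchar(template$pattern)
  ok <- nchar(forms) == L
  for (i in seq_len(L)) {
    ok <- ok & substring(forms, i, i) %in% template$slots[[i]]
  }
  ok
}

#' Generate unique pseudoword candidates
#'
#' Draws `n` unique template-conformant strings that are not words of the
#' reference lexicon, sampling each slot uniformly from its alphabet.
#' Deterministic given `seed`; candidates are returned in first-draw order.
#'
#' @param n Number of candidates (the study evaluated 10,000).
#' @param template A `stim_template`.
#' @param lex A `lexicon` whose words are excluded.
#' @param seed Integer seed.
#' @return Character vector of `n` unique non-word forms.
#' @export
generate_candidates <- function(n, template = cvcvc_template(), lex = NULL,
                                seed = 1) {
  stopifnot(n >= 1)
  real_words <- if (is.null(lex)) character(0) else lex$word
  space <- prod(lengths(template$slots))
  capacity <- space - sum(matches_template(real_words, template))
  if (n > capacity)
    stop("template alphabet too small: ", n, " unique non-words requested but only ",
         capacity, " exist")
  with_seed(seed, {
    out <- character(0)
    while (length(out) < n) {
      batch_n <- max(1000L, ceiling((n - length(out)) * 1.3))
      cols <- lapply(template$slots, function(a) sample(a, batch_n, replace = TRUE))
      batch <- do.call(paste0, cols)
      out <- setdiff(unique(c(out, batch)), real_words)
    }
    out[seq_len(n)]
  })
}

#' Template-preserving single-substitution neighbors
#'
#' All strings at Hamming distance exactly one from `form` in which the
#' substituted letter still respects the slot alphabet (consonant slots take
#' only template consonants, vowel slots only vowels). The form itself is
#' excluded. Deterministic order: position-major, then alphabetical.
#'
#' @param form A template-conformant string.
#' @param template A `stim_template`.
#' @return Character vector of neighbor forms.
#' @export
substitution_neighbors <- function(form, template = cvcvc_template()) {
  form <- tolower(form)
  if (!matches_template(form, template))
    stop("form does not match the template: ", form)
  L <- nchar(form)
  out <- character(0)
  for (i in seq_len(L)) {
    cur <- substring(form, i, i)
    for (a in sort(setdiff(template$slots[[i]], cur))) {
      w <- form
      substring(w, i, i) <- a
      out <- c(out, w)
    }
  }
  out
}

# round-robin onset-balanced draw of k forms from an eligible pool.
# Each round visits every onset letter that still has candidates (in seeded
# random order) and takes one random candidate from it; a hard cap of
# ceiling(k / #onset-alphabet) per onset enforces the balanced distribution,
# and exhausting the capped pools before reaching k is an error.
onset_balanced_draw <- function(forms, k, cap) {
  if (k == 0) return(character(0))
  pool <- split(forms, substring(forms, 1, 1))
  pool <- lapply(pool, function(x) x[sample.int(length(x))])
  taken <- stats::setNames(integer(length(pool)), names(pool))
  sel <- character(0)
  while (length(sel) < k) {
    live <- names(pool)[vapply(pool, length, 1L) > 0 & taken < cap]
    if (!length(live))
      stop("onset-balanced selection infeasible: only ", length(sel), " of ",
           k, " items drawable under the per-onset cap of ", cap,
           " (pool covers ", sum(lengths(pool) > 0), " onset letters)")
    for (o in sample(live)) {
      if (length(sel) >= k) break
      if (taken[o] >= cap || !length(pool[[o]])) next
      sel <- c(sel, pool[[o]][1])
      pool[[o]] <- pool[[o]][-1]
      taken[o] <- taken[o] + 1L
    }
  }
  sel
}

#' Select an onset-balanced bridge word list
#'
#' Filters scored candidates to the required side of the similarity threshold
#' (Familiar: composite above the high threshold; Unfamiliar: composite below
#' the low threshold) and draws `k` of them with a balanced distribution of
#' word-onset letters: greedy round-robin over onsets under a hard per-onset
#' cap of `ceiling(k / #onset-alphabet-letters)` (3 for 48 items over 18
#' consonants). Selection fails with an informative error when the eligible
#' pool cannot satisfy the cap.
#'
#' @param candidates Scored candidate data frame from [composite_similarity()].
#' @param model A `similarity_model` (supplies the thresholds).
#' @param condition `"Familiar"` or `"Unfamiliar"`.
#' @param k List size (the study used 48).
#' @param seed Integer seed.
#' @param template A `stim_template` (supplies the onset alphabet for the cap).
#' @return Data frame of `k` rows: the candidate columns plus `condition` and
#'   `role = "bridge"`.
#' @export
select_bridge_list <- function(candidates, model, condition = c("Familiar", "Unfamiliar"),
                               k = 48, seed = 1, template = cvcvc_template()) {
  condition <- match.arg(condition)
  eligible <- if (condition == "Familiar")
    candidates[candidates$composite > model$high_threshold, , drop = FALSE]
  else
    candidates[candidates$composite < model$low_threshold, , drop = FALSE]
  if (nrow(eligible) < k)
    stop(condition, " bridge selection: only ", nrow(eligible),
         " eligible candidates for k = ", k,
         " (shortfall ", k - nrow(eligible), ")")
  cap <- ceiling(k / length(unique(template$slots[[1]])))
  sel <- with_seed(seed, onset_balanced_draw(eligible$form, k, cap))
  out <- eligible[match(sel, eligible$form), , drop = FALSE]
  out$condition <- rep(condition, nrow(out))
  out$role <- rep("bridge", nrow(out))
  rownames(out) <- NULL
  out
}

# per-bridge-word sets of usable terminus neighbors: template-preserving
# non-word substitution neighbors scoring below the low threshold, with forms
# that neighbor >= 2 bridge words removed (the study excluded such duplicates)
terminus_neighbor_sets <- function(bridge_forms, model, lex,
                                   template = cvcvc_template(),
                                   pronunciations = NULL) {
  nbs <- lapply(bridge_forms, function(f) {
    nb <- setdiff(substitution_neighbors(f, template), lex$word)
    if (!length(nb)) return(character(0))
    sc <- composite_similarity(nb, model, pronunciations)
    nb[sc$composite < model$low_threshold]
  })
  all_nb <- unlist(nbs)
  dup <- unique(all_nb[duplicated(all_nb)])
  nbs <- lapply(nbs, setdiff, y = dup)
  stats::setNames(nbs, bridge_forms)
}

# draw one terminus neighbor per bridge form (sets are disjoint after the
# duplicate exclusion, so draws are automatically distinct)
draw_terminus <- function(nbsets) {
  vapply(nbsets, function(s) s[sample.int(length(s), 1)], character(1))
}

welch_p <- function(x, y) {
  if (stats::sd(x) == 0 && stats::sd(y) == 0) return(if (mean(x) == mean(y)) 1 else 0)
  stats::t.test(x, y, var.equal = FALSE)$p.value
}

#' Build a terminus list for one bridge list
#'
#' Single-condition construction: each terminus item is a below-threshold
#' non-word substitution neighbor of a distinct bridge word (forms neighboring
#' two or more bridge words are excluded before selection). No cross-condition
#' matching tests are applied here; see [build_terminus_lists()] for the full
#' matched build.
#'
#' @param bridge Bridge list data frame from [select_bridge_list()].
#' @param model A `similarity_model`.
#' @param lex The reference `lexicon` (real-word exclusion).
#' @param template A `stim_template`.
#' @param k Number of terminus items (`k <= nrow(bridge)`).
#' @param seed Integer seed.
#' @param pronunciations Optional transcription table for neighbor scoring.
#' @return Data frame of `k` rows with candidate columns plus `condition`,
#'   `role = "terminus"`, and `neighbor_form` (the linked bridge word).
#' @export
build_terminus_list <- function(bridge, model, lex, template = cvcvc_template(),
                                k = nrow(bridge), seed = 1, pronunciations = NULL) {
  stopifnot(k <= nrow(bridge))
  nbsets <- terminus_neighbor_sets(bridge$form, model, lex, template, pronunciations)
  usable <- names(nbsets)[lengths(nbsets) > 0]
  if (length(usable) < k)
    stop("only ", length(usable), " bridge words have usable terminus neighbors ",
         "(need ", k, "); unusable: ",
         paste(utils::head(setdiff(names(nbsets), usable), 5), collapse = ", "))
  with_seed(seed, {
    chosen_bridges <- if (length(usable) > k) sample(usable, k) else usable
    forms <- draw_terminus(nbsets[chosen_bridges])
    sc <- composite_similarity(forms, model, pronunciations)
    sc$condition <- bridge$condition[1]
    sc$role <- "terminus"
    sc$neighbor_form <- chosen_bridges
    sc
  })
}

#' Build matched terminus lists for both conditions
#'
#' Joint construction of the Familiar and Unfamiliar terminus lists under the
#' study's matching constraints: every terminus item is a below-low-threshold
#' non-word substitution neighbor of a distinct bridge word in its condition,
#' duplicate neighbors (of two or more bridge words) are excluded, and the
#' selection is resampled (seeded rejection sampling) until Welch t-tests on
#' mean bigram and mean biphone probabilities are non-significant for (a)
#' Familiar-terminus vs Unfamiliar-terminus and (b) Unfamiliar bridge vs
#' Unfamiliar terminus (all p > `p_threshold`).
#'
#' @param bridge_familiar,bridge_unfamiliar Bridge lists from
#'   [select_bridge_list()].
#' @param model A `similarity_model`.
#' @param lex The reference `lexicon`.
#' @param template A `stim_template`.
#' @param k Terminus list size per condition.
#' @param seed Integer seed.
#' @param max_iters Maximum rejection-sampling iterations.
#' @param p_threshold Matching criterion (the study required all p > 0.1).
#' @param pronunciations Optional transcription table.
#' @return List with `familiar` and `unfamiliar` terminus data frames (as in
#'   [build_terminus_list()]), `p_values` (the four matching tests), and
#'   `iterations`.
#' @export
build_terminus_lists <- function(bridge_familiar, bridge_unfamiliar, model, lex,
                                 template = cvcvc_template(), k = 48, seed = 1,
                                 max_iters = 10000, p_threshold = 0.1,
                                 pronunciations = NULL) {
  nb_f <- terminus_neighbor_sets(bridge_familiar$form, model, lex, template,
                                 pronunciations)
  nb_u <- terminus_neighbor_sets(bridge_unfamiliar$form, model, lex, template,
                                 pronunciations)
  for (cond in list(c("Familiar", "nb_f"), c("Unfamiliar", "nb_u"))) {
    sets <- get(cond[2])
    usable <- sum(lengths(sets) > 0)
    if (usable < k)
      stop(cond[1], ": only ", usable, " bridge words have usable terminus ",
           "neighbors (need ", k, ")")
  }
  mb_u_bridge <- bridge_unfamiliar$mean_bigram_p
  mp_u_bridge <- bridge_unfamiliar$mean_biphone_p
  with_seed(seed, {
    pick_sets <- function(sets) {
      usable <- names(sets)[lengths(sets) > 0]
      sets[if (length(usable) > k) sample(usable, k) else usable]
    }
    sets_f <- pick_sets(nb_f)
    sets_u <- pick_sets(nb_u)
    best <- -Inf; best_p <- NULL
    for (it in seq_len(max_iters)) {
      tf <- draw_terminus(sets_f)
      tu <- draw_terminus(sets_u)
      sc_f <- composite_similarity(tf, model, pronunciations)
      sc_u <- composite_similarity(tu, model, pronunciations)
      p <- c(term_bigram = welch_p(sc_f$mean_bigram_p, sc_u$mean_bigram_p),
             term_biphone = welch_p(sc_f$mean_biphone_p, sc_u$mean_biphone_p),
             unfam_bridge_term_bigram = welch_p(mb_u_bridge, sc_u$mean_bigram_p),
             unfam_bridge_term_biphone = welch_p(mp_u_bridge, sc_u$mean_biphone_p))
      if (min(p) > best) { best <- min(p); best_p <- p }
      if (all(p > p_threshold)) {
        finish <- function(sc, bridge_forms, condition) {
          sc$condition <- condition
          sc$role <- "terminus"
          sc$neighbor_form <- bridge_forms
          rownames(sc) <- NULL
          sc
        }
        return(list(familiar = finish(sc_f, names(sets_f), "Familiar"),
                    unfamiliar = finish(sc_u, names(sets_u), "Unfamiliar"),
                    p_values = p, iterations = it))
      }
    }
    stop("terminus matching constraints unsatisfiable within ", max_iters,
         " iterations; best p-values: ",
         paste(names(best_p), round(best_p, 4), sep = "=", collapse = ", "))
  })
}

#' Split meaning norms into matched A and B lists
#'
#' Constrained re-randomization: the norm table is split into two halves with
#' equal concrete/abstract counts, resampling (seeded) until Welch t-tests on
#' imageability, age of acquisition, familiarity, and zipf frequency are all
#' non-significant at `alpha`.
#'
#' @param norms Data frame with columns `word`, `imageability`, `aoa`,
#'   `familiarity`, `zipf`, `class` (values `concrete`/`abstract`), even row
#'   count and equal class counts.
#' @param seed Integer seed.
#' @param alpha Matching criterion (the study required p > 0.05).
#' @param max_iters Maximum re-randomization iterations.
#' @return List with `listA`, `listB` (norm data frames), `p_values`, and
#'   `iterations`.
#' @export
split_meanings <- function(norms, seed = 1, alpha = 0.05, max_iters = 10000) {
  n <- nrow(norms)
  if (n %% 2 != 0) stop("number of meanings must be even")
  counts <- table(norms$class)
  if (!setequal(names(counts), c("abstract", "concrete")) ||
      counts[["concrete"]] != counts[["abstract"]])
    stop("norms must contain equal numbers of concrete and abstract words")
  vars <- c("imageability", "aoa", "familiarity", "zipf")
  idx_con <- which(norms$class == "concrete")
  idx_abs <- which(norms$class == "abstract")
  with_seed(seed, {
    best <- -Inf; best_p <- NULL
    for (it in seq_len(max_iters)) {
      a <- c(sample(idx_con, length(idx_con) / 2),
             sample(idx_abs, length(idx_abs) / 2))
      b <- setdiff(seq_len(n), a)
      p <- vapply(vars, function(v) welch_p(norms[[v]][a], norms[[v]][b]),
                  numeric(1))
      if (min(p) > best) { best <- min(p); best_p <- p }
      if (all(p > alpha)) {
        ord <- function(i) { d <- norms[i, , drop = FALSE]; d[order(d$word), ] }
        la <- ord(a); lb <- ord(b)
        rownames(la) <- rownames(lb) <- NULL
        return(list(listA = la, listB = lb, p_values = p, iterations = it))
      }
    }
    stop("no matched split found within ", max_iters, " iterations; best p-values: ",
         paste(names(best_p), round(best_p, 4), sep = "=", collapse = ", "))
  })
}

#' Resolve meaning assignments under counterbalancing
#'
#' Each stimulus row carries the meaning it takes under the A-first and B-first
#' counterbalancing (`meaning_listA`, `meaning_listB`). Group 1 participants
#' use list A meanings in the bridge session and list B in the terminus
#' session; group 2 is reversed. The resolved `meaning` column therefore picks
#' `meaning_listA` for (group 1, bridge) and (group 2, terminus) rows, and
#' `meaning_listB` otherwise, so each participant sees all meanings exactly
#' once.
#'
#' @param stimuli Stimulus data frame with `role`, `meaning_listA`,
#'   `meaning_listB` columns (one condition).
#' @param counterbalance_group 1 or 2.
#' @return `stimuli` with a resolved `meaning` column.
#' @export
assign_pairings <- function(stimuli, counterbalance_group = 1) {
  stopifnot(counterbalance_group %in% c(1, 2))
  if (nrow(stimuli) == 0) { stimuli$meaning <- character(0); return(stimuli) }
  use_a <- (stimuli$role == "bridge") == (counterbalance_group == 1)
  stimuli$meaning <- ifelse(use_a, stimuli$meaning_listA, stimuli$meaning_listB)
  if (anyDuplicated(stimuli$meaning))
    stop("meaning assignment is not a bijection: duplicated meanings")
  stimuli
}

#' Count novel-word/English-word pairs with overlapping bigrams
#'
#' A pair overlaps when the two strings share at least one adjacent letter pair
#' at any position (case-insensitive); the study used this as a near-cognate
#' check on the novel-word/meaning pairings.
#'
#' @param novel,english Equal-length character vectors of paired forms.
#' @return Integer count of overlapping pairs.
#' @export
bigram_overlap_count <- function(novel, english) {
  stopifnot(length(novel) == length(english))
  if (!length(novel)) return(0L)
  sum(vapply(seq_along(novel), function(i) {
    length(intersect(letter_bigrams(tolower(novel[i])),
                     letter_bigrams(tolower(english[i])))) > 0
  }, logical(1)))
}

#' Design the full bridge/terminus stimulus set
#'
#' End-to-end similarity-controlled design: fits the similarity model on the
#' reference lexicon, generates `n_candidates` template pseudowords, selects
#' onset-balanced bridge lists per condition (restricted to candidates that
#' have at least one usable terminus neighbor, so the neighbor construction
#' cannot strand a bridge word), builds the matched terminus lists, splits the
#' meaning norms into matched A/B lists, and pairs meanings with items.
#'
#' @param lex Reference `lexicon` (one shared word length).
#' @param pronunciations Transcription table covering the lexicon.
#' @param norms Meaning norm table (see [split_meanings()]); needs
#'   `2 * k` rows.
#' @param template A `stim_template`.
#' @param n_candidates Number of generated candidates (study: 10,000).
#' @param k List size per role and condition (study: 48).
#' @param high_pct,low_pct Similarity threshold percentiles.
#' @param seed Master seed; fanned out to per-stage seeds.
#' @param max_iters Rejection-sampling cap for matching constraints.
#' @return A `stimulus_design`: list with `familiar` and `unfamiliar` stimulus
#'   data frames (2k rows each: bridge + terminus, with meanings), `model`,
#'   `norms`, and a `report` (matching p-values, iterations, bigram-overlap
#'   counts, seed).
#' @export
design_stimuli <- function(lex, pronunciations, norms,
                           template = cvcvc_template(), n_candidates = 10000,
                           k = 48, high_pct = 20, low_pct = 99, seed = 1,
                           max_iters = 10000) {
  if (nrow(norms) != 2 * k)
    stop("need exactly ", 2 * k, " meaning norms, got ", nrow(norms))
  seeds <- fan_out_seeds(seed, c("candidates", "bridge_f", "bridge_u",
                                 "terminus", "meanings", "pairing"))
  model <- similarity_model(lex, pronunciations, high_pct, low_pct)
  cand <- generate_candidates(n_candidates, template, lex, seeds["candidates"])
  scored <- composite_similarity(cand, model)

  # restrict bridge eligibility to candidates with >= 1 usable terminus
  # neighbor; otherwise the distinct-bridge bijection can be unsatisfiable
  eligible <- scored[scored$composite > model$high_threshold |
                       scored$composite < model$low_threshold, , drop = FALSE]
  nb_list <- lapply(eligible$form, function(f)
    setdiff(substitution_neighbors(f, template), lex$word))
  all_nb <- unlist(nb_list)
  usable_nb <- unique(all_nb)
  nb_ok <- stats::setNames(
    composite_similarity(usable_nb, model)$composite < model$low_threshold,
    usable_nb)
  has_any <- vapply(nb_list, function(nb) length(nb) > 0 && any(nb_ok[nb]),
                    logical(1))
  bridgeable <- eligible[has_any, , drop = FALSE]

  # rejection sampling extends to the bridge draw: the duplicate-neighbor
  # exclusion can strand a selected bridge word, in which case the bridge
  # lists are redrawn with advanced seeds
  term <- NULL
  for (round in 0:9) {
    bridge_f <- select_bridge_list(bridgeable, model, "Familiar", k,
                                   seeds["bridge_f"] + round, template)
    bridge_u <- select_bridge_list(bridgeable, model, "Unfamiliar", k,
                                   seeds["bridge_u"] + round, template)
    term <- tryCatch(
      build_terminus_lists(bridge_f, bridge_u, model, lex, template, k,
                           seeds["terminus"] + round, max_iters),
      error = function(e) e)
    if (!inherits(term, "error")) break
  }
  if (inherits(term, "error")) stop(term)
  split <- split_meanings(norms, seeds["meanings"], alpha = 0.05,
                          max_iters = max_iters)

  assemble <- function(bridge, terminus, perm) {
    bridge$neighbor_form <- NA_character_
    cols <- c("condition", "role", "form", "neighbor_form", "mean_bigram_p",
              "mean_biphone_p", "z_ortho", "z_phono", "composite")
    out <- rbind(bridge[, cols], terminus[, cols])
    # itemwise meaning slots: row i of each role takes the i-th word of the
    # permuted A and B lists; counterbalancing resolves which applies
    a <- split$listA$word[perm$a]
    b <- split$listB$word[perm$b]
    out$meaning_listA <- c(a, a)[seq_len(nrow(out))]
    out$meaning_listB <- c(b, b)[seq_len(nrow(out))]
    rownames(out) <- NULL
    out
  }
  perms <- with_seed(seeds["pairing"], list(
    f = list(a = sample.int(k), b = sample.int(k)),
    u = list(a = sample.int(k), b = sample.int(k))))
  fam <- assemble(bridge_f, term$familiar, perms$f)
  unf <- assemble(bridge_u, term$unfamiliar, perms$u)

  overlap <- c(
    familiar_bridge = bigram_overlap_count(fam$form[fam$role == "bridge"],
                                           fam$meaning_listA[fam$role == "bridge"]) +
      bigram_overlap_count(fam$form[fam$role == "bridge"],
                           fam$meaning_listB[fam$role == "bridge"]),
    unfamiliar_bridge = bigram_overlap_count(unf$form[unf$role == "bridge"],
                                             unf$meaning_listA[unf$role == "bridge"]) +
      bigram_overlap_count(unf$form[unf$role == "bridge"],
                           unf$meaning_listB[unf$role == "bridge"]),
    familiar_terminus = bigram_overlap_count(fam$form[fam$role == "terminus"],
                                             fam$meaning_listA[fam$role == "terminus"]) +
      bigram_overlap_count(fam$form[fam$role == "terminus"],
                           fam$meaning_listB[fam$role == "terminus"]),
    unfamiliar_terminus = bigram_overlap_count(unf$form[unf$role == "terminus"],
                                               unf$meaning_listA[unf$role == "terminus"]) +
      bigram_overlap_count(unf$form[unf$role == "terminus"],
                           unf$meaning_listB[unf$role == "terminus"]))

  structure(list(
    familiar = fam, unfamiliar = unf, model = model, norms = norms,
    template = template,
    report = list(matching_p_values = term$p_values,
                  terminus_iterations = term$iterations,
                  meaning_p_values = split$p_values,
                  meaning_iterations = split$iterations,
                  bigram_overlap = overlap,
                  seed = seed, k = k, n_candidates = n_candidates)),
    class = "stimulus_design")
}

#' Write a stimulus design to CSV files
#'
#' One comma-separated file per condition with columns `condition`, `role`,
#' `form`, `neighbor_form`, `meaning_listA`, `meaning_listB`,
#' `composite_score`, `z_ortho`, `z_phono`, in deterministic row order, plus a
#' JSON constraint report.
#'
#' @param design A `stimulus_design`.
#' @param dir Output directory (created if absent).
#' @return Character vector of file paths, invisibly.
#' @export
write_stimulus_design <- function(design, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  out <- character(0)
  for (cond in c("familiar", "unfamiliar")) {
    df <- design[[cond]]
    df$composite_score <- df$composite
    df <- df[, c("condition", "role", "form", "neighbor_form", "meaning_listA",
                 "meaning_listB", "composite_score", "z_ortho", "z_phono")]
    path <- file.path(dir, paste0(cond, "_stimuli.csv"))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    out <- c(out, path)
  }
  report_path <- file.path(dir, "constraint_report.json")
  jsonlite::write_json(design$report, report_path, auto_unbox = TRUE, digits = NA)
  invisible(c(out, report_path))
}
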