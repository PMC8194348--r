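#' Load a reference lexicon
#'
#' Reads a SUBTLEX-style tab-separated lexicon with columns `word` and
#' `freq_per_million` (and optionally `zipf`). Words are lower-cased,
#' non-alphabetic entries dropped, and duplicate words collapsed keeping the
#' maximum frequency. Optional filters restrict word length and minimum
#' frequency-per-million (the reference set for similarity scoring is typically
#' all 5-letter words at 0.33 per million or more).
#'
#' @param path Path to a tab-separated file with a header row.
#' @param length_filter Optional integer; keep only words of this length.
#' @param min_freq Optional minimum `freq_per_million` (inclusive).
#' @return A `lexicon`: data frame with columns `word`, `freq_per_million`,
#'   `zipf`, ordered by word. The zipf value is `log10` frequency per billion
#'   (`log10(freq_per_million) + 3`) when not supplied in the file.
#' @export
load_lexicon <- function(path, length_filter = NULL, min_freq = NULL) {
  if (!file.exists(path)) stop("lexicon file not found: ", path)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("word", "freq_per_million")
  miss <- setdiff(required, names(raw))
  if (length(miss))
    stop("lexicon file is missing required column(s): ", paste(miss, collapse = ", "))
  df <- data.frame(
    word = tolower(trimws(as.character(raw$word))),
    freq_per_million = as.numeric(raw$freq_per_million),
    stringsAsFactors = FALSE
  )
  df$zipf <- if ("zipf" %in% names(raw)) as.numeric(raw$zipf) else
    log10(df$freq_per_million) + 3
  df <- df[grepl("^[a-z]+$", df$word) & !is.na(df$freq_per_million) &
             df$freq_per_million >= 0, , drop = FALSE]
  # collapse duplicates keeping max frequency
  df <- df[order(df$word, -df$freq_per_million), , drop = FALSE]
  df <- df[!duplicated(df$word), , drop = FALSE]
  if (!is.null(length_filter)) df <- df[nchar(df$word) == length_filter, , drop = FALSE]
  if (!is.null(min_freq)) df <- df[df$freq_per_million >= min_freq, , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("lexicon", "data.frame"),
            length_filter = length_filter, min_freq = min_freq)
}

#' Build a lexicon object from vectors
#'
#' Programmatic counterpart of [load_lexicon()] for lexicons constructed in
#' code (tests, simulation).
#'
#' @param word Character vector of lowercase alphabetic words.
#' @param freq_per_million Non-negative numeric vector.
#' @return A `lexicon` data frame.
#' @export
lexicon <- function(word, freq_per_million) {
  stopifnot(length(word) == length(freq_per_million))
  word <- tolower(word)
  if (any(!grepl("^[a-z]+$", word))) stop("words must be non-empty and letters only")
  if (any(freq_per_million < 0)) stop("freq_per_million must be non-negative")
  if (anyDuplicated(word)) stop("duplicate words in lexicon")
  df <- data.frame(word = word, freq_per_million = freq_per_million,
                   zipf = log10(pmax(freq_per_million, .Machine$double.xmin)) + 3,
                   stringsAsFactors = FALSE)
  df <- df[order(df$word), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("lexicon", "data.frame"))
}

#' Load a pronunciation table
#'
#' Reads a tab-separated two-column table mapping word forms to transcriptions
#' in an ASCII phone alphabet (X-SAMPA-like). Transcriptions are treated as
#' sequences of phone symbols; with the default empty delimiter every character
#' is one phone.
#'
#' @param path Path to a tab-separated file with columns `word`,
#'   `transcription`.
#' @return Named character vector (names are lower-cased words).
#' @export
load_pronunciations <- function(path) {
  if (!file.exists(path)) stop("pronunciation file not found: ", path)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(c("word", "transcription"), names(raw))
  if (length(miss))
    stop("pronunciation file is missing required column(s): ",
         paste(miss, collapse = ", "))
  stats::setNames(as.character(raw$transcription), tolower(as.character(raw$word)))
}

#' Rule-based fallback transcription
#'
#' Deterministic one-phone-per-letter transcription: each letter is its own
#' ASCII phone symbol. Used for pseudoword candidates that have no entry in a
#' pronunciation table, and by the synthetic-lexicon generator. This is a
#' transparent stand-in for a grapheme-to-phoneme system; it preserves the
#' pipeline's structure (separate orthographic and phonological channels with
#' different positional conventions) rather than any phonetic detail.
#'
#' @param forms Character vector of word forms.
#' @return Named character vector of transcriptions.
#' @export
rule_based_transcription <- function(forms) {
  stats::setNames(tolower(forms), tolower(forms))
}

# split transcriptions into phone sequences
split_phones <- function(transcriptions, phone_delim = "") {
  if (identical(phone_delim, "")) strsplit(transcriptions, "", fixed = TRUE)
  else strsplit(transcriptions, phone_delim, fixed = TRUE)
}

# look up transcriptions for forms; fall back to rule-based when allowed
get_transcriptions <- function(forms, pronunciations = NULL, fallback = FALSE) {
  forms <- tolower(forms)
  if (is.null(pronunciations)) {
    if (!fallback) stop("no pronunciation table given")
    return(rule_based_transcription(forms))
  }
  tr <- unname(pronunciations[forms])
  if (anyNA(tr)) {
    missing <- forms[is.na(tr)]
    if (fallback) tr[is.na(tr)] <- missing
    else stop("no transcription for word(s): ",
              paste(utils::head(missing, 5), collapse = ", "))
  }
  if (any(!nzchar(tr))) stop("empty transcription for word(s): ",
                             paste(utils::head(forms[!nzchar(tr)], 5), collapse = ", "))
  stats::setNames(tr, forms)
}

#' Fit a position-specific bigram probability model
#'
#' Token-weighted (Vitevitch & Luce style) positional bigram probabilities:
#' for each adjacent-letter position `i` and letter pair `b`, the probability
#' is the summed `freq_per_million` of lexicon words carrying `b` at position
#' `i`, divided by the total frequency mass. Probabilities at each position sum
#' to one over observed pairs.
#'
#' @param lex A `lexicon` whose words all share one length >= 2.
#' @return A `bigram_model`: list with `length`, `tables` (one named numeric
#'   vector per position), and `total_token_mass`.
#' @export
fit_bigram_model <- function(lex) {
  if (nrow(lex) == 0) stop("cannot fit bigram model on an empty lexicon")
  L <- unique(nchar(lex$word))
  if (length(L) != 1) stop("mixed word lengths in lexicon: ",
                           paste(sort(L), collapse = ", "))
  if (L < 2) stop("words must have length >= 2")
  tot <- sum(lex$freq_per_million)
  if (tot <= 0) stop("total token mass must be positive")
  tables <- lapply(seq_len(L - 1), function(i) {
    pair <- substring(lex$word, i, i + 1)
    v <- tapply(lex$freq_per_million, pair, sum) / tot
    v <- v[order(names(v))]
    stats::setNames(as.numeric(v), names(v))
  })
  structure(list(length = L, tables = tables, total_token_mass = tot),
            class = "bigram_model")
}

#' Fit a position-independent biphone probability model
#'
#' Token-weighted probabilities of adjacent phone pairs, pooled over positions
#' (transcription lengths vary, so positional tables are not well defined).
#' Each occurrence of a phone pair in a word's transcription contributes that
#' word's `freq_per_million`; the table is normalized over all adjacent phone
#' pairs in the reference set.
#'
#' @param lex A `lexicon`.
#' @param pronunciations Named character vector (see [load_pronunciations()]).
#' @param phone_delim Phone separator inside transcriptions; `""` means one
#'   character per phone.
#' @return A `biphone_model`: list with `table` (named numeric, names
#'   `"p1 p2"`), `phone_delim`, and `total_token_mass`.
#' @export
fit_biphone_model <- function(lex, pronunciations, phone_delim = "") {
  if (nrow(lex) == 0) stop("cannot fit biphone model on an empty lexicon")
  tr <- get_transcriptions(lex$word, pronunciations)
  phones <- split_phones(unname(tr), phone_delim)
  npairs <- lengths(phones) - 1L
  if (any(npairs < 1)) stop("transcription with fewer than two phones for word(s): ",
                            paste(utils::head(lex$word[npairs < 1], 5), collapse = ", "))
  keys <- unlist(lapply(phones, function(p) {
    paste(p[-length(p)], p[-1])
  }))
  w <- rep(lex$freq_per_million, npairs)
  tot <- sum(w)
  if (tot <= 0) stop("total token mass must be positive")
  v <- tapply(w, keys, sum) / tot
  v <- v[order(names(v))]
  structure(list(table = stats::setNames(as.numeric(v), names(v)),
                 phone_delim = phone_delim, total_token_mass = tot),
            class = "biphone_model")
}

#' Mean positional bigram probability of word forms
#'
#' Arithmetic mean of the positional bigram probabilities over a form's
#' adjacent-letter pairs; pairs never observed at a position contribute zero.
#'
#' @param forms Character vector, each of the model's word length.
#' @param model A `bigram_model`.
#' @return Numeric vector of mean probabilities.
#' @export
mean_bigram_probability <- function(forms, model) {
  forms <- tolower(forms)
  if (any(nchar(forms) != model$length))
    stop("form length must equal model length (", model$length, ")")
  L <- model$length
  acc <- numeric(length(forms))
  for (i in seq_len(L - 1)) {
    p <- model$tables[[i]][substring(forms, i, i + 1)]
    p[is.na(p)] <- 0
    acc <- acc + p
  }
  unname(acc / (L - 1))
}

#' Mean biphone probability of word forms
#'
#' Mean of the position-independent biphone probabilities over the adjacent
#' phone pairs of each form's transcription; unseen pairs contribute zero.
#'
#' @param forms Character vector of forms.
#' @param model A `biphone_model`.
#' @param pronunciations Optional named transcription table; forms missing from
#'   it (or a `NULL` table) use [rule_based_transcription()].
#' @return Numeric vector of mean probabilities.
#' @export
mean_biphone_probability <- function(forms, model, pronunciations = NULL) {
  tr <- get_transcriptions(forms, pronunciations, fallback = TRUE)
  phones <- split_phones(unname(tr), model$phone_delim)
  vapply(phones, function(p) {
    if (length(p) < 2) return(0)
    keys <- paste(p[-length(p)], p[-1])
    v <- model$table[keys]
    v[is.na(v)] <- 0
    mean(v)
  }, numeric(1))
}

#' Percentile thresholds on a descending similarity ranking
#'
#' Reference scores are rank-ordered from most to least similar; the threshold
#' at percentile `p` is the score at rank `ceiling(p/100 * N)`. Scores above
#' the high threshold are more similar than all but the top `high_pct` percent
#' of reference words; scores below the low threshold are less similar than
#' `low_pct` percent of them. Rank ties are resolved by the sorted score value
#' itself, so equal scores give equal thresholds.
#'
#' @param reference_scores Non-empty numeric vector.
#' @param high_pct,low_pct Percent values with `0 < high_pct < low_pct <= 100`.
#' @return Named numeric vector `c(high_threshold =, low_threshold =)`.
#' @export
percentile_thresholds <- function(reference_scores, high_pct = 20, low_pct = 99) {
  if (length(reference_scores) == 0) stop("reference scores must be non-empty")
  if (!(high_pct > 0 && high_pct < low_pct && low_pct <= 100))
    stop("need 0 < high_pct < low_pct <= 100")
  s <- sort(reference_scores, decreasing = TRUE)
  n <- length(s)
  at <- function(p) s[max(1L, ceiling(p / 100 * n))]
  c(high_threshold = at(high_pct), low_threshold = at(low_pct))
}

#' Build a composite English-similarity model
#'
#' Fits the positional bigram and pooled biphone models on the reference
#' lexicon, computes each reference word's mean probabilities, the reference
#' moments used for z-transformation, and the high/low percentile thresholds on
#' the composite score (mean of the two z channels).
#'
#' @param lex Reference `lexicon` (one shared word length).
#' @param pronunciations Named transcription table covering the lexicon.
#' @param high_pct,low_pct Threshold percentiles (defaults 20 and 99).
#' @param phone_delim Phone separator (see [fit_biphone_model()]).
#' @return A `similarity_model`: list with the two probability models, the
#'   reference moments (`ref_mean_bigram`, `ref_sd_bigram`, `ref_mean_biphone`,
#'   `ref_sd_biphone`), `high_threshold`, `low_threshold`, the percentile
#'   settings, and the reference scores.
#' @export
similarity_model <- function(lex, pronunciations, high_pct = 20, low_pct = 99,
                             phone_delim = "") {
  bm <- fit_bigram_model(lex)
  pm <- fit_biphone_model(lex, pronunciations, phone_delim)
  mo <- mean_bigram_probability(lex$word, bm)
  mp <- mean_biphone_probability(lex$word, pm, pronunciations)
  ref <- list(ref_mean_bigram = mean(mo), ref_sd_bigram = stats::sd(mo),
              ref_mean_biphone = mean(mp), ref_sd_biphone = stats::sd(mp))
  if (ref$ref_sd_bigram <= 0 || ref$ref_sd_biphone <= 0)
    stop("degenerate reference: zero standard deviation in a similarity channel")
  z <- ((mo - ref$ref_mean_bigram) / ref$ref_sd_bigram +
          (mp - ref$ref_mean_biphone) / ref$ref_sd_biphone) / 2
  thr <- percentile_thresholds(z, high_pct, low_pct)
  structure(c(list(bigram_model = bm, biphone_model = pm), ref,
              list(high_threshold = unname(thr["high_threshold"]),
                   low_threshold = unname(thr["low_threshold"]),
                   high_percentile = high_pct, low_percentile = low_pct,
                   reference_scores = stats::setNames(z, lex$word))),
            class = "similarity_model")
}

#' Composite similarity scores for word forms
#'
#' z-transforms each form's mean bigram and biphone probabilities against the
#' model's reference moments and averages the two z channels.
#'
#' @param forms Character vector of forms (model word length).
#' @param model A `similarity_model`.
#' @param pronunciations Optional transcription table; missing forms fall back
#'   to [rule_based_transcription()].
#' @return Data frame with columns `form`, `mean_bigram_p`, `mean_biphone_p`,
#'   `z_ortho`, `z_phono`, `composite`.
#' @export
composite_similarity <- function(forms, model, pronunciations = NULL) {
  forms <- tolower(forms)
  mo <- mean_bigram_probability(forms, model$bigram_model)
  mp <- mean_biphone_probability(forms, model$biphone_model, pronunciations)
  z_o <- (mo - model$ref_mean_bigram) / model$ref_sd_bigram
  z_p <- (mp - model$ref_mean_biphone) / model$ref_sd_biphone
  data.frame(form = forms, mean_bigram_p = mo, mean_biphone_p = mp,
             z_ortho = z_o, z_phono = z_p, composite = (z_o + z_p) / 2,
             stringsAsFactors = FALSE)
}

#' Serialize a similarity model to JSON
#'
#' Writes the bigram tables (positions as string keys), biphone table,
#' reference moments, and thresholds in a documented JSON layout readable by
#' [read_similarity_model()].
#'
#' @param model A `similarity_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_similarity_model <- function(model, path) {
  payload <- list(
    bigram_model = list(
      length = model$bigram_model$length,
      total_token_mass = model$bigram_model$total_token_mass,
      tables = stats::setNames(
        lapply(model$bigram_model$tables, as.list),
        as.character(seq_along(model$bigram_model$tables)))
    ),
    biphone_model = list(
      phone_delim = model$biphone_model$phone_delim,
      total_token_mass = model$biphone_model$total_token_mass,
      table = as.list(model$biphone_model$table)
    ),
    ref_mean_bigram = model$ref_mean_bigram, ref_sd_bigram = model$ref_sd_bigram,
    ref_mean_biphone = model$ref_mean_biphone, ref_sd_biphone = model$ref_sd_biphone,
    high_threshold = model$high_threshold, low_threshold = model$low_threshold,
    high_percentile = model$high_percentile, low_percentile = model$low_percentile,
    reference_scores = as.list(model$reference_scores)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a similarity model from JSON
#'
#' @param path Path written by [write_similarity_model()].
#' @return A `similarity_model`.
#' @export
read_similarity_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  bm <- structure(list(length = x$bigram_model$length,
                       tables = lapply(x$bigram_model$tables, unlist),
                       total_token_mass = x$bigram_model$total_token_mass),
                  class = "bigram_model")
  pm <- structure(list(table = unlist(x$biphone_model$table),
                       phone_delim = x$biphone_model$phone_delim %||% "",
                       total_token_mass = x$biphone_model$total_token_mass),
                  class = "biphone_model")
  structure(list(bigram_model = bm, biphone_model = pm,
                 ref_mean_bigram = x$ref_mean_bigram, ref_sd_bigram = x$ref_sd_bigram,
                 ref_mean_biphone = x$ref_mean_biphone, ref_sd_biphone = x$ref_sd_biphone,
                 high_threshold = x$high_threshold, low_threshold = x$low_threshold,
                 high_percentile = x$high_percentile, low_percentile = x$low_percentile,
                 reference_scores = unlist(x$reference_scores)),
            class = "similarity_model")
}
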