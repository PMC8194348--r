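# English-like letter frequency weights (percent of running text), used by the
# synthetic lexicon and norms generators
.letter_weights <- c(
  a = 8.2, b = 1.49, c = 2.78, d = 4.25, e = 12.7, f = 2.23, g = 2.02,
  h = 6.09, i = 7.0, j = 0.15, k = 0.77, l = 4.03, m = 2.41, n = 6.75,
  o = 7.5, p = 1.93, r = 5.99, s = 6.33, t = 9.06, u = 2.8, v = 0.98,
  w = 2.36, z = 0.07)

#' Simulation configuration
#'
#' Parameters of the synthetic two-session study. Defaults reproduce the study
#' conditions: group sizes 17 (Familiar) and 21 (Unfamiliar); bridge-session
#' cell means of 34.03 and 16.16 percent; terminus accuracy generated
#' conditionally on each participant's realized bridge-knowledge category,
#' with condition-specific category means (Familiar: Known 27.60, Partly-Known
#' 24.55, Unknown 19.36; Unfamiliar: 30.75, 12.68, 16.25). The terminus
#' columns of `cell_means_pct` (22.18, 17.66) are the study's marginal means;
#' they drive generation only when `condition_on_knowledge = FALSE`. Variance
#' components are on the percent scale; the study reports none, so the
#' defaults (participant intercept 12, other components 5) are recorded
#' placeholders, not study values.
#'
#' @param n_familiar,n_unfamiliar Participants per condition.
#' @param cell_means_pct 2x2 matrix (conditions x sessions), percent.
#' @param knowledge_means_pct 2x3 matrix (conditions x Known/PartlyKnown/
#'   Unknown), percent.
#' @param sd_participant_intercept,sd_participant_slope,sd_form,sd_meaning
#'   Random-effect standard deviations, percent scale.
#' @param covariate_betas Named numeric slopes for `imageability`, `aoa`,
#'   `familiarity`, `zipf` (applied to mean-centered norms; default 0).
#' @param response_noise `"binomial"` (letters correct ~ Binomial(5, p), so
#'   simulated responses flow through the real scorer) or `"none"`
#'   (deterministic accuracy equal to the latent mean; no response strings).
#' @param condition_on_knowledge Generate terminus accuracy from the realized
#'   bridge-knowledge category (default) or from the terminus cell means.
#' @param seed Integer seed.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_familiar = 17, n_unfamiliar = 21,
                       cell_means_pct = matrix(
                         c(34.03, 16.16, 22.18, 17.66), nrow = 2,
                         dimnames = list(c("Familiar", "Unfamiliar"),
                                         c("Bridge", "Terminus"))),
                       knowledge_means_pct = matrix(
                         c(27.60, 30.75, 24.55, 12.68, 19.36, 16.25), nrow = 2,
                         dimnames = list(c("Familiar", "Unfamiliar"),
                                         c("Known", "PartlyKnown", "Unknown"))),
                       sd_participant_intercept = 12, sd_participant_slope = 5,
                       sd_form = 5, sd_meaning = 5,
                       covariate_betas = c(imageability = 0, aoa = 0,
                                           familiarity = 0, zipf = 0),
                       response_noise = c("binomial", "none"),
                       condition_on_knowledge = TRUE, seed = 1) {
  response_noise <- match.arg(response_noise)
  bad <- character(0)
  if (!(is.numeric(n_familiar) && n_familiar >= 0)) bad <- c(bad, "n_familiar")
  if (!(is.numeric(n_unfamiliar) && n_unfamiliar >= 0)) bad <- c(bad, "n_unfamiliar")
  if (!(is.matrix(cell_means_pct) && all(dim(cell_means_pct) == c(2, 2)) &&
        all(cell_means_pct >= 0 & cell_means_pct <= 100)))
    bad <- c(bad, "cell_means_pct")
  if (!(is.matrix(knowledge_means_pct) && all(dim(knowledge_means_pct) == c(2, 3)) &&
        all(knowledge_means_pct >= 0 & knowledge_means_pct <= 100)))
    bad <- c(bad, "knowledge_means_pct")
  for (nm in c("sd_participant_intercept", "sd_participant_slope", "sd_form",
               "sd_meaning")) {
    v <- get(nm)
    if (!(is.numeric(v) && length(v) == 1 && v >= 0)) bad <- c(bad, nm)
  }
  if (!all(c("imageability", "aoa", "familiarity", "zipf") %in%
             names(covariate_betas)))
    bad <- c(bad, "covariate_betas")
  if (length(bad))
    stop("invalid sim_config field(s): ", paste(bad, collapse = ", "))
  structure(list(n_familiar = n_familiar, n_unfamiliar = n_unfamiliar,
                 cell_means_pct = cell_means_pct,
                 knowledge_means_pct = knowledge_means_pct,
                 sd_participant_intercept = sd_participant_intercept,
                 sd_participant_slope = sd_participant_slope,
                 sd_form = sd_form, sd_meaning = sd_meaning,
                 covariate_betas = covariate_betas,
                 response_noise = response_noise,
                 condition_on_knowledge = condition_on_knowledge,
                 seed = seed),
            class = "sim_config")
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# build a response string realizing `letters` correct positions of `target`;
# wrong positions draw a different letter from the slot alphabet
realize_response <- function(target, letters, template) {
  correct_at <- sort(sample.int(5, letters))
  chars <- strsplit(target, "")[[1]]
  for (i in setdiff(1:5, correct_at)) {
    chars[i] <- sample(setdiff(template$slots[[i]], chars[i]), 1)
  }
  paste(chars, collapse = "")
}

#' Simulate a two-session bridge/terminus study
#'
#' Generates per-trial latent accuracy as the configured cell (or
#' bridge-knowledge) mean plus participant, session-slope, form, meaning, and
#' centered-covariate contributions, clamped to the percent scale, and draws
#' letters-correct as Binomial(5, p) so that simulated response strings pass
#' through the package's scorer. The bridge session is generated first;
#' terminus accuracy conditions on each participant's realized
#' bridge-knowledge category for the linked neighbor. Deterministic given the
#' config seed.
#'
#' @param config A `sim_config`.
#' @param design A `stimulus_design` from [design_stimuli()].
#' @return A `simulated_study`: list with `responses` (the trial-level data
#'   frame), `config`, `clamp_fraction` (share of latent means clamped), and
#'   `truth` (generating cell means from [truth_cell_means()]).
#' @export
simulate_study <- function(config, design) {
  stopifnot(inherits(config, "sim_config"), inherits(design, "stimulus_design"))
  template <- design$template %||% cvcvc_template()
  norms <- design$norms
  centered <- lapply(c("imageability", "aoa", "familiarity", "zipf"),
                     function(v) stats::setNames(norms[[v]] - mean(norms[[v]]),
                                                 norms$word))
  names(centered) <- c("imageability", "aoa", "familiarity", "zipf")
  cov_term <- Reduce(`+`, lapply(names(centered), function(v)
    config$covariate_betas[[v]] * centered[[v]]))
  cov_term <- stats::setNames(as.numeric(cov_term), norms$word)

  all_forms <- unique(c(design$familiar$form, design$unfamiliar$form))
  all_meanings <- norms$word
  n_clamped <- 0; n_latent <- 0

  rows <- with_seed(config$seed, {
    u_form <- stats::setNames(stats::rnorm(length(all_forms), 0, config$sd_form),
                              all_forms)
    u_meaning <- stats::setNames(stats::rnorm(length(all_meanings), 0,
                                              config$sd_meaning), all_meanings)
    conds <- c(rep("Familiar", config$n_familiar),
               rep("Unfamiliar", config$n_unfamiliar))
    ids <- c(sprintf("F%02d", seq_len(config$n_familiar)),
             sprintf("U%02d", seq_len(config$n_unfamiliar)))
    groups <- ((seq_along(ids) - 1L) %% 2L) + 1L
    out <- vector("list", length(ids))
    for (j in seq_along(ids)) {
      cond <- conds[j]
      stim <- assign_pairings(design[[tolower(cond)]], groups[j])
      b <- stats::rnorm(1, 0, config$sd_participant_intercept)
      s <- stats::rnorm(1, 0, config$sd_participant_slope)
      one_session <- function(rows_df, base_pct, session) {
        slope <- if (session == "Terminus") s else 0
        latent <- base_pct + b + slope + u_form[rows_df$form] +
          u_meaning[rows_df$meaning] + cov_term[rows_df$meaning]
        p <- clamp01(latent / 100)
        n_clamped <<- n_clamped + sum(latent < 0 | latent > 100)
        n_latent <<- n_latent + length(latent)
        if (config$response_noise == "binomial") {
          letters <- stats::rbinom(length(p), 5, p)
          resp <- vapply(seq_along(letters), function(i)
            realize_response(rows_df$form[i], letters[i], template), character(1))
        } else {
          letters <- NA_integer_
          resp <- NA_character_
        }
        data.frame(participant = ids[j], condition = cond,
                   counterbalance_group = groups[j], session = session,
                   form = rows_df$form, neighbor_form = rows_df$neighbor_form,
                   meaning = rows_df$meaning, target = rows_df$form,
                   response = resp, latent_pct = pmin(pmax(latent, 0), 100),
                   stringsAsFactors = FALSE)
      }
      bridge_stim <- stim[stim$role == "bridge", , drop = FALSE]
      term_stim <- stim[stim$role == "terminus", , drop = FALSE]
      bridge_rows <- one_session(bridge_stim,
                                 config$cell_means_pct[cond, "Bridge"], "Bridge")
      if (config$response_noise == "binomial") {
        sc <- score_response(bridge_rows$response, bridge_rows$target)
        bridge_letters <- stats::setNames(sc$letters_correct, bridge_rows$form)
      } else {
        bridge_letters <- NULL
      }
      if (config$condition_on_knowledge && !is.null(bridge_letters)) {
        cat_t <- knowledge_category(bridge_letters[term_stim$neighbor_form])
        base_t <- config$knowledge_means_pct[cond, as.character(cat_t)]
      } else {
        cat_t <- factor(rep(NA, nrow(term_stim)),
                        levels = c("Known", "PartlyKnown", "Unknown"))
        base_t <- rep(config$cell_means_pct[cond, "Terminus"], nrow(term_stim))
      }
      term_rows <- one_session(term_stim, base_t, "Terminus")
      bridge_rows$category <- factor(NA, levels = levels(cat_t))
      term_rows$category <- cat_t
      out[[j]] <- rbind(bridge_rows, term_rows)
    }
    do.call(rbind, out)
  })

  if (is.null(rows)) {
    rows <- data.frame(participant = character(0), condition = character(0),
                       counterbalance_group = integer(0), session = character(0),
                       form = character(0), neighbor_form = character(0),
                       meaning = character(0), target = character(0),
                       response = character(0), latent_pct = numeric(0),
                       category = factor(character(0),
                                         levels = c("Known", "PartlyKnown",
                                                    "Unknown")),
                       response_clean = character(0), score = numeric(0),
                       letters_correct = integer(0))
  } else if (config$response_noise == "binomial") {
    rows <- score_log(rows)
  } else {
    rows$response_clean <- NA_character_
    rows$score <- rows$latent_pct / 100
    rows$letters_correct <- NA_integer_
  }
  rows$accuracy <- 100 * rows$score
  nv <- c("imageability", "aoa", "familiarity", "zipf")
  rows[nv] <- norms[match(rows$meaning, norms$word), nv]
  rownames(rows) <- NULL
  structure(list(responses = rows, config = config,
                 clamp_fraction = n_clamped / max(n_latent, 1),
                 truth = truth_cell_means(config)),
            class = "simulated_study")
}

# stratified normal nodes: midpoint quantiles with equal weights
norm_nodes <- function(mean = 0, sd = 1, n = 201) {
  if (sd == 0) return(list(x = mean, w = 1))
  z <- stats::qnorm((seq_len(n) - 0.5) / n)
  list(x = mean + sd * z, w = rep(1 / n, n))
}

#' Generating cell means implied by a simulation configuration
#'
#' Computes, by numeric integration over the random-effect distributions, the
#' expected accuracy (percent) in each condition-by-session cell of data drawn
#' from [simulate_study()], together with the expected bridge-knowledge
#' category proportions. Because terminus accuracy conditions on realized
#' bridge categories, the terminus truth is a mixture of the knowledge means
#' weighted by Binomial(5, p) category probabilities and is generally not the
#' configured terminus cell mean.
#'
#' @param config A `sim_config`.
#' @param n_nodes Integration nodes per dimension.
#' @return List with `cell_means` (2x2 matrix, percent), `category_probs`
#'   (2x3 matrix), and the derived `contrasts` (similarity effect per session,
#'   session effect per condition, interaction).
#' @export
truth_cell_means <- function(config, n_nodes = 201) {
  sp <- config$sd_participant_intercept; ss <- config$sd_participant_slope
  sw <- sqrt(config$sd_form^2 + config$sd_meaning^2)
  cells <- matrix(NA_real_, 2, 2,
                  dimnames = dimnames(config$cell_means_pct))
  probs <- matrix(NA_real_, 2, 3,
                  dimnames = dimnames(config$knowledge_means_pct))
  clamp_mean <- function(mu, sd) {
    nd <- norm_nodes(0, sd, n_nodes)
    sum(nd$w * pmin(pmax(mu + nd$x, 0), 100))
  }
  for (cond in rownames(cells)) {
    sig_b <- sqrt(sp^2 + sw^2)
    cells[cond, "Bridge"] <- clamp_mean(config$cell_means_pct[cond, "Bridge"], sig_b)
    if (!config$condition_on_knowledge) {
      cells[cond, "Terminus"] <- clamp_mean(config$cell_means_pct[cond, "Terminus"],
                                            sqrt(sp^2 + ss^2 + sw^2))
      next
    }
    nb <- norm_nodes(0, sp, n_nodes)
    nw <- norm_nodes(0, sw, n_nodes)
    mu_b <- config$cell_means_pct[cond, "Bridge"]
    kappa <- config$knowledge_means_pct[cond, ]
    sv <- sqrt(ss^2 + sw^2)
    term_mean <- 0
    cat_probs <- c(Known = 0, PartlyKnown = 0, Unknown = 0)
    for (i in seq_along(nb$x)) {
      b <- nb$x[i]
      p <- clamp01((mu_b + b + nw$x) / 100)
      p_unknown <- sum(nw$w * (1 - p)^5)
      p_known <- sum(nw$w * (5 * p^4 * (1 - p) + p^5))
      p_partly <- 1 - p_unknown - p_known
      pc <- c(Known = p_known, PartlyKnown = p_partly, Unknown = p_unknown)
      cat_probs <- cat_probs + nb$w[i] * pc
      cond_means <- vapply(names(kappa), function(k)
        clamp_mean(kappa[[k]] + b, sv), numeric(1))
      term_mean <- term_mean + nb$w[i] * sum(pc * cond_means)
    }
    cells[cond, "Terminus"] <- term_mean
    probs[cond, ] <- cat_probs
  }
  contrasts <- list(
    similarity_bridge = cells["Familiar", "Bridge"] - cells["Unfamiliar", "Bridge"],
    similarity_terminus = cells["Familiar", "Terminus"] - cells["Unfamiliar", "Terminus"],
    session_familiar = cells["Familiar", "Terminus"] - cells["Familiar", "Bridge"],
    session_unfamiliar = cells["Unfamiliar", "Terminus"] - cells["Unfamiliar", "Bridge"],
    interaction = (cells["Familiar", "Terminus"] - cells["Familiar", "Bridge"]) -
      (cells["Unfamiliar", "Terminus"] - cells["Unfamiliar", "Bridge"]))
  list(cell_means = cells, category_probs = probs, contrasts = contrasts)
}

#' Generate a synthetic reference lexicon with pronunciations
#'
#' Draws unique fixed-length words on an alternating consonant-vowel template
#' with English-like letter frequencies, assigns power-law (zipf-like)
#' frequencies-per-million with multiplicative jitter, and attaches rule-based
#' one-phone-per-letter transcriptions. A stand-in for a real frequency-normed
#' lexicon plus grapheme-to-phoneme system, with enough letter-statistic
#' structure that composite similarity scores have positive variance.
#'
#' @param n_words Number of words (>= 50 recommended for stable thresholds).
#' @param length Word length (default 5).
#' @param zipf_exponent Power-law exponent of the rank-frequency curve.
#' @param seed Integer seed.
#' @return List with `lexicon` (a `lexicon` data frame) and `pronunciations`
#'   (named character vector).
#' @export
make_synthetic_lexicon <- function(n_words = 500, length = 5,
                                   zipf_exponent = 1.05, seed = 1) {
  stopifnot(n_words >= 1, length >= 2)
  template <- cvcvc_template(paste(rep(c("C", "V"), length.out = length),
                                   collapse = ""))
  cons_w <- .letter_weights[template$consonants]
  vow_w <- .letter_weights[template$vowels]
  with_seed(seed, {
    words <- character(0)
    while (base::length(words) < n_words) {
      batch <- max(1000L, 2L * (n_words - base::length(words)))
      cols <- lapply(template$slots, function(a) {
        w <- if (identical(sort(a), sort(template$consonants))) cons_w else vow_w
        sample(a, batch, replace = TRUE, prob = w[a])
      })
      words <- unique(c(words, do.call(paste0, cols)))
    }
    words <- words[seq_len(n_words)]
    fpm <- 2000 / seq_len(n_words)^zipf_exponent *
      stats::runif(n_words, 0.8, 1.25)
    lex <- lexicon(words, fpm)
    list(lexicon = lex, pronunciations = rule_based_transcription(lex$word))
  })
}

#' Generate a synthetic meaning-norm table
#'
#' Emulates a rated-norms input: half concrete, half abstract nouns with
#' imageability, age of acquisition, and familiarity drawn from class-specific
#' uniform ranges on a 100-700 rating scale (concrete imageability 450-650 vs
#' abstract 200-400; concrete AoA 150-450 vs abstract 250-550; familiarity
#' 400-650 for both) and zipf frequency from a clipped normal (mean 4, sd
#' 0.7). The ranges are recorded in the `meta` attribute. Word strings are
#' unique random letter strings of length 4-8 with English-like letter
#' frequencies.
#'
#' @param n Even number of meanings.
#' @param seed Integer seed.
#' @return Data frame with columns `word`, `imageability`, `aoa`,
#'   `familiarity`, `zipf`, `class`.
#' @export
make_synthetic_norms <- function(n = 96, seed = 1) {
  if (n %% 2 != 0) stop("n must be even (equal concrete/abstract counts)")
  meta <- list(imageability = list(concrete = c(450, 650), abstract = c(200, 400)),
               aoa = list(concrete = c(150, 450), abstract = c(250, 550)),
               familiarity = c(400, 650), zipf = list(mean = 4, sd = 0.7,
                                                      range = c(1.5, 7)))
  with_seed(seed, {
    words <- character(0)
    while (length(words) < n) {
      len <- sample(4:8, n, replace = TRUE)
      batch <- vapply(len, function(L)
        paste(sample(names(.letter_weights), L, replace = TRUE,
                     prob = .letter_weights), collapse = ""), character(1))
      words <- unique(c(words, batch))
    }
    words <- words[seq_len(n)]
    cls <- rep(c("concrete", "abstract"), each = n / 2)
    runif_by <- function(ranges) ifelse(cls == "concrete",
                                        stats::runif(n, ranges$concrete[1], ranges$concrete[2]),
                                        stats::runif(n, ranges$abstract[1], ranges$abstract[2]))
    df <- data.frame(
      word = words,
      imageability = runif_by(meta$imageability),
      aoa = runif_by(meta$aoa),
      familiarity = stats::runif(n, meta$familiarity[1], meta$familiarity[2]),
      zipf = pmin(pmax(stats::rnorm(n, meta$zipf$mean, meta$zipf$sd),
                       meta$zipf$range[1]), meta$zipf$range[2]),
      class = cls, stringsAsFactors = FALSE)
    attr(df, "meta") <- meta
    df
  })
}
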