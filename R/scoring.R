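#' Normalize a typed response
#'
#' Lower-cases, strips surrounding whitespace, transliterates diacritics where
#' the platform supports it, and removes all non-alphabetic characters.
#'
#' @param raw Character vector of raw typed responses.
#' @return Character vector of cleaned responses (possibly empty strings).
#' @export
normalize_response <- function(raw) {
  x <- tolower(trimws(as.character(raw)))
  ascii <- suppressWarnings(iconv(x, from = "UTF-8", to = "ASCII//TRANSLIT"))
  x[!is.na(ascii)] <- ascii[!is.na(ascii)]
  gsub("[^a-z]", "", x)
}

#' Positional partial-credit scoring
#'
#' Each correct letter in the correct position scores 0.2 points, for a
#' maximum of 1 on a five-letter target. Responses shorter than the target are
#' scored on the positions they cover; responses longer than the target are
#' scored on their first five positions.
#'
#' @param response Character vector of (normalized) responses.
#' @param target Character vector of 5-letter targets (recycled if scalar).
#' @return Data frame with columns `score` (in \{0, 0.2, ..., 1\}) and
#'   `letters_correct` (0-5).
#' @export
score_response <- function(response, target) {
  if (length(target) == 1) target <- rep(target, length(response))
  stopifnot(length(response) == length(target))
  if (any(nchar(target) != 5)) stop("targets must have exactly 5 letters")
  response <- tolower(as.character(response))
  target <- tolower(target)
  letters_correct <- integer(length(response))
  for (i in 1:5) {
    m <- nchar(response) >= i & substring(response, i, i) == substring(target, i, i)
    letters_correct <- letters_correct + as.integer(m)
  }
  data.frame(score = 0.2 * letters_correct, letters_correct = letters_correct)
}

#' Bridge-knowledge category from letters correct
#'
#' @param letters_correct Integer vector 0-5.
#' @return Factor with levels `Known` (4-5 letters), `PartlyKnown` (1-3),
#'   `Unknown` (0).
#' @export
knowledge_category <- function(letters_correct) {
  stopifnot(all(letters_correct %in% 0:5))
  factor(ifelse(letters_correct >= 4, "Known",
                ifelse(letters_correct >= 1, "PartlyKnown", "Unknown")),
         levels = c("Known", "PartlyKnown", "Unknown"))
}

#' Categorize terminus items by bridge-word knowledge
#'
#' For each participant and terminus item, looks up how well that participant
#' learned the linked bridge word in the prior session and assigns the
#' Known (4-5 letters correct), Partly-Known (1-3), or Unknown (0) category.
#' Categories are assigned individually per participant, so category counts
#' are generally unbalanced.
#'
#' @param bridge_records Data frame of scored bridge-session records with
#'   columns `participant`, `form`, `letters_correct`.
#' @param neighbor_map Data frame with columns `terminus_form`, `bridge_form`.
#' @return Data frame with `participant`, `terminus_form`, `bridge_form`,
#'   `source_letters_correct`, `category`.
#' @export
categorize_bridge_knowledge <- function(bridge_records, neighbor_map) {
  stopifnot(all(c("participant", "form", "letters_correct") %in% names(bridge_records)),
            all(c("terminus_form", "bridge_form") %in% names(neighbor_map)))
  participants <- unique(bridge_records$participant)
  out <- do.call(rbind, lapply(participants, function(p) {
    rec <- bridge_records[bridge_records$participant == p, , drop = FALSE]
    idx <- match(neighbor_map$bridge_form, rec$form)
    if (anyNA(idx)) {
      bad <- neighbor_map$terminus_form[is.na(idx)][1]
      stop("terminus form '", bad, "' has no scored bridge record for ",
           "participant ", p)
    }
    data.frame(participant = p,
               terminus_form = neighbor_map$terminus_form,
               bridge_form = neighbor_map$bridge_form,
               source_letters_correct = rec$letters_correct[idx],
               stringsAsFactors = FALSE)
  }))
  out$category <- knowledge_category(out$source_letters_correct)
  rownames(out) <- NULL
  out
}

#' Condition-by-category contingency table
#'
#' Counts and row percentages of bridge-knowledge categories per condition
#' (the study's Table-1 layout); row percentages sum to 100.
#'
#' @param categories Data frame with columns `category` and the grouping
#'   column.
#' @param by Name of the grouping column (default `"condition"`).
#' @return A `category_table`: list with integer matrix `counts` and numeric
#'   matrix `percent` (rows = groups, columns = categories).
#' @export
category_table <- function(categories, by = "condition") {
  if (nrow(categories) == 0) {
    empty <- matrix(numeric(0), nrow = 0, ncol = 3,
                    dimnames = list(NULL, c("Known", "PartlyKnown", "Unknown")))
    return(structure(list(counts = empty, percent = empty),
                     class = "category_table"))
  }
  cat_f <- factor(categories$category, levels = c("Known", "PartlyKnown", "Unknown"))
  counts <- table(categories[[by]], cat_f)
  counts <- matrix(as.integer(counts), nrow = nrow(counts),
                   dimnames = unname(dimnames(counts)))
  percent <- 100 * counts / rowSums(counts)
  structure(list(counts = counts, percent = percent), class = "category_table")
}

#' Score a raw response log
#'
#' Normalizes responses and applies positional scoring against the `target`
#' column, adding `response_clean`, `score`, and `letters_correct` columns.
#'
#' @param log_df Data frame with at least `target` and `response` columns.
#' @return The data frame with scoring columns appended.
#' @export
score_log <- function(log_df) {
  stopifnot(all(c("target", "response") %in% names(log_df)))
  clean <- normalize_response(log_df$response)
  sc <- score_response(clean, log_df$target)
  log_df$response_clean <- clean
  log_df$score <- sc$score
  log_df$letters_correct <- sc$letters_correct
  log_df
}
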