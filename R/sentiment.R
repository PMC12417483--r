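#' Load a word-score sentiment lexicon
#'
#' Reads a Boson-style lexicon: UTF-8, TAB-separated `word<TAB>score` lines,
#' `#` comments allowed. When a token appears more than once the later entry
#' overwrites the earlier one and a warning reports how many were overwritten.
#'
#' @param path File path.
#' @return A tibble with columns `word` (NFC-normalized, unique) and `score`
#'   (double), class `"sentiment_lexicon"`.
#' @examples
#' f <- tempfile()
#' writeLines(c("good\t2.0", "bad\t-3.0"), f)
#' load_lexicon(f)
#' @export
load_lexicon <- function(path) {
  if (!file.exists(path)) abort_input(paste0("lexicon file not found: ", path))
  lines <- readr::read_lines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0) {
    warning("empty lexicon: ", path)
    out <- tibble(word = character(0), score = double(0))
    class(out) <- c("sentiment_lexicon", class(out))
    return(out)
  }
  parts <- stringi::stri_split_fixed(lines[idx], "\t")
  words <- character(length(idx))
  scores <- double(length(idx))
  for (i in seq_along(idx)) {
    p <- parts[[i]]
    sc <- if (length(p) >= 2) suppressWarnings(as.numeric(p[2])) else NA_real_
    if (length(p) < 2 || is.na(sc) || !is.finite(sc) || trimws(p[1]) == "") {
      abort_input(paste0("malformed lexicon line ", idx[i], ": '", lines[idx[i]], "'"))
    }
    words[i] <- stringi::stri_trans_nfc(trimws(p[1]))
    scores[i] <- sc
  }
  dup <- duplicated(words, fromLast = TRUE)
  if (any(dup)) {
    warning(sum(dup), " duplicate lexicon token(s) overwritten by later entries")
  }
  out <- tibble(word = words[!dup], score = scores[!dup])
  class(out) <- c("sentiment_lexicon", class(out))
  out
}

#' Build a lexicon from a data frame
#'
#' For lexicons constructed in code (e.g. by [make_complaint_corpus()]).
#' Later duplicates overwrite earlier entries, as in [load_lexicon()].
#'
#' @param df Data frame with columns `word` and `score`.
#' @return A `"sentiment_lexicon"` tibble.
#' @export
as_lexicon <- function(df) {
  stopifnot(all(c("word", "score") %in% names(df)))
  words <- stringi::stri_trans_nfc(as.character(df$word))
  dup <- duplicated(words, fromLast = TRUE)
  out <- tibble(word = words[!dup], score = as.numeric(df$score)[!dup])
  class(out) <- c("sentiment_lexicon", class(out))
  out
}

lexicon_lookup <- function(lexicon) {
  stats::setNames(lexicon$score, lexicon$word)
}

#' Score tokens against the lexicon
#'
#' A token found in the lexicon gets its lexicon score; any token absent from
#' the lexicon scores exactly 0. Matching is exact string equality after NFC
#' normalization — no stemming, negation handling or degree adverbs.
#'
#' @param token Character vector of tokens.
#' @param lexicon A `"sentiment_lexicon"` tibble.
#' @return Numeric vector of per-token scores.
#' @export
score_token <- function(token, lexicon) {
  if (length(token) == 0) {
    return(double(0))
  }
  lk <- lexicon_lookup(lexicon)
  s <- unname(lk[stringi::stri_trans_nfc(token)])
  s[is.na(s)] <- 0
  s
}

polarity_of <- function(score) {
  ifelse(score > 0, "positive", ifelse(score < 0, "negative", "neutral"))
}

#' Score one document
#'
#' The document score is the plain cumulative sum of its tokens' lexicon
#' scores; every occurrence of a token scores (no deduplication). Polarity is
#' positive for score > 0, negative for score < 0, neutral for exactly 0
#' (an empty document is neutral with score 0).
#'
#' @param tokens Character vector of tokens.
#' @param lexicon A `"sentiment_lexicon"` tibble.
#' @return One-row tibble: `score`, `polarity`.
#' @export
score_document <- function(tokens, lexicon) {
  s <- sum(score_token(tokens, lexicon))
  tibble(score = s, polarity = polarity_of(s))
}

#' Score a tokenized corpus
#'
#' @param records Tibble with a `tokens` list-column (see
#'   [preprocess_corpus()]) and a `record_id` column.
#' @param lexicon A `"sentiment_lexicon"` tibble.
#' @return Tibble: `record_id`, `score`, `polarity`.
#' @export
score_corpus <- function(records, lexicon) {
  lk <- lexicon_lookup(lexicon)
  scores <- purrr::map_dbl(records$tokens, function(toks) {
    if (length(toks) == 0) {
      return(0)
    }
    s <- lk[stringi::stri_trans_nfc(toks)]
    sum(s, na.rm = TRUE)
  })
  tibble(
    record_id = records$record_id,
    score = scores,
    polarity = polarity_of(scores)
  )
}

#' Polarity distribution of scored documents
#'
#' Counts and proportions of positive (> 0), negative (< 0) and neutral (= 0)
#' documents, in that fixed order.
#'
#' @param results Tibble with a `polarity` column (from [score_corpus()]) or a
#'   numeric vector of scores.
#' @return Tibble: `polarity`, `n`, `proportion` (three rows summing to 1).
#' @export
polarity_distribution <- function(results) {
  pol <- if (is.numeric(results)) {
    polarity_of(results)
  } else {
    results$polarity
  }
  if (length(pol) == 0) abort_input("polarity_distribution needs at least one document")
  lev <- c("positive", "negative", "neutral")
  n <- vapply(lev, function(l) sum(pol == l), integer(1))
  tibble(polarity = factor(lev, levels = lev), n = unname(n), proportion = unname(n) / length(pol))
}
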