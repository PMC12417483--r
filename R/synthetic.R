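# All generators are pure functions of (spec, seed): each scopes the RNG with
# its own offset from the spec seed, so adding a generator (or reordering
# calls) never perturbs fixtures produced by another one.
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed %% .Machine$integer.max)
  force(code)
}

#' Specification for a planted-blob point cloud
#'
#' @param centers Numeric matrix, one center per row (>= 2 rows).
#' @param points_per_center Points drawn around each center.
#' @param sigma Isotropic Gaussian standard deviation (> 0).
#' @param seed Integer seed.
#' @return A list of class `"blob_spec"`.
#' @export
blob_spec <- function(centers, points_per_center = 15L, sigma = 0.05, seed = 1L) {
  centers <- as.matrix(centers)
  if (nrow(centers) < 2) abort_config("blob_spec needs >= 2 centers")
  if (sigma <= 0) abort_config("sigma must be > 0")
  structure(
    list(
      centers = centers, points_per_center = as.integer(points_per_center),
      sigma = sigma, seed = as.integer(seed)
    ),
    class = "blob_spec"
  )
}

#' Generate an isotropic Gaussian blob mixture with known labels
#'
#' Draws `points_per_center` i.i.d. Gaussian points around each center.
#' Deterministic for a fixed spec: two calls return bit-identical output.
#' Cluster-recovery tests are meaningful when `sigma` is at most about a
#' tenth of the smallest center separation.
#'
#' @param spec A [blob_spec()].
#' @return List: `points` (matrix), `labels` (integer ground-truth blob ids,
#'   1-based).
#' @export
make_blobs <- function(spec) {
  stopifnot(inherits(spec, "blob_spec"))
  with_local_seed(spec$seed + 101L, {
    k <- nrow(spec$centers)
    d <- ncol(spec$centers)
    pts <- do.call(rbind, lapply(seq_len(k), function(i) {
      matrix(rnorm(spec$points_per_center * d, sd = spec$sigma),
        ncol = d
      ) + matrix(spec$centers[i, ], spec$points_per_center, d, byrow = TRUE)
    }))
    list(points = pts, labels = rep(seq_len(k), each = spec$points_per_center))
  })
}

default_topics <- function() {
  list(
    service = list(
      keywords = c(
        "rude", "attitude", "ignored", "queue", "crowded",
        "dirty", "noisy", "unhelpful"
      ),
      sentiment = c(
        terrible = -4, awful = -3, angry = -3, disappointed = -2, unacceptable = -4
      )
    ),
    care = list(
      keywords = c(
        "nurse", "recovery", "surgery", "ward", "medication",
        "therapy", "checkup", "discharge"
      ),
      sentiment = c(
        excellent = 4, professional = 3, thankful = 3, satisfied = 2, kind = 2
      )
    )
  )
}

default_stoplist <- function() {
  c("the", "a", "an", "of", "to", "and", "in", "was", "is", "at")
}

#' Specification for a synthetic complaint corpus
#'
#' Each topic is a disjoint keyword vocabulary paired with a pool of
#' sentiment words carrying known integer lexicon scores; a document samples
#' keywords from its topic, sentiment words from its topic's pool, and shared
#' stop-words. The defaults plant one negative topic (service complaints)
#' and one positive topic (care praise) so the planted negative vocabulary is
#' recoverable downstream.
#'
#' @param n_docs Number of documents.
#' @param topics Named list; each element has `keywords` (character) and
#'   `sentiment` (named numeric scores). Keyword sets must be pairwise
#'   disjoint.
#' @param mixing Topic mixing proportions (sums to 1).
#' @param tokens_per_doc Range (min, max) of topic-keyword tokens per
#'   document.
#' @param sentiment_per_doc Range of sentiment tokens per document.
#' @param stopwords_per_doc Range of stop-word tokens per document.
#' @param stoplist Shared stop-words.
#' @param seed Integer seed.
#' @return A list of class `"corpus_spec"`.
#' @export
corpus_spec <- function(n_docs = 60L, topics = default_topics(),
                        mixing = NULL, tokens_per_doc = c(6L, 12L),
                        sentiment_per_doc = c(2L, 4L),
                        stopwords_per_doc = c(1L, 3L),
                        stoplist = default_stoplist(), seed = 1L) {
  if (is.null(mixing)) mixing <- rep(1 / length(topics), length(topics))
  if (abs(sum(mixing) - 1) > 1e-8) abort_config("mixing proportions must sum to 1")
  if (length(mixing) != length(topics)) abort_config("one mixing proportion per topic")
  kw <- lapply(topics, `[[`, "keywords")
  if (any(duplicated(unlist(kw)))) abort_config("topic keyword sets must be pairwise disjoint")
  structure(
    list(
      n_docs = as.integer(n_docs), topics = topics, mixing = mixing,
      tokens_per_doc = as.integer(tokens_per_doc),
      sentiment_per_doc = as.integer(sentiment_per_doc),
      stopwords_per_doc = as.integer(stopwords_per_doc),
      stoplist = stoplist, seed = as.integer(seed)
    ),
    class = "corpus_spec"
  )
}

#' Generate a complaint corpus with planted topics and known sentiment
#'
#' @param spec A [corpus_spec()].
#' @return List:
#'   * `records` — tibble `record_id`, `date`, `channel`, `raw_text`
#'     (compatible with [preprocess_corpus()]);
#'   * `lexicon` — toy `"sentiment_lexicon"` covering every planted
#'     sentiment word (integer scores, so document scores are exact);
#'   * `stoplist` — the shared stop-words;
#'   * `topic` — integer ground-truth topic id per document;
#'   * `topic_names` — id-to-name map;
#'   * `true_score` — the closed-form document score (sum of the sampled
#'     sentiment words' lexicon scores);
#'   * `true_polarity` — sign-rule polarity of `true_score`.
#' @export
make_complaint_corpus <- function(spec) {
  stopifnot(inherits(spec, "corpus_spec"))
  with_local_seed(spec$seed + 211L, {
    n <- spec$n_docs
    n_topics <- length(spec$topics)
    topic <- sample.int(n_topics, n, replace = TRUE, prob = spec$mixing)
    rint <- function(range) sample(seq(range[1], range[2]), 1)
    docs <- vector("list", n)
    true_score <- numeric(n)
    for (i in seq_len(n)) {
      tp <- spec$topics[[topic[i]]]
      kws <- sample(tp$keywords, rint(spec$tokens_per_doc), replace = TRUE)
      sent <- sample(names(tp$sentiment), rint(spec$sentiment_per_doc), replace = TRUE)
      stops <- sample(spec$stoplist, rint(spec$stopwords_per_doc), replace = TRUE)
      toks <- sample(c(kws, sent, stops))
      docs[[i]] <- toks
      true_score[i] <- sum(tp$sentiment[sent])
    }
    dates <- format(
      as.Date("2023-01-01") + sample.int(730, n, replace = TRUE) - 1, "%Y-%m-%d"
    )
    lex <- as_lexicon(tibble(
      word = unlist(lapply(spec$topics, function(t) names(t$sentiment))),
      score = unlist(lapply(spec$topics, function(t) unname(t$sentiment)))
    ))
    list(
      records = tibble(
        record_id = sprintf("c%04d", seq_len(n)),
        date = dates,
        channel = sample(c("internal", "external"), n, replace = TRUE),
        raw_text = vapply(docs, paste, character(1), collapse = " ")
      ),
      lexicon = lex,
      stoplist = spec$stoplist,
      topic = topic,
      topic_names = names(spec$topics),
      true_score = true_score,
      true_polarity = polarity_of(true_score)
    )
  })
}

#' Generate a synthetic satisfaction-survey table
#'
#' Multinomial draws over the three response levels.
#'
#' @param n Number of respondents.
#' @param probs Length-3 probability vector for (satisfied, generally
#'   satisfied, dissatisfied); must sum to 1.
#' @param seed Integer seed.
#' @return Tibble: `record_id`, `satisfaction` (factor with the three
#'   levels).
#' @export
make_satisfaction_records <- function(n, probs = c(0.3, 0.5, 0.2), seed = 1L) {
  if (length(probs) != 3 || any(probs < 0) || abs(sum(probs) - 1) > 1e-8) {
    abort_config("probs must be 3 non-negative values summing to 1")
  }
  with_local_seed(seed + 307L, {
    lev <- c("satisfied", "generally_satisfied", "dissatisfied")
    tibble(
      record_id = sprintf("s%05d", seq_len(n)),
      satisfaction = factor(sample(lev, n, replace = TRUE, prob = probs), levels = lev)
    )
  })
}

#' Tally a satisfaction table into level counts
#' @param records Tibble from [make_satisfaction_records()] (or any tibble
#'   with a `satisfaction` column).
#' @return Named list: `satisfied`, `generally_satisfied`, `dissatisfied`.
#' @export
satisfaction_counts <- function(records) {
  lev <- c("satisfied", "generally_satisfied", "dissatisfied")
  as.list(stats::setNames(
    vapply(lev, function(l) sum(records$satisfaction == l), integer(1)), lev
  ))
}
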