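#' Per-cluster keyword extraction
#'
#' Ranks keywords for each cluster by salience = (term frequency within the
#' cluster) x (IDF of the term over the whole corpus, smoothed log form as in
#' [tfidf()]). The corpus-wide IDF damps boilerplate terms that occur in
#' every cluster. Ties are broken lexicographically. Noise documents (label
#' -1) are excluded from summaries; their count is reported via the
#' `"noise_size"` attribute.
#'
#' @param docs List of token vectors, or a tibble with a `tokens`
#'   list-column.
#' @param labels Integer cluster labels aligned with `docs` (noise `-1`).
#' @param top_n Keywords to keep per cluster (default 5).
#' @return Tibble: `cluster`, `rank`, `term`, `salience`, `size` (cluster
#'   member count). Empty (with a warning) when every document is noise.
#' @export
cluster_keywords <- function(docs, labels, top_n = 5L) {
  if (is.data.frame(docs)) docs <- docs$tokens
  if (length(docs) != length(labels)) {
    abort_input("labels must align one-to-one with docs")
  }
  if (top_n < 1) abort_config("top_n must be >= 1")
  empty <- tibble(
    cluster = integer(0), rank = integer(0), term = character(0),
    salience = double(0), size = integer(0)
  )
  clusters <- sort(unique(labels[labels >= 0]))
  if (length(clusters) == 0) {
    warning("all documents are noise; no cluster keywords to report")
    attr(empty, "noise_size") <- sum(labels == -1L)
    return(empty)
  }
  # corpus-wide idf (noise docs included: they are part of the corpus)
  n_docs <- length(docs)
  df <- table(unlist(lapply(docs, unique), use.names = FALSE))
  idf <- log((1 + n_docs) / (1 + as.numeric(df))) + 1
  names(idf) <- names(df)
  out <- purrr::map(clusters, function(cl) {
    member_docs <- docs[labels == cl]
    tf <- table(unlist(member_docs, use.names = FALSE))
    if (length(tf) == 0) {
      return(empty)
    }
    sal <- as.numeric(tf) * idf[names(tf)]
    ord <- order(-sal, names(tf), method = "radix")
    keep <- head(ord, top_n)
    tibble(
      cluster = cl,
      rank = seq_along(keep),
      term = names(tf)[keep],
      salience = unname(sal[keep]),
      size = length(member_docs)
    )
  })
  out <- dplyr::bind_rows(out)
  attr(out, "noise_size") <- sum(labels == -1L)
  out
}

#' Period-level negative-sentiment report
#'
#' Aggregates a scored, clustered corpus into the per-period deliverable:
#' the negative score (an aggregate — mean by default — over the sentiment
#' scores of negative-polarity documents; a larger magnitude means deeper
#' negative emotion), polarity counts, and the per-cluster keyword
#' summaries. When no document is negative the negative score is reported as
#' absent (`NA`) and the report is still produced.
#'
#' @param results Tibble from [score_corpus()] (`record_id`, `score`,
#'   `polarity`).
#' @param labels Cluster labels aligned with `results` (may be `NULL`).
#' @param summaries Keyword tibble from [cluster_keywords()] (may be `NULL`).
#' @param period Period label, e.g. `"2023"`.
#' @param aggregate `"mean"` (default), `"sum"` or `"min"` over the
#'   negative-document scores.
#' @return A list of class `"period_report"`: `period`, `negative_score`,
#'   `aggregate`, `polarity_counts` (tibble), `keywords` (tibble or `NULL`).
#' @export
negative_report <- function(results, labels = NULL, summaries = NULL,
                            period = "all", aggregate = c("mean", "sum", "min")) {
  aggregate <- match.arg(aggregate)
  if (!is.null(labels) && length(labels) != nrow(results)) {
    abort_input("labels must align one-to-one with results")
  }
  neg <- results$score[results$polarity == "negative"]
  negative_score <- if (length(neg) == 0) {
    NA_real_
  } else {
    switch(aggregate, mean = mean(neg), sum = sum(neg), min = min(neg))
  }
  structure(
    list(
      period = period,
      negative_score = negative_score,
      aggregate = aggregate,
      polarity_counts = polarity_distribution(results),
      keywords = summaries
    ),
    class = "period_report"
  )
}

#' @export
print.period_report <- function(x, ...) {
  cat("Complaint report — period ", x$period, "\n", sep = "")
  if (is.na(x$negative_score)) {
    cat("  negative score: none (no negative documents)\n")
  } else {
    cat("  negative score (", x$aggregate, " over negative docs): ",
      signif(x$negative_score, 5), "\n",
      sep = ""
    )
  }
  pc <- x$polarity_counts
  cat("  polarity counts: ", paste0(pc$polarity, "=", pc$n, collapse = ", "), "\n", sep = "")
  if (!is.null(x$keywords) && nrow(x$keywords) > 0) {
    for (cl in unique(x$keywords$cluster)) {
      kw <- x$keywords[x$keywords$cluster == cl, ]
      cat("  cluster ", cl, " (n=", kw$size[1], "): ",
        paste(kw$term, collapse = ", "), "\n",
        sep = ""
      )
    }
  }
  invisible(x)
}

#' Flatten a period report to a tibble
#' @param x A `"period_report"`.
#' @param ... Unused.
#' @return One-row tibble: `period`, `negative_score`, `aggregate`, and
#'   polarity counts as columns.
#' @export
tidy.period_report <- function(x, ...) {
  pc <- x$polarity_counts
  tibble(
    period = x$period,
    negative_score = x$negative_score,
    aggregate = x$aggregate,
    n_positive = pc$n[pc$polarity == "positive"],
    n_negative = pc$n[pc$polarity == "negative"],
    n_neutral = pc$n[pc$polarity == "neutral"]
  )
}
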