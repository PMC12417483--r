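#' Term-weight a tokenized corpus into a document-term matrix
#'
#' Builds a dense docs-by-terms matrix with TF-IDF weights (the default),
#' raw term frequencies, or binary presence. The IDF uses the smoothed
#' logarithmic form `idf(t) = ln((1 + n_docs) / (1 + df(t))) + 1`, so that a
#' term present in every document still carries weight 1 and no term divides
#' by zero. The vocabulary is ordered bytewise-lexicographically for
#' determinism across platforms.
#'
#' @param corpus List of character token vectors, or a tibble with a `tokens`
#'   list-column (and optionally `record_id` for row names).
#' @param weighting One of `"tfidf"`, `"tf"`, `"binary"`.
#' @return A numeric matrix (docs x terms) with `rownames` = document ids and
#'   `colnames` = vocabulary; attribute `"idf"` holds the per-term IDF vector.
#' @examples
#' tfidf(list(c("poor", "service"), c("long", "wait", "wait")))
#' @export
tfidf <- function(corpus, weighting = c("tfidf", "tf", "binary")) {
  weighting <- match.arg(weighting)
  if (is.data.frame(corpus)) {
    ids <- if ("record_id" %in% names(corpus)) as.character(corpus$record_id) else NULL
    corpus_list <- corpus$tokens
  } else {
    ids <- names(corpus)
    corpus_list <- corpus
  }
  n_docs <- length(corpus_list)
  if (n_docs == 0 || all(lengths(corpus_list) == 0)) {
    abort_input("tfidf needs at least one non-empty document")
  }
  vocab <- sort(unique(unlist(corpus_list, use.names = FALSE)), method = "radix")
  tf <- matrix(0, nrow = n_docs, ncol = length(vocab),
               dimnames = list(ids %||% as.character(seq_len(n_docs)), vocab))
  for (d in seq_len(n_docs)) {
    toks <- corpus_list[[d]]
    if (length(toks) == 0) next
    tab <- table(factor(toks, levels = vocab))
    tf[d, ] <- as.numeric(tab)
  }
  df <- colSums(tf > 0)
  idf <- log((1 + n_docs) / (1 + df)) + 1
  w <- switch(weighting,
    tfidf = sweep(tf, 2, idf, `*`),
    tf = tf,
    binary = (tf > 0) * 1
  )
  attr(w, "idf") <- idf
  w
}

#' Standardize matrix columns to zero mean and unit variance
#'
#' Column-wise centering and scaling with the population variance (divide by
#' `n`), so a two-point column becomes exactly (-1, +1). Constant columns,
#' which carry no clustering information, map to all-zero rather than
#' NaN.
#'
#' @param m Numeric matrix with at least 2 rows.
#' @return Matrix of the same shape.
#' @export
standardize <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 2) abort_input("standardize needs at least 2 rows")
  mu <- colMeans(m)
  centered <- sweep(m, 2, mu)
  sd_pop <- sqrt(colMeans(centered^2))
  const <- sd_pop == 0
  sd_pop[const] <- 1
  out <- sweep(centered, 2, sd_pop, `/`)
  out[, const] <- 0
  out
}

#' Reduce a matrix to its leading principal components
#'
#' PCA on the (centered) input; components are ordered by decreasing
#' explained variance. `target` is either an integer component count or a
#' retained-variance fraction in (0, 1], in which case the smallest component
#' count reaching that fraction is used. For determinism across linear-algebra
#' backends each component's largest-magnitude loading is made positive.
#'
#' @param m Numeric matrix (docs x features).
#' @param target Component count (integer >= 1) or variance fraction
#'   (0 < f <= 1). A value of exactly `1` is read as one component; use
#'   `1.0` with `fraction = TRUE` to keep all variance.
#' @param fraction Force `target` to be interpreted as a variance fraction.
#' @return Matrix of component scores with attributes
#'   `"explained_variance_ratio"` (for the kept components) and `"rotation"`.
#' @export
pca_reduce <- function(m, target, fraction = FALSE) {
  m <- as.matrix(m)
  p <- prcomp(m, center = TRUE, scale. = FALSE)
  var_ratio <- p$sdev^2 / sum(p$sdev^2)
  max_comps <- min(nrow(m), ncol(m))
  if (fraction || (target > 0 && target < 1)) {
    if (target <= 0 || target > 1) {
      abort_config("variance-fraction target must be in (0, 1]")
    }
    k <- which(cumsum(var_ratio) >= target - 1e-12)[1]
    if (is.na(k)) k <- length(var_ratio)
  } else {
    k <- as.integer(target)
    if (k < 1 || k > max_comps) {
      abort_config(paste0(
        "component count must be between 1 and ", max_comps, ", got ", target
      ))
    }
    k <- min(k, ncol(p$rotation))
  }
  rot <- p$rotation[, seq_len(k), drop = FALSE]
  scores <- p$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i_max <- which.max(abs(rot[, j]))
    if (rot[i_max, j] < 0) {
      rot[, j] <- -rot[, j]
      scores[, j] <- -scores[, j]
    }
  }
  rownames(scores) <- rownames(m)
  attr(scores, "explained_variance_ratio") <- var_ratio[seq_len(k)]
  attr(scores, "rotation") <- rot
  scores
}

#' Default corpus-to-matrix pipeline for clustering
#'
#' TF-IDF, then column standardization, then PCA to
#' `min(50, n_docs - 1)` components when the vocabulary exceeds 100 terms
#' (high-dimensional corpora benefit from noise reduction; small toy corpora
#' are left in full dimension).
#'
#' @param records Tibble with a `tokens` list-column.
#' @param weighting Passed to [tfidf()].
#' @param pca_vocab_threshold Vocabulary size above which PCA is applied.
#' @return Numeric matrix ready for [kann_dbscan()].
#' @export
vectorize_corpus <- function(records, weighting = "tfidf", pca_vocab_threshold = 100L) {
  m <- tfidf(records, weighting = weighting)
  z <- standardize(m)
  if (ncol(z) > pca_vocab_threshold) {
    z <- pca_reduce(z, min(50L, nrow(z) - 1L))
  }
  z
}
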