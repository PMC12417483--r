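test_that("blank-content rows are excluded and counted; order preserved", {
  path <- write_complaints_csv(c(
    "1,2024-01-02,internal,long wait at desk",
    "2,2024-01-03,internal,",
    "3,2024-01-04,external,rude answer",
    "4,2024-01-05,internal,   ",
    "5,2024-01-06,external,no explanation given"
  ))
  recs <- read_complaints(path)
  expect_equal(recs$record_id, c("1", "3", "5"))
  cl <- cleaning_summary(recs)
  expect_equal(cl$rows_read, 5)
  expect_equal(cl$rows_dropped, 2)
  # conservation: rows read = records returned + records dropped
  expect_equal(cl$rows_read, nrow(recs) + cl$rows_dropped)
})

test_that("unparseable dates are sentineled, never dropped", {
  path <- write_complaints_csv(c(
    "1,2024-13-45,internal,impossible month",
    "2,2024/02/03,internal,slash format ok",
    "3,not-a-date,internal,free text date",
    "4,2024-02-29,internal,leap day ok"
  ))
  recs <- read_complaints(path)
  expect_equal(nrow(recs), 4)
  expect_equal(recs$date, c("—", "2024-02-03", "—", "2024-02-29"))
  expect_equal(cleaning_summary(recs)$dates_sentineled, 2)
})

test_that("header-only table gives an empty result with zero drops", {
  path <- write_complaints_csv(character(0))
  recs <- read_complaints(path)
  expect_equal(nrow(recs), 0)
  expect_equal(cleaning_summary(recs)$rows_dropped, 0)
})

test_that("missing required columns raise a configuration error naming them", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,content", "1,hello"), path)
  expect_error(read_complaints(path), "text", class = "complaintlens_config_error")
  expect_error(
    read_complaints(path, id_col = "case"), "case",
    class = "complaintlens_config_error"
  )
})

test_that("non-UTF-8 bytes raise an input error with a byte offset", {
  path <- withr::local_tempfile(fileext = ".csv")
  con <- file(path, "wb")
  writeBin(c(charToRaw("id,text\n1,ok"), as.raw(0xff), charToRaw("x\n")), con)
  close(con)
  expect_error(read_complaints(path), "offset", class = "complaintlens_input_error")
})

test_that("cleaning conservation holds on random tables", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(1:12, 1)
    text <- ifelse(runif(n) < 0.3, "", paste0("complaint ", seq_len(n)))
    path <- write_complaints_csv(sprintf("%d,2024-01-01,internal,%s", seq_len(n), text))
    recs <- read_complaints(path)
    cl <- cleaning_summary(recs)
    expect_equal(cl$rows_read, nrow(recs) + cl$rows_dropped)
  }
})

test_that("mechanical compression collapses adjacent repeats to a fixed point", {
  expect_equal(mechanical_compress(strrep("好", 4), max_unit = 1), "好")
  expect_equal(mechanical_compress("abcabcabc", max_unit = 3), "abc")
  expect_equal(mechanical_compress("abcd"), "abcd")
  expect_equal(mechanical_compress(""), "")
  # nested repeats: run of units itself collapses
  expect_equal(mechanical_compress("aabaab"), "ab")
  expect_error(mechanical_compress("x", max_unit = 0), class = "complaintlens_config_error")
})

test_that("mechanical compression is idempotent and never lengthens (500 random cases)", {
  set.seed(17)
  for (i in 1:500) {
    x <- paste(sample(c("a", "b", "c"), sample(0:15, 1), replace = TRUE), collapse = "")
    y <- mechanical_compress(x)
    expect_identical(mechanical_compress(y), y)
    expect_lte(nchar(y), nchar(x))
  }
})

test_that("tokenizers split deterministically and cover the content", {
  expect_equal(tokenize("poor attitude here"), c("poor", "attitude", "here"))
  expect_equal(tokenize(""), character(0))
  expect_equal(tokenize("  spaced   out  "), c("spaced", "out"))
  # concatenating whitespace tokens reproduces the non-separator content
  x <- "long wait\tat the desk"
  expect_equal(paste(tokenize(x), collapse = ""), gsub("\\s", "", x))
})

test_that("the CJK character segmenter is stable across calls (frozen snapshot)", {
  sent <- "态度差 service 很不满意123"
  first <- tokenize(sent, segmenter = "character")
  # frozen from the adapter's recorded output
  expect_equal(first, c(
    "态", "度", "差", "service",
    "很", "不", "满", "意", "123"
  ))
  expect_identical(tokenize(sent, segmenter = "character"), first)
})

test_that("unknown segmenter ids raise a configuration error listing options", {
  expect_error(
    tokenize("x", segmenter = "jieba"), "whitespace",
    class = "complaintlens_config_error"
  )
})

test_that("stop-word removal is exact, order-preserving and idempotent", {
  expect_equal(
    remove_stopwords(c("the", "poor", "the", "service"), "the"),
    c("poor", "service")
  )
  expect_equal(remove_stopwords(c("a", "b"), c("a", "b")), character(0))
  expect_equal(remove_stopwords(c("x", "y"), character(0)), c("x", "y"))
  set.seed(5)
  for (i in 1:50) {
    toks <- random_tokens(sample(0:20, 1))
    s1 <- sample(c("aa", "bb"), 1)
    s2 <- sample(c("cc", "dd"), 1)
    once <- remove_stopwords(toks, c(s1, s2))
    expect_identical(remove_stopwords(once, c(s1, s2)), once)
    # sequential removal commutes with removal under the stoplist union
    expect_identical(remove_stopwords(remove_stopwords(toks, s1), s2), once)
  }
})

test_that("stop-list files support comments and NFC-deduplication", {
  path <- withr::local_tempfile()
  writeLines(c("# boilerplate", "the", "of  ", "", "the", "ward # inline"), path)
  expect_equal(read_stoplist(path), c("the", "of", "ward"))
})

test_that("preprocess_corpus chains compression, tokenization and stop-words", {
  recs <- tibble::tibble(
    record_id = "r1",
    raw_text = paste0(strrep("the ", 3), "waitwaitwait was awful")
  )
  out <- preprocess_corpus(recs, stoplist = "the", max_unit = 5)
  expect_equal(out$tokens[[1]], c("wait", "was", "awful"))
})
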