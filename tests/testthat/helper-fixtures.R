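# fixtures are built in code at test time; nothing is stored on disk

write_complaints_csv <- function(rows, path = withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())) {
  writeLines(c("id,date,channel,text", rows), path)
  path
}

write_lexicon_tsv <- function(lines, path = withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())) {
  writeLines(lines, path)
  path
}

toy_lexicon <- function() {
  as_lexicon(data.frame(
    word = c("good", "bad", "poor", "great", "awful"),
    score = c(2, -3, -2, 3, -4)
  ))
}

# two labelings describe the same partition iff their co-membership
# relations coincide (label names irrelevant)
same_partition <- function(a, b) {
  length(a) == length(b) &&
    identical(outer(a, a, `==`), outer(b, b, `==`))
}

random_tokens <- function(n, alphabet = c("aa", "bb", "cc", "dd", "ee", "zz")) {
  sample(alphabet, n, replace = TRUE)
}
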